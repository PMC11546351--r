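## Molecular-level interpretability: marginalize bilinear attention mass
## back onto drug atoms and protein residues.

#' Interaction maps of a fitted model for one drug--target pair
#'
#' Runs an eval-mode forward pass capturing, per bilinear attention head,
#' the interaction matrix I (atoms x protein substructures) and, when
#' attention pooling is active, the cell weight matrix W.
#'
#' @param model fitted \code{nfsa_dti}
#' @param smiles drug SMILES
#' @param sequence protein sequence
#' @return list with \code{I_heads}, \code{W_heads}, \code{graph},
#'   \code{encoded}, \code{probability}
#' @export
attention_maps <- function(model, smiles, sequence) {
  cfg <- model$config
  graph <- smiles_to_graph(smiles, max_nodes = cfg$max_nodes)
  enc <- encode_protein(sequence, max_len = cfg$max_len)
  out <- forward_sample(model$net, enc, graph, train = FALSE, capture = TRUE)
  list(I_heads = out$I_heads, W_heads = out$W_heads, graph = graph,
       encoded = enc, probability = out$p$v[1L])
}

.clip_marginal <- function(I_heads, axis, signed = FALSE) {
  acc <- NULL
  for (I in I_heads) {
    M <- if (signed) I else pmax(I, 0)
    m <- if (axis == 1L) rowSums(M) else colSums(M)
    acc <- if (is.null(acc)) m else acc + m
  }
  acc
}

#' Per-atom attribution scores from interaction maps
#'
#' Sums (non-negative) interaction intensities over heads and protein
#' substructures for each real atom and normalizes to a probability simplex.
#' An all-zero map yields uniform scores with a warning.
#'
#' @param I_heads list of interaction matrices (or a single matrix)
#' @param graph the \code{molecular_graph} the maps were computed on
#' @param signed keep negative intensities instead of clipping at zero
#' @return object of class \code{atom_attribution}: \code{scores} (sums to 1
#'   over real atoms), \code{smiles}, \code{n_atoms}
#' @export
atom_scores <- function(I_heads, graph, signed = FALSE) {
  if (is.matrix(I_heads)) I_heads <- list(I_heads)
  raw <- .clip_marginal(I_heads, 1L, signed)
  if (length(raw) != graph$n_real_atoms)
    stop("atom_scores: map rows do not match the graph's real atoms")
  if (all(raw == 0)) {
    warning("atom_scores: all-zero interaction map; returning uniform scores")
    raw <- rep(1, length(raw))
  }
  structure(list(scores = raw / sum(raw), smiles = graph$smiles,
                 n_atoms = graph$n_real_atoms),
            class = "atom_attribution")
}

#' Per-residue attribution scores from interaction maps
#'
#' Sums (non-negative) intensities over heads and atoms for each protein
#' substructure index j, spreads each substructure's mass uniformly over its
#' receptive field (residues j .. j + rf - 1, rf = sum(kernels - 1) + 1,
#' i.e. 16 for kernels 3/6/9), clips to the real sequence, and normalizes.
#'
#' @inheritParams atom_scores
#' @param encoded the \code{encoded_protein} the maps were computed on
#' @param kernel_sizes convolution kernels of the model (receptive field)
#' @return object of class \code{residue_attribution}: \code{scores} (sums
#'   to 1 over real residues), \code{n_residues}, \code{receptive_field}
#' @export
residue_scores <- function(I_heads, encoded, kernel_sizes = c(3L, 6L, 9L),
                           signed = FALSE) {
  if (is.matrix(I_heads)) I_heads <- list(I_heads)
  sub <- .clip_marginal(I_heads, 2L, signed)
  n_res <- sum(encoded$mask)
  rf <- receptive_field(kernel_sizes)
  if (length(sub) != n_res - rf + 1L)
    stop("residue_scores: map columns do not match the protein's substructures")
  if (all(sub == 0)) {
    warning("residue_scores: all-zero interaction map; returning uniform scores")
    sub <- rep(1, length(sub))
  }
  scores <- numeric(n_res)
  for (j in seq_along(sub)) {
    span <- j:min(j + rf - 1L, n_res)
    scores[span] <- scores[span] + sub[j] / rf
  }
  structure(list(scores = scores / sum(scores), n_residues = n_res,
                 receptive_field = rf),
            class = "residue_attribution")
}

#' Explain a prediction at the atom and residue level
#'
#' Convenience wrapper: forward pass with map capture, then atom and residue
#' attributions.
#'
#' @inheritParams attention_maps
#' @param source \code{"interaction"} marginalizes the raw interaction map
#'   I; \code{"pooling"} marginalizes the attention-pooling weights W
#' @param signed keep negative intensities (interaction source only)
#' @return list of class \code{dti_explanation}: \code{atoms},
#'   \code{residues}, \code{probability}, \code{maps}
#' @export
explain <- function(model, smiles, sequence,
                    source = c("interaction", "pooling"), signed = FALSE) {
  source <- match.arg(source)
  maps <- attention_maps(model, smiles, sequence)
  hs <- if (source == "interaction") maps$I_heads else {
    if (!length(maps$W_heads))
      stop("explain: pooling weights unavailable (sum-pooling model); use source = 'interaction'")
    maps$W_heads
  }
  structure(list(atoms = atom_scores(hs, maps$graph, signed = signed),
                 residues = residue_scores(hs, maps$encoded,
                                           model$config$kernel_sizes,
                                           signed = signed),
                 probability = maps$probability,
                 maps = maps),
            class = "dti_explanation")
}

#' Export an explanation to JSON
#'
#' Writes SMILES, per-atom scores (in SMILES atom order), sequence length,
#' and per-residue scores. \code{\link{read_explanation}} round-trips the
#' file.
#'
#' @param explanation a \code{dti_explanation} (or list with \code{atoms}
#'   and \code{residues})
#' @param path output file
#' @return \code{path}, invisibly
#' @export
export_explanation <- function(explanation, path) {
  obj <- list(smiles = explanation$atoms$smiles,
              atom_scores = explanation$atoms$scores,
              n_atoms = explanation$atoms$n_atoms,
              residue_scores = explanation$residues$scores,
              n_residues = explanation$residues$n_residues,
              receptive_field = explanation$residues$receptive_field,
              probability = explanation$probability)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_explanation
#' @export
read_explanation <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Planted-binding-site recovery on synthetic data
#'
#' For each sample whose drug carries the planted motif, computes the
#' fraction of atom-attribution mass falling on the motif atoms and compares
#' it to the uniform baseline (motif size / atom count). Significance of the
#' mean enrichment is assessed by a one-sided permutation test that shuffles
#' each molecule's atom scores.
#'
#' @param model fitted \code{nfsa_dti}
#' @param data data.frame of samples (e.g. a test partition)
#' @param truth matching \code{truth} entries from
#'   \code{\link{generate_dti_dataset}} (subset to the same rows)
#' @param n_perm permutations (default 200)
#' @param seed RNG seed for the permutations
#' @return list: \code{mean_ratio} (observed mass over uniform baseline),
#'   \code{p_value}, \code{n_used}, \code{per_sample} data.frame
#' @export
motif_recovery <- function(model, data, truth, n_perm = 200L, seed = 1L) {
  use <- which(truth$has_drug_motif &
                 vapply(truth$drug_motif_atoms, length, 1L) > 0L)
  if (!length(use)) stop("motif_recovery: no samples with a planted drug motif")
  obs <- numeric(length(use)); base <- numeric(length(use))
  score_list <- vector("list", length(use)); motif_list <- vector("list", length(use))
  for (k in seq_along(use)) {
    i <- use[k]
    maps <- attention_maps(model, data$smiles[i], data$sequence[i])
    at <- suppressWarnings(atom_scores(maps$I_heads, maps$graph))
    m <- truth$drug_motif_atoms[[i]]
    obs[k] <- sum(at$scores[m])
    base[k] <- length(m) / at$n_atoms
    score_list[[k]] <- at$scores
    motif_list[[k]] <- m
  }
  obs_mean <- mean(obs)
  perm_ge <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_perm), function(b) {
      mean(vapply(seq_along(score_list), function(k) {
        s <- sample(score_list[[k]])
        sum(s[seq_along(motif_list[[k]])])
      }, numeric(1L))) >= obs_mean
    }, logical(1L)))
  })
  list(mean_ratio = obs_mean / mean(base),
       p_value = (1 + perm_ge) / (1 + n_perm),
       n_used = length(use),
       per_sample = data.frame(mass = obs, baseline = base,
                               ratio = obs / base))
}
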