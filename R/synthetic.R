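## Synthetic DTI benchmark with a planted, recoverable interaction rule:
## a pair interacts (pre-noise) iff the drug carries a marker substructure
## AND the protein carries a marker motif. Negatives are stratified over the
## three non-interacting marker combinations so that neither encoder alone
## can solve the task.

#' Specification of a synthetic DTI benchmark
#'
#' @param n_samples number of drug--target pairs
#' @param p2n_ratio positive:negative ratio (1 = balanced; 0.725 mimics an
#'   unbalanced public benchmark)
#' @param drug_motif SMILES fragment planted in interacting drugs (default
#'   carboxylate \code{"C(=O)O"}; the generator grafts it as a branch)
#' @param protein_motif residue motif planted in interacting targets
#' @param label_noise probability of independently flipping each label
#'   (must be < 0.5)
#' @param seq_len_range protein length range (residues)
#' @param mol_size_range heavy-atom count range of generated molecules
#' @param seed integer seed; generation is bit-reproducible given the spec
#' @return object of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(n_samples = 500L, p2n_ratio = 1,
                           drug_motif = "C(=O)O", protein_motif = "HKLM",
                           label_noise = 0, seq_len_range = c(50L, 100L),
                           mol_size_range = c(8L, 24L), seed = 1L) {
  if (label_noise < 0 || label_noise >= 0.5)
    stop("synthetic_spec: 'label_noise' must be in [0, 0.5)")
  if (p2n_ratio <= 0) stop("synthetic_spec: 'p2n_ratio' must be positive")
  if (nchar(protein_motif) > seq_len_range[1L])
    stop("synthetic_spec: protein motif longer than the minimum sequence length")
  if (mol_size_range[1L] < 5L)
    stop("synthetic_spec: molecules must have at least 5 heavy atoms")
  structure(list(n_samples = as.integer(n_samples), p2n_ratio = p2n_ratio,
                 drug_motif = drug_motif, protein_motif = protein_motif,
                 label_noise = label_noise,
                 seq_len_range = as.integer(seq_len_range),
                 mol_size_range = as.integer(mol_size_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## number of heavy atoms in a linear/branch SMILES fragment (no brackets)
.count_atoms <- function(frag) {
  sum(strsplit(frag, "")[[1L]] %in% c("C", "N", "O", "S", "c", "n", "o", "s"))
}

#' Generate a random small molecule, optionally carrying the marker motif
#'
#' Molecules are alkyl/heteroatom chains with small branches and an optional
#' ring, drawn from a minimal grammar; when \code{include_motif} is
#' \code{TRUE} the motif fragment is grafted as a branch at a random carbon.
#' Uses the current RNG state.
#'
#' @param include_motif plant the motif?
#' @param size_range heavy-atom count range
#' @param motif SMILES fragment (branch-attachable)
#' @return list with \code{smiles} and \code{motif_atoms} (1-based atom
#'   indices of the motif in SMILES atom order; empty if not planted)
#' @export
generate_molecule <- function(include_motif, size_range = c(8L, 24L),
                              motif = "C(=O)O") {
  m_atoms <- .count_atoms(motif)
  for (try in 1:10) {
    target <- sample(size_range[1L]:size_range[2L], 1L)
    budget <- target - if (include_motif) m_atoms else 0L
    use_ring <- budget >= 9L && stats::runif(1) < 0.4
    ring_frag <- if (use_ring) sample(c("C1CCCCC1", "c1ccccc1"), 1L) else NULL
    ring_n <- if (use_ring) 6L else 0L
    nb <- budget - ring_n
    if (nb < 3L) { use_ring <- FALSE; ring_frag <- NULL; nb <- budget }
    n_branch <- if (nb >= 6L) stats::rbinom(1L, nb %/% 5L, 0.6) else 0L
    n_bb <- nb - n_branch

    symbols <- character(n_bb)
    symbols[1L] <- "C"
    for (i in seq_len(n_bb)[-1L]) {
      symbols[i] <- if (symbols[i - 1L] %in% c("N", "O")) "C"
                    else sample(c("C", "N", "O"), 1L, prob = c(0.78, 0.12, 0.10))
    }
    ## attachments keyed by backbone position (carbons only, one each)
    carbons <- which(symbols == "C")
    extras <- vector("list", n_bb)
    free <- carbons
    pick <- function() {
      if (!length(free)) return(NA_integer_)
      i <- if (length(free) == 1L) free else sample(free, 1L)
      free <<- setdiff(free, i)
      i
    }
    for (b in seq_len(n_branch)) {
      i <- pick(); if (is.na(i)) break
      extras[[i]] <- c(extras[[i]], "C")
    }
    if (use_ring) {
      i <- pick()
      if (is.na(i)) next
      extras[[i]] <- c(extras[[i]], ring_frag)
    }
    motif_slot <- NA_integer_
    if (include_motif) {
      motif_slot <- pick()
      if (is.na(motif_slot)) next
      extras[[motif_slot]] <- c(extras[[motif_slot]], motif)
    }

    smi <- ""
    atom_n <- 0L
    motif_atoms <- integer(0)
    for (i in seq_len(n_bb)) {
      smi <- paste0(smi, symbols[i])
      atom_n <- atom_n + 1L
      for (frag in extras[[i]]) {
        na <- .count_atoms(frag)
        if (include_motif && !is.na(motif_slot) && i == motif_slot &&
            identical(frag, motif))
          motif_atoms <- atom_n + seq_len(na)
        smi <- paste0(smi, "(", frag, ")")
        atom_n <- atom_n + na
      }
    }
    g <- tryCatch(smiles_to_graph(smi), error = function(e) NULL)
    if (!is.null(g) && g$n_real_atoms == atom_n)
      return(list(smiles = smi, motif_atoms = motif_atoms))
  }
  stop("generate_molecule: grammar failed after 10 attempts")
}

#' Generate a random protein sequence, optionally carrying the marker motif
#'
#' Residues are i.i.d. over the 20 standard amino acids; with
#' \code{include_motif} the motif overwrites a random window (and the draw is
#' rejected unless it occurs exactly once), otherwise draws containing the
#' motif are rejected. Uses the current RNG state.
#'
#' @param include_motif plant the motif?
#' @param len_range sequence length range
#' @param motif residue motif
#' @return list with \code{sequence} and \code{motif_pos} (1-based start
#'   position, or \code{NA})
#' @export
generate_protein <- function(include_motif, len_range = c(50L, 100L),
                             motif = "HKLM") {
  ml <- nchar(motif)
  repeat {
    n <- sample(len_range[1L]:len_range[2L], 1L)
    s <- paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
    if (include_motif) {
      pos <- sample(n - ml + 1L, 1L)
      substr(s, pos, pos + ml - 1L) <- motif
      hits <- gregexpr(motif, s, fixed = TRUE)[[1L]]
      if (length(hits) == 1L && hits[1L] == pos)
        return(list(sequence = s, motif_pos = pos))
    } else {
      if (!grepl(motif, s, fixed = TRUE))
        return(list(sequence = s, motif_pos = NA_integer_))
    }
  }
}

#' Generate a synthetic DTI dataset with planted ground truth
#'
#' Positive pairs carry both the drug substructure and the protein motif;
#' negatives are stratified across the three non-interacting combinations
#' (drug only, protein only, neither). Each label is then flipped
#' independently with probability \code{label_noise}. With zero noise the
#' labels are perfectly separable by the planted AND rule.
#'
#' @param spec a \code{\link{synthetic_spec}}
#' @return list of class \code{dti_synthetic}: \code{data} (data.frame
#'   \code{smiles}/\code{sequence}/\code{label}), \code{truth} (per-sample
#'   flags, motif positions, pre-noise labels, flip indicator), \code{spec}
#' @examples
#' syn <- generate_dti_dataset(synthetic_spec(n_samples = 20, seed = 7))
#' table(syn$data$label)
#' @export
generate_dti_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    n_pos <- round(n * spec$p2n_ratio / (1 + spec$p2n_ratio))
    n_neg <- n - n_pos
    ## stratify negatives over (drug motif, protein motif) in {TF, FT, FF}
    combo <- rep(c("TF", "FT", "FF"), length.out = n_neg)
    flags <- rbind(data.frame(drug = rep(TRUE, n_pos), prot = rep(TRUE, n_pos)),
                   data.frame(drug = combo == "TF", prot = combo == "FT"))
    ord <- sample.int(n)
    flags <- flags[ord, , drop = FALSE]
    smiles <- character(n); sequence <- character(n)
    motif_atoms <- vector("list", n); motif_pos <- integer(n)
    for (i in seq_len(n)) {
      mol <- generate_molecule(flags$drug[i], spec$mol_size_range,
                               spec$drug_motif)
      prt <- generate_protein(flags$prot[i], spec$seq_len_range,
                              spec$protein_motif)
      smiles[i] <- mol$smiles
      motif_atoms[[i]] <- mol$motif_atoms
      sequence[i] <- prt$sequence
      motif_pos[i] <- prt$motif_pos
    }
    pre_label <- as.integer(flags$drug & flags$prot)
    flipped <- stats::runif(n) < spec$label_noise
    label <- ifelse(flipped, 1L - pre_label, pre_label)
    structure(list(
      data = data.frame(smiles = smiles, sequence = sequence,
                        label = as.integer(label), stringsAsFactors = FALSE),
      truth = list(has_drug_motif = flags$drug,
                   has_protein_motif = flags$prot,
                   drug_motif_atoms = motif_atoms,
                   protein_motif_pos = motif_pos,
                   pre_noise_label = pre_label,
                   flipped = flipped),
      spec = spec), class = "dti_synthetic")
  })
}

#' Does a molecular graph contain a carboxylate-type substructure?
#'
#' Checks for a carbon bearing both a double-bonded and a single-bonded
#' oxygen -- the default planted drug marker. Used to verify planted
#' molecules independently of the generator's bookkeeping.
#'
#' @param graph a \code{molecular_graph}
#' @return logical
#' @export
has_carboxyl_group <- function(graph) {
  bonds <- graph$edges[graph$edge_features != "self", , drop = FALSE]
  types <- graph$edge_features[graph$edge_features != "self"]
  el <- graph$elements
  for (c_idx in which(el == "C")) {
    inc <- bonds[, 1L] == c_idx | bonds[, 2L] == c_idx
    nb <- ifelse(bonds[inc, 1L] == c_idx, bonds[inc, 2L], bonds[inc, 1L])
    bt <- types[inc]
    has_dbl_o <- any(el[nb] == "O" & bt == "double")
    has_sgl_o <- any(el[nb] == "O" & bt == "single")
    if (has_dbl_o && has_sgl_o) return(TRUE)
  }
  FALSE
}
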