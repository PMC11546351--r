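## Input featurization: DTI tables, protein sequence encoding, SMILES -> graph.

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
## 23-symbol amino-acid vocabulary: the 20 standard residues plus the
## ambiguity codes B and Z, with X as the catch-all for anything else.
AA_VOCAB <- c(AA_STANDARD, "B", "Z", "X")

ATOM_ELEMENTS <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I", "B")
BOND_TYPES <- c("single", "double", "triple", "aromatic", "self")

#' Amino-acid vocabulary used by the protein encoder
#'
#' Token ids are 1..23 in the order of the returned vector; 0 is reserved for
#' padding. Unknown characters map to \code{"X"}.
#'
#' @return character vector of 23 residue symbols
#' @export
aa_vocab <- function() AA_VOCAB

#' Encode a protein sequence as a fixed-length padded index vector
#'
#' Residues are mapped to integer ids over the 23-symbol vocabulary
#' (\code{\link{aa_vocab}}); sequences longer than \code{max_len} are truncated
#' keeping the N-terminal prefix, shorter ones are padded at the tail with id 0.
#'
#' @param sequence single-letter amino-acid string
#' @param max_len maximum sequence length (default 1200)
#' @return object of class \code{encoded_protein} with fields \code{indices}
#'   (integer, length \code{max_len}), \code{mask} (logical, \code{TRUE} = real
#'   residue) and \code{original_length}
#' @examples
#' p <- encode_protein("MKTAYIAKQR", max_len = 50)
#' sum(p$mask)
#' @export
encode_protein <- function(sequence, max_len = 1200L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("encode_protein: 'sequence' must be a non-empty string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  ids <- match(chars, AA_VOCAB)
  ids[is.na(ids)] <- match("X", AA_VOCAB)
  keep <- min(n, max_len)
  indices <- integer(max_len)
  indices[seq_len(keep)] <- ids[seq_len(keep)]
  mask <- logical(max_len)
  mask[seq_len(keep)] <- TRUE
  structure(list(indices = indices, mask = mask, original_length = n),
            class = "encoded_protein")
}

## MDL old-style atom charge codes -> formal charge
.mdl_charge <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L,
                 "5" = -1L, "6" = -2L, "7" = -3L)

## SMILES -> molfile (V2000) via OpenBabel, parsed from text. ChemmineR's
## SDF reader rejects bond-free molecules (e.g. methane), so the atom and
## bond blocks are read here directly.
.parse_mol <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L) stop("OpenBabel could not parse SMILES")
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || na < 1L) stop("no atoms parsed")
  atom_lines <- lines[4L + seq_len(na)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  code <- trimws(substr(atom_lines, 37L, 39L))
  charge <- unname(.mdl_charge[ifelse(code %in% names(.mdl_charge), code, "0")])
  bonds <- matrix(integer(0), 0L, 3L)
  if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    bonds <- cbind(as.integer(substr(bl, 1L, 3L)),
                   as.integer(substr(bl, 4L, 6L)),
                   as.integer(substr(bl, 7L, 9L)))
  }
  ## property-block charges override the atom-line codes
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1L]])
    k <- f[1L]
    for (t in seq_len(k)) charge[f[2L * t]] <- f[2L * t + 1L]
  }
  list(elements = elements, charge = charge, bonds = bonds,
       sdf_lines = lines)
}

## aromatic ring perception (ChemmineR); returns logical flag per atom and
## the set of ring bonds belonging to an aromatic ring
.aromatic_info <- function(mol) {
  n <- length(mol$elements)
  out <- list(atoms = logical(n), pairs = character(0))
  if (nrow(mol$bonds) < 3L) return(out)
  rr <- suppressWarnings(tryCatch({
    sdfset <- ChemmineR::read.SDFset(mol$sdf_lines)
    ChemmineR::rings(sdfset[[1L]], upper = 10L, type = "all", arom = TRUE)
  }, error = function(e) NULL))
  if (is.null(rr) || !length(rr$RINGS)) return(out)
  for (k in seq_along(rr$RINGS)) {
    if (!isTRUE(rr$AROMATIC[[k]])) next
    idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
    out$atoms[idx] <- TRUE
    m <- length(idx)
    for (t in seq_len(m)) {
      i <- idx[t]; j <- idx[if (t == m) 1L else t + 1L]
      out$pairs <- c(out$pairs, paste(min(i, j), max(i, j)))
    }
  }
  out
}

#' Convert a SMILES string to a masked, size-capped molecular graph
#'
#' Atoms become real nodes carrying a one-hot featurization (element over a
#' fixed common-element list plus "other", heavy-atom degree, formal charge,
#' aromaticity flag); bonds become undirected edges typed as
#' single/double/triple/aromatic, and every real node receives a self-loop
#' edge. Node capacity is fixed at \code{max_nodes}; positions beyond the real
#' atoms are virtual padding nodes (all-zero features, no edges), tracked by
#' \code{node_mask}. Molecules with more than \code{max_nodes} atoms are
#' rejected rather than truncated.
#'
#' @param smiles SMILES string
#' @param max_nodes node capacity of the padded graph (default 290)
#' @return object of class \code{molecular_graph}: \code{node_features}
#'   (n_real x n_feature matrix), \code{edges} (2-column matrix of undirected
#'   bonds plus self-loops), \code{edge_features} (character codes per edge),
#'   \code{node_mask} (logical, length \code{max_nodes}), \code{n_real_atoms},
#'   \code{elements}, \code{smiles}
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_real_atoms
#' @export
smiles_to_graph <- function(smiles, max_nodes = 290L) {
  mol <- tryCatch(.parse_mol(smiles),
                  error = function(e) stop("smiles_to_graph: cannot parse SMILES '",
                                           smiles, "': ", conditionMessage(e)))
  n <- length(mol$elements)
  if (n > max_nodes)
    stop("smiles_to_graph: molecule has ", n, " atoms, exceeding the ",
         max_nodes, "-node cap")

  arom <- .aromatic_info(mol)

  edges <- matrix(integer(0), 0L, 2L)
  etype <- character(0)
  degree <- integer(n)
  if (nrow(mol$bonds) > 0L) {
    a1 <- mol$bonds[, 1L]; a2 <- mol$bonds[, 2L]; ord <- mol$bonds[, 3L]
    key <- paste(pmin(a1, a2), pmax(a1, a2))
    etype <- ifelse(key %in% arom$pairs, "aromatic",
                    c("single", "double", "triple", "aromatic")[pmin(ord, 4L)])
    edges <- cbind(a1, a2)
    degree <- as.integer(table(factor(c(a1, a2), levels = seq_len(n))))
  }
  ## self-loop on every real node
  edges <- rbind(edges, cbind(seq_len(n), seq_len(n)))
  etype <- c(etype, rep("self", n))
  dimnames(edges) <- NULL

  node_features <- .atom_feature_matrix(mol$elements, degree, mol$charge,
                                        arom$atoms)
  node_mask <- c(rep(TRUE, n), rep(FALSE, max_nodes - n))

  structure(list(node_features = node_features,
                 edges = edges,
                 edge_features = etype,
                 node_mask = node_mask,
                 n_real_atoms = n,
                 elements = mol$elements,
                 smiles = smiles,
                 max_nodes = as.integer(max_nodes)),
            class = "molecular_graph")
}

## one-hot element (10 + other) / degree (0..5, capped) / formal charge
## (-2..+2, clipped) / aromatic flag  =>  11 + 6 + 5 + 1 = 23 columns
.atom_feature_matrix <- function(elements, degree, charge, aromatic) {
  n <- length(elements)
  el <- match(elements, ATOM_ELEMENTS)
  el[is.na(el)] <- length(ATOM_ELEMENTS) + 1L
  deg <- pmin(pmax(degree, 0L), 5L) + 1L
  chg <- pmin(pmax(charge, -2L), 2L) + 3L
  X <- matrix(0, n, length(ATOM_ELEMENTS) + 1L + 6L + 5L + 1L)
  off_deg <- length(ATOM_ELEMENTS) + 1L
  off_chg <- off_deg + 6L
  off_ar <- off_chg + 5L
  for (i in seq_len(n)) {
    X[i, el[i]] <- 1
    X[i, off_deg + deg[i]] <- 1
    X[i, off_chg + chg[i]] <- 1
    if (aromatic[i]) X[i, off_ar + 1L] <- 1
  }
  X
}

n_atom_features <- function() length(ATOM_ELEMENTS) + 1L + 6L + 5L + 1L
n_edge_features <- function() length(BOND_TYPES)

edge_feature_matrix <- function(etype) {
  E <- matrix(0, length(etype), length(BOND_TYPES))
  E[cbind(seq_along(etype), match(etype, BOND_TYPES))] <- 1
  E
}

#' Load a drug--target interaction table
#'
#' Reads a delimited text file with one drug--target pair per row. Rows whose
#' SMILES cannot be parsed into a molecule are dropped with a warning giving
#' the count.
#'
#' @param path file path; comma- or tab-delimited (sniffed from the header
#'   line unless \code{sep} is given)
#' @param col_smiles,col_protein,col_label column names (defaults "SMILES",
#'   "Protein", "Y")
#' @param sep field separator; \code{NULL} to auto-detect
#' @return data.frame with columns \code{smiles}, \code{sequence},
#'   \code{label} (integer 0/1)
#' @examples
#' tsv <- system.file("extdata", "example_dti.tsv", package = "nfsadti")
#' load_dti_table(tsv)
#' @export
load_dti_table <- function(path, col_smiles = "SMILES", col_protein = "Protein",
                           col_label = "Y", sep = NULL) {
  if (!file.exists(path)) stop("load_dti_table: file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("load_dti_table: empty table: ", path)
  for (cn in c(col_smiles, col_protein, col_label))
    if (!cn %in% names(df))
      stop("load_dti_table: missing column '", cn, "' (found: ",
           paste(names(df), collapse = ", "), ")")
  lab <- suppressWarnings(as.integer(as.character(df[[col_label]])))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("load_dti_table: labels must be 0/1")
  out <- data.frame(smiles = as.character(df[[col_smiles]]),
                    sequence = toupper(as.character(df[[col_protein]])),
                    label = lab, stringsAsFactors = FALSE)
  ok <- vapply(unique(out$smiles), function(s) {
    !inherits(tryCatch(.parse_mol(s), error = function(e) e), "error")
  }, logical(1L))
  bad <- names(ok)[!ok]
  if (length(bad)) {
    drop <- out$smiles %in% bad
    warning("load_dti_table: dropped ", sum(drop),
            " row(s) with unparseable SMILES")
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' Convenience reader returning plain single-letter strings named by record id.
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_fasta_sequences requires the Biostrings package")
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Randomly split a DTI table into train/validation/test sets
#'
#' Samples are permuted under the given seed and partitioned contiguously at
#' the requested ratios (default 0.7/0.1/0.2).
#'
#' @param data data.frame as returned by \code{\link{load_dti_table}} or
#'   \code{\link{generate_dti_dataset}}
#' @param ratios length-3 numeric summing to 1
#' @param seed integer seed making the split reproducible
#' @return object of class \code{dti_split}: list with \code{train},
#'   \code{validation}, \code{test} data.frames and \code{seed}
#' @export
split_dataset <- function(data, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("split_dataset: 'ratios' must be three numbers summing to 1")
  n <- nrow(data)
  if (n < 10L) stop("split_dataset: need at least 10 samples")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- round(ratios[1L] * n)
  n_val <- round(ratios[2L] * n)
  if (n_train + n_val >= n) n_val <- max(0L, n - n_train - 1L)
  idx_train <- perm[seq_len(n_train)]
  idx_val <- perm[n_train + seq_len(n_val)]
  idx_test <- perm[(n_train + n_val + 1L):n]
  structure(list(train = data[idx_train, , drop = FALSE],
                 validation = data[idx_val, , drop = FALSE],
                 test = data[idx_test, , drop = FALSE],
                 seed = as.integer(seed)),
            class = "dti_split")
}
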