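test_that("protein encoding pads, truncates, and is deterministic", {
  p <- encode_protein("MKTAYIAKQR", max_len = 1200)
  expect_length(p$indices, 1200)
  expect_true(all(p$indices[1:10] %in% 1:23))
  expect_true(all(p$indices[11:1200] == 0))
  expect_equal(sum(p$mask), 10)
  expect_identical(p$indices == 0, !p$mask)

  long <- paste(rep("ACDE", 375), collapse = "")  # 1500 residues
  pl <- encode_protein(long, max_len = 1200)
  expect_equal(pl$original_length, 1500)
  expect_equal(sum(pl$mask), 1200)
  ## truncation keeps the N-terminal prefix
  expect_equal(pl$indices[1:4], match(c("A", "C", "D", "E"), aa_vocab()))

  expect_identical(encode_protein("AAA"), encode_protein("AAA"))
  ## unknown symbols map to the catch-all X
  pu <- encode_protein("AU*A", max_len = 10)
  expect_equal(pu$indices[2:3], rep(match("X", aa_vocab()), 2))
  expect_error(encode_protein(""), "non-empty")
})

test_that("SMILES conversion builds masked self-looped graphs", {
  g <- smiles_to_graph("C")
  expect_equal(g$n_real_atoms, 1)
  expect_equal(nrow(g$edges), 1)          # just the self-loop
  expect_equal(g$edge_features, "self")
  expect_equal(sum(g$node_mask), 1)
  expect_length(g$node_mask, 290)

  g <- smiles_to_graph("CCO")
  expect_equal(g$n_real_atoms, 3)
  expect_equal(sum(g$edge_features != "self"), 2)
  expect_equal(sum(g$edge_features == "self"), 3)
  expect_equal(sum(g$node_mask), 3)

  ## cyclohexane: 6 atoms, 6 ring bonds, every atom bonded degree 2
  g <- smiles_to_graph("C1CCCCC1")
  expect_equal(g$n_real_atoms, 6)
  bonds <- g$edges[g$edge_features != "self", , drop = FALSE]
  expect_equal(nrow(bonds), 6)
  degree <- table(factor(c(bonds[, 1], bonds[, 2]), levels = 1:6))
  expect_true(all(degree == 2))
  ## every real node has a self-loop
  self <- g$edges[g$edge_features == "self", , drop = FALSE]
  expect_setequal(self[, 1], 1:6)

  expect_error(smiles_to_graph("not_a_molecule"), "cannot parse")
  expect_error(smiles_to_graph("CCCCCCCC", max_nodes = 5), "cap")
})

test_that("graphs are invariant to kekulization in atom count and degrees", {
  for (pair in list(c("c1ccccc1", "C1=CC=CC=C1"),
                    c("c1ccccc1C(=O)O", "C1=CC=CC=C1C(=O)O"))) {
    a <- smiles_to_graph(pair[1]); b <- smiles_to_graph(pair[2])
    expect_equal(a$n_real_atoms, b$n_real_atoms)
    deg <- function(g) {
      bb <- g$edges[g$edge_features != "self", , drop = FALSE]
      sort(as.integer(table(factor(c(bb[, 1], bb[, 2]),
                                   levels = seq_len(g$n_real_atoms)))))
    }
    expect_equal(deg(a), deg(b))
    expect_equal(a$node_features, b$node_features)
  }
})

test_that("DTI tables load with bad-SMILES rows dropped and labels coerced", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("SMILES\tProtein\tY",
               "CCO\tMKTAYIAK\t1",
               "CCN\tMKTAYIAK\t0",
               "CCC\tAAAAKKKK\t1"), tsv)
  d <- load_dti_table(tsv)
  expect_equal(nrow(d), 3)
  expect_identical(d$label, c(1L, 0L, 1L))  # string labels parsed to integers

  writeLines(c("SMILES\tProtein\tY",
               "CCO\tMKTAYIAK\t1",
               "not_a_molecule\tMKTAYIAK\t0",
               "CCC\tAAAAKKKK\t1"), tsv)
  expect_warning(d2 <- load_dti_table(tsv), "dropped 1")
  expect_equal(nrow(d2), 2)

  writeLines(c("smi\tProtein\tY", "CCO\tM\t1"), tsv)
  expect_error(load_dti_table(tsv), "missing column")
  unlink(tsv)
})

test_that("splitting is reproducible, disjoint, exhaustive, near-ratio", {
  mk <- function(n) data.frame(smiles = paste0("C", seq_len(n)),
                               sequence = paste0("M", seq_len(n)),
                               label = rep_len(0:1, n))
  d <- mk(100)
  s <- split_dataset(d, seed = 7)
  expect_equal(nrow(s$train), 70)
  expect_equal(nrow(s$validation), 10)
  expect_equal(nrow(s$test), 20)
  expect_identical(split_dataset(d, seed = 7), s)

  s10 <- split_dataset(mk(10), seed = 1)
  expect_equal(vapply(s10[1:3], nrow, 1L), c(train = 7L, validation = 1L, test = 2L))

  ## property: disjoint and exhaustive for assorted n and seeds
  for (n in c(11, 37, 101)) for (seed in c(1, 99)) {
    s <- split_dataset(mk(n), seed = seed)
    all_ids <- c(s$train$smiles, s$validation$smiles, s$test$smiles)
    expect_equal(sort(all_ids), sort(mk(n)$smiles))
    expect_equal(anyDuplicated(all_ids), 0)
  }
  expect_error(split_dataset(mk(20), ratios = c(0.5, 0.2, 0.2)), "summing to 1")
  expect_error(split_dataset(mk(5)), "at least 10")
})
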