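test_that("molecule generator plants (or withholds) the marker exactly", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      mol <- generate_molecule(TRUE)
      g <- smiles_to_graph(mol$smiles)
      expect_true(has_carboxyl_group(g))
      ## recorded motif atoms really are the C(=O)O atoms
      expect_length(mol$motif_atoms, 3)
      expect_equal(g$elements[mol$motif_atoms], c("C", "O", "O"))
      ## size range respected
      expect_true(g$n_real_atoms >= 8 && g$n_real_atoms <= 24)

      mol0 <- generate_molecule(FALSE)
      expect_false(has_carboxyl_group(smiles_to_graph(mol0$smiles)))
      expect_length(mol0$motif_atoms, 0)
    }
  })
  ## fixed seed -> identical molecule
  m1 <- withr::with_seed(5, generate_molecule(TRUE))
  m2 <- withr::with_seed(5, generate_molecule(TRUE))
  expect_identical(m1, m2)
})

test_that("protein generator plants the motif exactly once at the recorded site", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      p <- generate_protein(TRUE)
      hits <- gregexpr("HKLM", p$sequence, fixed = TRUE)[[1]]
      expect_length(hits, 1)
      expect_equal(hits[1], p$motif_pos)
      p0 <- generate_protein(FALSE)
      expect_false(grepl("HKLM", p0$sequence, fixed = TRUE))
    }
    lens <- replicate(200, nchar(generate_protein(FALSE, c(50, 100))$sequence))
    expect_true(all(lens >= 50 & lens <= 100))
  })
})

test_that("dataset generation follows the AND rule, ratio, and stratification", {
  syn <- generate_dti_dataset(synthetic_spec(n_samples = 100, p2n_ratio = 1,
                                             label_noise = 0, seed = 9))
  expect_equal(sum(syn$data$label), 50)
  both <- syn$truth$has_drug_motif & syn$truth$has_protein_motif
  expect_identical(syn$data$label, as.integer(both))
  ## negatives stratified over the three non-interacting combinations
  neg <- !both
  combos <- paste0(syn$truth$has_drug_motif[neg], syn$truth$has_protein_motif[neg])
  expect_true(max(table(combos)) - min(table(combos)) <= 1)
  ## reproducibility
  syn2 <- generate_dti_dataset(synthetic_spec(n_samples = 100, p2n_ratio = 1,
                                              label_noise = 0, seed = 9))
  expect_identical(syn$data, syn2$data)
})

test_that("unbalanced P2N ratios are matched within rounding", {
  syn <- generate_dti_dataset(synthetic_spec(n_samples = 200, p2n_ratio = 0.725,
                                             seed = 4))
  p2n <- sum(syn$data$label == 1) / sum(syn$data$label == 0)
  expect_lt(abs(p2n - 0.725), 0.02)
})

test_that("label noise flips the expected fraction", {
  syn <- generate_dti_dataset(synthetic_spec(n_samples = 600, label_noise = 0.1,
                                             seed = 8))
  flipped <- mean(syn$truth$flipped)
  ## binomial 3-sigma band around 0.1
  expect_lt(abs(flipped - 0.1), 3 * sqrt(0.1 * 0.9 / 600))
  expect_identical(syn$data$label,
                   ifelse(syn$truth$flipped, 1L - syn$truth$pre_noise_label,
                          syn$truth$pre_noise_label))
  ## with zero noise the planted rule classifies perfectly
  syn0 <- generate_dti_dataset(synthetic_spec(n_samples = 60, seed = 2))
  rule <- as.numeric(syn0$truth$has_drug_motif & syn0$truth$has_protein_motif)
  expect_equal(auroc(rule, syn0$data$label), 1.0)
})

test_that("generated SMILES survive the featurization round-trip", {
  syn <- generate_dti_dataset(synthetic_spec(n_samples = 30, seed = 3))
  for (smi in syn$data$smiles) {
    g <- smiles_to_graph(smi)
    expect_gt(g$n_real_atoms, 0)
    expect_true(all(g$edges <= g$n_real_atoms))
  }
})
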