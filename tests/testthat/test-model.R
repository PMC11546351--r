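## small shared fixtures for training-mechanics tests
tiny_cfg <- function(...) {
  dti_config_small(max_len = 60L, aa_embed_dim = 8L, n_filters = c(8L, 8L, 8L),
                   atom_embed_dim = 8L, hidden_dims = c(8L, 8L, 8L),
                   fingerprint_dim = 8L, bilinear_dim = 16L, att_pool_dim = 4L,
                   fc_hidden = 8L, batch_size = 8L, ...)
}

tiny_data <- function(n = 16, seed = 2) {
  syn <- generate_dti_dataset(synthetic_spec(n_samples = n, seq_len_range = c(30L, 50L),
                                             mol_size_range = c(6L, 12L), seed = seed))
  syn$data
}

test_that("zero decoder weights give probability exactly one half", {
  cfg <- tiny_cfg()
  net <- nfsadti:::new_net(cfg)
  net$par$W_fc2$v[] <- 0; net$par$b_fc2$v[] <- 0
  enc <- encode_protein(paste(rep("MKTAYIAKQR", 3), collapse = ""), max_len = 60)
  g <- smiles_to_graph("CCO")
  expect_equal(nfsadti:::forward_sample(net, enc, g)$p$v[1], 0.5)
})

test_that("predicted probabilities are strictly inside (0, 1)", {
  cfg <- tiny_cfg()
  net <- nfsadti:::new_net(cfg)
  d <- tiny_data(10)
  feats <- nfsadti:::prepare_features(d, cfg)
  p <- nfsadti:::.predict_net(net, d, feats)
  expect_true(all(p > 0 & p < 1))
})

test_that("autograd loss gradient matches finite differences end to end", {
  cfg <- tiny_cfg()
  net <- nfsadti:::new_net(cfg)
  d <- tiny_data(6)[1:2, ]
  feats <- nfsadti:::prepare_features(d, cfg)
  out <- nfsadti:::model_loss_grad(net, d, feats, lambda = 1e-3, train = TRUE)
  v0 <- nfsadti:::param_flatten(net$par)
  set.seed(3)
  idx <- sample(length(v0), 40)
  for (i in idx) {
    eps <- 1e-5
    v <- v0; v[i] <- v0[i] + eps
    nfsadti:::param_assign(net$par, v)
    up <- nfsadti:::model_loss_grad(net, d, feats, 1e-3, grad = FALSE, train = TRUE)$loss
    v[i] <- v0[i] - eps
    nfsadti:::param_assign(net$par, v)
    dn <- nfsadti:::model_loss_grad(net, d, feats, 1e-3, grad = FALSE, train = TRUE)$loss
    nfsadti:::param_assign(net$par, v0)
    fd <- (up - dn) / (2 * eps)
    expect_lt(abs(fd - out$grads[i]) / max(abs(fd), 1e-6), 1e-4)
  }
})

test_that("a zero learning rate leaves parameters unchanged", {
  d <- tiny_data(16)
  fit <- nfsa_dti(d, tiny_cfg(epochs = 1L, lr = 0), seed = 5)
  ref <- nfsadti:::new_net(fit$config)
  expect_equal(nfsadti:::param_flatten(fit$net$par),
               nfsadti:::param_flatten(ref$par), tolerance = 1e-12)
})

test_that("training is reproducible under the seed", {
  d <- tiny_data(16)
  f1 <- nfsa_dti(d, tiny_cfg(epochs = 2L), seed = 11)
  f2 <- nfsa_dti(d, tiny_cfg(epochs = 2L), seed = 11)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(nfsadti:::param_flatten(f1$net$par),
                   nfsadti:::param_flatten(f2$net$par))
})

test_that("eval-mode predictions are batching-invariant", {
  cfg <- tiny_cfg()
  net <- nfsadti:::new_net(cfg)
  d <- tiny_data(8)
  feats <- nfsadti:::prepare_features(d, cfg)
  p_all <- nfsadti:::.predict_net(net, d, feats)
  p_one <- nfsadti:::.predict_net(net, d[3, , drop = FALSE], feats)
  expect_equal(p_one, p_all[3], tolerance = 1e-12)
})

test_that("the fitted object supports the standard S3 verbs", {
  d <- tiny_data(24, seed = 6)
  fit <- nfsa_dti(d, tiny_cfg(epochs = 2L), seed = 7)
  expect_s3_class(fit, "nfsa_dti")
  expect_output(print(fit), "bilinear")
  p <- predict(fit, d)
  expect_length(p, nrow(d))
  expect_true(all(p > 0 & p < 1))
  cls <- predict(fit, d, type = "class")
  expect_true(all(cls %in% 0:1))
  r <- residuals(fit)
  expect_equal(length(r), nrow(fit$split$train))
  co <- coef(fit)
  expect_true(all(c("Ep", "W_fc1", "W_atom") %in% names(co)))
  sm <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sm), c(nrow(fit$split$train), 2))
  ev <- dti_evaluate(fit)
  expect_s3_class(ev, "dti_eval")
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  h <- fit$history
  expect_equal(nrow(h), 2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("ablation variants assemble and train without error", {
  d <- tiny_data(16, seed = 8)
  for (args in list(list(use_esacm = FALSE), list(use_fingerprint = FALSE),
                    list(att_pool = FALSE))) {
    cfg <- do.call(tiny_cfg, c(list(epochs = 1L), args))
    fit <- nfsa_dti(d, cfg, seed = 2)
    expect_true(is.finite(fit$history$train_loss[1]))
  }
})

test_that("training loss trends downward on a small planted dataset", {
  syn <- generate_dti_dataset(synthetic_spec(n_samples = 50, seq_len_range = c(30L, 50L),
                                             mol_size_range = c(6L, 12L), seed = 13))
  fit <- nfsa_dti(syn$data, tiny_cfg(epochs = 10L, lr = 3e-3), seed = 4)
  dl <- diff(fit$history$train_loss)
  expect_lte(sum(dl > 0), 2)  # monotone trend, at most two violations
  expect_lt(fit$history$train_loss[10], fit$history$train_loss[1])
})
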