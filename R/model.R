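## Model fitting: minibatch Adam on the L2-regularized cross-entropy,
## per-epoch validation, best-checkpoint selection, and the S3 interface.

## featurize every unique sequence/SMILES once; reused across epochs
prepare_features <- function(data, cfg) {
  seqs <- unique(data$sequence)
  enc <- lapply(seqs, encode_protein, max_len = cfg$max_len)
  names(enc) <- seqs
  rf <- receptive_field(cfg$kernel_sizes)
  short <- vapply(enc, function(e) sum(e$mask) < rf, logical(1L))
  if (any(short))
    stop("prepare_features: ", sum(short), " protein(s) shorter than the ",
         rf, "-residue receptive field")
  smis <- unique(data$smiles)
  graphs <- lapply(smis, smiles_to_graph, max_nodes = cfg$max_nodes)
  names(graphs) <- smis
  gts <- lapply(graphs, graph_tensors)
  list(enc = enc, graphs = graphs, gts = gts)
}

## per-sample cross-entropy on the tape, computed from the logit for
## numerical stability: -log p = softplus(-z), -log(1-p) = softplus(z)
.bce_ag <- function(z_ag, y) {
  ag_softplus(ag_scale(z_ag, if (y == 1L) -1 else 1))
}

param_flatten <- function(par) {
  unlist(lapply(par, function(t) as.numeric(t$v)), use.names = FALSE)
}

param_assign <- function(par, vec) {
  i <- 0L
  for (t in par) {
    n <- length(t$v)
    t$v[] <- vec[i + seq_len(n)]
    i <- i + n
  }
  invisible(par)
}

grad_flatten <- function(par) {
  unlist(lapply(par, function(t) {
    if (is.null(t$g)) numeric(length(t$v)) else as.numeric(t$g)
  }), use.names = FALSE)
}

zero_grads <- function(par) {
  for (t in par) t$g <- NULL
  invisible(par)
}

## loss (and accumulated parameter gradients) of a set of samples;
## used by training and by finite-difference checks
model_loss_grad <- function(net, data, feats, lambda = 0, grad = TRUE,
                            train = TRUE) {
  zero_grads(net$par)
  total <- 0
  for (i in seq_len(nrow(data))) {
    smi <- data$smiles[i]; sq <- data$sequence[i]
    if (grad) ag_tape_begin()
    out <- forward_sample(net, feats$enc[[sq]], feats$graphs[[smi]],
                          gt = feats$gts[[smi]], train = train)
    L <- .bce_ag(out$z, data$label[i])
    total <- total + L$v[1L]
    if (grad) ag_backward(L)
  }
  if (lambda > 0) {
    for (t in net$par) {
      total <- total + lambda / 2 * sum(t$v^2)
      if (grad) t$g <- (if (is.null(t$g)) 0 else t$g) + lambda * t$v
    }
  }
  ## the pad row of the protein embedding is frozen at zero
  if (grad && !is.null(net$par$Ep$g)) net$par$Ep$g[1L, ] <- 0
  list(loss = total, grads = if (grad) grad_flatten(net$par) else NULL)
}

adam_state <- function(par) {
  list(m = lapply(par, function(t) t$v * 0),
       v = lapply(par, function(t) t$v * 0),
       t = 0L)
}

adam_step <- function(par, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t; b2t <- 1 - beta2^st$t
  nm <- names(par)
  for (k in nm) {
    t <- par[[k]]
    g <- t$g
    if (is.null(g)) next
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    t$v <- t$v - lr * (st$m[[k]] / b1t) / (sqrt(st$v[[k]] / b2t) + eps)
  }
  st
}

.predict_net <- function(net, data, feats) {
  vapply(seq_len(nrow(data)), function(i) {
    out <- forward_sample(net, feats$enc[[data$sequence[i]]],
                          feats$graphs[[data$smiles[i]]],
                          gt = feats$gts[[data$smiles[i]]], train = FALSE)
    out$p$v[1L]
  }, numeric(1L))
}

#' Fit the drug--target interaction model
#'
#' Trains the full architecture -- self-attention-enhanced CNN protein
#' encoder, neural-fingerprint message-passing drug encoder, bilinear
#' attention fusion with attention pooling, and a sigmoid decoder -- by
#' minibatch Adam on the L2-regularized binary cross-entropy. The dataset is
#' split 0.7/0.1/0.2 into train/validation/test (unless a prebuilt
#' \code{dti_split} is supplied); validation AUROC is tracked every epoch and
#' the best-validation checkpoint is restored at the end. The classification
#' threshold is frozen at the optimal-F1 cutoff on the validation set.
#'
#' @param data data.frame with columns \code{smiles}, \code{sequence},
#'   \code{label} (as from \code{\link{load_dti_table}} or
#'   \code{\link{generate_dti_dataset}}), or a \code{dti_split}
#' @param config a \code{\link{dti_config}}
#' @param seed integer seed controlling the split, initialization, and
#'   shuffling (defaults to \code{config$seed})
#' @param threshold_source \code{"validation"} (default) or \code{"test"}:
#'   which partition the optimal-F1 threshold is computed on
#' @param verbose print per-epoch progress
#' @return object of class \code{nfsa_dti} with the fitted parameters,
#'   the training history (\code{$history}), the frozen \code{$threshold},
#'   the \code{$split} used, and the best epoch index
#' @examples
#' \donttest{
#' syn <- generate_dti_dataset(synthetic_spec(n_samples = 60, seed = 1))
#' fit <- nfsa_dti(syn$data, dti_config_small(epochs = 2L), seed = 1)
#' predict(fit, syn$data[1:3, ])
#' }
#' @export
nfsa_dti <- function(data, config = dti_config_small(), seed = config$seed,
                     threshold_source = c("validation", "test"),
                     verbose = FALSE) {
  threshold_source <- match.arg(threshold_source)
  stopifnot(inherits(config, "dti_config"))
  split <- if (inherits(data, "dti_split")) data
           else split_dataset(data, seed = seed)
  cfg <- config
  cfg$seed <- as.integer(seed)
  all_data <- rbind(split$train, split$validation, split$test)
  feats <- prepare_features(all_data, cfg)
  net <- new_net(cfg)
  st <- adam_state(net$par)
  n_train <- nrow(split$train)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auroc = numeric(0), val_auprc = numeric(0))
  best <- list(score = -Inf, epoch = 0L, par = NULL, bn = NULL)
  val_ok <- nrow(split$validation) > 1L &&
    length(unique(split$validation$label)) == 2L

  for (epoch in seq_len(cfg$epochs)) {
    ord <- withr::with_seed(cfg$seed + epoch, sample.int(n_train))
    epoch_loss <- 0
    for (start in seq(1L, n_train, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
      out <- model_loss_grad(net, split$train[idx, , drop = FALSE], feats,
                             lambda = cfg$lambda, grad = TRUE, train = TRUE)
      if (!is.finite(out$loss))
        stop("nfsa_dti: non-finite loss at epoch ", epoch,
             " -- training diverged (try a lower learning rate)")
      epoch_loss <- epoch_loss + out$loss
      st <- adam_step(net$par, st, cfg$lr)
      net$par$Ep$v[1L, ] <- 0
      zero_grads(net$par)
    }
    if (val_ok) {
      vp <- .predict_net(net, split$validation, feats)
      va <- auroc(vp, split$validation$label)
      vpr <- auprc(vp, split$validation$label)
      score <- va
    } else {
      va <- NA_real_; vpr <- NA_real_
      score <- -epoch_loss
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_auroc = va, val_auprc = vpr))
    if (score > best$score) {
      best <- list(score = score, epoch = epoch,
                   par = lapply(net$par, function(t) t$v),
                   bn = as.list(net$bn))
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %10.4f  val AUROC %s", epoch,
                      epoch_loss, ifelse(is.na(va), "-", sprintf("%.4f", va))))
  }

  ## restore the best-validation checkpoint
  if (!is.null(best$par)) {
    for (k in names(best$par)) net$par[[k]]$v <- best$par[[k]]
    for (k in names(best$bn)) net$bn[[k]] <- best$bn[[k]]
  }

  thr_data <- if (threshold_source == "validation" && val_ok)
    split$validation else split$test
  thr_scores <- .predict_net(net, thr_data, feats)
  threshold <- optimal_f1_threshold(thr_scores, thr_data$label)

  structure(list(net = net, config = cfg, history = history,
                 best_epoch = best$epoch, threshold = threshold,
                 threshold_source = threshold_source, split = split,
                 seed = as.integer(seed)),
            class = "nfsa_dti")
}

#' Predict interaction probabilities
#'
#' @param object fitted \code{nfsa_dti} model
#' @param newdata data.frame with \code{smiles} and \code{sequence} columns
#'   (the training data if omitted)
#' @param type \code{"response"} for probabilities, \code{"class"} for 0/1
#'   calls at the model's frozen threshold
#' @param ... unused
#' @return numeric vector of probabilities (or integer class calls)
#' @export
predict.nfsa_dti <- function(object, newdata = NULL, type = c("response", "class"),
                             ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$split$train
  if (!all(c("smiles", "sequence") %in% names(newdata)))
    stop("predict.nfsa_dti: 'newdata' needs 'smiles' and 'sequence' columns")
  feats <- prepare_features(newdata, object$config)
  p <- .predict_net(object$net, newdata, feats)
  if (type == "class") as.integer(p >= object$threshold) else p
}

#' Evaluate a fitted model on a labelled dataset
#'
#' Computes AUROC, AUPRC, and threshold metrics at the model's frozen
#' optimal-F1 threshold (or a supplied one).
#'
#' @param model fitted \code{nfsa_dti}
#' @param data labelled data.frame; the model's test partition if omitted
#' @param threshold classification cutoff; the model's frozen threshold by
#'   default
#' @return a \code{\link{eval_report}} object
#' @export
dti_evaluate <- function(model, data = NULL, threshold = model$threshold) {
  if (is.null(data)) data <- model$split$test
  eval_report(predict(model, data), data$label, threshold = threshold)
}

#' @export
print.nfsa_dti <- function(x, ...) {
  cat("Drug-target interaction model (neural fingerprint + self-attention)\n")
  print(x$config)
  n <- vapply(x$split[c("train", "validation", "test")], nrow, 1L)
  cat(sprintf("  data:    %d train / %d validation / %d test\n", n[1], n[2], n[3]))
  va <- x$history$val_auroc[x$best_epoch]
  cat(sprintf("  best epoch %d of %d | validation AUROC %s | threshold %.4f (%s)\n",
              x$best_epoch, nrow(x$history),
              ifelse(is.na(va), "-", sprintf("%.4f", va)),
              x$threshold, x$threshold_source))
  invisible(x)
}

#' @export
summary.nfsa_dti <- function(object, ...) {
  out <- list(model = object,
              train = dti_evaluate(object, object$split$train),
              test = dti_evaluate(object, object$split$test))
  class(out) <- "summary.nfsa_dti"
  out
}

#' @export
print.summary.nfsa_dti <- function(x, ...) {
  print(x$model)
  cat("train: "); print(x$train)
  cat("test:  "); print(x$test)
  invisible(x)
}

#' @export
coef.nfsa_dti <- function(object, ...) {
  lapply(object$net$par, function(t) t$v)
}

#' @export
residuals.nfsa_dti <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$split$train
  newdata$label - predict(object, newdata)
}

#' @export
fitted.nfsa_dti <- function(object, ...) predict(object, object$split$train)

#' @export
plot.nfsa_dti <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "Loss", ...)
  if (!all(is.na(h$val_auroc))) {
    plot(h$epoch, h$val_auroc, type = "l", xlab = "epoch",
         ylab = "validation AUROC", main = "Validation", ylim = c(0.4, 1), ...)
    graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  }
  invisible(x)
}

#' @export
simulate.nfsa_dti <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$split$train
  p <- predict(object, newdata)
  as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
}
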