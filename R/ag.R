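#' @keywords internal
"_PACKAGE"

## Minimal tape-based reverse-mode automatic differentiation.
##
## The model's forward pass is written in terms of the ag_* operations below.
## When a tape is active every operation records a backward closure; ag_backward()
## replays the tape in reverse and accumulates gradients into the participating
## tensors' `g` slots. With no tape active the same code runs as plain matrix
## arithmetic (eval mode). All values are stored as base-R matrices; scalars are
## 1x1 matrices.

.ag_env <- new.env(parent = emptyenv())
.ag_env$tape <- NULL

#' Wrap a numeric matrix as an autograd tensor
#'
#' Tensors are environments holding a value `v` and an accumulated gradient `g`
#' (`NULL` until backward reaches them). Model parameters are long-lived tensors;
#' intermediates are created by the `ag_*` operations.
#'
#' @param v numeric matrix (or vector, coerced to a one-column matrix)
#' @return an object of class `ag`
#' @keywords internal
ag_tensor <- function(v) {
  if (!is.matrix(v)) v <- as.matrix(v)
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  class(e) <- "ag"
  e
}

is_ag <- function(x) inherits(x, "ag")

as_ag <- function(x) if (is_ag(x)) x else ag_tensor(x)

#' Begin recording a gradient tape
#' @keywords internal
ag_tape_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$ops <- vector("list", 512L)
  t$n <- 0L
  .ag_env$tape <- t
  invisible(t)
}

#' Stop recording (discard the active tape)
#' @keywords internal
ag_tape_end <- function() {
  .ag_env$tape <- NULL
  invisible(NULL)
}

ag_recording <- function() !is.null(.ag_env$tape)

## Create an output tensor and, if recording, push its backward closure.
## bw(gout) must return a list of gradients aligned with `parents`
## (NULL entries for non-differentiable parents).
ag_node <- function(v, parents, bw) {
  out <- ag_tensor(v)
  t <- .ag_env$tape
  if (!is.null(t)) {
    n <- t$n + 1L
    if (n > length(t$ops)) t$ops <- c(t$ops, vector("list", length(t$ops)))
    t$ops[[n]] <- list(out = out, parents = parents, bw = bw)
    t$n <- n
  }
  out
}

#' Reverse-mode sweep over the active tape
#'
#' Seeds `root$g` and accumulates gradients into every tensor on the tape,
#' including long-lived parameter tensors (whose `g` therefore sums across
#' successive backward calls until reset). The tape is discarded afterwards.
#'
#' @param root tensor whose (scalar) value is differentiated
#' @param seed gradient seed, default 1
#' @keywords internal
ag_backward <- function(root, seed = 1) {
  t <- .ag_env$tape
  if (is.null(t)) stop("ag_backward: no active tape")
  root$g <- matrix(seed, nrow(root$v), ncol(root$v))
  if (t$n > 0L) {
    for (i in t$n:1L) {
      op <- t$ops[[i]]
      gout <- op$out$g
      if (is.null(gout)) next
      gs <- op$bw(gout)
      ps <- op$parents
      for (k in seq_along(ps)) {
        gk <- gs[[k]]
        if (is.null(gk)) next
        p <- ps[[k]]
        p$g <- if (is.null(p$g)) gk else p$g + gk
      }
    }
  }
  ag_tape_end()
  invisible(NULL)
}

## ---- arithmetic ------------------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(a$v %*% b$v, list(a, b), function(g) {
    list(g %*% t(b$v), crossprod(a$v, g))
  })
}

## a %*% C with C a plain constant matrix
ag_matmulc <- function(a, C) {
  ag_node(a$v %*% C, list(a), function(g) list(tcrossprod(g, C)))
}

## C %*% a with C a plain constant matrix
ag_cmatmul <- function(C, a) {
  ag_node(C %*% a$v, list(a), function(g) list(crossprod(C, g)))
}

ag_t <- function(a) {
  ag_node(t(a$v), list(a), function(g) list(t(g)))
}

## add with limited broadcasting: b may be same shape, 1x1, or a 1xC row
ag_add <- function(a, b) {
  av <- a$v; bv <- b$v
  if (identical(dim(av), dim(bv))) {
    ag_node(av + bv, list(a, b), function(g) list(g, g))
  } else if (nrow(bv) == 1L && ncol(bv) == 1L) {
    ag_node(av + bv[1L], list(a, b), function(g) list(g, matrix(sum(g), 1L, 1L)))
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    ag_node(sweep(av, 2L, bv[1L, ], "+"), list(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else stop("ag_add: incompatible shapes")
}

## elementwise product with the same broadcasting rules as ag_add
ag_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  if (identical(dim(av), dim(bv))) {
    ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
  } else if (nrow(bv) == 1L && ncol(bv) == 1L) {
    ag_node(av * bv[1L], list(a, b), function(g) {
      list(g * bv[1L], matrix(sum(g * av), 1L, 1L))
    })
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    ag_node(sweep(av, 2L, bv[1L, ], "*"), list(a, b), function(g) {
      list(sweep(g, 2L, bv[1L, ], "*"), matrix(colSums(g * av), 1L))
    })
  } else stop("ag_mul: incompatible shapes")
}

ag_scale <- function(a, k) {
  ag_node(a$v * k, list(a), function(g) list(g * k))
}

ag_addc <- function(a, C) {
  ag_node(a$v + C, list(a), function(g) list(g))
}

ag_mulc <- function(a, C) {
  ag_node(a$v * C, list(a), function(g) list(g * C))
}

## ---- elementwise nonlinearities -------------------------------------------

ag_relu <- function(a) {
  m <- a$v > 0
  ag_node(a$v * m, list(a), function(g) list(g * m))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  h <- tanh(a$v)
  ag_node(h, list(a), function(g) list(g * (1 - h * h)))
}

## numerically stable log(1 + exp(x)); gradient is sigmoid(x)
ag_softplus <- function(a) {
  x <- a$v
  v <- pmax(x, 0) + log1p(exp(-abs(x)))
  ag_node(v, list(a), function(g) list(g / (1 + exp(-x))))
}

ag_exp <- function(a) {
  e <- exp(a$v)
  ag_node(e, list(a), function(g) list(g * e))
}

ag_log <- function(a) {
  ag_node(log(a$v), list(a), function(g) list(g / a$v))
}

## elementwise power with a constant exponent
ag_powc <- function(a, p) {
  ag_node(a$v^p, list(a), function(g) list(g * p * a$v^(p - 1)))
}

## clamp into [lo, hi]; gradient is zero where clamped
ag_clamp <- function(a, lo, hi) {
  inside <- a$v >= lo & a$v <= hi
  ag_node(pmin(pmax(a$v, lo), hi), list(a), function(g) list(g * inside))
}

## ---- shape / gather --------------------------------------------------------

## row gather; idx may repeat rows. Backward scatter-adds.
ag_rows <- function(a, idx) {
  nr <- nrow(a$v); nc <- ncol(a$v)
  ag_node(a$v[idx, , drop = FALSE], list(a), function(g) {
    z <- matrix(0, nr, nc)
    rs <- rowsum(g, group = idx)
    z[as.integer(rownames(rs)), ] <- rs
    list(z)
  })
}

ag_cbind <- function(xs) {
  vs <- lapply(xs, function(x) x$v)
  widths <- vapply(vs, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(do.call(cbind, vs), xs, function(g) {
    lapply(seq_along(xs), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ag_sum <- function(a) {
  ag_node(matrix(sum(a$v), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], nrow(a$v), ncol(a$v)))
  })
}

## sliding-window unfold for valid 1D convolution: rows of the output are
## the k consecutive input rows, concatenated (im2col)
ag_unfold <- function(a, k) {
  L <- nrow(a$v); C <- ncol(a$v)
  Lout <- L - k + 1L
  if (Lout < 1L) stop("ag_unfold: input shorter than kernel")
  v <- matrix(0, Lout, k * C)
  for (s in seq_len(k))
    v[, ((s - 1L) * C + 1L):(s * C)] <- a$v[s:(s + Lout - 1L), , drop = FALSE]
  ag_node(v, list(a), function(g) {
    z <- matrix(0, L, C)
    for (s in seq_len(k)) {
      rows <- s:(s + Lout - 1L)
      z[rows, ] <- z[rows, ] + g[, ((s - 1L) * C + 1L):(s * C), drop = FALSE]
    }
    list(z)
  })
}

## fused batch normalization over rows (per-column statistics), with the
## standard closed-form backward
ag_batchnorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$v
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  vr <- colMeans(xc * xc)
  inv <- 1 / sqrt(vr + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma$v[1L, ], "*"), 2L, beta$v[1L, ], "+")
  out <- ag_node(y, list(a, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- sweep(g, 2L, gamma$v[1L, ], "*")
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * xhat)
    dx <- sweep(dxhat, 2L, t1 / n) - sweep(xhat, 2L, t2 / n, "*")
    dx <- sweep(dx, 2L, inv, "*")
    list(dx, dgamma, dbeta)
  })
  out$bn_mu <- mu
  out$bn_var <- vr
  out
}

## column-major reshape (base-R matrix semantics)
ag_reshape <- function(a, nr, nc) {
  d <- dim(a$v)
  ag_node(matrix(a$v, nr, nc), list(a), function(g) list(matrix(g, d[1L], d[2L])))
}

## ---- softmax ---------------------------------------------------------------

#' Row-wise softmax with an optional key mask
#'
#' Masked columns receive exactly zero probability; each row's probabilities
#' sum to one over the unmasked columns.
#'
#' @param a tensor of logits
#' @param keymask logical vector, length `ncol(a)`, `TRUE` = valid key
#' @keywords internal
ag_softmax_rows <- function(a, keymask = NULL) {
  x <- a$v
  if (!is.null(keymask)) x[, !keymask] <- -Inf
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e[is.nan(e)] <- 0     # rows that are entirely -Inf
  s <- e / rowSums(e)
  ag_node(s, list(a), function(g) {
    gin <- s * (g - rowSums(g * s))
    if (!is.null(keymask)) gin[, !keymask] <- 0
    list(gin)
  })
}
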