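## Independent brute-force oracles used to check the vectorized
## implementations. These are deliberately written as plain loops over the
## defining formulas and share no code with the package internals.

## multi-head self-attention, position by position
naive_self_attention <- function(H, Wq, Wk, Wv, Wout, bout) {
  M <- nrow(H)
  heads_out <- list()
  for (h in seq_along(Wq)) {
    d <- ncol(Wq[[h]])
    O <- matrix(0, M, ncol(Wv[[h]]))
    for (i in seq_len(M)) {
      q <- drop(H[i, ] %*% Wq[[h]])
      logits <- vapply(seq_len(M), function(j) {
        sum(q * drop(H[j, ] %*% Wk[[h]])) / sqrt(d)
      }, numeric(1))
      w <- exp(logits - max(logits)); w <- w / sum(w)
      for (j in seq_len(M))
        O[i, ] <- O[i, ] + w[j] * drop(H[j, ] %*% Wv[[h]])
    }
    heads_out[[h]] <- O
  }
  do.call(cbind, heads_out) %*% Wout +
    matrix(bout, M, length(bout), byrow = TRUE)
}

## neural fingerprint from the bond list, node by node
naive_fingerprint <- function(graph, W_embed, b_embed, Hh, Wo) {
  n <- graph$n_real_atoms
  R <- graph$node_features %*% W_embed +
    matrix(b_embed, n, length(b_embed), byrow = TRUE)
  bonds <- graph$edges[graph$edge_features != "self", , drop = FALSE]
  f <- numeric(ncol(Wo))
  for (i in seq_len(n)) {
    v <- R[i, ]
    for (b in seq_len(nrow(bonds))) {
      if (bonds[b, 1L] == i) v <- v + R[bonds[b, 2L], ]
      if (bonds[b, 2L] == i) v <- v + R[bonds[b, 1L], ]
    }
    z <- drop(pmax(v %*% Hh, 0) %*% Wo)
    e <- exp(z - max(z))
    f <- f + e / sum(e)
  }
  f
}

## one message-passing layer as an explicit per-directed-edge loop:
## m_ij = relu(W_rho [h_i, h_j, e_ij] + b), m_i = sum over incoming,
## h_i' = relu(W_phi [h_i, m_i, f] + b)
naive_message_pass <- function(H, tgt, src, Ef, fvec, W_rho, b_rho,
                               W_phi, b_phi) {
  n <- nrow(H)
  hl <- ncol(W_rho)
  Magg <- matrix(0, n, hl)
  for (e in seq_along(tgt)) {
    m <- pmax(drop(c(H[tgt[e], ], H[src[e], ], Ef[e, ]) %*% W_rho) + b_rho, 0)
    Magg[tgt[e], ] <- Magg[tgt[e], ] + m
  }
  out <- matrix(0, n, ncol(W_phi))
  for (i in seq_len(n))
    out[i, ] <- pmax(drop(c(H[i, ], Magg[i, ], fvec) %*% W_phi) + b_phi, 0)
  out
}

## elementwise bilinear interaction, cell by cell: I_ij = q^T (relu(U^T hd_i) o relu(V^T hp_j))
naive_interaction <- function(Hd, Hp, U, V, q) {
  n <- nrow(Hd); m <- nrow(Hp)
  I <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    I[i, j] <- sum(q * pmax(drop(t(U) %*% Hd[i, ]), 0) *
                       pmax(drop(t(V) %*% Hp[j, ]), 0))
  }
  I
}

## bilinear pooling as a triple loop over (i, j, k)
naive_bilinear_pool <- function(Hd, Hp, I, U, V) {
  A <- pmax(Hd %*% U, 0); B <- pmax(Hp %*% V, 0)
  K <- ncol(U)
  f <- numeric(K)
  for (k in seq_len(K))
    for (i in seq_len(nrow(I)))
      for (j in seq_len(ncol(I)))
        f[k] <- f[k] + A[i, k] * I[i, j] * B[j, k]
  f
}

## attention-pooling weights, scalar by scalar
naive_att_weights <- function(I, u_att, b_att) {
  g <- matrix(0, nrow(I), ncol(I))
  for (i in seq_len(nrow(I))) for (j in seq_len(ncol(I)))
    g[i, j] <- sum(b_att * tanh(u_att * I[i, j]))
  e <- exp(g - max(g))
  e / sum(e)
}

## average precision by a literal threshold sweep (independent of the
## package's step integration)
naive_auprc <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in ts) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

## tiny random weight helper
rw <- function(nr, nc, sd = 0.5) matrix(rnorm(nr * nc, sd = sd), nr, nc)
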