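## Network assembly: parameter initialization and the forward passes of the
## protein encoder (CNN + self-attention enhancing unit), the drug encoder
## (neural fingerprint + fingerprint-conditioned message passing), the
## bilinear attention fusion, and the fully connected decoder.

.xavier <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

## All learnable tensors, created under the config seed. Names are stable;
## flatten/assign helpers below rely on the list order.
init_params <- function(cfg) {
  withr::with_seed(cfg$seed, {
    p <- list()
    ## protein embedding; row 1 is the frozen zero pad row, rows 2..24 residues
    Ep <- .xavier(length(AA_VOCAB) + 1L, cfg$aa_embed_dim)
    Ep[1L, ] <- 0
    p$Ep <- Ep
    in_ch <- cfg$aa_embed_dim
    for (l in seq_along(cfg$kernel_sizes)) {
      k <- cfg$kernel_sizes[l]; f <- cfg$n_filters[l]
      p[[paste0("W_conv", l)]] <- .xavier(k * in_ch, f)
      p[[paste0("b_conv", l)]] <- matrix(0, 1L, f)
      if (cfg$batch_norm) {
        p[[paste0("bn_gamma", l)]] <- matrix(1, 1L, f)
        p[[paste0("bn_beta", l)]] <- matrix(0, 1L, f)
      }
      in_ch <- f
    }
    e <- cfg$n_filters[length(cfg$n_filters)]
    if (cfg$use_esacm) {
      dh <- e %/% cfg$sa_heads
      for (h in seq_len(cfg$sa_heads)) {
        p[[paste0("W_q", h)]] <- .xavier(e, dh)
        p[[paste0("W_k", h)]] <- .xavier(e, dh)
        p[[paste0("W_v", h)]] <- .xavier(e, dh)
      }
      p$W_sa_out <- .xavier(e, e)
      p$b_sa_out <- matrix(0, 1L, e)
    }
    ## drug encoder
    p$W_atom <- .xavier(n_atom_features(), cfg$atom_embed_dim)
    p$b_atom <- matrix(0, 1L, cfg$atom_embed_dim)
    if (cfg$use_fingerprint) {
      p$Hh <- .xavier(cfg$atom_embed_dim, cfg$atom_embed_dim)
      p$Wo_fp <- .xavier(cfg$atom_embed_dim, cfg$fingerprint_dim)
    }
    h_in <- cfg$atom_embed_dim
    for (l in seq_along(cfg$hidden_dims)) {
      hl <- cfg$hidden_dims[l]
      p[[paste0("W_rho", l)]] <- .xavier(2L * h_in + n_edge_features(), hl)
      p[[paste0("b_rho", l)]] <- matrix(0, 1L, hl)
      p[[paste0("W_phi", l)]] <- .xavier(h_in + hl + cfg$fingerprint_dim, hl)
      p[[paste0("b_phi", l)]] <- matrix(0, 1L, hl)
      h_in <- hl
    }
    ## bilinear attention heads
    hd <- cfg$hidden_dims[length(cfg$hidden_dims)]
    for (h in seq_len(cfg$bilinear_heads)) {
      p[[paste0("U", h)]] <- .xavier(hd, cfg$bilinear_dim)
      p[[paste0("V", h)]] <- .xavier(e, cfg$bilinear_dim)
      p[[paste0("q", h)]] <- .xavier(1L, cfg$bilinear_dim)
      if (cfg$att_pool) {
        p[[paste0("u_att", h)]] <- .xavier(1L, cfg$att_pool_dim)
        p[[paste0("b_att", h)]] <- .xavier(cfg$att_pool_dim, 1L)
        p[[paste0("bias_att", h)]] <- matrix(0, 1L, cfg$bilinear_dim)
      }
    }
    ## decoder
    p$W_fc1 <- .xavier(cfg$bilinear_dim, cfg$fc_hidden)
    p$b_fc1 <- matrix(0, 1L, cfg$fc_hidden)
    p$W_fc2 <- .xavier(cfg$fc_hidden, 1L)
    p$b_fc2 <- matrix(0, 1L, 1L)
    lapply(p, ag_tensor)
  })
}

new_net <- function(cfg) {
  bn <- new.env(parent = emptyenv())
  for (l in seq_along(cfg$kernel_sizes)) {
    bn[[paste0("rmean", l)]] <- rep(0, cfg$n_filters[l])
    bn[[paste0("rvar", l)]] <- rep(1, cfg$n_filters[l])
  }
  list(par = init_params(cfg), bn = bn, cfg = cfg)
}

## ---- protein encoder -------------------------------------------------------

receptive_field <- function(kernel_sizes) sum(kernel_sizes - 1L) + 1L

## one valid (no padding) 1D convolution as an unfolded matrix product
.conv_layer <- function(H, W, b, k) {
  if (nrow(H$v) < k) stop("sequence shorter than convolution kernel")
  ag_add(ag_matmul(ag_unfold(H, k), W), b)
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

.bn_layer <- function(net, l, H, train) {
  par <- net$par
  gam <- par[[paste0("bn_gamma", l)]]; bet <- par[[paste0("bn_beta", l)]]
  if (train) {
    out <- ag_batchnorm(H, gam, bet, eps = .bn_eps)
    bn <- net$bn
    key_m <- paste0("rmean", l); key_v <- paste0("rvar", l)
    bn[[key_m]] <- (1 - .bn_momentum) * bn[[key_m]] + .bn_momentum * out$bn_mu
    bn[[key_v]] <- (1 - .bn_momentum) * bn[[key_v]] + .bn_momentum * out$bn_var
    out
  } else {
    rm_ <- net$bn[[paste0("rmean", l)]]
    rs <- 1 / sqrt(net$bn[[paste0("rvar", l)]] + .bn_eps)
    Hn <- ag_mulc(ag_addc(H, matrix(-rm_, nrow(H$v), ncol(H$v), byrow = TRUE)),
                  matrix(rs, nrow(H$v), ncol(H$v), byrow = TRUE))
    ag_add(ag_mul(Hn, gam), bet)
  }
}

## multi-head scaled dot-product self-attention over the sequence axis,
## concatenated heads projected back to the input width
.sa_core <- function(H, Wqs, Wks, Wvs, Wout, bout, keymask = NULL) {
  outs <- vector("list", length(Wqs))
  for (h in seq_along(Wqs)) {
    Q <- ag_matmul(H, Wqs[[h]])
    K <- ag_matmul(H, Wks[[h]])
    V <- ag_matmul(H, Wvs[[h]])
    d <- ncol(Q$v)
    S <- ag_scale(ag_matmul(Q, ag_t(K)), 1 / sqrt(d))
    A <- ag_softmax_rows(S, keymask)
    outs[[h]] <- ag_matmul(A, V)
  }
  ag_add(ag_matmul(ag_cbind(outs), Wout), bout)
}

## Encode one protein (already reduced to its real-residue prefix) into the
## substructure representation. Returns an ag tensor of shape M x e with
## M = n_res - (receptive field - 1).
forward_protein <- function(net, enc, train = FALSE) {
  cfg <- net$cfg
  n_res <- sum(enc$mask)
  rf <- receptive_field(cfg$kernel_sizes)
  if (n_res < rf)
    stop("protein of length ", n_res, " is shorter than the encoder's ",
         rf, "-residue receptive field")
  ids <- enc$indices[seq_len(n_res)] + 1L  # row 1 of Ep is the pad row
  H <- ag_rows(net$par$Ep, ids)
  for (l in seq_along(cfg$kernel_sizes)) {
    H <- .conv_layer(H, net$par[[paste0("W_conv", l)]],
                     net$par[[paste0("b_conv", l)]], cfg$kernel_sizes[l])
    if (cfg$batch_norm) H <- .bn_layer(net, l, H, train)
    H <- ag_relu(H)
  }
  if (cfg$use_esacm) {
    hs <- seq_len(cfg$sa_heads)
    A <- .sa_core(H,
                  lapply(hs, function(h) net$par[[paste0("W_q", h)]]),
                  lapply(hs, function(h) net$par[[paste0("W_k", h)]]),
                  lapply(hs, function(h) net$par[[paste0("W_v", h)]]),
                  net$par$W_sa_out, net$par$b_sa_out)
    H <- if (cfg$sa_residual) ag_add(A, H) else A
  }
  H
}

## ---- drug encoder ----------------------------------------------------------

## constant tensors derived from a molecular graph
graph_tensors <- function(graph) {
  n <- graph$n_real_atoms
  bonds <- graph$edges[graph$edge_features != "self", , drop = FALSE]
  Aplus <- diag(n)
  if (nrow(bonds)) {
    Aplus[bonds] <- 1
    Aplus[bonds[, c(2L, 1L), drop = FALSE]] <- 1
  }
  ## directed edges: both directions of each bond, one self-loop per atom
  tgt <- c(bonds[, 1L], bonds[, 2L], seq_len(n))
  src <- c(bonds[, 2L], bonds[, 1L], seq_len(n))
  etype <- c(rep(graph$edge_features[graph$edge_features != "self"], 2L),
             rep("self", n))
  Ef <- edge_feature_matrix(etype)
  Agg <- matrix(0, n, length(tgt))
  Agg[cbind(tgt, seq_along(tgt))] <- 1
  ## only rows of real atoms enter the computation; any padding rows in
  ## node_features are structurally ignored
  list(X = graph$node_features[seq_len(n), , drop = FALSE], Aplus = Aplus,
       tgt = tgt, src = src, Ef = Ef, Agg = Agg, n = n)
}

## neural fingerprint: per-node softmax contributions summed over real atoms
.fp_core <- function(R, Aplus, Hh, Wo) {
  v <- ag_cmatmul(Aplus, R)
  S <- ag_softmax_rows(ag_matmul(ag_relu(ag_matmul(v, Hh)), Wo))
  n <- nrow(R$v)
  list(f = ag_cmatmul(matrix(1, 1L, n), S), per_node = S)
}

forward_drug <- function(net, graph, gt = NULL, train = FALSE) {
  cfg <- net$cfg
  if (is.null(gt)) gt <- graph_tensors(graph)
  par <- net$par
  R <- ag_add(ag_cmatmul(gt$X, par$W_atom), par$b_atom)
  if (cfg$use_fingerprint) {
    fp <- .fp_core(R, gt$Aplus, par$Hh, par$Wo_fp)$f
  } else {
    fp <- ag_tensor(matrix(0, 1L, cfg$fingerprint_dim))
  }
  H <- R
  n <- gt$n
  fprep_idx <- rep(1L, n)
  Ef <- ag_tensor(gt$Ef)
  for (l in seq_along(cfg$hidden_dims)) {
    Hi <- ag_rows(H, gt$tgt)
    Hj <- ag_rows(H, gt$src)
    Msg <- ag_relu(ag_add(ag_matmul(ag_cbind(list(Hi, Hj, Ef)),
                                    par[[paste0("W_rho", l)]]),
                          par[[paste0("b_rho", l)]]))
    Agg <- ag_cmatmul(gt$Agg, Msg)
    Fb <- ag_rows(fp, fprep_idx)
    H <- ag_relu(ag_add(ag_matmul(ag_cbind(list(H, Agg, Fb)),
                                  par[[paste0("W_phi", l)]]),
                        par[[paste0("b_phi", l)]]))
  }
  list(H = H, fingerprint = fp)
}

## ---- bilinear attention fusion --------------------------------------------

## low-rank bilinear interaction map of one head:
## I = ((1 q^T) o relu(Hd U)) relu(Hp V)^T
.bilinear_head <- function(Hd, Hp, U, V, q) {
  A <- ag_relu(ag_matmul(Hd, U))
  B <- ag_relu(ag_matmul(Hp, V))
  I <- ag_matmul(ag_mul(A, q), ag_t(B))
  list(A = A, B = B, I = I)
}

## per-channel bilinear pooling: f'_k = A[,k]^T I B[,k]
.bilinear_pool_core <- function(A, I, B) {
  n <- nrow(A$v)
  ag_cmatmul(matrix(1, 1L, n), ag_mul(A, ag_matmul(I, B)))
}

## attention pooling over the interaction map's cells; returns the joint
## vector and the cell weight matrix (as a plain matrix, for interpretability)
.att_pool_core <- function(I, fprime, u, b_a, bias, cfg) {
  n <- nrow(I$v); m <- ncol(I$v)
  Iv <- ag_reshape(I, n * m, 1L)
  G <- ag_matmul(ag_tanh(ag_matmul(Iv, u)), b_a)   # per-cell gate, NM x 1
  if (cfg$att_pool_variant == "global") {
    Wrow <- ag_softmax_rows(ag_reshape(G, 1L, n * m))
    W <- ag_reshape(Wrow, n * m, 1L)
  } else {
    w <- cfg$att_pool_window
    ti <- (matrix(rep(seq_len(n), m), n, m) - 1L) %/% w
    tj <- (matrix(rep(seq_len(m), each = n), n, m) - 1L) %/% w
    tile <- as.integer(as.factor(ti + tj * 1e6))
    ntile <- max(tile)
    E <- ag_exp(ag_addc(G, -max(G$v)))
    Ind <- matrix(0, n * m, ntile)
    Ind[cbind(seq_len(n * m), tile)] <- 1
    sums <- ag_cmatmul(t(Ind), E)
    W <- ag_scale(ag_mul(E, ag_powc(ag_cmatmul(Ind, sums), -1)), 1 / ntile)
  }
  s <- ag_matmul(ag_t(W), G)                        # 1 x 1
  f <- if (cfg$att_pool_form == "rescale") {
    ag_add(ag_mul(fprime, s), bias)
  } else {
    ag_mul(fprime, ag_mul(bias, s))
  }
  list(f = f, W = matrix(W$v, n, m))
}

forward_fusion <- function(net, Hd, Hp, capture = FALSE) {
  cfg <- net$cfg
  par <- net$par
  joint <- NULL
  I_heads <- list(); W_heads <- list()
  for (h in seq_len(cfg$bilinear_heads)) {
    bh <- .bilinear_head(Hd, Hp, par[[paste0("U", h)]],
                         par[[paste0("V", h)]], par[[paste0("q", h)]])
    fprime <- .bilinear_pool_core(bh$A, bh$I, bh$B)
    if (cfg$att_pool) {
      ap <- .att_pool_core(bh$I, fprime, par[[paste0("u_att", h)]],
                           par[[paste0("b_att", h)]],
                           par[[paste0("bias_att", h)]], cfg)
      fh <- ap$f
      if (capture) W_heads[[h]] <- ap$W
    } else {
      fh <- fprime
    }
    if (capture) I_heads[[h]] <- bh$I$v
    joint <- if (is.null(joint)) fh else ag_add(joint, fh)
  }
  list(f = joint, I_heads = I_heads, W_heads = W_heads)
}

forward_classifier <- function(net, f) {
  par <- net$par
  h <- ag_relu(ag_add(ag_matmul(f, par$W_fc1), par$b_fc1))
  z <- ag_add(ag_matmul(h, par$W_fc2), par$b_fc2)
  list(p = ag_sigmoid(z), z = z)
}

## full forward pass for one drug--target pair
forward_sample <- function(net, enc, graph, gt = NULL, train = FALSE,
                           capture = FALSE) {
  Hp <- forward_protein(net, enc, train = train)
  dr <- forward_drug(net, graph, gt = gt, train = train)
  fu <- forward_fusion(net, dr$H, Hp, capture = capture)
  cl <- forward_classifier(net, fu$f)
  list(p = cl$p, z = cl$z, f = fu$f, I_heads = fu$I_heads,
       W_heads = fu$W_heads, Hd = dr$H, Hp = Hp, fingerprint = dr$fingerprint)
}

## ---- exported module surfaces (plain-matrix wrappers) ----------------------

#' Compute the neural fingerprint of a molecular graph
#'
#' Atom features are embedded by a learned linear map, each node's embedding
#' is summed with its bonded neighbors', passed through a ReLU hidden layer
#' and an output projection, and normalized per node by a softmax over the
#' fingerprint channels; node contributions are summed over real atoms. The
#' entries therefore sum exactly to the number of real atoms.
#'
#' @param graph a \code{molecular_graph}
#' @param W_embed,b_embed atom embedding weight (n_features x d) and bias (1 x d)
#' @param Hh hidden weight (d x d)
#' @param Wo output weight (d x fingerprint length)
#' @return object of class \code{neural_fingerprint}: \code{f} (numeric
#'   vector), \code{contributing_nodes}, \code{per_node} (node x channel
#'   softmax matrix)
#' @export
compute_fingerprint <- function(graph, W_embed, b_embed, Hh, Wo) {
  gt <- graph_tensors(graph)
  R <- ag_add(ag_cmatmul(gt$X, ag_tensor(W_embed)), ag_tensor(b_embed))
  out <- .fp_core(R, gt$Aplus, ag_tensor(Hh), ag_tensor(Wo))
  structure(list(f = as.numeric(out$f$v),
                 contributing_nodes = gt$n,
                 per_node = out$per_node$v),
            class = "neural_fingerprint")
}

#' Multi-head self-attention enhancing unit
#'
#' Scaled dot-product self-attention over the sequence axis: per head,
#' queries/keys/values are linear projections of the input rows, attention
#' weights are a softmax of q k^T / sqrt(d) over (unmasked) positions, and
#' the concatenated head outputs are projected back to the input width.
#'
#' @param H input matrix (positions x features)
#' @param Wq,Wk,Wv lists of per-head projection matrices
#' @param Wout,bout output projection and bias
#' @param keymask optional logical vector; \code{FALSE} positions receive
#'   zero attention weight as keys
#' @return matrix of the same shape as \code{H}
#' @export
self_attention_enhance <- function(H, Wq, Wk, Wv, Wout, bout, keymask = NULL) {
  .sa_core(ag_tensor(H), lapply(Wq, ag_tensor), lapply(Wk, ag_tensor),
           lapply(Wv, ag_tensor), ag_tensor(Wout), ag_tensor(bout),
           keymask = keymask)$v
}

#' Attention weights of the self-attention unit (single head)
#'
#' Exposes the row-stochastic attention matrix used internally, for
#' normalization checks and oracle comparisons.
#'
#' @inheritParams self_attention_enhance
#' @param Wq,Wk single-head projection matrices
#' @return positions x positions row-stochastic matrix
#' @export
self_attention_weights <- function(H, Wq, Wk, keymask = NULL) {
  Q <- H %*% Wq; K <- H %*% Wk
  S <- ag_tensor(Q %*% t(K) / sqrt(ncol(Q)))
  ag_softmax_rows(S, keymask)$v
}

#' Stack of valid 1D convolutions with optional batch normalization
#'
#' Each layer is a valid (unpadded) 1D convolution with stride 1 followed by
#' ReLU; with \code{gamma}/\code{beta} given, the pre-activation is
#' batch-normalized over the sequence positions. Output length is
#' \code{nrow(X) - sum(kernel_sizes - 1)}.
#'
#' @param X input matrix (positions x channels)
#' @param kernel_sizes integer vector
#' @param weights list of (k*in_channels x filters) weight matrices
#' @param biases list of 1 x filters biases
#' @param gamma,beta optional lists of batch-norm scale/shift rows
#' @return matrix (reduced positions x last filter count)
#' @export
conv_stack <- function(X, kernel_sizes, weights, biases,
                       gamma = NULL, beta = NULL) {
  H <- ag_tensor(X)
  for (l in seq_along(kernel_sizes)) {
    H <- .conv_layer(H, ag_tensor(weights[[l]]), ag_tensor(biases[[l]]),
                     kernel_sizes[l])
    if (!is.null(gamma)) {
      H <- ag_batchnorm(H, ag_tensor(gamma[[l]]), ag_tensor(beta[[l]]),
                        eps = .bn_eps)
    }
    H <- ag_relu(H)
  }
  H$v
}

#' Bilinear interaction map between drug and protein representations
#'
#' Computes the drug-substructure x protein-substructure interaction matrix
#' of one bilinear attention head,
#' \code{I = ((1 q^T) o relu(Hd U)) \%*\% relu(Hp V)^T}, whose (i, j) entry
#' equals \code{q^T (relu(U^T hd_i) o relu(V^T hp_j))}.
#'
#' @param Hd drug representation (atoms x hidden)
#' @param Hp protein representation (substructures x e)
#' @param U,V bilinear projection matrices (hidden x K, e x K)
#' @param q bilinear weight vector (length K)
#' @return atoms x substructures interaction matrix
#' @export
interaction_matrix <- function(Hd, Hp, U, V, q) {
  out <- .bilinear_head(ag_tensor(Hd), ag_tensor(Hp), ag_tensor(U),
                        ag_tensor(V), ag_tensor(matrix(q, 1L)))
  out$I$v
}

#' Bilinear pooling of an interaction map
#'
#' Per channel k, \code{f'_k = relu(Hd U)[, k]^T I relu(Hp V)[, k]}, using
#' the same U and V as the interaction map.
#'
#' @inheritParams interaction_matrix
#' @param I interaction matrix from \code{\link{interaction_matrix}}
#' @return numeric vector of length \code{ncol(U)}
#' @export
bilinear_pool <- function(Hd, Hp, I, U, V) {
  A <- ag_relu(ag_matmul(ag_tensor(Hd), ag_tensor(U)))
  B <- ag_relu(ag_matmul(ag_tensor(Hp), ag_tensor(V)))
  as.numeric(.bilinear_pool_core(A, ag_tensor(I), B)$v)
}

#' Attention pooling over the cells of an interaction map
#'
#' Each cell receives a scalar gate \code{b_a^T tanh(u_a I_ij)}; a softmax
#' over cells (globally, or within window tiles renormalized globally) turns
#' the gates into weights, and the attention-weighted gate evidence rescales
#' the bilinear-pooled representation.
#'
#' @param I interaction matrix
#' @param fprime bilinear-pooled vector
#' @param u_att 1 x d gate weight row
#' @param b_att d x 1 gate projection
#' @param bias 1 x length(fprime) bias row
#' @param variant \code{"global"} or \code{"windowed"}
#' @param window,stride tile geometry of the windowed variant
#' @param form \code{"rescale"} or \code{"broadcast"} (see
#'   \code{\link{dti_config}})
#' @return list with \code{f} (joint vector) and \code{W} (cell weight
#'   matrix summing to 1)
#' @export
attention_pool <- function(I, fprime, u_att, b_att, bias,
                           variant = "global", window = 3L, stride = 3L,
                           form = "rescale") {
  if (all(I == 0)) warning("attention_pool: all-zero interaction map")
  cfg <- list(att_pool_variant = variant, att_pool_window = as.integer(window),
              att_pool_stride = as.integer(stride), att_pool_form = form)
  out <- .att_pool_core(ag_tensor(I), ag_tensor(matrix(fprime, 1L)),
                        ag_tensor(u_att), ag_tensor(b_att),
                        ag_tensor(matrix(bias, 1L)), cfg)
  list(f = as.numeric(out$f$v), W = out$W)
}

#' Merge per-head joint representations
#'
#' Head outputs are summed elementwise (the bilinear attention convention),
#' preserving length.
#'
#' @param heads list of numeric vectors of equal length
#' @return numeric vector
#' @export
head_merge <- function(heads) {
  stopifnot(length(heads) >= 1L)
  Reduce(`+`, heads)
}
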