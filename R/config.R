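#' Model configuration
#'
#' Collects every architectural and training hyperparameter of the DTI
#' predictor. The defaults are the published configuration of the method:
#' 128-dim amino-acid embedding, three 1D convolutions with kernel sizes
#' 3/6/9 and 128 filters each, 2 self-attention heads, 128-dim atom
#' embedding, three 128-dim message-passing layers, 2 bilinear attention
#' heads, 768-dim bilinear embedding, attention-pooling window/stride 3,
#' a 512-unit fully connected decoder, Adam at learning rate 5e-5, 100
#' epochs, batch size 64.
#'
#' @param max_len maximum protein length (longer sequences are truncated)
#' @param aa_embed_dim amino-acid embedding dimension
#' @param kernel_sizes integer vector of 1D convolution kernel sizes
#' @param n_filters filters per convolution layer (same length as
#'   \code{kernel_sizes})
#' @param sa_heads number of self-attention heads (must divide the last
#'   filter count)
#' @param use_esacm logical; \code{FALSE} drops the self-attention enhancing
#'   unit, leaving a pure CNN protein encoder (ablation variant)
#' @param sa_residual logical; add the attention output to the CNN output
#'   instead of replacing it
#' @param batch_norm logical; batch-normalize each convolution output
#' @param max_nodes molecular graph node capacity
#' @param atom_embed_dim initial atom embedding dimension
#' @param hidden_dims hidden node dimensions of the three message-passing
#'   layers
#' @param fingerprint_dim neural fingerprint length
#' @param use_fingerprint logical; \code{FALSE} feeds a zero fingerprint to
#'   the vertex update, reducing the drug encoder to plain message passing
#'   (ablation variant)
#' @param bilinear_dim bilinear embedding dimension
#' @param bilinear_heads number of bilinear attention heads
#' @param att_pool logical; \code{FALSE} replaces attention pooling with sum
#'   pooling (ablation variant)
#' @param att_pool_dim rows of the attention-pooling gate weight matrix
#' @param att_pool_window,att_pool_stride tile size/stride of the windowed
#'   pooling variant
#' @param att_pool_variant \code{"global"}: one softmax over all interaction
#'   cells; \code{"windowed"}: softmax within non-overlapping
#'   window-by-window tiles, renormalized globally
#' @param att_pool_form how the pooled attention evidence enters the joint
#'   representation: \code{"rescale"} (default) rescales the bilinear-pooled
#'   vector by the attention-weighted gate and adds the bias;
#'   \code{"broadcast"} multiplies elementwise by the scalar-scaled bias
#' @param fc_hidden hidden neurons of the fully connected decoder
#' @param lr Adam learning rate
#' @param epochs training epochs (no early stopping; the best-validation
#'   checkpoint is kept)
#' @param batch_size minibatch size
#' @param lambda L2 regularization weight
#' @param seed integer seed for parameter initialization and shuffling
#' @return object of class \code{dti_config} (a validated list)
#' @seealso \code{\link{dti_config_small}} for a desk-scale preset
#' @export
dti_config <- function(max_len = 1200L,
                       aa_embed_dim = 128L,
                       kernel_sizes = c(3L, 6L, 9L),
                       n_filters = c(128L, 128L, 128L),
                       sa_heads = 2L,
                       use_esacm = TRUE,
                       sa_residual = FALSE,
                       batch_norm = TRUE,
                       max_nodes = 290L,
                       atom_embed_dim = 128L,
                       hidden_dims = c(128L, 128L, 128L),
                       fingerprint_dim = 128L,
                       use_fingerprint = TRUE,
                       bilinear_dim = 768L,
                       bilinear_heads = 2L,
                       att_pool = TRUE,
                       att_pool_dim = 16L,
                       att_pool_window = 3L,
                       att_pool_stride = 3L,
                       att_pool_variant = c("global", "windowed"),
                       att_pool_form = c("rescale", "broadcast"),
                       fc_hidden = 512L,
                       lr = 5e-5,
                       epochs = 100L,
                       batch_size = 64L,
                       lambda = 1e-4,
                       seed = 1L) {
  cfg <- list(max_len = as.integer(max_len),
              aa_embed_dim = as.integer(aa_embed_dim),
              kernel_sizes = as.integer(kernel_sizes),
              n_filters = as.integer(n_filters),
              sa_heads = as.integer(sa_heads),
              use_esacm = isTRUE(use_esacm),
              sa_residual = isTRUE(sa_residual),
              batch_norm = isTRUE(batch_norm),
              max_nodes = as.integer(max_nodes),
              atom_embed_dim = as.integer(atom_embed_dim),
              hidden_dims = as.integer(hidden_dims),
              fingerprint_dim = as.integer(fingerprint_dim),
              use_fingerprint = isTRUE(use_fingerprint),
              bilinear_dim = as.integer(bilinear_dim),
              bilinear_heads = as.integer(bilinear_heads),
              att_pool = isTRUE(att_pool),
              att_pool_dim = as.integer(att_pool_dim),
              att_pool_window = as.integer(att_pool_window),
              att_pool_stride = as.integer(att_pool_stride),
              att_pool_variant = match.arg(att_pool_variant),
              att_pool_form = match.arg(att_pool_form),
              fc_hidden = as.integer(fc_hidden),
              lr = lr,
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              lambda = lambda,
              seed = as.integer(seed))
  if (length(cfg$kernel_sizes) != length(cfg$n_filters))
    stop("dti_config: 'kernel_sizes' and 'n_filters' must have equal length")
  e <- cfg$n_filters[length(cfg$n_filters)]
  if (cfg$use_esacm && e %% cfg$sa_heads != 0L)
    stop("dti_config: 'sa_heads' must divide the last filter count")
  num_pos <- c(cfg$max_len, cfg$aa_embed_dim, cfg$kernel_sizes, cfg$n_filters,
               cfg$sa_heads, cfg$max_nodes, cfg$atom_embed_dim,
               cfg$hidden_dims, cfg$fingerprint_dim, cfg$bilinear_dim,
               cfg$bilinear_heads, cfg$att_pool_dim, cfg$att_pool_window,
               cfg$att_pool_stride, cfg$fc_hidden, cfg$epochs, cfg$batch_size)
  if (any(num_pos <= 0L)) stop("dti_config: size hyperparameters must be positive")
  if (cfg$lr < 0 || cfg$lambda < 0)
    stop("dti_config: 'lr' and 'lambda' must be nonnegative")
  structure(cfg, class = "dti_config")
}

#' Desk-scale configuration preset
#'
#' A reduced configuration for synthetic benchmarks and examples: 32-dim
#' hidden layers, 64-dim bilinear embedding, protein capacity 120 residues,
#' and a learning rate of 1e-3 suited to datasets of a few hundred pairs.
#' Architectural structure (three convolutions, self-attention, three
#' message-passing layers, two bilinear heads, attention pooling) is
#' unchanged.
#'
#' @param ... overrides passed on to \code{\link{dti_config}}
#' @return a \code{dti_config}
#' @export
dti_config_small <- function(...) {
  defaults <- list(max_len = 120L, aa_embed_dim = 32L,
                   kernel_sizes = c(3L, 6L, 9L), n_filters = c(32L, 32L, 32L),
                   sa_heads = 2L, atom_embed_dim = 32L,
                   hidden_dims = c(32L, 32L, 32L), fingerprint_dim = 32L,
                   bilinear_dim = 64L, bilinear_heads = 2L, att_pool_dim = 8L,
                   fc_hidden = 64L, lr = 1e-3, epochs = 60L, batch_size = 32L)
  args <- utils::modifyList(defaults, list(...))
  do.call(dti_config, args)
}

#' @export
print.dti_config <- function(x, ...) {
  cat("DTI model configuration\n")
  cat("  protein: max_len", x$max_len, "| embed", x$aa_embed_dim,
      "| kernels", paste(x$kernel_sizes, collapse = "/"),
      "| filters", paste(x$n_filters, collapse = "/"),
      "| SA heads", if (x$use_esacm) x$sa_heads else "off", "\n")
  cat("  drug:    max_nodes", x$max_nodes, "| embed", x$atom_embed_dim,
      "| hidden", paste(x$hidden_dims, collapse = "/"),
      "| fingerprint", if (x$use_fingerprint) x$fingerprint_dim else "off", "\n")
  cat("  fusion:  bilinear", x$bilinear_dim, "x", x$bilinear_heads, "heads |",
      if (x$att_pool) paste0("attention pooling (", x$att_pool_variant, ")")
      else "sum pooling", "\n")
  cat("  train:   lr", x$lr, "| epochs", x$epochs, "| batch", x$batch_size,
      "| lambda", x$lambda, "\n")
  invisible(x)
}
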