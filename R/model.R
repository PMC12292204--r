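#' CNN model configuration
#'
#' Architecture hyperparameters of the seven-layer interpretable network:
#' a pointwise (1 x 1 over channels) convolution with `spatial_filters`
#' output maps demixes the montage into S virtual sources; a depthwise
#' temporal convolution slides `depth_multiplier` kernels of length
#' `temporal_kernel_len` over each demixed source independently (true
#' grouped convolution, one group per source); ReLU, batch normalization,
#' global average pooling over time, a dense read-out and log-softmax
#' complete the network.
#'
#' @param n_channels,n_samples input epoch geometry.
#' @param spatial_filters S, number of demixed sources.
#' @param temporal_kernel_len L, depthwise kernel length (must be <
#'   `n_samples`).
#' @param depth_multiplier D, kernels per demixed source (S*D feature
#'   maps).
#' @param n_classes number of output classes.
#' @param batchnorm_eps,batchnorm_momentum batch-norm numerical floor and
#'   running-statistics update rate.
#' @param pointwise_bias,depthwise_bias whether the two convolutions carry
#'   bias terms.
#' @param init_scheme initialization; `"uniform_fanin"` draws every weight
#'   from U(-1/sqrt(fan_in), 1/sqrt(fan_in)), biases start at zero.
#' @param init_seed integer seed making initialization reproducible.
#' @return List of class `eegcnn_config`.
#' @export
model_config <- function(n_channels = 60L, n_samples = 320L,
                         spatial_filters = 16L, temporal_kernel_len = 64L,
                         depth_multiplier = 2L, n_classes = 2L,
                         batchnorm_eps = 1e-5, batchnorm_momentum = 0.1,
                         pointwise_bias = TRUE, depthwise_bias = FALSE,
                         init_scheme = "uniform_fanin", init_seed = 1L) {
  stopifnot(spatial_filters >= 1, depth_multiplier >= 1, n_classes >= 1,
            n_channels >= 1)
  if (n_samples <= temporal_kernel_len) {
    stop("`n_samples` must exceed `temporal_kernel_len`", call. = FALSE)
  }
  out <- list(n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples),
              spatial_filters = as.integer(spatial_filters),
              temporal_kernel_len = as.integer(temporal_kernel_len),
              depth_multiplier = as.integer(depth_multiplier),
              n_classes = as.integer(n_classes),
              batchnorm_eps = batchnorm_eps,
              batchnorm_momentum = batchnorm_momentum,
              pointwise_bias = isTRUE(pointwise_bias),
              depthwise_bias = isTRUE(depthwise_bias),
              init_scheme = init_scheme,
              init_seed = as.integer(init_seed))
  class(out) <- "eegcnn_config"
  out
}

#' Layer-by-layer output shapes
#'
#' Returns the output shape of each of the seven layers for a symbolic
#' batch size N.  With the default configuration the trace is
#' (N,16,1,320), (N,32,1,257), (N,32,1,257), (N,32,1,257), (N,32), (N,2),
#' (N,2): the depthwise stage shortens time to
#' `n_samples - temporal_kernel_len + 1` (valid convolution).
#'
#' @param config an [model_config()].
#' @return Named list of integer vectors; `NA` marks the batch dimension.
#' @export
layer_shapes <- function(config) {
  S <- config$spatial_filters
  M <- S * config$depth_multiplier
  Tn <- config$n_samples
  Tp <- Tn - config$temporal_kernel_len + 1L
  K <- config$n_classes
  list(pointwise_conv = c(NA, S, 1L, Tn),
       depthwise_conv = c(NA, M, 1L, Tp),
       relu           = c(NA, M, 1L, Tp),
       batchnorm      = c(NA, M, 1L, Tp),
       global_avg_pool = c(NA, M),
       dense          = c(NA, K),
       softmax        = c(NA, K))
}

#' Allocate and initialize model parameters
#'
#' @param config an [model_config()].
#' @return List of class `eegcnn_params` with elements `pointwise`
#'   (S x n_channels), `pointwise_bias`, `depthwise` (L x S*D; kernel m
#'   filters demixed source `floor((m-1)/D) + 1`), `depthwise_bias`,
#'   `bn_gamma`, `bn_beta`, `bn_mean`, `bn_var`, `dense`
#'   (n_classes x S*D), `dense_bias`, and the `config`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "eegcnn_config"))
  S <- config$spatial_filters
  C <- config$n_channels
  L <- config$temporal_kernel_len
  M <- S * config$depth_multiplier
  K <- config$n_classes
  if (config$init_scheme != "uniform_fanin") {
    stop("unknown init_scheme: ", config$init_scheme, call. = FALSE)
  }
  u <- function(n, fan_in) stats::runif(n, -1, 1) / sqrt(fan_in)
  params <- with_seed(config$init_seed, {
    list(pointwise = matrix(u(S * C, C), S, C),
         pointwise_bias = if (config$pointwise_bias) numeric(S) else NULL,
         depthwise = matrix(u(L * M, L), L, M),
         depthwise_bias = if (config$depthwise_bias) numeric(M) else NULL,
         bn_gamma = rep(1, M), bn_beta = numeric(M),
         bn_mean = numeric(M), bn_var = rep(1, M),
         dense = matrix(u(K * M, M), K, M),
         dense_bias = numeric(K))
  })
  params$config <- config
  class(params) <- "eegcnn_params"
  params
}

# Column-wise affine transform X[, m] * mult[m] + add[m] without sweep()'s
# aperm overhead.
col_affine <- function(X, mult, add) {
  n <- nrow(X)
  X * rep(mult, each = n) + rep(add, each = n)
}

# Coerce input epochs to a (C, T, B) array.
as_epoch_array <- function(x, config) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[1] != config$n_channels || dim(x)[2] != config$n_samples) {
    stop(sprintf("epochs are %d x %d but the model expects %d x %d",
                 dim(x)[1], dim(x)[2], config$n_channels, config$n_samples),
         call. = FALSE)
  }
  x
}

# Forward pass.  x: (C, T, B) array.  Returns log-probabilities (K x B)
# plus, if keep = TRUE, every intermediate needed for backprop and for
# relevance reconstruction.  In train mode batch statistics normalize and
# the running statistics are updated (returned in `cache$bn_mean/bn_var`);
# in eval mode the stored running statistics are used.
nn_forward <- function(params, x, train_mode = FALSE, keep = FALSE) {
  cfg <- params$config
  x <- as_epoch_array(x, cfg)
  C <- cfg$n_channels; Tn <- cfg$n_samples
  S <- cfg$spatial_filters; D <- cfg$depth_multiplier
  M <- S * D; L <- cfg$temporal_kernel_len
  Tp <- Tn - L + 1L
  B <- dim(x)[3]

  # (T*B, C) with rows ordered time-within-batch; all later stages share
  # this time-major layout so no array transposes are needed
  Xt <- t(matrix(x, C, Tn * B))
  Dm <- Xt %*% t(params$pointwise)                 # (T*B, S)
  if (!is.null(params$pointwise_bias)) {
    Dm <- Dm + rep(params$pointwise_bias, each = Tn * B)
  }
  dm_arr <- Dm
  dim(dm_arr) <- c(Tn, B, S)

  conv <- dw_conv_forward_cpp(dm_arr, params$depthwise, D)   # (Tp, B, M)
  if (!is.null(params$depthwise_bias)) {
    conv <- conv + rep(params$depthwise_bias, each = Tp * B)
  }

  # work in (Tp*B, M) matrix space for the per-map stages
  relu_tm <- pmax(conv, 0)
  dim(relu_tm) <- c(Tp * B, M)

  n_eff <- Tp * B
  if (train_mode) {
    mu <- .colMeans(relu_tm, n_eff, M)
    vb <- .colMeans(relu_tm^2, n_eff, M) - mu^2    # biased, for normalization
    vb <- pmax(vb, 0)
    v_unb <- vb * n_eff / max(1, n_eff - 1)
    mom <- cfg$batchnorm_momentum
    run_mean <- (1 - mom) * params$bn_mean + mom * mu
    run_var <- (1 - mom) * params$bn_var + mom * v_unb
  } else {
    mu <- params$bn_mean
    vb <- params$bn_var
    run_mean <- params$bn_mean
    run_var <- params$bn_var
  }
  invstd <- 1 / sqrt(vb + cfg$batchnorm_eps)
  xhat <- col_affine(relu_tm, invstd, -mu * invstd)
  bn_tm <- col_affine(xhat, params$bn_gamma, params$bn_beta)

  # global average pool over time: (Tp, B, M) blocks -> (M, B)
  pooled <- t(matrix(.colMeans(bn_tm, Tp, B * M), B, M))

  logits <- params$dense %*% pooled
  logits <- logits + params$dense_bias
  mx <- apply(logits, 2, max)
  sh <- sweep(logits, 2, mx)
  lse <- log(colSums(exp(sh)))
  log_probs <- sweep(sh, 2, lse)

  out <- list(log_probs = log_probs, bn_mean = run_mean, bn_var = run_var)
  if (keep) {
    out <- c(out, list(Xt = Xt, dm_arr = dm_arr, conv = conv,
                       relu_tm = relu_tm, xhat = xhat,
                       bn_tm = bn_tm, pooled = pooled, mu = mu, vb = vb,
                       invstd = invstd, dims = c(Tp = Tp, M = M, B = B)))
  }
  out
}

# Backward pass for the mean NLL loss.  `cache` comes from nn_forward(...,
# train_mode = TRUE, keep = TRUE); `y` are 1-based class indices.  Returns
# gradients named like the parameters.
nn_backward <- function(params, cache, y) {
  cfg <- params$config
  Tp <- cache$dims[["Tp"]]; M <- cache$dims[["M"]]; B <- cache$dims[["B"]]
  S <- cfg$spatial_filters; D <- cfg$depth_multiplier
  K <- cfg$n_classes

  probs <- exp(cache$log_probs)                    # K x B
  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B

  g_dense <- dlogits %*% t(cache$pooled)
  g_dense_bias <- rowSums(dlogits)
  dpooled <- t(params$dense) %*% dlogits           # M x B

  # pooling spreads gradient uniformly over time
  dbn_tm <- t(dpooled)[rep(seq_len(B), each = Tp), , drop = FALSE] / Tp

  # batch-norm backward (batch statistics)
  g_gamma <- colSums(dbn_tm * cache$xhat)
  g_beta <- colSums(dbn_tm)
  n_eff <- Tp * B
  dxhat <- col_affine(dbn_tm, params$bn_gamma, 0 * params$bn_gamma)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
  drelu <- col_affine(dxhat - col_affine(cache$xhat, sum_dxhat_xhat / n_eff,
                                         sum_dxhat / n_eff),
                      cache$invstd, 0 * cache$invstd)
  drelu <- drelu * (cache$relu_tm > 0)

  g_dw_bias <- if (!is.null(params$depthwise_bias)) colSums(drelu) else NULL
  dconv <- drelu
  dim(dconv) <- c(Tp, B, M)

  g_depthwise <- dw_grad_kernels_cpp(cache$dm_arr, dconv,
                                     cfg$temporal_kernel_len, D)
  gx <- dw_grad_input_cpp(dconv, params$depthwise, S, cfg$n_samples, D)
  ddemixed <- gx
  dim(ddemixed) <- c(cfg$n_samples * B, S)         # (T*B, S)

  g_pointwise <- crossprod(ddemixed, cache$Xt)     # S x C
  g_pw_bias <- if (!is.null(params$pointwise_bias)) colSums(ddemixed) else NULL

  list(pointwise = g_pointwise, pointwise_bias = g_pw_bias,
       depthwise = g_depthwise, depthwise_bias = g_dw_bias,
       bn_gamma = g_gamma, bn_beta = g_beta,
       dense = g_dense, dense_bias = g_dense_bias)
}

# Mean negative log-likelihood of 1-based class indices y under K x B
# log-probabilities.
nll_loss <- function(log_probs, y) {
  -mean(log_probs[cbind(y, seq_len(ncol(log_probs)))])
}

#' Intermediate activations for one epoch
#'
#' Runs the network in evaluation mode on a single epoch and returns every
#' intermediate signal in its natural shape -- the quantities the
#' relevance reconstruction operates on.
#'
#' @param params an `eegcnn_params` (or a fitted [eegcnn()] model).
#' @param epoch channels x samples matrix.
#' @return List with `demixed` (S x T), `conv_out`, `relu_out`, `bn_out`
#'   (each S*D x T'), `pooled` (length S*D), `log_probs` (length
#'   n_classes).
#' @export
nn_activations <- function(params, epoch) {
  if (inherits(params, "eegcnn")) params <- params$params
  stopifnot(inherits(params, "eegcnn_params"))
  fw <- nn_forward(params, epoch, train_mode = FALSE, keep = TRUE)
  Tp <- fw$dims[["Tp"]]; M <- fw$dims[["M"]]
  Tn <- params$config$n_samples
  S <- params$config$spatial_filters
  list(demixed = t(matrix(fw$dm_arr, Tn, S)),
       conv_out = t(matrix(fw$conv, Tp, M)),
       relu_out = t(matrix(fw$relu_tm, Tp, M)),
       bn_out = t(matrix(fw$bn_tm, Tp, M)),
       pooled = fw$pooled[, 1],
       log_probs = fw$log_probs[, 1])
}

#' Save / load a model checkpoint
#'
#' Single-file serialization of the named parameter arrays together with
#' the model configuration (and, for fitted models, the training history).
#' The round trip is bit-exact: a reloaded model reproduces forward passes
#' identically.
#'
#' @param object an `eegcnn_params` or fitted `eegcnn` object.
#' @param path file path.
#' @return `load_eegcnn` returns the restored object.
#' @export
save_eegcnn <- function(object, path) {
  stopifnot(inherits(object, c("eegcnn", "eegcnn_params")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_eegcnn
#' @export
load_eegcnn <- function(path) {
  out <- readRDS(path)
  if (!inherits(out, c("eegcnn", "eegcnn_params"))) {
    stop("file does not contain a model checkpoint", call. = FALSE)
  }
  out
}
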