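## The contact-prediction network: a fully convolutional residual model.
##
##   input (C x L x L)
##     -> convolutional Maxout layer (1x1, `maxout_pieces` linear pieces),
##        reducing C channels to `width`
##     -> instance normalization
##     -> `n_blocks` residual blocks; each block is
##        conv(5x5, dilation d) -> ReLU -> conv(5x5, dilation d),
##        plus a skip connection from block input, then a final ReLU
##     -> 1x1 conv to a single channel, instance normalization, sigmoid.
##
## The model is length-agnostic: any L gives an L x L output. Forward and
## backward passes are implemented here (conv kernels in C++); no
## external deep-learning framework is used.

#' Network configuration
#'
#' The default configuration is the full-scale model: 501 input
#' channels, width 64, 18 residual blocks whose dilation schedule
#' alternates regular and dilated 5x5 convolutions with rates
#' 1, 2, 4, 8, 16, 32, 64 and finishes with non-dilated blocks.
#'
#' @param in_channels Number of input feature channels.
#' @param width Feature maps per conv layer.
#' @param n_blocks Number of residual blocks.
#' @param dilation_schedule Integer dilation rate per block (both convs
#'   of a block share its rate).
#' @param maxout_pieces Linear pieces in the Maxout input layer.
#' @param kernel Residual-block kernel size (odd).
#' @return A `model_config` list.
#' @export
model_config <- function(in_channels = 501L, width = 64L, n_blocks = 18L,
                         dilation_schedule = default_dilation_schedule(n_blocks),
                         maxout_pieces = 2L, kernel = 5L) {
  stopifnot(length(dilation_schedule) == n_blocks,
            all(dilation_schedule >= 1L), kernel %% 2L == 1L,
            maxout_pieces >= 1L, width >= 1L, in_channels >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 width = as.integer(width), n_blocks = as.integer(n_blocks),
                 dilation_schedule = as.integer(dilation_schedule),
                 maxout_pieces = as.integer(maxout_pieces),
                 kernel = as.integer(kernel)),
            class = "model_config")
}

#' Default per-block dilation schedule
#'
#' Blocks 1-12 alternate regular and dilated convolutions as
#' 1, 2, 1, 4, 1, 8, 1, 16, 1, 32, 1, 64; remaining blocks are regular
#' (rate 1). Uses exactly the rates 1, 2, 4, 8, 16, 32, 64 with all
#' trailing blocks non-dilated.
#'
#' @param n_blocks Number of residual blocks (>= 12 for the full ramp).
#' @return Integer vector of dilation rates.
#' @export
default_dilation_schedule <- function(n_blocks = 18L) {
  ramp <- as.integer(rbind(1L, c(2L, 4L, 8L, 16L, 32L, 64L)))
  if (n_blocks <= length(ramp)) return(ramp[seq_len(n_blocks)])
  c(ramp, rep(1L, n_blocks - length(ramp)))
}

xavier_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build a model with Xavier-initialized weights
#'
#' Weights are drawn from the Xavier uniform distribution using the
#' current R RNG (seed beforehand for reproducibility); biases start at
#' zero, instance-norm scales at one.
#'
#' @param cfg A [model_config()].
#' @param channel_map Optional channel-name vector recorded with the
#'   model; prediction then refuses tensors with a different map.
#' @return A `contact_model` object.
#' @export
build_model <- function(cfg = model_config(), channel_map = NULL) {
  k <- cfg$kernel; w <- cfg$width; cin <- cfg$in_channels
  params <- list(
    maxout_W = lapply(seq_len(cfg$maxout_pieces), function(p)
      xavier_uniform(w, cin, fan_in = cin, fan_out = w)),
    maxout_b = lapply(seq_len(cfg$maxout_pieces), function(p) numeric(w)),
    in_gamma = rep(1, w), in_beta = numeric(w),
    blocks = lapply(seq_len(cfg$n_blocks), function(b) {
      fan <- w * k * k
      list(W1 = xavier_uniform(w, w * k * k, fan, fan), b1 = numeric(w),
           W2 = xavier_uniform(w, w * k * k, fan, fan), b2 = numeric(w))
    }),
    out_W = xavier_uniform(1, w, fan_in = w, fan_out = 1), out_b = 0,
    out_gamma = 1, out_beta = 0)
  structure(list(cfg = cfg, params = params, channel_map = channel_map),
            class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf(paste0("contact_model: %d -> %d channels, %d residual blocks ",
                     "(dilations %s), %s parameters\n"),
              x$cfg$in_channels, x$cfg$width, x$cfg$n_blocks,
              paste(x$cfg$dilation_schedule, collapse = ","),
              format(n_parameters(x$cfg), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters implied by a configuration
#'
#' @param cfg A [model_config()] (or a `contact_model`).
#' @return Integer parameter count.
#' @export
n_parameters <- function(cfg) {
  if (inherits(cfg, "contact_model")) cfg <- cfg$cfg
  k <- cfg$kernel; w <- cfg$width
  cfg$maxout_pieces * (w * cfg$in_channels + w) +   # maxout weights + biases
    2 * w +                                         # input instance norm
    cfg$n_blocks * 2 * (w * w * k * k + w) +        # block convs
    (w + 1) + 2                                     # output conv + norm
}

#' Receptive field of the dilated stack (in residues)
#'
#' Each k x k convolution with dilation d widens the receptive field by
#' (k - 1) * d; the 1x1 Maxout and output layers add nothing.
#'
#' @param cfg A [model_config()].
#' @return Integer receptive-field side length.
#' @export
receptive_field <- function(cfg = model_config()) {
  1L + sum(2L * (cfg$kernel - 1L) * cfg$dilation_schedule)
}

IN_EPS <- 1e-5

instnorm_fwd <- function(m, gamma, beta) {
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  sd <- sqrt(pmax(v, 0) + IN_EPS)
  xhat <- sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
  list(out = sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+"),
       xhat = xhat, sd = sd)
}

instnorm_bwd <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  list(dx = sweep(t1 - t2, 2L, cache$sd, "/"), dgamma = dgamma, dbeta = dbeta)
}

#' Forward pass
#'
#' @param model A `contact_model`.
#' @param x A `feature_tensor` or an L x L x C array.
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return List with `scores` (raw L x L sigmoid output, not yet
#'   symmetrized) and, if requested, `cache`.
#' @export
model_forward <- function(model, x, keep_cache = FALSE) {
  if (inherits(x, "feature_tensor")) {
    if (!is.null(model$channel_map) &&
        !identical(model$channel_map, x$channel_map)) {
      stop("feature tensor channel map does not match the model's")
    }
    x <- x$data
  }
  p <- model$params; cfg <- model$cfg
  L <- dim(x)[1]
  if (dim(x)[3] != cfg$in_channels) {
    stop("expected ", cfg$in_channels, " input channels, got ", dim(x)[3])
  }
  LL <- L * L
  xmat <- matrix(x, LL, cfg$in_channels)

  ## Maxout input layer (1x1 conv pieces, elementwise max)
  zs <- lapply(seq_len(cfg$maxout_pieces), function(pc)
    sweep(tcrossprod(xmat, p$maxout_W[[pc]]), 2L, p$maxout_b[[pc]], "+"))
  m <- zs[[1L]]
  amax <- matrix(1L, LL, cfg$width)
  if (cfg$maxout_pieces > 1L) {
    for (pc in 2:cfg$maxout_pieces) {
      upd <- zs[[pc]] > m
      amax[upd] <- pc
      m[upd] <- zs[[pc]][upd]
    }
  }
  innorm <- instnorm_fwd(m, p$in_gamma, p$in_beta)
  a <- array(innorm$out, dim = c(L, L, cfg$width))

  blocks_cache <- if (keep_cache) vector("list", cfg$n_blocks) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    bp <- p$blocks[[b]]
    d <- cfg$dilation_schedule[b]
    c1 <- conv2d_forward(a, bp$W1, bp$b1, cfg$kernel, d)
    h1 <- pmax(c1, 0)
    c2 <- conv2d_forward(h1, bp$W2, bp$b2, cfg$kernel, d)
    out <- pmax(a + c2, 0)
    if (keep_cache) blocks_cache[[b]] <- list(x_in = a, h1 = h1, out = out)
    a <- out
  }

  amat <- matrix(a, LL, cfg$width)
  z <- as.vector(amat %*% t(p$out_W)) + p$out_b
  onorm <- instnorm_fwd(matrix(z, ncol = 1L), p$out_gamma, p$out_beta)
  s <- as.vector(onorm$out)
  scores <- matrix(1 / (1 + exp(-s)), L, L)

  cache <- NULL
  if (keep_cache) {
    cache <- list(L = L, xmat = xmat, amax = amax, innorm = innorm,
                  blocks = blocks_cache, amat = amat, onorm = onorm,
                  scores = scores)
  }
  list(scores = scores, cache = cache)
}

#' Backward pass
#'
#' Backpropagates a gradient with respect to the pre-sigmoid output
#' through the whole network.
#'
#' @param model A `contact_model`.
#' @param cache Cache from [model_forward()] with `keep_cache = TRUE`.
#' @param gs L x L matrix (or vector): dLoss / d(pre-sigmoid activation).
#' @return Gradient list with the same structure as `model$params`.
#' @export
model_backward <- function(model, cache, gs) {
  p <- model$params; cfg <- model$cfg
  L <- cache$L; LL <- L * L
  gs <- matrix(as.vector(gs), ncol = 1L)

  ob <- instnorm_bwd(gs, cache$onorm, p$out_gamma)
  dz <- as.vector(ob$dx)
  g_out_W <- matrix(dz, 1L, LL) %*% cache$amat
  g_out_b <- sum(dz)
  da <- array(dz %*% p$out_W, dim = c(L, L, cfg$width))

  g_blocks <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    bc <- cache$blocks[[b]]
    bp <- p$blocks[[b]]
    d <- cfg$dilation_schedule[b]
    dpre <- da * (bc$out > 0)
    r2 <- conv2d_backward(bc$h1, bp$W2, dpre, cfg$kernel, d)
    gh1 <- r2$gx * (bc$h1 > 0)
    r1 <- conv2d_backward(bc$x_in, bp$W1, gh1, cfg$kernel, d)
    g_blocks[[b]] <- list(W1 = r1$gw, b1 = as.vector(r1$gb),
                          W2 = r2$gw, b2 = as.vector(r2$gb))
    da <- dpre + r1$gx
  }

  damat <- matrix(da, LL, cfg$width)
  ib <- instnorm_bwd(damat, cache$innorm, p$in_gamma)
  dm <- ib$dx
  g_maxW <- vector("list", cfg$maxout_pieces)
  g_maxb <- vector("list", cfg$maxout_pieces)
  for (pc in seq_len(cfg$maxout_pieces)) {
    dz_pc <- dm * (cache$amax == pc)
    g_maxW[[pc]] <- crossprod(dz_pc, cache$xmat)
    g_maxb[[pc]] <- colSums(dz_pc)
  }

  list(maxout_W = g_maxW, maxout_b = g_maxb,
       in_gamma = ib$dgamma, in_beta = ib$dbeta,
       blocks = g_blocks,
       out_W = g_out_W, out_b = g_out_b,
       out_gamma = ob$dgamma, out_beta = ob$dbeta)
}

#' Symmetrize a raw score matrix
#'
#' Averages the predictions for (i, j) and (j, i).
#'
#' @param raw Square numeric matrix.
#' @return Symmetric matrix of the same size.
#' @export
symmetrize <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("score matrix must be square")
  (raw + t(raw)) / 2
}

#' Predict a symmetrized contact score map with one model
#'
#' @param model A `contact_model`.
#' @param x A `feature_tensor` or array.
#' @return Symmetric L x L matrix of probabilities in \[0, 1\].
#' @export
predict_contacts <- function(model, x) {
  symmetrize(model_forward(model, x)$scores)
}

#' Ensemble prediction
#'
#' Elementwise mean of the symmetrized score maps of several
#' independently trained models (canonically five).
#'
#' @param models Nonempty list of `contact_model`s.
#' @param x A `feature_tensor` or array.
#' @return Symmetric L x L score matrix.
#' @export
ensemble_predict <- function(models, x) {
  if (length(models) == 0L) stop("need at least one model")
  maps <- lapply(models, predict_contacts, x = x)
  Reduce(`+`, maps) / length(maps)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration and (when present) the
#' channel map the model was trained on; loading a checkpoint and
#' predicting on a tensor with a different channel map fails.
#'
#' @param model A `contact_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "contact_model")) stop("not a model checkpoint: ", path)
  model
}
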