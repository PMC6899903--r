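## Training: masked binary cross-entropy, Matthews correlation
## coefficient, Adam optimization with per-example gradient accumulation,
## and MCC-based early stopping.
##
## Examples are passed through the network one at a time and gradients
## accumulated over a batch (mean of per-example losses), so examples of
## differing length need no padding. The checkpoint with the best
## validation MCC is returned, not the final epoch's.

#' Training configuration
#'
#' @param batch_size Examples per optimizer step.
#' @param lr Initial Adam learning rate.
#' @param min_sep Minimum sequence separation entering the loss/MCC
#'   (pairs with |i - j| < `min_sep` are excluded; default 5, i.e.
#'   separation greater than 4).
#' @param patience Consecutive epochs without validation-MCC improvement
#'   before stopping.
#' @param max_epochs Hard epoch cap.
#' @param mcc_threshold Score threshold binarizing predictions for MCC.
#' @param seed RNG seed controlling initialization, shuffling and
#'   augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 8L, lr = 0.001, min_sep = 5L,
                         patience = 10L, max_epochs = 100L,
                         mcc_threshold = 0.5, seed = 1L) {
  stopifnot(batch_size >= 1L, lr > 0, min_sep >= 1L, patience >= 1L,
            max_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 min_sep = as.integer(min_sep), patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 mcc_threshold = mcc_threshold, seed = as.integer(seed)),
            class = "train_config")
}

## Upper-triangle eligibility mask: i < j and |i - j| >= min_sep.
sep_mask <- function(L, min_sep) {
  d <- outer(seq_len(L), seq_len(L), function(i, j) j - i)
  d >= min_sep
}

#' Masked binary cross-entropy
#'
#' Mean of `-[y log p + (1 - y) log(1 - p)]` over upper-triangle residue
#' pairs with sequence separation at least `min_sep`. Probabilities are
#' clamped to \[1e-7, 1 - 1e-7\] before the logs.
#'
#' @param pred L x L predicted probabilities.
#' @param truth L x L binary contact map.
#' @param min_sep Minimum separation (default 5).
#' @return Scalar loss.
#' @export
masked_bce <- function(pred, truth, min_sep = 5L) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  mask <- sep_mask(nrow(pred), min_sep)
  if (!any(mask)) stop("no residue pairs with separation >= ", min_sep)
  p <- pmin(pmax(pred[mask], 1e-7), 1 - 1e-7)
  y <- truth[mask]
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Gradient of masked_bce w.r.t. the pre-sigmoid activation, as an L x L
## matrix ((p - y) / n on eligible pairs, 0 elsewhere). Exact for
## unclamped p; the clamp only guards the loss value itself.
bce_grad_presigmoid <- function(pred, truth, min_sep = 5L) {
  mask <- sep_mask(nrow(pred), min_sep)
  g <- matrix(0, nrow(pred), ncol(pred))
  g[mask] <- (pred[mask] - truth[mask]) / sum(mask)
  g
}

#' Matthews correlation coefficient of thresholded contact predictions
#'
#' Predictions are binarized at `threshold` over eligible upper-triangle
#' pairs (separation >= `min_sep`); MCC is 0 when any confusion-matrix
#' marginal is zero.
#'
#' @param pred L x L score matrix.
#' @param truth L x L binary contact map.
#' @param threshold Binarization threshold (default 0.5).
#' @param min_sep Minimum separation (default 5).
#' @return Scalar in \[-1, 1\].
#' @export
mcc <- function(pred, truth, threshold = 0.5, min_sep = 5L) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  mask <- sep_mask(nrow(pred), min_sep)
  yhat <- pred[mask] >= threshold
  y <- truth[mask] == 1
  tp <- sum(yhat & y); tn <- sum(!yhat & !y)
  fp <- sum(yhat & !y); fn <- sum(!yhat & y)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

## ---- parameter-tree utilities and Adam ------------------------------------

## Apply f to corresponding numeric leaves of parallel nested lists.
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- lapply(seq_along(trees[[1L]]), function(i)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(trees[[1L]])
    out
  } else {
    do.call(f, trees)
  }
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

adam_init <- function(params, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = tree_zero(params), v = tree_zero(params))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  params <- tree_map(function(p, m, v)
    p - state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps),
    params, state$m, state$v)
  list(state = state, params = params)
}

## ---- training loop ---------------------------------------------------------

#' Train a contact-prediction model
#'
#' Optimizes the masked binary cross-entropy with Adam. Each batch is
#' augmented on the fly, then examples are forwarded one at a time with
#' gradients accumulated (mean of per-example losses) before a single
#' optimizer step. After every epoch the mean per-protein MCC of the
#' symmetrized predictions on the validation set is computed; training
#' stops once it has not improved for `patience` consecutive epochs (or
#' at `max_epochs`), and the weights with the best validation MCC are
#' returned.
#'
#' @param model A `contact_model` (e.g. from [build_model()]).
#' @param train_set,val_set Nonempty lists of [training_example()]s
#'   (lengths may differ between examples).
#' @param cfg A [train_config()].
#' @param augment_cfg An [augment_config()]; pass probabilities of 0 to
#'   disable augmentation.
#' @return List with `model` (best-MCC weights), `history` (data frame
#'   of epoch, mean train loss, validation MCC) and `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        augment_cfg = augment_config()) {
  stopifnot(length(train_set) > 0L, length(val_set) > 0L)
  set.seed(cfg$seed)
  opt <- adam_init(model$params, lr = cfg$lr)
  best_mcc <- -Inf
  best_params <- model$params
  best_epoch <- 0L
  since_improve <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mcc = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(train_set))
    epoch_losses <- c()
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      batch <- augment_batch(train_set[idx], augment_cfg)
      nb <- length(batch)
      acc <- NULL
      batch_loss <- 0
      for (ex in batch) {
        fw <- model_forward(model, ex$x, keep_cache = TRUE)
        loss <- masked_bce(fw$scores, ex$y, cfg$min_sep)
        if (!is.finite(loss)) stop("divergent loss (non-finite) at epoch ",
                                   epoch, "; aborting")
        batch_loss <- batch_loss + loss / nb
        gs <- bce_grad_presigmoid(fw$scores, ex$y, cfg$min_sep) / nb
        g <- model_backward(model, fw$cache, gs)
        acc <- if (is.null(acc)) g else tree_map(`+`, acc, g)
      }
      upd <- adam_step(opt, model$params, acc)
      opt <- upd$state
      model$params <- upd$params
      epoch_losses <- c(epoch_losses, batch_loss)
    }

    val_mcc <- mean(vapply(val_set, function(ex)
      mcc(predict_contacts(model, ex$x), ex$y, cfg$mcc_threshold,
          cfg$min_sep), numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(epoch_losses),
                                         val_mcc = val_mcc))
    if (val_mcc > best_mcc) {
      best_mcc <- val_mcc
      best_params <- model$params
      best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$patience) break
    }
  }

  model$params <- best_params
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_mcc = best_mcc)
}
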