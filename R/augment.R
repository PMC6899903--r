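## Training-time data augmentation: loop sampling (deletion of loop
## residues), feature interpolation between deep- and shallow-alignment
## tensors (mixup on inputs only), and 180-degree flips (chain reversal).

#' A training example
#'
#' Bundles an input [feature_tensor()], its true contact map, the loop
#' mask used for loop sampling, and optionally a second tensor built from
#' a shallower alignment of the same protein (the mixup partner).
#'
#' @param x A `feature_tensor`.
#' @param y L x L symmetric 0/1 contact map with zero diagonal.
#' @param loop_mask Length-L logical; TRUE marks loop residues.
#' @param x_alt Optional `feature_tensor` of identical shape/channels.
#' @return A `training_example` object.
#' @export
training_example <- function(x, y, loop_mask, x_alt = NULL) {
  y <- as.matrix(y)
  L <- x$L
  stopifnot(all(dim(y) == c(L, L)), length(loop_mask) == L)
  if (any(y != 0 & y != 1)) stop("contact map must be binary")
  if (any(y != t(y))) stop("contact map must be symmetric")
  if (any(diag(y) != 0)) stop("contact map diagonal must be zero")
  if (!is.null(x_alt) && !identical(x_alt$channel_map, x$channel_map)) {
    stop("x_alt channel map differs from x")
  }
  structure(list(x = x, y = y, loop_mask = as.logical(loop_mask),
                 x_alt = x_alt),
            class = "training_example")
}

#' Augmentation configuration
#'
#' Probabilities of the three augmentations. Loop sampling runs with
#' probability `p_loop_apply`, only on examples whose loop fraction is at
#' most `max_loop_frac`, and then deletes each loop residue independently
#' with probability `p_residue_del`. Mixup is applied with probability
#' `p_mixup` whenever the example carries a shallow-alignment partner
#' tensor. With probability `p_flip` a batch is extended by 180-degree
#' flipped copies of all its examples.
#'
#' @param p_loop_apply,p_residue_del,max_loop_frac,p_flip,p_mixup
#'   Probabilities/fractions in \[0, 1\].
#' @param rng_seed Optional integer; when set, [augment_batch()] seeds
#'   the RNG with it so the augmented batch is fully reproducible.
#' @return An `augment_config` list.
#' @export
augment_config <- function(p_loop_apply = 0.5, p_residue_del = 0.3,
                           max_loop_frac = 0.4, p_flip = 0.5, p_mixup = 1,
                           rng_seed = NULL) {
  probs <- c(p_loop_apply, p_residue_del, max_loop_frac, p_flip, p_mixup)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(p_loop_apply = p_loop_apply, p_residue_del = p_residue_del,
                 max_loop_frac = max_loop_frac, p_flip = p_flip,
                 p_mixup = p_mixup, rng_seed = rng_seed),
            class = "augment_config")
}

## Excise residues (rows+columns) from a feature tensor and rebuild the
## separation channel for the new length. Striped channels remain valid
## stripes under excision; the bounds channel remains all ones.
excise_residues <- function(ft, keep) {
  data <- ft$data[keep, keep, , drop = FALSE]
  dimnames(data)[[3]] <- ft$channel_map
  if ("separation" %in% ft$channel_map) {
    cap <- if (!is.null(ft$meta$sep_cap)) ft$meta$sep_cap else 100
    data[, , "separation"] <- separation_channel(sum(keep), cap = cap)
  }
  feature_tensor(data, ft$channel_map, ft$meta)
}

#' Loop-sampling augmentation
#'
#' Simulates tolerated loop deletions: with probability `p_loop_apply`,
#' and only when at most `max_loop_frac` of residues are loops, each loop
#' residue is independently deleted with probability `p_residue_del`.
#' Deleted residues' rows and columns are removed from every channel and
#' from the contact map, and the separation channel is recomputed for the
#' shortened sequence. At least one residue is always retained.
#'
#' @param ex A [training_example()].
#' @param cfg An [augment_config()].
#' @return A (possibly shortened) `training_example`.
#' @export
loop_sampling <- function(ex, cfg = augment_config()) {
  L <- ex$x$L
  if (mean(ex$loop_mask) > cfg$max_loop_frac) return(ex)
  if (runif(1) >= cfg$p_loop_apply) return(ex)
  del <- ex$loop_mask & (runif(L) < cfg$p_residue_del)
  if (all(del)) del[which(del)[1L]] <- FALSE
  if (!any(del)) return(ex)
  keep <- !del
  training_example(excise_residues(ex$x, keep),
                   ex$y[keep, keep, drop = FALSE],
                   ex$loop_mask[keep],
                   x_alt = if (is.null(ex$x_alt)) NULL else
                     excise_residues(ex$x_alt, keep))
}

#' Linear interpolation of two feature tensors (mixup on inputs)
#'
#' `m * x1 + (1 - m) * x2` elementwise. The contact map is never
#' interpolated: a mixed input keeps the original true map.
#'
#' @param x1,x2 `feature_tensor`s of identical shape and channel map.
#' @param m Mixing scalar in \[0, 1\].
#' @return A `feature_tensor`.
#' @export
interpolate_features <- function(x1, x2, m) {
  if (!identical(dim(x1$data), dim(x2$data)) ||
      !identical(x1$channel_map, x2$channel_map)) {
    stop("feature tensors differ in shape or channel map")
  }
  stopifnot(m >= 0, m <= 1)
  feature_tensor(m * x1$data + (1 - m) * x2$data, x1$channel_map, x1$meta)
}

#' 180-degree flip of a training example (chain reversal)
#'
#' Reverses every channel and the contact map along both spatial axes,
#' and reverses the loop mask. The separation channel is invariant
#' (|i - j| is symmetric under reversal) and the bounds channel is all
#' ones, so both remain valid without recomputation.
#'
#' @param ex A [training_example()].
#' @return The flipped `training_example`.
#' @export
flip_example <- function(ex) {
  L <- ex$x$L
  rev_idx <- L:1
  flip_ft <- function(ft) {
    data <- ft$data[rev_idx, rev_idx, , drop = FALSE]
    feature_tensor(data, ft$channel_map, ft$meta)
  }
  training_example(flip_ft(ex$x), ex$y[rev_idx, rev_idx],
                   rev(ex$loop_mask),
                   x_alt = if (is.null(ex$x_alt)) NULL else flip_ft(ex$x_alt))
}

#' Apply the augmentation pipeline to a batch
#'
#' Per example: mixup with the shallow-alignment partner (when present,
#' with probability `p_mixup`, mixing scalar drawn uniformly once per
#' example), then loop sampling. Finally one batch-level coin with
#' probability `p_flip` appends flipped copies of every (augmented)
#' example, doubling the batch.
#'
#' @param batch Nonempty list of [training_example()]s.
#' @param cfg An [augment_config()]; if `rng_seed` is set the RNG is
#'   seeded first, making the output reproducible.
#' @return List of `training_example`s (possibly longer than the input).
#' @export
augment_batch <- function(batch, cfg = augment_config()) {
  if (length(batch) == 0L) stop("empty batch")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  out <- lapply(batch, function(ex) {
    if (!is.null(ex$x_alt) && cfg$p_mixup > 0 && runif(1) < cfg$p_mixup) {
      m <- runif(1)
      ex <- training_example(interpolate_features(ex$x, ex$x_alt, m),
                             ex$y, ex$loop_mask, x_alt = ex$x_alt)
    }
    loop_sampling(ex, cfg)
  })
  if (cfg$p_flip > 0 && runif(1) < cfg$p_flip) {
    out <- c(out, lapply(out, flip_example))
  }
  out
}
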