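## Weighted column statistics and pairwise substitution features:
## single and pair frequencies, the 441-channel raw covariance tensor,
## mutual information (nats) with APC correction, and joint entropy.
##
## The gap is a first-class 21st state throughout, so pair tables are
## 21 x 21 = 441 cells. Sequence weighting (inverse 62%-identity
## neighbourhood size) down-weights redundant alignment rows before
## counting.

#' Inverse-neighbourhood sequence weights
#'
#' Weight of sequence s is `1 / n_s` where `n_s` counts alignment rows
#' (including s itself) at least `ident_threshold` identical to s under
#' [pairwise_identity()].
#'
#' @param m An [msa] object.
#' @param ident_threshold Identity threshold (default 0.62).
#' @return Numeric vector of N weights in (0, 1].
#' @export
sequence_weights <- function(m, ident_threshold = 0.62) {
  id <- identity_matrix(m)
  counts <- rowSums(id >= ident_threshold)
  1 / pmax(counts, 1)
}

#' Weighted single- and pair-column frequencies
#'
#' @param m An [msa] object.
#' @param weights Per-sequence weights (length N); default all 1
#'   (unweighted counting).
#' @return A `column_stats` list with `weights`, `f1` (L x 21, rows sum
#'   to 1) and `f2` (an (L*21) x (L*21) matrix; block (i,j) is the 21 x 21
#'   joint table of columns i and j, each summing to 1). Use [f2_pair()]
#'   to extract a single pair table.
#' @export
column_stats <- function(m, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, m$N)
  if (length(weights) != m$N) stop("weights length must equal N")
  wsum <- sum(weights)
  if (wsum <= 0) stop("zero total sequence weight")
  X <- one_hot_flat(m)
  f1flat <- colSums(X * weights) / wsum
  f2 <- crossprod(X, X * weights) / wsum
  f1 <- t(matrix(f1flat, nrow = N_STATES))          # L x 21
  structure(list(weights = weights, f1 = f1, f2 = f2, L = m$L),
            class = "column_stats")
}

#' Joint 21 x 21 frequency table of one column pair
#'
#' @param stats A [column_stats()] result.
#' @param i,j Column indices (1-based).
#' @return 21 x 21 matrix; cell (a, b) is the weighted frequency of state
#'   a in column i co-occurring with state b in column j.
#' @export
f2_pair <- function(stats, i, j) {
  ri <- (i - 1L) * N_STATES + seq_len(N_STATES)
  rj <- (j - 1L) * N_STATES + seq_len(N_STATES)
  stats$f2[ri, rj]
}

## Reshape an (L*21) x (L*21) pair-indexed matrix into an L x L x 441 array
## with channel index (a-1)*21 + b for the (a, b) residue-type pair.
pair_flat_to_channels <- function(M, L) {
  A <- array(M, dim = c(N_STATES, L, N_STATES, L))   # [a, i, b, j]
  A <- aperm(A, c(2L, 4L, 3L, 1L))                   # [i, j, b, a]
  dim(A) <- c(L, L, N_STATES * N_STATES)             # ch = (a-1)*21 + b
  A
}

#' Raw covariance features (441 channels)
#'
#' Channel (a, b) at pair (i, j) is `f2[i,j,a,b] - f1[i,a] * f1[j,b]`:
#' the deviation of the joint column frequency from the product of
#' marginals, for every ordered residue-type pair including the gap.
#'
#' @param stats A [column_stats()] result.
#' @return L x L x 441 array; channel index is `(a-1)*21 + b` with names
#'   `cov_<a>_<b>` over the 21-state alphabet (gap written `-`).
#' @export
covariance_features <- function(stats) {
  L <- stats$L
  f1flat <- as.vector(t(stats$f1))                   # (i, a) order, a fastest
  covflat <- stats$f2 - outer(f1flat, f1flat)
  A <- pair_flat_to_channels(covflat, L)
  st <- c(AA_ALPHABET, "-")
  dimnames(A) <- list(NULL, NULL,
                      paste0("cov_", rep(st, each = N_STATES), "_", st))
  A
}

#' Mutual information, APC-corrected MI and joint entropy
#'
#' Plug-in estimates in nats from the weighted frequencies. For each
#' column pair, `mi = sum f2 * ln(f2 / (f1_i f1_j))` over cells with
#' `f2 > 0` (which guarantees both marginals are positive, so no floor is
#' needed) and `joint_entropy = -sum f2 ln f2`. The diagonal of `mi` is
#' the column entropy. `mi_apc` subtracts the average product correction
#' `mean_i * mean_j / mean_all` computed over off-diagonal pairs; its
#' diagonal is 0.
#'
#' @param stats A [column_stats()] result.
#' @return List with L x L matrices `mi`, `mi_apc`, `joint_entropy`.
#' @export
mutual_information <- function(stats) {
  L <- stats$L
  P <- stats$f2
  f1flat <- as.vector(t(stats$f1))
  Q <- outer(f1flat, f1flat)
  pos <- P > 0
  Tmi <- matrix(0, nrow(P), ncol(P))
  Tmi[pos] <- P[pos] * (log(P[pos]) - log(Q[pos]))
  Th <- matrix(0, nrow(P), ncol(P))
  Th[pos] <- -P[pos] * log(P[pos])
  sum_pairs <- function(M) {
    A <- pair_flat_to_channels(M, L)
    out <- matrix(0, L, L)
    for (ch in seq_len(dim(A)[3])) out <- out + A[, , ch]
    out
  }
  mi <- sum_pairs(Tmi)
  mi[mi < 0] <- 0                                   # clip tiny negative noise
  je <- sum_pairs(Th)
  mi_apc <- apc_correct(mi)
  list(mi = mi, mi_apc = mi_apc, joint_entropy = je)
}

#' Average product correction of a coupling matrix
#'
#' Subtracts `rowmean_i * colmean_j / grandmean`, all means taken over
#' off-diagonal entries. Diagonal of the result is 0.
#'
#' @param mi Square coupling matrix.
#' @return Corrected matrix of the same size.
#' @export
apc_correct <- function(mi) {
  L <- nrow(mi)
  if (L == 1L) return(matrix(0, 1L, 1L))
  off <- mi
  diag(off) <- NA
  mrow <- rowMeans(off, na.rm = TRUE)
  mall <- mean(off, na.rm = TRUE)
  out <- if (mall == 0) matrix(0, L, L) else mi - outer(mrow, mrow) / mall
  diag(out) <- 0
  out
}

#' Write / read a flat L x L matrix (PSICOV-style layout)
#'
#' Whitespace-separated, row-major, one matrix row per line.
#'
#' @param mat Square numeric matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_flat <- function(mat, path) {
  lines <- apply(mat, 1L, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_flat
#' @export
read_matrix_flat <- function(path) {
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  rows <- rows[lengths(rows) > 0L]
  mat <- do.call(rbind, lapply(rows, as.numeric))
  if (nrow(mat) != ncol(mat)) stop("matrix file is not square: ", path)
  mat
}
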