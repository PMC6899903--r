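## Effective sequence count (Meff) by greedy identity clustering.
##
## Meff is the number of clusters obtained when alignment rows are
## clustered greedily at a 62% identity threshold, CD-HIT style: sort by
## descending non-gap length (ties by input order), the longest sequence
## founds the first cluster, and each subsequent sequence joins the first
## representative it is >= threshold identical to, else founds a new
## cluster. Identity = identical aligned non-gap matches divided by the
## shorter sequence's non-gap length.

#' Fractional sequence identity between two aligned rows
#'
#' Counts columns where both sequences carry the same non-gap residue and
#' divides by the smaller of the two non-gap lengths. Returns 0 if either
#' sequence is all-gap.
#'
#' @param a,b Integer code vectors (1..21, 21 = gap) of equal length.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (length(a) != length(b)) stop("aligned rows differ in length")
  na <- sum(a != GAP_STATE)
  nb <- sum(b != GAP_STATE)
  if (na == 0L || nb == 0L) return(0)
  sum(a == b & a != GAP_STATE) / min(na, nb)
}

## All-pairs identity matrix via one-hot cross-products (gap column zeroed);
## equals pairwise_identity applied to every row pair.
identity_matrix <- function(m) {
  X <- one_hot_flat(m)
  gap_cols <- (seq_len(m$L) - 1L) * N_STATES + GAP_STATE
  X[, gap_cols] <- 0
  matches <- tcrossprod(X)
  nongap <- rowSums(m$codes != GAP_STATE)
  denom <- outer(nongap, nongap, pmin)
  id <- matrix(0, m$N, m$N)
  ok <- denom > 0
  id[ok] <- matches[ok] / denom[ok]
  id
}

#' Greedy incremental clustering of alignment rows
#'
#' @param m An [msa] object.
#' @param threshold Identity fraction for cluster membership (default 0.62).
#' @return A list of class `cluster_result` with `assignment` (per-sequence
#'   cluster index, in input order), `representatives` (sequence index of
#'   each cluster's founder), `n_clusters` and `threshold`.
#' @export
greedy_cluster <- function(m, threshold = 0.62) {
  nongap <- rowSums(m$codes != GAP_STATE)
  ord <- order(-nongap, seq_len(m$N))
  id <- identity_matrix(m)
  reps <- integer(0)
  assignment <- integer(m$N)
  for (s in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (id[s, reps[k]] >= threshold) { hit <- k; break }
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      hit <- length(reps)
    }
    assignment[s] <- hit
  }
  structure(list(assignment = assignment, representatives = reps,
                 n_clusters = length(reps), threshold = threshold),
            class = "cluster_result")
}

#' Effective sequence count of an alignment
#'
#' The number of clusters found by [greedy_cluster()] at 62% identity.
#' Always satisfies `1 <= Meff <= N`.
#'
#' @param m An [msa] object.
#' @param threshold Identity threshold (default 0.62).
#' @return Integer cluster count.
#' @export
compute_meff <- function(m, threshold = 0.62) {
  greedy_cluster(m, threshold)$n_clusters
}
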