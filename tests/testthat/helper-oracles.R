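# Fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (double loops, direct formulas) and share no code
# with the package internals they check.

ALPHA21 <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")

random_msa <- function(N, L, gap_prob = 0.1) {
  codes <- matrix(sample.int(20L, N * L, replace = TRUE), N, L)
  gaps <- matrix(runif(N * L) < gap_prob, N, L)
  codes[gaps] <- 21L
  msa(apply(codes, 1L, function(r) paste(ALPHA21[r], collapse = "")))
}

oracle_identity <- function(a, b) {
  match_ct <- 0L; na <- 0L; nb <- 0L
  for (k in seq_along(a)) {
    if (a[k] != 21L) na <- na + 1L
    if (b[k] != 21L) nb <- nb + 1L
    if (a[k] != 21L && a[k] == b[k]) match_ct <- match_ct + 1L
  }
  if (na == 0L || nb == 0L) return(0)
  match_ct / min(na, nb)
}

# Greedy CD-HIT-style clustering, written independently with scalar loops.
oracle_meff <- function(m, threshold = 0.62) {
  nongap <- apply(m$codes, 1L, function(r) sum(r != 21L))
  ord <- order(-nongap, seq_len(m$N))
  reps <- integer(0)
  for (s in ord) {
    joined <- FALSE
    for (r in reps) {
      if (oracle_identity(m$codes[s, ], m$codes[r, ]) >= threshold) {
        joined <- TRUE; break
      }
    }
    if (!joined) reps <- c(reps, s)
  }
  length(reps)
}

oracle_weights <- function(m, threshold = 0.62) {
  w <- numeric(m$N)
  for (s in seq_len(m$N)) {
    n_nb <- 0L
    for (t in seq_len(m$N)) {
      if (oracle_identity(m$codes[s, ], m$codes[t, ]) >= threshold) {
        n_nb <- n_nb + 1L
      }
    }
    w[s] <- 1 / n_nb
  }
  w
}

# Unvectorized weighted frequency counting.
oracle_f1 <- function(m, w) {
  f1 <- matrix(0, m$L, 21L)
  for (i in seq_len(m$L)) {
    for (s in seq_len(m$N)) f1[i, m$codes[s, i]] <- f1[i, m$codes[s, i]] + w[s]
  }
  f1 / sum(w)
}

oracle_f2_pair <- function(m, w, i, j) {
  tab <- matrix(0, 21L, 21L)
  for (s in seq_len(m$N)) {
    tab[m$codes[s, i], m$codes[s, j]] <- tab[m$codes[s, i], m$codes[s, j]] + w[s]
  }
  tab / sum(w)
}

oracle_cov_pair <- function(m, w, i, j) {
  f1 <- oracle_f1(m, w)
  oracle_f2_pair(m, w, i, j) - outer(f1[i, ], f1[j, ])
}

oracle_mi_pair <- function(m, w, i, j) {
  f1 <- oracle_f1(m, w)
  f2 <- oracle_f2_pair(m, w, i, j)
  mi <- 0; h <- 0
  for (a in 1:21) for (b in 1:21) {
    if (f2[a, b] > 0) {
      mi <- mi + f2[a, b] * log(f2[a, b] / (f1[i, a] * f1[j, b]))
      h <- h - f2[a, b] * log(f2[a, b])
    }
  }
  c(mi = mi, h = h)
}

# Exhaustive sort-and-count top-L/k precision.
oracle_topk <- function(scores, truth, k, min_sep) {
  L <- nrow(scores)
  rec <- NULL
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    if (j - i >= min_sep) rec <- rbind(rec, c(i, j, scores[i, j], truth[i, j]))
  }
  rec <- rec[order(-rec[, 3], rec[, 1], rec[, 2]), , drop = FALSE]
  n <- min(max(1, floor(L / k)), nrow(rec))
  100 * sum(rec[seq_len(n), 4]) / n
}

oracle_mcc <- function(tp, fp, fn, tn) {
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Small fully-populated feature tensor with deterministic content.
tiny_example <- function(L = 12L, seed = 42L, with_alt = FALSE) {
  set.seed(seed)
  m <- random_msa(8L, L, gap_prob = 0.05)
  stats <- column_stats(m, sequence_weights(m))
  prof <- stats$f1
  ss3 <- matrix(1 / 3, L, 3L)
  solv <- runif(L)
  loop_mask <- rep(c(FALSE, TRUE), length.out = L)
  res <- residue_features(prof, ss3, solv, loop_mask)
  ft <- suppressWarnings(assemble_features(m, res, pair_matrices(stats)))
  y <- matrix(0, L, L)
  y[1, L] <- y[L, 1] <- 1
  j2 <- max(7L, floor(0.75 * L))
  y[2, j2] <- y[j2, 2] <- 1
  alt <- NULL
  if (with_alt) {
    m2 <- random_msa(4L, L, gap_prob = 0.05)
    stats2 <- column_stats(m2, sequence_weights(m2))
    res2 <- residue_features(stats2$f1, ss3, solv, loop_mask)
    alt <- suppressWarnings(assemble_features(m2, res2, pair_matrices(stats2)))
  }
  training_example(ft, y, loop_mask, x_alt = alt)
}
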