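test_that("sequence weights are inverse neighbourhood sizes", {
  distinct <- msa(c("AAAAAAAAAA", "CCCCCCCCCC", "DDDDDDDDDD"))
  expect_equal(sequence_weights(distinct), rep(1, 3))

  copies <- msa(rep("ACDEFGHIKL", 4))
  expect_equal(sequence_weights(copies), rep(1 / 4, 4))

  set.seed(5)
  m <- random_msa(10L, 9L, gap_prob = 0.2)
  expect_equal(sequence_weights(m), oracle_weights(m), tolerance = 1e-12)
})

test_that("column stats match the double-loop counting oracle", {
  m1 <- msa("AC")
  st1 <- column_stats(m1)
  expect_equal(st1$f1[1, ], c(1, rep(0, 20)))
  expect_equal(f2_pair(st1, 1, 2)[1, 5], 1)
  expect_equal(sum(f2_pair(st1, 1, 2)), 1)

  m2 <- msa(c("AC", "AD"))
  st2 <- column_stats(m2)
  expect_equal(st2$f1[2, c(5, 4)], c(0.5, 0.5))

  set.seed(6)
  m <- random_msa(5L, 7L, gap_prob = 0.15)
  w <- sequence_weights(m)
  st <- column_stats(m, w)
  expect_equal(st$f1, oracle_f1(m, w), tolerance = 1e-12)
  for (i in 1:7) for (j in 1:7) {
    expect_equal(f2_pair(st, i, j), oracle_f2_pair(m, w, i, j),
                 tolerance = 1e-12)
  }
  # structural invariants
  expect_equal(rowSums(st$f1), rep(1, 7), tolerance = 1e-9)
  expect_equal(f2_pair(st, 2, 5), t(f2_pair(st, 5, 2)), tolerance = 1e-12)
  expect_equal(diag(f2_pair(st, 3, 3)), st$f1[3, ], tolerance = 1e-12)
  expect_error(column_stats(m, rep(0, m$N)), "zero total")
})

test_that("covariance features equal f2 - f1*f1 with 441 channels", {
  # single sequence: f2 equals the outer product, all channels zero
  st <- column_stats(msa("ACDEF"))
  cov1 <- covariance_features(st)
  expect_equal(dim(cov1)[3], 441L)
  expect_true(max(abs(cov1)) < 1e-12)

  # two perfectly coupled binary columns: cov = 0.5 - 0.25
  m <- msa(c("AC", "AC", "GD", "GD"))
  cov <- covariance_features(column_stats(m))
  expect_equal(unname(cov[1, 2, (1 - 1) * 21 + 5]), 0.25)   # channel (A, C)
  expect_equal(unname(cov[1, 2, (8 - 1) * 21 + 4]), 0.25)   # channel (G, D)
  expect_equal(unname(cov[1, 2, (1 - 1) * 21 + 4]), -0.25)  # channel (A, D)

  set.seed(8)
  mr <- random_msa(6L, 5L, gap_prob = 0.1)
  w <- sequence_weights(mr)
  covr <- covariance_features(column_stats(mr, w))
  for (i in 1:5) for (j in 1:5) {
    ora <- oracle_cov_pair(mr, w, i, j)
    expect_equal(matrix(covr[i, j, ], 21, 21, byrow = TRUE), ora,
                 tolerance = 1e-12)
  }
  # channel symmetry cov(a,b)[i,j] == cov(b,a)[j,i]
  for (a in c(1, 7)) for (b in c(3, 21)) {
    expect_equal(unname(covr[2, 4, (a - 1) * 21 + b]),
                 unname(covr[4, 2, (b - 1) * 21 + a]), tolerance = 1e-12)
  }
  # covariances of a partitioned table sum to zero at every pair
  sums <- apply(covr, c(1, 2), sum)
  expect_true(max(abs(sums)) < 1e-9)
})

test_that("mutual information and joint entropy match analytic values", {
  # constant column against anything: zero MI
  m0 <- msa(c("AC", "AD", "AC", "AD"))
  mi0 <- mutual_information(column_stats(m0))
  expect_equal(mi0$mi[1, 2], 0, tolerance = 1e-12)

  # perfectly coupled pair, two equiprobable symbol pairs: MI = ln 2
  m1 <- msa(c("AC", "AC", "GD", "GD"))
  mi1 <- mutual_information(column_stats(m1))
  expect_equal(mi1$mi[1, 2], log(2), tolerance = 1e-12)
  expect_equal(mi1$joint_entropy[1, 2], log(2), tolerance = 1e-12)
  # diagonal is the column entropy
  expect_equal(mi1$mi[1, 1], log(2), tolerance = 1e-12)

  set.seed(9)
  m <- random_msa(7L, 6L, gap_prob = 0.1)
  w <- sequence_weights(m)
  st <- column_stats(m, w)
  miv <- mutual_information(st)
  for (i in 1:6) for (j in 1:6) {
    ora <- oracle_mi_pair(m, w, i, j)
    expect_equal(miv$mi[i, j], max(ora[["mi"]], 0), tolerance = 1e-9)
    expect_equal(miv$joint_entropy[i, j], ora[["h"]], tolerance = 1e-9)
  }
  # bounds: mi >= 0, mi <= min column entropy, joint entropy <= ln 441
  expect_true(all(miv$mi >= -1e-9))
  for (i in 1:6) for (j in 1:6) {
    expect_lte(miv$mi[i, j], min(miv$mi[i, i], miv$mi[j, j]) + 1e-9)
  }
  expect_true(all(miv$joint_entropy >= -1e-12 &
                  miv$joint_entropy <= log(441) + 1e-12))
  # APC of a constant off-diagonal coupling matrix is zero off-diagonal
  const <- matrix(1, 4, 4)
  expect_true(max(abs(apc_correct(const)[upper.tri(const)])) < 1e-12)
})

test_that("independent columns at large N give near-zero MI after APC", {
  set.seed(10)
  # independent uniform columns, no gaps, N = 2000
  codes <- matrix(sample.int(4L, 2000L * 4L, replace = TRUE), 2000L, 4L)
  m <- msa(apply(codes, 1, function(r) paste(ALPHA21[r], collapse = "")))
  miv <- mutual_information(column_stats(m))
  offdiag <- miv$mi_apc[upper.tri(miv$mi_apc)]
  expect_true(all(abs(offdiag) < 0.02))
})

test_that("pair statistics are invariant under row permutation", {
  set.seed(12)
  m <- random_msa(9L, 6L, gap_prob = 0.1)
  perm <- msa(msa_sequences(m)[sample(m$N)])
  st <- column_stats(m, sequence_weights(m))
  stp <- column_stats(perm, sequence_weights(perm))
  expect_equal(covariance_features(st), covariance_features(stp),
               tolerance = 1e-12)
  expect_equal(mutual_information(st)$mi, mutual_information(stp)$mi,
               tolerance = 1e-12)
})

test_that("flat matrix writer round-trips to 6 decimals", {
  set.seed(13)
  mat <- matrix(runif(25), 5, 5)
  p <- withr::local_tempfile()
  write_matrix_flat(mat, p)
  expect_equal(read_matrix_flat(p), mat, tolerance = 1e-6)
})
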