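test_that("striping turns per-residue vectors into constant-row/col maps", {
  v <- c(1, 2, 3)
  s <- stripe_1d(v)
  expect_equal(dim(s), c(3L, 3L, 2L))
  expect_equal(s[, , 1], matrix(c(1, 2, 3), 3, 3))        # rows constant
  expect_equal(s[, , 2], matrix(c(1, 2, 3), 3, 3, byrow = TRUE))
  expect_equal(stripe_1d(rep(4, 5))[, , 1], matrix(4, 5, 5))

  # reversing the vector equals the 180-degree flip of the stripes
  set.seed(1)
  v2 <- runif(6)
  fl <- stripe_1d(rev(v2))
  direct <- stripe_1d(v2)
  expect_equal(fl[, , 1], direct[6:1, 6:1, 1])
  expect_equal(fl[, , 2], direct[6:1, 6:1, 2])
})

test_that("separation and bounds channels follow their encodings", {
  expect_equal(separation_channel(1), matrix(0, 1, 1))
  s <- separation_channel(5)
  expect_equal(s[1, 2], 0.01)
  expect_equal(s, t(s))
  expect_true(all(diag(s) == 0))
  big <- separation_channel(300)
  expect_equal(big[1, 251], 1)       # |i-j| = 250 saturates at the cap
  b <- bounds_channel(3)
  expect_equal(b, matrix(1, 3, 3))
  expect_equal(sum(bounds_channel(7)), 49)
})

test_that("contact potential map is the profile expectation of the table", {
  tab <- contact_potential_table()
  expect_equal(dim(tab), c(20L, 20L))
  expect_equal(tab, t(tab))

  # single sequence: raw table entries
  m1 <- msa("AIK")
  cp <- contact_potential_map(m1)
  expect_equal(cp[1, 2], tab["A", "I"])
  expect_equal(cp[2, 3], tab["I", "K"])

  # uniform profile: constant map at the table mean
  prof <- matrix(c(rep(1 / 20, 20), 0), 21, 2)
  cpu <- contactnet:::profile_potential_map(t(prof))
  expect_equal(cpu[1, 2], mean(tab), tolerance = 1e-12)

  # toy 3-sequence MSA vs double-loop oracle
  m3 <- msa(c("AIK", "AVK", "GIR"))
  st <- column_stats(m3)
  cp3 <- contact_potential_map(m3)
  aa <- aa_alphabet()
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (a in 1:20) for (b in 1:20) {
      acc <- acc + st$f1[i, a] * st$f1[j, b] * tab[aa[a], aa[b]]
    }
    expect_equal(cp3[i, j], acc, tolerance = 1e-12)
  }
})

test_that("assembled tensor has the full 501-channel layout", {
  set.seed(30)
  m <- random_msa(20L, 15L, gap_prob = 0.08)
  w <- sequence_weights(m)
  stats <- column_stats(m, w)
  res <- residue_features(stats$f1, matrix(1 / 3, 15, 3), runif(15),
                          rep(FALSE, 15))
  pm <- pair_matrices(stats)
  expect_warning(ft <- assemble_features(m, res, pm), "zero-filled")

  expect_equal(length(ft$channel_map), 501L)
  expect_equal(dim(ft$data), c(15L, 15L, 501L))
  expect_false(anyDuplicated(ft$channel_map) > 0)
  expect_true(all(is.finite(ft$data)))
  expect_equal(ft$meta$missing_external,
               c("psicov", "ccmpred", "freecontact"))

  # covariance block is the covariance_features output bit-for-bit
  cov_idx <- grep("^cov_", ft$channel_map)
  expect_equal(length(cov_idx), 441L)
  expect_identical(as.vector(ft$data[, , cov_idx]), as.vector(pm$cov))

  # missing external maps are all-zero; supplied ones pass through
  expect_true(all(ft$data[, , "psicov"] == 0))
  ext <- matrix(runif(225), 15, 15)
  ft2 <- suppressWarnings(
    assemble_features(m, res, pm, external = list(ccmpred = ext)))
  expect_equal(ft2$data[, , "ccmpred"], ext)
  expect_equal(ft2$data[, , -match("ccmpred", ft2$channel_map)],
               ft$data[, , -match("ccmpred", ft$channel_map)])

  # striped channels are constant along the right axis
  expect_true(all(ft$data[, , "solv_i"] == matrix(res$solv, 15, 15)))
  expect_true(all(ft$data[, , "solv_j"] ==
                  matrix(res$solv, 15, 15, byrow = TRUE)))
  expect_true(all(ft$data[, , "bounds"] == 1))
  expect_equal(ft$data[, , "separation"], separation_channel(15))

  # deterministic assembly
  ft3 <- suppressWarnings(assemble_features(m, res, pm))
  expect_identical(ft3$data, ft$data)

  # length mismatch rejected
  res_bad <- residue_features(stats$f1[1:14, ] / rowSums(stats$f1[1:14, ]),
                              matrix(1 / 3, 14, 3), runif(14), rep(FALSE, 14))
  expect_error(suppressWarnings(assemble_features(m, res_bad, pm)), "disagree")
})

test_that("feature tensors save and load losslessly", {
  ex <- tiny_example(L = 10L)
  p <- withr::local_tempfile(fileext = ".rds")
  write_feature_tensor(ex$x, p)
  back <- read_feature_tensor(p)
  expect_identical(back$data, ex$x$data)
  expect_identical(back$channel_map, ex$x$channel_map)
})

test_that("ss2 files round-trip through the reader", {
  set.seed(31)
  aa <- sample(aa_alphabet(), 8, replace = TRUE)
  ss3 <- matrix(runif(24), 8, 3)
  ss3 <- ss3 / rowSums(ss3)
  p <- withr::local_tempfile(fileext = ".ss2")
  write_ss2(aa, ss3, p)
  back <- read_ss2(p)
  expect_equal(back$aa, aa)
  expect_equal(back$ss3, ss3, tolerance = 2e-3, ignore_attr = TRUE)
})
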