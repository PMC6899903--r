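small_cfg <- function() {
  model_config(in_channels = 4, width = 4, n_blocks = 1,
               dilation_schedule = 1L, kernel = 3)
}

random_xy <- function(L, C = 4, n_contacts = 3) {
  x <- array(rnorm(L * L * C), c(L, L, C))
  y <- matrix(0, L, L)
  ij <- cbind(sample(1:(L - 6), n_contacts), sample((L - 5):L, n_contacts))
  y[ij] <- 1
  y <- 1 * ((y + t(y)) > 0)
  diag(y) <- 0
  list(x = x, y = y)
}

test_that("masked BCE uses only pairs with separation at least 5", {
  L <- 12
  y <- matrix(0, L, L); y[1, 8] <- y[8, 1] <- 1
  perfect <- matrix(1e-9, L, L); perfect[1, 8] <- perfect[8, 1] <- 1 - 1e-9
  expect_lte(masked_bce(perfect, y), 1e-6)

  # scores at short-range pairs are irrelevant
  p1 <- matrix(0.2, L, L)
  p2 <- p1
  p2[3, 6] <- 0.99; p2[5, 6] <- 0.01   # separations 3 and 1
  expect_equal(masked_bce(p1, y), masked_bce(p2, y))
  p3 <- p1; p3[1, 8] <- 0.9            # separation 7: counts
  expect_false(masked_bce(p3, y) == masked_bce(p1, y))

  # uniform 0.5 gives exactly ln 2
  expect_equal(masked_bce(matrix(0.5, L, L), y), log(2), tolerance = 1e-12)

  expect_error(masked_bce(matrix(0.5, 4, 4), matrix(0, 4, 4)), "separation")
  expect_error(masked_bce(matrix(0.5, 4, 5), matrix(0, 4, 4)), "mismatch")
})

test_that("MCC matches its closed form on hand-built confusions", {
  L <- 10
  y <- matrix(0, L, L); y[1, 7] <- y[7, 1] <- 1; y[2, 8] <- y[8, 2] <- 1
  expect_equal(mcc(y, y), 1)
  expect_equal(mcc(1 - y, y), -1)

  # hand-built confusion TP=3, FP=1, FN=2, TN=9 on a synthetic mask
  # (15 eligible pairs on L=10 with min_sep 5: pairs (i,j), j-i>=5)
  elig <- which(outer(1:L, 1:L, function(i, j) j - i) >= 5, arr.ind = TRUE)
  expect_equal(nrow(elig), 15L)
  truth <- matrix(0, L, L); pred <- matrix(0, L, L)
  truth[elig[1:5, ]] <- 1                      # 5 positives
  pred[elig[1:3, ]] <- 1                       # 3 TP
  pred[elig[6, , drop = FALSE]] <- 1           # 1 FP
  truth <- 1 * ((truth + t(truth)) > 0); pred <- 1 * ((pred + t(pred)) > 0)
  diag(truth) <- 0
  expect_equal(mcc(pred, truth), oracle_mcc(tp = 3, fp = 1, fn = 2, tn = 9))

  # all-negative prediction: zero marginal, MCC defined as 0
  expect_equal(mcc(matrix(0, L, L), truth), 0)
})

test_that("training overfits a single example and history is recorded", {
  set.seed(50)
  d <- random_xy(14)
  ex <- training_example(feature_tensor(d$x, paste0("c", 1:4)), d$y,
                         rep(FALSE, 14))
  model <- build_model(small_cfg())
  off <- augment_config(p_loop_apply = 0, p_flip = 0, p_mixup = 0)
  fit <- train_model(model, list(ex), list(ex),
                     train_config(batch_size = 1, max_epochs = 15,
                                  patience = 15, lr = 0.01, seed = 2),
                     off)
  expect_equal(nrow(fit$history), 15L)
  # loss decreases substantially while overfitting one example
  expect_lt(fit$history$train_loss[15], fit$history$train_loss[1] * 0.5)
  expect_equal(fit$best_epoch, which.max(fit$history$val_mcc))
})

test_that("accumulated per-example gradients equal the batch-loss gradient", {
  set.seed(51)
  model <- build_model(small_cfg())
  exs <- lapply(1:3, function(i) random_xy(11))
  # accumulate (1/n) * per-example gradients as the training loop does
  acc <- NULL
  for (d in exs) {
    fw <- model_forward(model, d$x, keep_cache = TRUE)
    gs <- contactnet:::bce_grad_presigmoid(fw$scores, d$y, 5) / length(exs)
    g <- model_backward(model, fw$cache, gs)
    acc <- if (is.null(acc)) g else contactnet:::tree_map(`+`, acc, g)
  }
  # numeric gradient of the summed (mean) batch loss
  batch_loss <- function(m) {
    mean(vapply(exs, function(d)
      masked_bce(model_forward(m, d$x)$scores, d$y, 5), numeric(1)))
  }
  eps <- 1e-5
  probes <- list(
    list(get = function(g) g$maxout_W[[1]][2, 3],
         set = function(p, e) { p$maxout_W[[1]][2, 3] <- p$maxout_W[[1]][2, 3] + e; p }),
    list(get = function(g) g$blocks[[1]]$W1[3, 10],
         set = function(p, e) { p$blocks[[1]]$W1[3, 10] <- p$blocks[[1]]$W1[3, 10] + e; p }),
    list(get = function(g) g$out_W[1, 2],
         set = function(p, e) { p$out_W[1, 2] <- p$out_W[1, 2] + e; p }),
    list(get = function(g) g$in_gamma[1],
         set = function(p, e) { p$in_gamma[1] <- p$in_gamma[1] + e; p }))
  for (pr in probes) {
    mp <- model; mp$params <- pr$set(mp$params, eps)
    mm <- model; mm$params <- pr$set(mm$params, -eps)
    fd <- (batch_loss(mp) - batch_loss(mm)) / (2 * eps)
    expect_equal(pr$get(acc), fd, tolerance = 1e-6)
  }
})

test_that("early stopping returns the best-MCC checkpoint, not the last", {
  set.seed(52)
  d <- random_xy(12)
  ex <- training_example(feature_tensor(d$x, paste0("c", 1:4)), d$y,
                         rep(FALSE, 12))
  model <- build_model(small_cfg())
  off <- augment_config(p_loop_apply = 0, p_flip = 0, p_mixup = 0)
  fit <- train_model(model, list(ex), list(ex),
                     train_config(batch_size = 1, max_epochs = 8, patience = 2,
                                  lr = 0.05, seed = 3),
                     off)
  best <- fit$best_epoch
  expect_equal(fit$history$val_mcc[best], max(fit$history$val_mcc))
  # returned weights reproduce the best epoch's validation MCC
  got <- mcc(predict_contacts(fit$model, ex$x), ex$y)
  expect_equal(got, fit$best_val_mcc, tolerance = 1e-12)
  # stopping happened within patience epochs of the best (or at the cap)
  expect_lte(nrow(fit$history), max(best + 2, 8))
})
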