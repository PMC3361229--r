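test_that("one-hot encoding follows the class order", {
  enc <- encode_onehot(c("b", "a", "c", "b"), c("a", "b", "c"))
  expect_equal(enc$Y[1, ], c(a = 0, b = 1, c = 0))
  expect_equal(rowSums(enc$Y), rep(1, 4))
  expect_error(encode_onehot(c("a", "zzz"), c("a", "b")), "zzz")
})

test_that("PLS2 fits an exact univariate linear relation with one component", {
  # centered orthogonal predictors so one latent variable suffices exactly
  X <- unclass(poly(1:20, 3))
  y <- matrix(2.5 * X[, 2] + 1, ncol = 1)
  f <- fit_pls2(X, y, 1)
  pred <- sweep(sweep(X, 2, f$x_mean) %*% pls_coefficients(f, 1), 2,
                f$y_mean, "+")
  expect_equal(as.vector(pred), as.vector(y), tolerance = 1e-9)
})

test_that("PLS2 at full rank equals the least-squares oracle on random fixtures", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(8:12, 1); p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- encode_onehot(sample(c("a", "b", "c"), n, replace = TRUE),
                       c("a", "b", "c"))$Y
    f <- fit_pls2(X, Y, p)
    pred <- sweep(sweep(X, 2, f$x_mean) %*% pls_coefficients(f), 2,
                  f$y_mean, "+")
    expect_equal(pred, unname(fitted(lm(Y ~ X))), tolerance = 1e-6)
  }
})

test_that("permuting response columns permutes coefficients identically", {
  set.seed(2)
  X <- matrix(rnorm(60), 15, 4)
  Y <- encode_onehot(sample(c("a", "b", "c"), 15, TRUE), c("a", "b", "c"))$Y
  B1 <- pls_coefficients(fit_pls2(X, Y, 3))
  B2 <- pls_coefficients(fit_pls2(X, Y[, c(3, 1, 2)], 3))
  expect_equal(B2, B1[, c(3, 1, 2)], tolerance = 1e-9)
})

test_that("the coefficient matrix reproduces the deflation-path fitted values", {
  set.seed(3)
  X <- matrix(rnorm(30 * 8), 30, 8)
  Y <- encode_onehot(sample(c("a", "b"), 30, TRUE), c("a", "b"))$Y
  k <- 4
  f <- fit_pls2(X, Y, k)
  # deflation path: y_mean + cumulative t_a q_a'
  E <- sweep(X, 2, f$x_mean)
  path <- matrix(rep(f$y_mean, each = 30), 30)
  for (a in seq_len(f$k)) {
    tt <- E %*% f$W[, a]
    path <- path + tt %*% t(f$Q[, a])
    E <- E - tt %*% t(f$P[, a])
  }
  direct <- sweep(sweep(X, 2, f$x_mean) %*% pls_coefficients(f, k), 2,
                  f$y_mean, "+")
  expect_equal(direct, path, tolerance = 1e-8)
})

test_that("prediction at the training mean returns the response mean", {
  set.seed(4)
  data <- small_spectra(n = 12, p = 10, labels = rep(c("a", "b", "c"), 4))
  m <- plsda(data, ncomp = 2)
  at_mean <- predict_response(m, matrix(m$fit$x_mean, 1))
  expect_equal(as.vector(at_mean), unname(m$fit$y_mean), tolerance = 1e-10)
  expect_error(predict_response(m, matrix(0, 1, 3)), "channels")
})

test_that("class assignment takes the response nearest to one", {
  m <- structure(list(classes = c("a", "b", "c"),
                      fit = list(x_mean = c(0, 0), y_mean = c(0, 0, 0)),
                      coefficients = matrix(0, 2, 3), k = 1),
                 class = "plsda")
  fake <- function(yhat) {
    m$fit$y_mean <- yhat
    predict_class(m, matrix(0, 1, 2))
  }
  expect_equal(fake(c(0.9, 0.3, -0.1)), "a")
  expect_equal(fake(c(1, 0, 0)), "a")
  expect_warning(got <- fake(c(0.5, 0.5, 0)), "tie")
  expect_equal(got, "a")
})

test_that("MCCV error traces are deterministic and find a constructed rank", {
  set.seed(5)
  scores <- matrix(rnorm(40 * 2), 40, 2)
  X <- scores %*% matrix(rnorm(2 * 10), 2, 10)
  Y <- scores %*% matrix(c(1, 0, 0, 1, 1, 1), 2, 3)   # exact rank-2 relation
  r1 <- suppressWarnings(mccv_rmse(X, Y, k_max = 5, seed = 99))
  r2 <- suppressWarnings(mccv_rmse(X, Y, k_max = 5, seed = 99))
  expect_identical(r1$rmse, r2$rmse)
  expect_lt(r1$rmse[2], 1e-6)
  expect_true(all(diff(r1$rmse[1:2]) <= 0))
  expect_equal(r1$n_pred, 100 * 12 * 3)
})

test_that("a single MCCV split equals the direct hold-out computation", {
  set.seed(6)
  X <- matrix(rnorm(10 * 4), 10, 4)
  Y <- encode_onehot(rep(c("a", "b"), 5), c("a", "b"))$Y
  r <- mccv_rmse(X, Y, k_max = 2, leave_out = 0.1, n_splits = 1, seed = 7)
  set.seed(7)
  out <- sample.int(10, 1)
  f <- fit_pls2(X[-out, ], Y[-out, ], 2)
  sse <- sapply(1:2, function(k) {
    B <- pls_coefficients(f, k)
    pred <- sweep(matrix(X[out, ] - f$x_mean, 1) %*% B, 2, f$y_mean, "+")
    sum((pred - Y[out, ])^2)
  })
  expect_equal(r$rmse, sqrt(sse / 2), tolerance = 1e-10)
})

test_that("the F-test rule selects parsimonious complexity", {
  mk <- function(rmse, n_pred) structure(list(rmse = rmse, n_pred = n_pred),
                                         class = "mccv_result")
  expect_equal(select_k_ftest(mk(c(1, 1, 1), 100)), 1L)
  # (0.50/0.49)^2 ~ 1.041 below the 0.75 quantile of F(200, 200) ~ 1.10
  expect_equal(select_k_ftest(mk(c(1.0, 0.50, 0.49), 200)), 2L)
  # large gaps: no earlier k passes
  expect_equal(select_k_ftest(mk(c(8, 4, 1), 200)), 3L)
  expect_equal(select_k_ftest(mk(c(1, 0, 0), 200)), 2L)
})

test_that("the full training path selects enough structure on synthetic classes", {
  gen <- generate_spectra(default_cfg(seed = 8))
  d2 <- apply_preprocess(gen$spectra, preprocess_spec("second_derivative"))
  m <- plsda(d2, k_max = 8, n_splits = 30, seed = 8)
  expect_gte(m$k, 2)
  expect_equal(predict_class(m, d2), d2$labels)
  expect_lte(m$k, which.min(m$mccv$rmse))
  one <- subset_samples(d2, d2$labels == "parent")
  expect_error(plsda(one), "2 classes")
  m1 <- plsda(d2, k_max = 1, n_splits = 10, seed = 8)
  expect_equal(m1$k, 1L)
})

test_that("relabeling classes permutes predictions consistently", {
  set.seed(9)
  data <- small_spectra(n = 15, p = 12, labels = rep(c("a", "b", "c"), 5))
  m1 <- plsda(data, ncomp = 3, classes = c("a", "b", "c"))
  m2 <- plsda(data, ncomp = 3, classes = c("c", "a", "b"))
  expect_equal(predict_class(m1, data), predict_class(m2, data))
})
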