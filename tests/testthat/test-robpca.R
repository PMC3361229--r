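test_that("outlyingness exposes a gross outlier under exhaustive directions", {
  X <- rbind(c(0, 0), c(1, 0.2), c(0.3, 1), c(-0.8, 0.1), c(25, 30))
  ol <- outlyingness(X, n_directions = choose(5, 2), seed = 1)
  expect_equal(which.max(ol), 5L)
})

test_that("outlyingness respects symmetry and duplication", {
  set.seed(2)
  Y <- matrix(rnorm(20), 10, 2)
  X <- rbind(Y, -Y)               # symmetric about the origin
  ol <- outlyingness(X, n_directions = choose(20, 2), seed = 2)
  expect_equal(ol[1:10], ol[11:20], tolerance = 1e-10)
  dup <- rbind(Y, Y)
  old <- outlyingness(dup, n_directions = 150, seed = 3)
  expect_equal(old[1:10], old[11:20], tolerance = 1e-12)
})

test_that("robust and classical PCA agree on clean Gaussian data", {
  set.seed(4)
  L <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:3]
  X <- matrix(rnorm(200 * 3), 200, 3) %*% diag(c(4, 2, 1)) %*% t(L) +
    matrix(rnorm(2000, sd = 0.05), 200, 10)
  rob <- robpca(X, k = 3, seed = 4)
  cl <- prcomp(X)
  ang <- principal_angles(rob$loadings, cl$rotation[, 1:3])
  expect_lt(max(ang), 10)
  # eigenvalues agree within 15% on outlier-free data
  expect_lt(max(abs(rob$eigenvalues / cl$sdev[1:3]^2 - 1)), 0.15)
})

test_that("robust PCA resists gross orthogonal contamination", {
  set.seed(5)
  L <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  basis <- L[, 1:2]
  ortho <- L[, 10]
  X <- matrix(rnorm(200 * 2), 200, 2) %*% diag(c(3, 1.5)) %*% t(basis) +
    matrix(rnorm(2000, sd = 0.05), 200, 10)
  clean_sub <- prcomp(X)$rotation[, 1:2]
  Xc <- X
  bad <- 1:20                     # 10% contamination off the plane
  Xc[bad, ] <- Xc[bad, ] + 8 * matrix(ortho, 20, 10, byrow = TRUE)
  rob <- robpca(Xc, k = 2, seed = 5)
  expect_lt(max(principal_angles(rob$loadings, clean_sub)), 10)
  classical <- prcomp(Xc)$rotation[, 1:2]
  expect_gt(max(principal_angles(classical, clean_sub)), 10)
})

test_that("degenerate data are rejected", {
  X <- matrix(1, 3, 4)
  expect_error(robpca(X, k = 1), "k must be|identical")
  expect_error(robpca(matrix(1, 10, 4), k = 2), "identical|rank")
  expect_error(outlyingness(matrix(1, 6, 3)), "degenerate")
})

test_that("score and orthogonal distances match naive loop computation", {
  set.seed(6)
  X <- matrix(rnorm(30 * 6), 30, 6)
  m <- robpca(X, k = 3, seed = 6)
  sd_got <- score_distance(m, X)
  od_got <- orthogonal_distance(m, X)
  sd_want <- od_want <- numeric(30)
  for (i in 1:30) {
    xc <- X[i, ] - m$center
    t <- as.vector(t(m$loadings) %*% xc)
    sd_want[i] <- sqrt(sum(t^2 / m$eigenvalues))
    od_want[i] <- sqrt(sum((xc - m$loadings %*% t)^2))
  }
  expect_equal(sd_got, sd_want, tolerance = 1e-10)
  expect_equal(od_got, od_want, tolerance = 1e-10)

  # closed forms
  expect_equal(score_distance(m, matrix(m$center, 1)), 0, tolerance = 1e-8)
  x1 <- m$center + sqrt(m$eigenvalues[1]) * m$loadings[, 1]
  expect_equal(score_distance(m, matrix(x1, 1)), 1, tolerance = 1e-8)
  expect_lt(orthogonal_distance(m, matrix(x1, 1)), 1e-9)
  expect_error(score_distance(m, X[, 1:3]), "columns")
})

test_that("distances are invariant under a joint orthogonal rotation", {
  set.seed(7)
  X <- matrix(rnorm(25 * 5), 25, 5)
  m <- robpca(X, k = 2, seed = 7)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  m2 <- m
  m2$center <- as.vector(m$center %*% Q)
  m2$loadings <- t(Q) %*% m$loadings
  expect_equal(score_distance(m2, X %*% Q), score_distance(m, X),
               tolerance = 1e-9)
  expect_equal(orthogonal_distance(m2, X %*% Q), orthogonal_distance(m, X),
               tolerance = 1e-9)
})

test_that("cutoffs use the chi-square quantile and Wilson-Hilferty form", {
  model <- structure(list(k = 2, significance = 0.05), class = "robpca")
  cuts <- distance_cutoffs(model, od = rchisq(50, 5))
  expect_equal(cuts$sd_cutoff, sqrt(qchisq(0.95, 2)), tolerance = 1e-10)
  expect_equal(cuts$sd_cutoff, 2.4477, tolerance = 1e-4)
  expect_warning(cz <- distance_cutoffs(model, od = rep(3, 20)),
                 "zero robust scale")
  expect_equal(cz$od_cutoff, 3, tolerance = 1e-10)
  expect_warning(c0 <- distance_cutoffs(model, od = rep(0, 20)), "zero")
  expect_equal(c0$od_cutoff, 0)
})

test_that("the orthogonal-distance cutoff is calibrated on chi-distributed residuals", {
  set.seed(8)
  model <- structure(list(k = 2, significance = 0.05), class = "robpca")
  fr <- replicate(50, {
    od <- sqrt(rchisq(200, df = 200)) * 0.01
    mean(od > distance_cutoffs(model, od)$od_cutoff)
  })
  se <- sqrt(0.05 * 0.95 / (50 * 200))
  expect_lt(abs(mean(fr) - 0.05), 3 * se)
})

test_that("the four-group rule follows the SD/OD quadrants with strict cutoffs", {
  grp <- classify_samples(sd = c(1, 3, 1, 3, 2, 2),
                          od = c(1, 1, 3, 3, 2, 2),
                          sd_cutoff = 2, od_cutoff = 2)
  expect_equal(grp, c("regular", "good_leverage", "orthogonal_outlier",
                      "bad_leverage", "regular", "regular"))
  expect_error(classify_samples(1:3, 1:2, 1, 1), "equal length")
})

test_that("PRESS-based dimension selection finds constructed ranks", {
  set.seed(9)
  scores <- matrix(rnorm(200 * 2), 200, 2) %*% diag(c(5, 3))
  basis <- qr.Q(qr(matrix(rnorm(400), 20, 20)))[, 1:2]
  X <- scores %*% t(basis) + matrix(rnorm(4000, sd = 0.01), 200, 20)
  expect_equal(select_k_by_press(X, k_max = 6, seed = 9), 2L)
  noise <- matrix(rnorm(4000), 200, 20)
  expect_equal(select_k_by_press(noise, k_max = 6, seed = 9), 1L)
  expect_equal(select_k_by_press(noise, k_max = 1, seed = 9), 1L)
  expect_error(select_k_by_press(noise, k_max = 0), ">= 1")
})

test_that("per-class diagnosis recovers injected outliers and keeps clean data", {
  gen <- generate_spectra(synth_config(seed = 20, outliers = list(
    list(class = "hybrid", kind = "orthogonal", magnitude = 0.1),
    list(class = "hybrid", kind = "orthogonal", magnitude = 0.1))))
  r <- restrict_range(gen$spectra, 4000, 10000)
  diag <- diagnose_class(r, "hybrid", seed = 20)
  inj <- gen$truth$sample_id[gen$truth$outlier == "orthogonal"]
  expect_true(all(inj %in% diag$sample_ids[diag$excluded]))
  expect_error(diagnose_class(r, "unobtainium"), "unknown class")
  small <- subset_samples(r, 1:5)
  expect_error(diagnose_class(small, "parent"), ">= 10")
})

test_that("rescreening a cleaned class does not mass-reflag", {
  refrac <- sapply(1:5, function(s) {
    gen <- generate_spectra(default_cfg(seed = 30 + s))
    r <- restrict_range(gen$spectra, 4000, 10000)
    d1 <- diagnose_class(r, "parent", seed = s)
    keep <- !(r$sample_ids %in% d1$sample_ids[d1$excluded]) |
      r$labels != "parent"
    d2 <- diagnose_class(subset_samples(r, keep), "parent", seed = s)
    mean(d2$excluded)
  })
  expect_lt(mean(refrac), 0.10)
})
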