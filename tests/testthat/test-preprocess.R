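test_that("range restriction keeps the right channels and rejects empty ranges", {
  gen <- generate_spectra(default_cfg(seed = 1))
  r <- restrict_range(gen$spectra, 4000, 10000)
  expect_equal(ncol(r$absorbance), 751L)
  full <- restrict_range(gen$spectra, 4000, 12000)
  expect_equal(full$absorbance, gen$spectra$absorbance)
  expect_error(restrict_range(gen$spectra, 20000, 30000), "no channels")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials exactly", {
  w <- seq(4000, by = 8, length.out = 60)
  const <- spectra_set(matrix(0.7, 1, 60), w, "a")
  expect_equal(sg_smooth(const, 11, 2)$absorbance, const$absorbance,
               tolerance = 1e-12)
  quad <- spectra_set(matrix(1e-7 * w^2 - 3e-4 * w + 2, 1, 60), w, "a")
  sm <- sg_smooth(quad, 11, 2)
  expect_lt(max(abs(sm$absorbance[1, 6:55] - quad$absorbance[1, 6:55])), 1e-9)
})

test_that("Savitzky-Golay smoothing equals the per-window least-squares oracle", {
  set.seed(10)
  x <- rnorm(80)
  data <- spectra_set(matrix(x, 1), seq(4000, by = 8, length.out = 80), "a")
  got <- sg_smooth(data, 11, 2)$absorbance[1, ]
  want <- sg_oracle(x, 11, 2, m = 0)
  interior <- which(!is.na(want))
  expect_equal(got[interior], want[interior], tolerance = 1e-9)
})

test_that("second derivative recovers the curvature of a quadratic", {
  w <- seq(4000, by = 8, length.out = 100)
  a <- 1e-7
  quad <- spectra_set(matrix(a * w^2, 1), w, "a")
  d2 <- sg_second_derivative(quad, 15, 3)$absorbance[1, ]
  expect_equal(d2[8:93], rep(2 * a, 86), tolerance = 1e-6)
  lin <- spectra_set(matrix(0.001 * w, 1), w, "a")
  expect_lt(max(abs(sg_second_derivative(lin, 15, 3)$absorbance[1, 8:93])),
            1e-12)
})

test_that("second derivative equals the per-window polynomial-fit oracle on noise", {
  set.seed(11)
  x <- rnorm(80, sd = 0.05)
  data <- spectra_set(matrix(x, 1), seq(4000, by = 8, length.out = 80), "a")
  got <- sg_second_derivative(data, 15, 3)$absorbance[1, ]
  want <- sg_oracle(x, 15, 3, m = 2, step = 8)
  interior <- which(!is.na(want))
  expect_equal(got[interior], want[interior], tolerance = 1e-9)
})

test_that("second derivative of a noisy quadratic is unbiased at fixed seed", {
  set.seed(12)
  w <- seq(4000, by = 8, length.out = 500)
  a <- 1e-7
  x <- a * w^2 + rnorm(500, sd = 0.001)
  data <- spectra_set(matrix(x, 1), w, "a")
  d2 <- sg_second_derivative(data, 15, 3)$absorbance[1, 8:493]
  expect_lt(abs(mean(d2) - 2 * a) / (2 * a), 0.05)
})

test_that("second derivative rejects invalid parameters and non-uniform grids", {
  data <- small_spectra(n = 2, p = 30)
  expect_error(sg_second_derivative(data, 15, 1), "polyorder")
  expect_error(sg_second_derivative(data, 14, 3), "odd")
  expect_error(sg_smooth(data, 31, 2), "exceeds")
  wobble <- spectra_set(data$absorbance, data$wavenumbers + c(0, 0.5,
                        rep(0, 28)), data$labels)
  expect_error(sg_second_derivative(wobble, 15, 3), "uniform")
})

test_that("SNV standardizes every row and rejects constant spectra", {
  row <- spectra_set(matrix(c(1, 3), 1), c(4000, 4008), "a")
  expect_equal(snv(row)$absorbance[1, ], c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  expect_error(snv(spectra_set(matrix(5, 1, 3), c(1, 2, 3), "a",
                               sample_ids = "s9")), "s9")
  gen <- generate_spectra(default_cfg(seed = 13))
  out <- snv(gen$spectra)$absorbance
  expect_lt(max(abs(rowMeans(out))), 1e-10)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-10)
})

test_that("SNV is idempotent and invariant to offset and positive scale", {
  data <- small_spectra(n = 4, p = 25, seed = 14)
  once <- snv(data)
  twice <- snv(once)
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-9)
  shifted <- spectra_set(3.2 * data$absorbance + 0.7, data$wavenumbers,
                         data$labels)
  expect_equal(snv(shifted)$absorbance, once$absorbance, tolerance = 1e-9)
})

test_that("SG operators are linear and commute with range restriction", {
  a <- small_spectra(n = 3, p = 40, seed = 15)
  b <- small_spectra(n = 3, p = 40, seed = 16)
  mix <- spectra_set(2 * a$absorbance - 0.5 * b$absorbance, a$wavenumbers,
                     a$labels)
  expect_equal(sg_smooth(mix, 11, 2)$absorbance,
               2 * sg_smooth(a, 11, 2)$absorbance -
                 0.5 * sg_smooth(b, 11, 2)$absorbance, tolerance = 1e-10)
  expect_equal(sg_second_derivative(mix, 15, 3)$absorbance,
               2 * sg_second_derivative(a, 15, 3)$absorbance -
                 0.5 * sg_second_derivative(b, 15, 3)$absorbance,
               tolerance = 1e-10)
  # row-wise SNV commutes with channel subsetting only through restriction
  # applied first; SG commutes when the window fits inside the kept range
  lo <- a$wavenumbers[1]; hi <- a$wavenumbers[40]
  expect_equal(restrict_range(snv(a), lo, hi)$absorbance,
               snv(restrict_range(a, lo, hi))$absorbance, tolerance = 1e-12)
})

test_that("apply_preprocess composes restriction with the chosen method", {
  gen <- generate_spectra(default_cfg(seed = 17))
  raw <- apply_preprocess(gen$spectra, preprocess_spec("raw"))
  expect_equal(ncol(raw$absorbance), 751L)
  d2 <- apply_preprocess(gen$spectra, preprocess_spec("second_derivative"))
  expect_equal(dim(d2$absorbance), dim(raw$absorbance))
  sn <- apply_preprocess(gen$spectra, preprocess_spec("snv"))
  again <- snv(sn)
  expect_equal(again$absorbance, sn$absorbance, tolerance = 1e-9)
  expect_error(preprocess_spec("smooth", window = 10), "odd")
  expect_error(preprocess_spec("smooth", window = 11, polyorder = 11), "<")
})
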