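#' Configuration for the synthetic NIR spectrum generator
#'
#' Builds a validated configuration describing three-class near-infrared-like
#' absorbance spectra: a set of smooth Gaussian absorbance bands shared by
#' all classes, class-sensitive bands around 7200 cm^-1 whose amplitudes
#' differ by class, a per-sample additive baseline (offset plus linear
#' tilt), a per-sample multiplicative scatter factor, and additive channel
#' noise that grows above 10000 cm^-1. Outlying samples (off-subspace
#' "orthogonal" contamination, or within-subspace "leverage" scaling) can be
#' injected with ground truth recorded.
#'
#' Two class-sensitive sub-bands are used rather than one: with a single
#' band the three class-mean spectra would be collinear, and a linear
#' one-hot discriminant cannot isolate the middle of three collinear
#' classes no matter how large the separation. Two nearby bands with
#' different per-class amplitude patterns put the class means at the
#' corners of a triangle, which is what distinct phenotype expression
#' patterns look like spectrally.
#'
#' Defaults emulate a three-genotype seed study: class sizes 41/40/40 on a
#' 4000-12000 cm^-1 grid at 8 cm^-1 spacing (1001 channels), low absorbance
#' (< 1 AU), and a class separation small relative to the baseline and
#' scatter variation so that preprocessing choices matter.
#'
#' @param n_per_class named integer vector of samples per class.
#' @param grid numeric `c(start, stop, step)` of the wavenumber axis, cm^-1.
#' @param shared_bands data frame with columns `center`, `width`
#'   (Gaussian sigma) and `amplitude`, all classes share these bands.
#' @param class_bands data frame (columns `center`, `width`, `amplitude`)
#'   of bands whose amplitudes are shifted per class.
#' @param class_effect numeric matrix of per-class amplitude offsets, one
#'   row per class (rownames must match `n_per_class` names), one column
#'   per row of `class_bands`.
#' @param baseline_mean,baseline_sd additive per-sample offset distribution
#'   (absorbance units).
#' @param tilt_sd standard deviation of the per-sample linear baseline slope
#'   (absorbance units per cm^-1).
#' @param drift_sd per-channel standard deviation of an optional per-sample
#'   smooth baseline drift (absorbance units); the drift is a stationary
#'   Gaussian random curve (white noise convolved with a Gaussian kernel of
#'   width `drift_scale`), emulating the sample-specific curved scattering
#'   baselines of powdered material. Off (0) by default: such drift has a
#'   high effective rank, and a class of ~40 samples cannot support enough
#'   robust components to keep the outlier screen calibrated in its
#'   presence (see the methods vignette).
#' @param drift_scale correlation length of the drift in cm^-1.
#' @param scatter_sd standard deviation of the per-sample multiplicative
#'   scatter factor around 1.
#' @param noise_sd additive channel noise level (absorbance units).
#' @param highband_noise_factor multiplier applied to `noise_sd` for
#'   channels above `highband_start`.
#' @param highband_start wavenumber above which channels are noisier.
#' @param outliers list of outlier specs, each a list with fields `class`,
#'   `kind` (`"orthogonal"` or `"leverage"`) and `magnitude`.
#' @param seed integer RNG seed; identical seeds give bit-identical spectra.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = c(parent = 41, transgenic = 40,
                                         hybrid = 40),
                         grid = c(4000, 12000, 8),
                         shared_bands = default_shared_bands(),
                         class_bands = data.frame(
                           center = c(7200, 7060),
                           width = c(80, 120),
                           amplitude = c(0.15, 0.12)),
                         class_effect = rbind(parent = c(0, 0),
                                              transgenic = c(0.03, 0.02),
                                              hybrid = c(-0.03, 0.02)),
                         baseline_mean = 0.10, baseline_sd = 0.05,
                         tilt_sd = 1e-5,
                         drift_sd = 0, drift_scale = 400,
                         scatter_sd = 0.05,
                         noise_sd = 0.0015,
                         highband_noise_factor = 5,
                         highband_start = 10000,
                         outliers = list(),
                         seed = 1L) {
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class))))
    stop("n_per_class must be a named vector of class sizes")
  if (any(n_per_class < 0)) stop("class counts must be >= 0")
  if (any(n_per_class == 0))
    stop("empty class: ", paste(names(n_per_class)[n_per_class == 0],
                                collapse = ", "))
  stopifnot(length(grid) == 3, grid[3] > 0, grid[1] < grid[2])
  if (baseline_sd < 0 || tilt_sd < 0 || scatter_sd < 0 || noise_sd < 0 ||
      drift_sd < 0)
    stop("dispersion parameters must be >= 0")
  class_effect <- as.matrix(class_effect)
  if (!setequal(rownames(class_effect), names(n_per_class)))
    stop("class_effect rownames must match n_per_class names")
  if (ncol(class_effect) != nrow(class_bands))
    stop("class_effect needs one column per class band")
  for (ol in outliers) {
    if (!ol$kind %in% c("orthogonal", "leverage"))
      stop("unknown outlier kind: ", ol$kind)
    if (!ol$class %in% names(n_per_class))
      stop("outlier references unknown or empty class: ", ol$class)
  }
  structure(
    list(n_per_class = n_per_class, grid = grid,
         shared_bands = shared_bands, class_bands = class_bands,
         class_effect = class_effect,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         tilt_sd = tilt_sd, drift_sd = drift_sd, drift_scale = drift_scale,
         scatter_sd = scatter_sd, noise_sd = noise_sd,
         highband_noise_factor = highband_noise_factor,
         highband_start = highband_start,
         outliers = outliers, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default shared absorbance bands
#'
#' Six smooth Gaussian bands spread over 4200-8800 cm^-1, low absorbance,
#' resembling the broad overtone/combination bands of powdered plant
#' material.
#'
#' @return data frame with columns `center`, `width`, `amplitude`.
#' @export
default_shared_bands <- function() {
  data.frame(
    center    = c(4350, 4750, 5200, 5800, 6900, 8600),
    width     = c(80, 120, 150, 250, 200, 300),
    amplitude = c(0.45, 0.35, 0.50, 0.25, 0.20, 0.10)
  )
}

gaussian_band <- function(w, center, width, amplitude) {
  amplitude * exp(-0.5 * ((w - center) / width)^2)
}

# stationary smooth random curves: one row per sample, unit-free shape
# scaled so each channel has standard deviation sd
smooth_drift <- function(n, w, sd, scale) {
  p <- length(w)
  step <- (w[p] - w[1]) / (p - 1)
  half <- ceiling(3 * scale / step)
  kern <- stats::dnorm(seq(-half, half) * step, sd = scale)
  kern <- kern / sqrt(sum(kern^2))      # unit output variance
  raw <- matrix(stats::rnorm(n * (p + 2 * half)), n)
  out <- matrix(0, n, p)
  for (i in seq_len(n))
    out[i, ] <- sd * stats::convolve(raw[i, ], kern, type = "filter")
  out
}

#' Generate synthetic three-class NIR spectra with ground truth
#'
#' Each clean spectrum is
#' `scatter * (shared bands + class band + baseline) + noise`, with the
#' noise standard deviation multiplied by `highband_noise_factor` for
#' channels above `highband_start`. Configured outliers are then injected
#' (see [inject_orthogonal_outlier()] and [inject_leverage_sample()]) into
#' randomly chosen samples of the stated class, and recorded in the ground
#' truth.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `spectra` (a [spectra_set()]) and `truth`
#'   (data frame `sample_id`, `class`, `outlier` where `outlier` is
#'   `"none"`, `"orthogonal"` or `"leverage"`).
#' @export
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  w <- seq(cfg$grid[1], cfg$grid[2], by = cfg$grid[3])
  p <- length(w)
  classes <- names(cfg$n_per_class)
  labels <- rep(classes, times = cfg$n_per_class)
  n <- length(labels)

  shared <- rep(0, p)
  for (i in seq_len(nrow(cfg$shared_bands)))
    shared <- shared + gaussian_band(w, cfg$shared_bands$center[i],
                                     cfg$shared_bands$width[i],
                                     cfg$shared_bands$amplitude[i])
  band_shapes <- sapply(seq_len(nrow(cfg$class_bands)), function(b)
    gaussian_band(w, cfg$class_bands$center[b], cfg$class_bands$width[b], 1))
  class_amp <- sweep(cfg$class_effect[labels, , drop = FALSE], 2,
                     cfg$class_bands$amplitude, "+")

  offset <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  slope <- stats::rnorm(n, 0, cfg$tilt_sd)
  drift <- if (cfg$drift_sd > 0)
    smooth_drift(n, w, cfg$drift_sd, cfg$drift_scale)
  scatter <- stats::rnorm(n, 1, cfg$scatter_sd)
  noise_scale <- ifelse(w > cfg$highband_start,
                        cfg$noise_sd * cfg$highband_noise_factor,
                        cfg$noise_sd)
  noise <- matrix(stats::rnorm(n * p), n, p) *
    matrix(noise_scale, n, p, byrow = TRUE)

  clean <- matrix(0, n, p)
  for (i in seq_len(n)) {
    signal_i <- shared + as.vector(band_shapes %*% class_amp[i, ]) +
      offset[i] + slope[i] * (w - w[1])
    if (cfg$drift_sd > 0) signal_i <- signal_i + drift[i, ]
    clean[i, ] <- scatter[i] * signal_i
  }
  X <- clean + noise

  data <- spectra_set(X, w, labels,
                      meta = list(history = "raw", source = "synthetic"))
  outlier_of <- rep("none", n)

  for (ol in cfg$outliers) {
    members <- which(labels == ol$class & outlier_of == "none")
    if (length(members) == 0)
      stop("no remaining sample in class ", ol$class,
           " to turn into an outlier")
    victim <- members[sample.int(length(members), 1)]
    id <- data$sample_ids[victim]
    if (ol$kind == "orthogonal") {
      data <- inject_orthogonal_outlier(data, id, ol$magnitude)
    } else {
      data <- inject_leverage_sample(data, id, ol$magnitude)
    }
    outlier_of[victim] <- ol$kind
  }

  truth <- data.frame(sample_id = data$sample_ids, class = labels,
                      outlier = outlier_of, stringsAsFactors = FALSE)
  list(spectra = data, truth = truth)
}

#' Inject an orthogonal outlier
#'
#' Adds a Gaussian band at a wavenumber where no shared band sits (default
#' 9000 cm^-1, sigma 60 cm^-1), pushing the sample off the principal
#' subspace of the clean data: small score distance, large orthogonal
#' distance.
#'
#' @param data a [spectra_set()].
#' @param sample_id identifier of the sample to contaminate.
#' @param magnitude peak height of the added band, absorbance units.
#' @param center,width band position and Gaussian sigma in cm^-1.
#' @return The modified `spectra_set`; all other samples untouched.
#' @export
inject_orthogonal_outlier <- function(data, sample_id, magnitude = 0.1,
                                      center = 9000, width = 60) {
  i <- sample_index(data, sample_id)
  data$absorbance[i, ] <- data$absorbance[i, ] +
    gaussian_band(data$wavenumbers, center, width, magnitude)
  data
}

#' Inject a leverage sample
#'
#' Multiplies one sample's spectrum by a factor, an extreme excursion along
#' its own direction within the data span: large score distance.
#'
#' @param data a [spectra_set()].
#' @param sample_id identifier of the sample to scale.
#' @param factor positive multiplier.
#' @return The modified `spectra_set`.
#' @export
inject_leverage_sample <- function(data, sample_id, factor = 5) {
  if (factor <= 0) stop("factor must be > 0")
  i <- sample_index(data, sample_id)
  data$absorbance[i, ] <- data$absorbance[i, ] * factor
  data
}
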