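#' Preprocessing specification
#'
#' One of the four variants compared in the workflow: `"raw"` (range
#' restriction only), `"smooth"` (Savitzky-Golay smoothing),
#' `"second_derivative"` (Savitzky-Golay second derivative) or `"snv"`
#' (standard normal variate). Window/order defaults follow common NIR
#' practice: 11/2 for smoothing, 15/3 for the derivative.
#'
#' @param method one of `"raw"`, `"smooth"`, `"second_derivative"`, `"snv"`.
#' @param window odd Savitzky-Golay window length in channels.
#' @param polyorder polynomial order, must be < `window`.
#' @param keep_range `c(lo, hi)` wavenumber range in cm^-1 retained before
#'   the transform; the default drops the noisy 10000-12000 cm^-1 interval.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("raw", "smooth", "second_derivative",
                                       "snv"),
                            window = NULL, polyorder = NULL,
                            keep_range = c(4000, 10000)) {
  method <- match.arg(method)
  if (is.null(window))
    window <- switch(method, smooth = 11, second_derivative = 15, NA_real_)
  if (is.null(polyorder))
    polyorder <- switch(method, smooth = 2, second_derivative = 3, NA_real_)
  if (method %in% c("smooth", "second_derivative")) {
    if (window %% 2 != 1) stop("window must be odd")
    if (polyorder >= window) stop("polyorder must be < window")
    if (method == "second_derivative" && polyorder < 2)
      stop("polyorder must be >= 2 for a second derivative")
  }
  stopifnot(length(keep_range) == 2, keep_range[1] < keep_range[2])
  structure(list(method = method, window = window, polyorder = polyorder,
                 keep_range = keep_range),
            class = "preprocess_spec")
}

#' Restrict a spectra set to a wavenumber range
#'
#' Drops channels outside `[lo, hi]`; typically used to exclude the noisy
#' 10000-12000 cm^-1 interval before any modelling.
#'
#' @param data a [spectra_set()].
#' @param lo,hi range bounds in cm^-1, inclusive.
#' @return A `spectra_set` with the retained channels, order preserved.
#' @export
restrict_range <- function(data, lo, hi) {
  validate_spectra_set(data)
  keep <- data$wavenumbers >= lo & data$wavenumbers <= hi
  if (!any(keep))
    stop("no channels inside [", lo, ", ", hi, "] cm^-1")
  spectra_set(data$absorbance[, keep, drop = FALSE], data$wavenumbers[keep],
              data$labels, data$sample_ids,
              append_history(data$meta, sprintf("restrict[%g,%g]", lo, hi)))
}

check_sg_args <- function(data, window, polyorder) {
  p <- ncol(data$absorbance)
  if (window %% 2 != 1) stop("window must be odd")
  if (window > p) stop("window (", window, ") exceeds channel count (", p, ")")
  if (polyorder >= window) stop("polyorder must be < window")
}

#' Savitzky-Golay smoothing
#'
#' Per-spectrum local least-squares polynomial smoothing. Edge channels are
#' handled by fitting the polynomial on the one-sided window, so the output
#' has the same length as the input.
#'
#' @param data a [spectra_set()].
#' @param window odd window length in channels.
#' @param polyorder polynomial order, < window.
#' @return A smoothed `spectra_set` of identical shape.
#' @export
sg_smooth <- function(data, window = 11, polyorder = 2) {
  validate_spectra_set(data)
  check_sg_args(data, window, polyorder)
  out <- t(apply(data$absorbance, 1, signal::sgolayfilt,
                 p = polyorder, n = window, m = 0))
  spectra_set(out, data$wavenumbers, data$labels, data$sample_ids,
              append_history(data$meta,
                             sprintf("smooth[w=%d,o=%d]", window, polyorder)))
}

#' Savitzky-Golay second derivative
#'
#' Per-spectrum second derivative with respect to wavenumber, in
#' AU * cm^2 units, using the uniform channel spacing as the step. Requires
#' a uniform wavenumber grid (relative spacing deviation below 1e-6).
#'
#' @param data a [spectra_set()].
#' @param window odd window length in channels.
#' @param polyorder polynomial order, >= 2 and < window.
#' @return A `spectra_set` of second-derivative spectra, same shape.
#' @export
sg_second_derivative <- function(data, window = 15, polyorder = 3) {
  validate_spectra_set(data)
  check_sg_args(data, window, polyorder)
  if (polyorder < 2) stop("polyorder must be >= 2 for a second derivative")
  d <- diff(data$wavenumbers)
  step <- mean(d)
  if (max(abs(d - step)) / step > 1e-6)
    stop("wavenumber grid is not uniform; second derivative needs equal spacing")
  out <- t(apply(data$absorbance, 1, signal::sgolayfilt,
                 p = polyorder, n = window, m = 2, ts = step))
  spectra_set(out, data$wavenumbers, data$labels, data$sample_ids,
              append_history(data$meta,
                             sprintf("d2[w=%d,o=%d]", window, polyorder)))
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum to mean 0 and unit standard deviation
#' (n - 1 denominator), removing additive baseline and multiplicative
#' scatter per sample.
#'
#' @param data a [spectra_set()].
#' @return An SNV-transformed `spectra_set`.
#' @export
snv <- function(data) {
  validate_spectra_set(data)
  m <- rowMeans(data$absorbance)
  s <- apply(data$absorbance, 1, stats::sd)
  if (any(s == 0))
    stop("constant spectrum (zero variance), sample_id: ",
         paste(data$sample_ids[s == 0], collapse = ", "))
  out <- (data$absorbance - m) / s
  spectra_set(out, data$wavenumbers, data$labels, data$sample_ids,
              append_history(data$meta, "snv"))
}

#' Apply a preprocessing specification
#'
#' Restricts the wavenumber range, then applies the chosen row-wise
#' transform (`"raw"` applies the restriction only). All transforms are
#' per-sample, so nothing is fitted: train and test sets can be processed
#' independently without information leakage.
#'
#' @param data a [spectra_set()].
#' @param spec a [preprocess_spec()].
#' @return The preprocessed `spectra_set`.
#' @export
apply_preprocess <- function(data, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  out <- restrict_range(data, spec$keep_range[1], spec$keep_range[2])
  switch(spec$method,
         raw = out,
         smooth = sg_smooth(out, spec$window, spec$polyorder),
         second_derivative = sg_second_derivative(out, spec$window,
                                                  spec$polyorder),
         snv = snv(out))
}
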