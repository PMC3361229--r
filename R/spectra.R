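#' Construct a spectra set
#'
#' The container passed between all stages of the workflow: an N x p
#' absorbance matrix on a common wavenumber axis, with a class label and a
#' unique identifier per sample.
#'
#' @param absorbance numeric matrix, N samples by p channels, absorbance units.
#' @param wavenumbers numeric vector of length p, channel positions in
#'   cm^-1, strictly increasing.
#' @param labels character vector of N class names.
#' @param sample_ids vector of N unique sample identifiers. Defaults to
#'   1-based integers so that samples can be referred to by the row index
#'   they had in the source table.
#' @param meta list of free-form provenance. `meta$history` records the
#'   preprocessing steps applied so far (starts at `"raw"`).
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(absorbance, wavenumbers, labels,
                        sample_ids = seq_len(nrow(absorbance)),
                        meta = list(history = "raw")) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  labels <- as.character(labels)
  if (is.null(meta$history)) meta$history <- "raw"
  x <- structure(
    list(
      wavenumbers = wavenumbers,
      absorbance = absorbance,
      labels = labels,
      sample_ids = sample_ids,
      meta = meta
    ),
    class = "spectra_set"
  )
  validate_spectra_set(x)
  x
}

#' Check the structural invariants of a spectra set
#'
#' Stops with an informative message if the axis length does not match the
#' matrix, labels/ids are not one per row, ids are duplicated, wavenumbers
#' are not strictly increasing, or any absorbance value is non-finite.
#'
#' @param x a `spectra_set`.
#' @return `x`, invisibly.
#' @export
validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  n <- nrow(x$absorbance)
  p <- ncol(x$absorbance)
  if (length(x$wavenumbers) != p)
    stop("wavenumbers length (", length(x$wavenumbers),
         ") does not match number of channels (", p, ")")
  if (length(x$labels) != n || length(x$sample_ids) != n)
    stop("labels and sample_ids must have one entry per sample row (N = ",
         n, ")")
  dup <- x$sample_ids[duplicated(x$sample_ids)]
  if (length(dup) > 0)
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  if (p > 1 && any(diff(x$wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  bad <- which(!is.finite(x$absorbance), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite absorbance at row ", bad[1, 1], " (sample_id ",
         x$sample_ids[bad[1, 1]], "), column ", bad[1, 2],
         " (wavenumber ", x$wavenumbers[bad[1, 2]], ")")
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("Spectra set:", nrow(x$absorbance), "samples x",
      ncol(x$absorbance), "channels\n")
  cat("  wavenumbers:", min(x$wavenumbers), "-", max(x$wavenumbers),
      "cm^-1\n")
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  cat("  history:", paste(x$meta$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param data a `spectra_set`.
#' @param idx integer row indices or logical mask over samples.
#' @return A `spectra_set` with the selected samples, same channel axis.
#' @export
subset_samples <- function(data, idx) {
  validate_spectra_set(data)
  spectra_set(data$absorbance[idx, , drop = FALSE], data$wavenumbers,
              data$labels[idx], data$sample_ids[idx], data$meta)
}

#' Look up sample row indices by id
#'
#' @param data a `spectra_set`.
#' @param ids sample identifiers.
#' @return Integer row positions.
#' @export
sample_index <- function(data, ids) {
  pos <- match(ids, data$sample_ids)
  if (anyNA(pos))
    stop("unknown sample_id: ", paste(ids[is.na(pos)], collapse = ", "))
  pos
}

# append a step to the preprocessing history, returning an updated meta list
append_history <- function(meta, step) {
  meta$history <- c(meta$history, step)
  meta
}
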