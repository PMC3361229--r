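#' Read a wide-format spectra CSV
#'
#' Expected header: `sample_id,label,<w1>,<w2>,...` where the remaining
#' column names are the channel wavenumbers in cm^-1. One row per sample.
#'
#' @param path path to an existing CSV file.
#' @return A [spectra_set()]; `meta$source` records the file and
#'   `meta$history` starts at `"raw"`.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "sample_id" || names(df)[2] != "label")
    stop("malformed header: expected 'sample_id', 'label', then wavenumbers")
  wn_chr <- names(df)[-(1:2)]
  wn <- suppressWarnings(as.numeric(wn_chr))
  if (anyNA(wn))
    stop("non-numeric wavenumber column header: ",
         paste(wn_chr[is.na(wn)], collapse = ", "))
  if (length(wn) > 1 && any(diff(wn) <= 0))
    stop("wavenumber columns are not strictly increasing")
  ids <- df$sample_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  absorb <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(absorb) <- "double"
  dimnames(absorb) <- NULL
  bad <- which(!is.finite(absorb), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("missing or non-numeric absorbance at sample_id ",
         ids[bad[1, 1]], ", wavenumber ", wn[bad[1, 2]])
  spectra_set(absorb, wn, df$label, ids,
              meta = list(history = "raw", source = path))
}

#' Write a spectra set as a wide-format CSV
#'
#' Values are written with 15 significant digits so a write/read round trip
#' preserves the matrix well beyond typical spectrometer precision.
#'
#' @param data a valid [spectra_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(data, path) {
  validate_spectra_set(data)
  if (nrow(data$absorbance) == 0)
    stop("refusing to write an empty spectra set (N = 0)")
  df <- data.frame(
    sample_id = data$sample_ids,
    label = data$labels,
    stringsAsFactors = FALSE
  )
  mat <- data$absorbance
  body <- as.data.frame(
    matrix(formatC(mat, digits = 15, format = "g"), nrow = nrow(mat)),
    stringsAsFactors = FALSE
  )
  names(body) <- formatC(data$wavenumbers, digits = 15, format = "g")
  out <- cbind(df, body)
  utils::write.csv(out, path, row.names = FALSE, quote = c(1, 2))
  invisible(path)
}

#' Write an outlier-diagnosis table as TSV
#'
#' One row per diagnosed sample: id, score distance, orthogonal distance,
#' group assignment and whether the sample is excluded from modelling.
#'
#' @param diag a `robpca_diagnosis` from [diagnose_class()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diagnosis_table <- function(diag, path) {
  stopifnot(inherits(diag, "robpca_diagnosis"))
  df <- as.data.frame(diag)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
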