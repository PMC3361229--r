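#' Full-workflow configuration
#'
#' Collects and validates every setting of the end-to-end workflow:
#' input source, wavenumber range, per-class robust-PCA outlier screening,
#' Kennard-Stone splitting, the preprocessing variants to compare, and the
#' PLSDA / MCCV settings. Validation happens here, before any computation.
#'
#' @param input a [synth_config()] to simulate spectra, or a path to a
#'   spectra CSV readable by [read_spectra_csv()].
#' @param variants list of [preprocess_spec()]; defaults to the four
#'   compared variants (raw, smoothing, second derivative, SNV).
#' @param keep_range retained wavenumber range in cm^-1 (the noisy band
#'   above 10000 cm^-1 is dropped by default).
#' @param significance tail probability of the outlier cutoffs.
#' @param coverage robust coverage fraction (h/N) of the rPCA estimator.
#' @param rpca_k fixed number of robust components, or `NULL` to select by
#'   cross-validated PRESS up to `rpca_k_max`.
#' @param rpca_k_max upper bound for the PRESS selection.
#' @param train_per_class Kennard-Stone training samples per class.
#' @param k_max,n_splits,leave_out,f_alpha PLSDA complexity-selection
#'   settings (see [plsda()]).
#' @param seed single global seed governing synthesis, rPCA direction
#'   sampling and MCCV resampling.
#' @param outdir directory for stage artifacts, or `NULL` to skip writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = synth_config(),
                            variants = default_variants(),
                            keep_range = c(4000, 10000),
                            significance = 0.05, coverage = 0.75,
                            rpca_k = NULL, rpca_k_max = 10,
                            train_per_class = 25,
                            k_max = 15, n_splits = 100, leave_out = 0.3,
                            f_alpha = 0.25, seed = 1L, outdir = NULL) {
  if (!inherits(input, "synth_config") && !is.character(input))
    stop("input must be a synth_config or a CSV path")
  if (length(variants) == 0 ||
      !all(vapply(variants, inherits, logical(1), "preprocess_spec")))
    stop("variants must be a non-empty list of preprocess_spec objects")
  if (n_splits < 1) stop("n_splits must be >= 1")
  if (leave_out <= 0 || leave_out > 0.5) stop("leave_out must be in (0, 0.5]")
  if (f_alpha <= 0 || f_alpha > 0.5) stop("f_alpha must be in (0, 0.5]")
  if (significance <= 0 || significance >= 1)
    stop("significance must be in (0, 1)")
  if (coverage < 0.5 || coverage > 1) stop("coverage must be in [0.5, 1]")
  if (train_per_class < 2) stop("train_per_class must be >= 2")
  structure(
    list(input = input, variants = variants, keep_range = keep_range,
         significance = significance, coverage = coverage,
         rpca_k = rpca_k, rpca_k_max = rpca_k_max,
         train_per_class = train_per_class, k_max = k_max,
         n_splits = n_splits, leave_out = leave_out, f_alpha = f_alpha,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' The four standard preprocessing variants
#'
#' @return List of [preprocess_spec()]: raw, smoothing, second derivative,
#'   SNV, all with the default 4000-10000 cm^-1 range.
#' @export
default_variants <- function() {
  list(preprocess_spec("raw"), preprocess_spec("smooth"),
       preprocess_spec("second_derivative"), preprocess_spec("snv"))
}

#' Run the full classification workflow
#'
#' Stage order: load or simulate spectra; restrict the wavenumber range;
#' per-class robust-PCA diagnosis on the restricted raw spectra; exclusion
#' of orthogonal outliers and bad leverage points (good leverage points are
#' retained); per-class Kennard-Stone split of the cleaned raw spectra,
#' shared by all preprocessing variants; then, per variant, preprocessing,
#' PLSDA training with MCCV/F-test complexity selection, and test-set
#' evaluation. The single seed in the configuration governs every source of
#' randomness, so reruns are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return An `evaluation_report` (see [evaluate_variants()]) with extra
#'   elements: `diagnoses`, `excluded_ids`, `split`, `truth` (for synthetic
#'   input) and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  if (inherits(cfg$input, "synth_config")) {
    sc <- cfg$input
    sc$seed <- cfg$seed
    gen <- generate_spectra(sc)
    data <- gen$spectra
    truth <- gen$truth
  } else {
    data <- read_spectra_csv(cfg$input)
  }

  restricted <- restrict_range(data, cfg$keep_range[1], cfg$keep_range[2])
  screening <- diagnose_outliers(restricted, k = cfg$rpca_k,
                                 k_max = cfg$rpca_k_max,
                                 significance = cfg$significance,
                                 alpha = cfg$coverage, seed = cfg$seed)
  clean <- screening$clean
  split <- split_per_class(clean, cfg$train_per_class)

  # split on raw restricted spectra, reused across all variants; the
  # variant transforms are per-sample so the split stays valid everywhere
  clean_full <- subset_samples(data,
                               data$sample_ids %in% clean$sample_ids)
  train <- subset_samples(clean_full,
                          clean_full$sample_ids %in% split$train_ids)
  test <- subset_samples(clean_full,
                         clean_full$sample_ids %in% split$test_ids)

  report <- evaluate_variants(train, test, cfg$variants,
                              k_max = cfg$k_max, n_splits = cfg$n_splits,
                              leave_out = cfg$leave_out,
                              f_alpha = cfg$f_alpha, seed = cfg$seed)
  report$diagnoses <- screening$diagnoses
  report$excluded_ids <- screening$excluded_ids
  report$split <- split
  report$truth <- truth
  report$config <- cfg

  if (!is.null(cfg$outdir)) write_pipeline_artifacts(report, clean_full,
                                                     train, test)
  report
}

write_pipeline_artifacts <- function(report, clean, train, test) {
  outdir <- report$config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_csv(clean, file.path(outdir, "clean.csv"))
  write_spectra_csv(train, file.path(outdir, "train.csv"))
  write_spectra_csv(test, file.path(outdir, "test.csv"))
  diag_df <- do.call(rbind, lapply(names(report$diagnoses), function(cl) {
    cbind(class = cl, as.data.frame(report$diagnoses[[cl]]))
  }))
  utils::write.table(diag_df, file.path(outdir, "diag.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$report, file.path(outdir, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    for (method in names(report$details)) {
      m <- report$details[[method]]$model
      jsonlite::write_json(
        list(classes = m$classes, k = m$k,
             x_mean = m$fit$x_mean, y_mean = m$fit$y_mean,
             coefficients = m$coefficients,
             rmse_mccv = if (!is.null(m$mccv)) m$mccv$rmse),
        file.path(outdir, paste0("model_", method, ".json")),
        digits = NA, auto_unbox = TRUE)
    }
  }
  invisible(outdir)
}
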