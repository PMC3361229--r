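#' Multiclass confusion matrix
#'
#' B x B table of counts with rows = true class, columns = predicted class,
#' plus the one-vs-rest TP/FN/TN/FP decomposition used by the sensitivity
#' and specificity formulas.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param classes ordered class names; every label must be among them.
#' @return Object of class `confusion`: `matrix` (integer B x B) and
#'   `classes`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, classes) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors must have equal length")
  ti <- match(true_labels, classes)
  pi <- match(predicted_labels, classes)
  if (anyNA(ti) || anyNA(pi))
    stop("label not among the declared classes: ",
         paste(unique(c(true_labels[is.na(ti)],
                        predicted_labels[is.na(pi)])), collapse = ", "))
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(ti)) m[ti[i], pi[i]] <- m[ti[i], pi[i]] + 1L
  structure(list(matrix = m, classes = classes), class = "confusion")
}

# one-vs-rest counts for a single class
ovr_counts <- function(counts, class) {
  stopifnot(inherits(counts, "confusion"))
  i <- match(class, counts$classes)
  if (is.na(i)) stop("unknown class: ", class)
  m <- counts$matrix
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  list(TP = tp, FN = fn, TN = tn, FP = fp)
}

#' Per-class sensitivity
#'
#' `TP / (TP + FN)` for the given class, one-vs-rest. Returns `NA` (an
#' explicit undefined marker, never 0) when the class is absent from the
#' truth.
#'
#' @param counts a [confusion_matrix()].
#' @param class class name.
#' @return Fraction in \[0, 1\], or `NA` if undefined.
#' @export
sensitivity <- function(counts, class) {
  n <- ovr_counts(counts, class)
  if (n$TP + n$FN == 0) return(NA_real_)
  n$TP / (n$TP + n$FN)
}

#' Per-class specificity
#'
#' `TN / (TN + FP)` for the given class, one-vs-rest. Returns `NA` when
#' every sample truly belongs to the class (no negatives).
#'
#' @inheritParams sensitivity
#' @return Fraction in \[0, 1\], or `NA` if undefined.
#' @export
specificity <- function(counts, class) {
  n <- ovr_counts(counts, class)
  if (n$TN + n$FP == 0) return(NA_real_)
  n$TN / (n$TN + n$FP)
}

#' Total classification accuracy
#'
#' `100 * trace / total`, in percent.
#'
#' @param counts a [confusion_matrix()].
#' @return Accuracy percentage.
#' @export
total_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion"))
  total <- sum(counts$matrix)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(counts$matrix)) / total
}

# half-up rounding to one decimal, the convention used in report tables
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' @export
print.confusion <- function(x, ...) {
  print(x$matrix)
  cat("Total accuracy:", round_half_up1(total_accuracy(x)), "%\n")
  invisible(x)
}

#' Compare preprocessing variants on a fixed train/test split
#'
#' For each preprocessing specification: preprocess training and test
#' spectra (all transforms are per-sample, so no statistics leak from the
#' test set; centering happens inside the PLSDA fit on training rows only),
#' fit a PLSDA model on the training set, predict the test set and tabulate
#' the confusion counts, per-class sensitivity/specificity and total
#' accuracy.
#'
#' @param train,test [spectra_set()] objects on the same channel axis.
#' @param variants list of [preprocess_spec()] objects.
#' @param k_max,n_splits,leave_out,f_alpha,seed passed to [plsda()].
#' @return Object of class `evaluation_report`: `report` (one row per
#'   variant: method, wrongly classified, total accuracy), `per_class`
#'   (sensitivity/specificity per variant and class) and `details`
#'   (fitted models and confusion objects).
#' @export
evaluate_variants <- function(train, test, variants, k_max = 15,
                              n_splits = 100, leave_out = 0.3,
                              f_alpha = 0.25, seed = 1L) {
  if (length(variants) == 0) stop("variants must be non-empty")
  classes <- unique(train$labels)
  rows <- list(); pc_rows <- list(); details <- list()
  for (v in seq_along(variants)) {
    spec <- variants[[v]]
    tr <- apply_preprocess(train, spec)
    te <- apply_preprocess(test, spec)
    model <- plsda(tr, k_max = k_max, n_splits = n_splits,
                   leave_out = leave_out, f_alpha = f_alpha, seed = seed,
                   classes = classes)
    pred <- predict_class(model, te)
    cm <- confusion_matrix(te$labels, pred, classes)
    wrong <- sum(cm$matrix) - sum(diag(cm$matrix))
    rows[[v]] <- data.frame(
      method = spec$method, k = model$k, n_test = sum(cm$matrix),
      wrong = wrong,
      accuracy = round_half_up1(total_accuracy(cm)),
      stringsAsFactors = FALSE
    )
    pc_rows[[v]] <- data.frame(
      method = spec$method, class = classes,
      sensitivity = vapply(classes, function(cl) sensitivity(cm, cl),
                           numeric(1)),
      specificity = vapply(classes, function(cl) specificity(cm, cl),
                           numeric(1)),
      stringsAsFactors = FALSE
    )
    details[[spec$method]] <- list(model = model, confusion = cm)
  }
  structure(
    list(report = do.call(rbind, c(rows, make.row.names = FALSE)),
         per_class = do.call(rbind, c(pc_rows, make.row.names = FALSE)),
         details = details),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Test-set classification by preprocessing variant:\n")
  print(x$report)
  cat("\nPer-class metrics:\n")
  print(x$per_class, digits = 4)
  invisible(x)
}
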