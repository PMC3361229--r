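#' Kennard-Stone sample selection
#'
#' Deterministic greedy max-min selection of a representative subset: start
#' with the two samples at maximum Euclidean distance, then repeatedly add
#' the candidate whose minimum distance to the already-selected set is
#' largest. Ties are broken by the lowest row index, so the algorithm has
#' no randomness at all.
#'
#' @param X numeric matrix, n x p.
#' @param m number of samples to select, `2 <= m <= n`.
#' @return List with `selected` (indices in selection order) and
#'   `remaining` (the rest, in ascending order).
#' @export
kennard_stone <- function(X, m) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (m < 2) stop("m must be >= 2 (the initial pair is forced)")
  if (m > n) stop("m (", m, ") exceeds the number of samples (", n, ")")
  D <- as.matrix(stats::dist(X))

  # lexicographically smallest pair attaining the maximum distance
  dmax <- max(D)
  best <- c(NA_integer_, NA_integer_)
  for (i in seq_len(n - 1)) {
    j_hit <- which(D[i, (i + 1):n] == dmax)
    if (length(j_hit) > 0) {
      best <- c(i, i + j_hit[1])
      break
    }
  }
  selected <- best
  mind <- pmin(D[, best[1]], D[, best[2]])
  mind[selected] <- -Inf

  while (length(selected) < m) {
    nxt <- which.max(mind)          # which.max returns the first (lowest) tie
    selected <- c(selected, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  list(selected = as.integer(unname(selected)),
       remaining = setdiff(seq_len(n), selected))
}

#' Kennard-Stone split within each class
#'
#' Runs the Kennard-Stone selection separately on every class (classes can
#' have different sample distributions, so a representative training set is
#' assembled per class) and merges the results into one train/test split.
#'
#' @param data a [spectra_set()], usually after outlier removal.
#' @param m_per_class training samples per class: a single number used for
#'   all classes, or a named vector keyed by class.
#' @return Object of class `split_result`: `train_ids`, `test_ids`, and
#'   `per_class` (data frame of class, train and test counts).
#' @export
split_per_class <- function(data, m_per_class = 25) {
  validate_spectra_set(data)
  classes <- unique(data$labels)
  if (is.null(names(m_per_class))) {
    m_of <- stats::setNames(rep(m_per_class[1], length(classes)), classes)
  } else {
    if (!all(classes %in% names(m_per_class)))
      stop("m_per_class is missing classes: ",
           paste(setdiff(classes, names(m_per_class)), collapse = ", "))
    m_of <- m_per_class
  }
  train_ids <- c()
  test_ids <- c()
  rows <- list()
  for (cl in classes) {
    idx <- which(data$labels == cl)
    m <- m_of[[cl]]
    if (length(idx) < m)
      stop("class ", cl, " has ", length(idx),
           " samples, fewer than the requested ", m)
    ks <- kennard_stone(data$absorbance[idx, , drop = FALSE], m)
    train_ids <- c(train_ids, data$sample_ids[idx[ks$selected]])
    test_ids <- c(test_ids, data$sample_ids[idx[ks$remaining]])
    rows[[cl]] <- data.frame(class = cl, n_train = m,
                             n_test = length(ks$remaining),
                             stringsAsFactors = FALSE)
  }
  if (length(test_ids) == 0)
    warning("empty test set: every sample was selected for training")
  structure(
    list(train_ids = train_ids, test_ids = test_ids,
         per_class = do.call(rbind, c(rows, make.row.names = FALSE))),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("Kennard-Stone split:", length(x$train_ids), "train /",
      length(x$test_ids), "test\n")
  print(x$per_class)
  invisible(x)
}
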