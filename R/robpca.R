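#' Stahel-Donoho outlyingness
#'
#' Projection-pursuit outlyingness: for each sample, the maximum over a set
#' of candidate directions of its robustly standardized distance from the
#' projected data median,
#' `max_v |x'v - med(Xv)| / MAD(Xv)`.
#' Directions run through pairs of data points; if the number of pairs
#' exceeds `n_directions` a seeded random subset of pairs is used, so the
#' result is deterministic for a fixed seed.
#'
#' @param X numeric matrix, N x p, N >= 4.
#' @param n_directions maximum number of point-pair directions.
#' @param seed integer seed for the direction subsample.
#' @return Numeric N-vector of outlyingness values.
#' @export
outlyingness <- function(X, n_directions = 250, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > n_directions) {
    set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), n_directions), drop = FALSE]
  }
  out <- rep(0, n)
  used <- 0L
  for (j in seq_len(ncol(pairs))) {
    v <- X[pairs[1, j], ] - X[pairs[2, j], ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    z <- as.vector(X %*% (v / nv))
    s <- stats::mad(z)
    if (s == 0) next
    out <- pmax(out, abs(z - stats::median(z)) / s)
    used <- used + 1L
  }
  if (used == 0L)
    stop("degenerate data: no direction with nonzero robust scale")
  out
}

#' Robust principal component analysis
#'
#' A projection-pursuit / MCD hybrid in the spirit of the ROBPCA algorithm:
#' (1) the data are projected onto their affine span by singular value
#' decomposition; (2) the `h = ceiling(alpha * N)` samples with the smallest
#' Stahel-Donoho outlyingness are retained; (3) classical PCA of that subset
#' gives an initial k-dimensional subspace; (4) an MCD-style reweighting
#' step (consistency-corrected covariance of the subset scores, chi-square
#' 0.999 weight cut) flags score-space outliers, and points whose residual
#' off the initial subspace is grossly inflated (orthogonal distance above
#' 2.5 times the median) are dropped as well; the final center, loadings and
#' eigenvalues are the classical PCA of the accepted points.
#'
#' The final refit on the accepted set matters when N is much smaller than
#' p: a subspace estimated from the covered subset alone absorbs that
#' subset's noise, which would leave every uncovered sample with a visibly
#' inflated residual and wreck the calibration of the orthogonal-distance
#' cutoff. Genuine outliers stay out of the refit through the two weight
#' rules.
#'
#' @param X numeric matrix, N samples x p variables.
#' @param k number of components, `1 <= k <= min(N - 1, p)`.
#' @param alpha coverage fraction of the robust estimator, in \[0.5, 1\].
#' @param significance tail probability used later for distance cutoffs;
#'   stored on the model.
#' @param n_directions,seed passed to [outlyingness()].
#' @return Object of class `robpca`: list with `center` (p-vector),
#'   `loadings` (p x k, orthonormal columns), `eigenvalues` (k, decreasing),
#'   `k`, `alpha`, `significance`.
#' @export
robpca <- function(X, k, alpha = 0.75, significance = 0.05,
                   n_directions = 250, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (k < 1 || k > min(n - 1, p))
    stop("k must be between 1 and min(N - 1, p) = ", min(n - 1, p))
  if (alpha < 0.5 || alpha > 1) stop("alpha must be in [0.5, 1]")
  h <- ceiling(alpha * n)
  if (h < k + 1) stop("coverage h = ", h, " too small for k = ", k)

  cmean <- colMeans(X)
  Xc <- sweep(X, 2, cmean)
  sv <- svd(Xc, nu = min(n, p), nv = min(n, p))
  tol <- max(dim(Xc)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r == 0) stop("degenerate data: all samples identical")
  if (r < k) stop("data rank (", r, ") below requested k = ", k)
  V0 <- sv$v[, seq_len(r), drop = FALSE]
  S <- Xc %*% V0                       # scores in the affine span

  ol <- if (r == 1) abs(S[, 1] - stats::median(S[, 1])) /
          max(stats::mad(S[, 1]), .Machine$double.eps)
        else outlyingness(S, n_directions, seed)
  keep <- order(ol)[seq_len(h)]

  ctr0 <- colMeans(S[keep, , drop = FALSE])
  C0 <- stats::cov(S[keep, , drop = FALSE])
  e0 <- eigen(C0, symmetric = TRUE)
  P0 <- e0$vectors[, seq_len(k), drop = FALSE]

  Sc <- sweep(S, 2, ctr0)
  Tk <- Sc %*% P0                      # all samples, initial k-subspace
  mh <- colMeans(Tk[keep, , drop = FALSE])
  # consistency factor so the subset covariance estimates the normal scale
  cfac <- alpha / stats::pchisq(stats::qchisq(alpha, df = k), df = k + 2)
  Ch <- stats::cov(Tk[keep, , drop = FALSE]) * cfac
  d2 <- stats::mahalanobis(Tk, mh, Ch)
  # a generous acceptance quantile: at small N, every clean point kept out
  # of the refit pays for it with an inflated orthogonal distance later
  w_sd <- d2 <= stats::qchisq(0.999, df = k)

  od0 <- sqrt(pmax(rowSums(Sc^2) - rowSums(Tk^2), 0))
  med_od <- stats::median(od0)
  w_od <- if (med_od > 0) od0 <= 2.5 * med_od else rep(TRUE, n)
  w <- w_sd & w_od
  if (sum(w) < k + 1)
    w <- seq_len(n) %in% keep[seq_len(k + 1)]

  ctr_w <- colMeans(S[w, , drop = FALSE])
  ew <- eigen(stats::cov(S[w, , drop = FALSE]), symmetric = TRUE)
  if (ew$values[k] <= 0)
    stop("robust covariance is singular at k = ", k,
         "; reduce the number of components")

  loadings <- V0 %*% ew$vectors[, seq_len(k), drop = FALSE]
  center <- cmean + as.vector(V0 %*% ctr_w)
  structure(
    list(center = center, loadings = loadings,
         eigenvalues = ew$values[seq_len(k)],
         k = k, alpha = alpha, significance = significance),
    class = "robpca"
  )
}

#' @export
print.robpca <- function(x, ...) {
  cat("Robust PCA model: k =", x$k, "components,",
      length(x$center), "variables\n")
  cat("  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  cat("  coverage alpha =", x$alpha,
      ", cutoff significance =", x$significance, "\n")
  invisible(x)
}

#' Score distance
#'
#' Mahalanobis-type distance of each sample from the robust center within
#' the principal subspace: `SD_i = sqrt(sum_j t_ij^2 / lambda_j)`.
#'
#' @param model a fitted [robpca()] model.
#' @param X matrix with the model's number of columns.
#' @return Numeric vector of score distances.
#' @export
score_distance <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop("X has ", ncol(X), " columns; model expects ", length(model$center))
  T <- sweep(X, 2, model$center) %*% model$loadings
  sqrt(rowSums(sweep(T^2, 2, model$eigenvalues, "/")))
}

#' Orthogonal distance
#'
#' Euclidean norm of each sample's residual off the principal subspace:
#' `OD_i = || (x_i - center) - P P' (x_i - center) ||`.
#'
#' @inheritParams score_distance
#' @return Numeric vector of orthogonal distances.
#' @export
orthogonal_distance <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop("X has ", ncol(X), " columns; model expects ", length(model$center))
  Xc <- sweep(X, 2, model$center)
  R <- Xc - (Xc %*% model$loadings) %*% t(model$loadings)
  sqrt(rowSums(R^2))
}

#' Distance cutoffs for outlier diagnosis
#'
#' The score-distance cutoff is the square root of the `1 - significance`
#' chi-square quantile with k degrees of freedom. The orthogonal-distance
#' cutoff uses the Wilson-Hilferty normal approximation of OD^(2/3):
#' `(m + s * z_{1-significance})^(3/2)` with m, s the median and
#' MAD (x 1.4826) of the observed OD^(2/3).
#'
#' @param model a fitted [robpca()] model.
#' @param od orthogonal distances of the fitted samples.
#' @param significance tail probability; defaults to the model's.
#' @return List with `sd_cutoff` and `od_cutoff`.
#' @export
distance_cutoffs <- function(model, od, significance = model$significance) {
  sd_cutoff <- sqrt(stats::qchisq(1 - significance, df = model$k))
  if (all(od == 0)) {
    warning("all orthogonal distances are zero; od_cutoff set to 0")
    return(list(sd_cutoff = sd_cutoff, od_cutoff = 0))
  }
  u <- od^(2 / 3)
  m <- stats::median(u)
  s <- stats::mad(u)
  if (s == 0) {
    warning("zero robust scale of orthogonal distances; ",
            "od_cutoff equals their median")
    return(list(sd_cutoff = sd_cutoff, od_cutoff = m^(3 / 2)))
  }
  list(sd_cutoff = sd_cutoff,
       od_cutoff = (m + s * stats::qnorm(1 - significance))^(3 / 2))
}

#' Four-group outlier classification
#'
#' Classifies samples by comparing score and orthogonal distances to their
#' cutoffs: regular (small SD, small OD), good leverage (large SD, small
#' OD), orthogonal outlier (small SD, large OD), bad leverage (large SD,
#' large OD). "Large" means strictly greater than the cutoff; a distance
#' exactly equal to its cutoff counts as small.
#'
#' @param sd,od numeric vectors of equal length.
#' @param sd_cutoff,od_cutoff scalars.
#' @return Character vector over `"regular"`, `"good_leverage"`,
#'   `"orthogonal_outlier"`, `"bad_leverage"`.
#' @export
classify_samples <- function(sd, od, sd_cutoff, od_cutoff) {
  if (length(sd) != length(od))
    stop("sd and od must have equal length")
  big_sd <- sd > sd_cutoff
  big_od <- od > od_cutoff
  ifelse(big_sd & big_od, "bad_leverage",
         ifelse(big_sd, "good_leverage",
                ifelse(big_od, "orthogonal_outlier", "regular")))
}

#' Select the number of robust components by cross-validated PRESS
#'
#' Each cross-validation fold is left out in turn; a robust PCA with
#' `k_max` components is fitted on the remainder and the held-out samples'
#' squared reconstruction residuals are computed for every truncation
#' `k <= k_max`. Residuals are trimmed (smallest `trim` fraction kept) for
#' robustness and the pooled residual is divided by the residual dimension
#' `p - k`: projecting onto any k directions removes k dimensions of pure
#' noise, so the unscaled reconstruction error would keep falling even with
#' no structure left, while the per-dimension error stays flat on noise.
#' The smallest k whose scaled PRESS is within a relative tolerance of the
#' minimum is selected, so extra components must buy a real reduction in
#' prediction error.
#'
#' @param X numeric matrix.
#' @param k_max largest number of components considered.
#' @param folds number of cross-validation folds.
#' @param seed seed for fold assignment and direction sampling.
#' @param tol relative PRESS tolerance (default 0.05).
#' @param trim fraction of smallest residuals kept per k.
#' @param alpha coverage passed to [robpca()].
#' @return Selected number of components (integer).
#' @export
select_k_by_press <- function(X, k_max, folds = 5, seed = 1L, tol = 0.05,
                              trim = 0.9, alpha = 0.75) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_max < 1) stop("k_max must be >= 1")
  k_max <- min(k_max, ncol(X) - 1)
  if (k_max <= 1) return(1L)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(folds), length.out = n))
  resid2 <- matrix(NA_real_, n, k_max)
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train <- X[-test, , drop = FALSE]
    kf <- min(k_max, nrow(train) - 1)
    fit <- robpca(train, k = kf, alpha = alpha, seed = seed)
    Xc <- sweep(X[test, , drop = FALSE], 2, fit$center)
    T <- Xc %*% fit$loadings
    total <- rowSums(Xc^2)
    cum <- t(apply(T^2, 1, cumsum))
    for (k in seq_len(k_max))
      resid2[test, k] <- total - cum[, min(k, kf)]
  }
  # expected trimmed mass of a chi-square with the residual dimension as df,
  # so that a pure-noise profile is flat in k after scaling
  press <- vapply(seq_len(k_max), function(k) {
    df <- ncol(X) - k
    denom <- df * stats::pchisq(stats::qchisq(trim, df), df + 2)
    r <- sort(pmax(resid2[, k], 0))
    sum(r[seq_len(floor(trim * length(r)))]) / denom
  }, numeric(1))
  best <- min(press)
  as.integer(which(press < (1 + tol) * best)[1])
}

#' Robust outlier diagnosis of one class
#'
#' Fits a robust PCA to the samples of a single class (the intended input
#' is range-restricted raw spectra) and classifies every sample of that
#' class into the four SD/OD groups. Orthogonal outliers and bad leverage
#' points are marked excluded; good leverage points are retained, since
#' they extend rather than distort the class subspace.
#'
#' @param data a [spectra_set()].
#' @param class_label class to diagnose; must have at least 10 samples.
#' @param k number of components; if `NULL`, chosen by
#'   [select_k_by_press()] up to `k_max`.
#' @param k_max upper bound for component selection.
#' @param significance tail probability for the distance cutoffs.
#' @param alpha robust coverage fraction.
#' @param seed seed for direction sampling and PRESS folds.
#' @return Object of class `robpca_diagnosis`: model, per-sample SD/OD,
#'   cutoffs, group labels and the excluded flags.
#' @export
diagnose_class <- function(data, class_label, k = NULL, k_max = 10,
                           significance = 0.05, alpha = 0.75, seed = 1L) {
  validate_spectra_set(data)
  idx <- which(data$labels == class_label)
  if (length(idx) == 0) stop("unknown class: ", class_label)
  if (length(idx) < 10)
    stop("class ", class_label, " has only ", length(idx),
         " samples; need >= 10")
  X <- data$absorbance[idx, , drop = FALSE]
  if (is.null(k)) {
    k_max <- min(k_max, length(idx) - 2, ncol(X))
    k <- select_k_by_press(X, k_max, seed = seed, alpha = alpha)
  }
  model <- robpca(X, k = k, alpha = alpha, significance = significance,
                  seed = seed)
  sd_v <- score_distance(model, X)
  od_v <- orthogonal_distance(model, X)
  cuts <- distance_cutoffs(model, od_v)
  grp <- classify_samples(sd_v, od_v, cuts$sd_cutoff, cuts$od_cutoff)
  structure(
    list(model = model, class_label = class_label,
         sample_ids = data$sample_ids[idx], sd = sd_v, od = od_v,
         sd_cutoff = cuts$sd_cutoff, od_cutoff = cuts$od_cutoff,
         group = grp,
         excluded = grp %in% c("orthogonal_outlier", "bad_leverage")),
    class = "robpca_diagnosis"
  )
}

#' @export
as.data.frame.robpca_diagnosis <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, SD = x$sd, OD = x$od,
             group = x$group, excluded = x$excluded,
             stringsAsFactors = FALSE)
}

#' @export
print.robpca_diagnosis <- function(x, ...) {
  cat("Robust PCA diagnosis of class '", x$class_label, "': ",
      length(x$sd), " samples, k = ", x$model$k, "\n", sep = "")
  cat("  cutoffs: SD ", signif(x$sd_cutoff, 4), ", OD ",
      signif(x$od_cutoff, 4), "\n", sep = "")
  print(table(x$group))
  if (any(x$excluded))
    cat("  excluded sample_ids:",
        paste(x$sample_ids[x$excluded], collapse = ", "), "\n")
  invisible(x)
}

#' Diagnostic distance-distance plot
#'
#' Score distance against orthogonal distance with the two cutoffs, the
#' classical display for reading off the four outlier groups.
#'
#' @param x a `robpca_diagnosis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.robpca_diagnosis <- function(x, ...) {
  cols <- c(regular = 1, good_leverage = 4, orthogonal_outlier = 2,
            bad_leverage = 6)
  graphics::plot(x$sd, x$od, col = cols[x$group], pch = 19,
                 xlab = "Score distance", ylab = "Orthogonal distance",
                 main = paste("Outlier diagnosis:", x$class_label), ...)
  graphics::abline(v = x$sd_cutoff, h = x$od_cutoff, lty = 2)
  invisible(x)
}

#' Per-class outlier screening
#'
#' Runs [diagnose_class()] on every class of a spectra set and removes the
#' samples flagged as orthogonal outliers or bad leverage points.
#'
#' @param data a [spectra_set()] (typically range-restricted raw spectra).
#' @param ... passed to [diagnose_class()].
#' @return List with `diagnoses` (one `robpca_diagnosis` per class),
#'   `excluded_ids`, and `clean` (the spectra set without excluded samples).
#' @export
diagnose_outliers <- function(data, ...) {
  classes <- unique(data$labels)
  diagnoses <- lapply(classes, function(cl) diagnose_class(data, cl, ...))
  names(diagnoses) <- classes
  excluded_ids <- unlist(lapply(diagnoses,
                                function(d) d$sample_ids[d$excluded]),
                         use.names = FALSE)
  keep <- !(data$sample_ids %in% excluded_ids)
  list(diagnoses = diagnoses, excluded_ids = excluded_ids,
       clean = subset_samples(data, keep))
}
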