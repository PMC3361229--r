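#' One-hot class encoding
#'
#' Builds the N x B response matrix for multiclass discriminant PLS: the
#' row of a sample in class i has 1 at position i and 0 elsewhere.
#'
#' @param labels character vector of class labels.
#' @param classes ordered vector of the B class names.
#' @return List with `classes` and the 0/1 matrix `Y` (N x B).
#' @export
encode_onehot <- function(labels, classes) {
  pos <- match(labels, classes)
  if (anyNA(pos))
    stop("label not among the declared classes: ",
         paste(unique(labels[is.na(pos)]), collapse = ", "))
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(pos), pos)] <- 1
  list(classes = classes, Y = Y)
}

#' Fit a PLS2 regression by NIPALS
#'
#' Mean-centers X and Y and extracts up to `k` latent variables by the
#' NIPALS algorithm with deflation. The deflation path is kept (weights W,
#' X-loadings P, Y-loadings Q), so predictions at every intermediate number
#' of components are available without refitting — the property the
#' Monte-Carlo cross-validation relies on. Extraction stops early, with a
#' warning, if the X residual is numerically exhausted. A response column
#' that is constant after centering simply receives zero loadings.
#'
#' @param X numeric matrix, N x p.
#' @param Y numeric matrix, N x B.
#' @param k number of latent variables, `k <= min(N - 1, p)`.
#' @return List of class `pls2_fit` with `x_mean`, `y_mean`, `W`, `P`, `Q`
#'   and `k` (the number actually extracted).
#' @export
fit_pls2 <- function(X, Y, k) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); b <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (k < 1 || k > min(n - 1, p))
    stop("k must be between 1 and min(N - 1, p) = ", min(n - 1, p))
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean)
  F <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, k); P <- matrix(0, p, k); Q <- matrix(0, b, k)
  x_scale <- sum(E^2)
  used <- 0L
  for (a in seq_len(k)) {
    if (sum(E^2) < 1e-12 * max(x_scale, 1)) {
      warning("X residual exhausted after ", used,
              " components; requested ", k)
      break
    }
    fss <- colSums(F^2)
    if (max(fss) < 1e-24) {
      # Y fully explained: extract a principal direction of E, zero q
      w <- crossprod(E, E[, which.max(colSums(E^2))])
      w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      q <- rep(0, b)
    } else {
      u <- F[, which.max(fss)]
      tt_old <- rep(0, n)
      for (iter in seq_len(200)) {
        w <- crossprod(E, u)
        w <- w / sqrt(sum(w^2))
        tt <- E %*% w
        q <- crossprod(F, tt) / sum(tt^2)
        if (sum(q^2) == 0) break
        u <- F %*% q / sum(q^2)
        if (sqrt(sum((tt - tt_old)^2)) <= 1e-12 * sqrt(sum(tt^2))) break
        tt_old <- tt
      }
    }
    pl <- crossprod(E, tt) / sum(tt^2)
    E <- E - tt %*% t(pl)
    F <- F - tt %*% t(q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q
    used <- a
  }
  structure(list(x_mean = x_mean, y_mean = y_mean,
                 W = W[, seq_len(used), drop = FALSE],
                 P = P[, seq_len(used), drop = FALSE],
                 Q = Q[, seq_len(used), drop = FALSE],
                 k = used),
            class = "pls2_fit")
}

#' Regression coefficients of a PLS2 fit at a given complexity
#'
#' `B_k = W_k (P_k' W_k)^{-1} Q_k'`, the direct p x B coefficient matrix
#' equivalent to the first k deflation steps.
#'
#' @param fit a [fit_pls2()] result.
#' @param k number of components, `<= fit$k`.
#' @return p x B coefficient matrix.
#' @export
pls_coefficients <- function(fit, k = fit$k) {
  stopifnot(k >= 1, k <= fit$k)
  Wk <- fit$W[, seq_len(k), drop = FALSE]
  Pk <- fit$P[, seq_len(k), drop = FALSE]
  Qk <- fit$Q[, seq_len(k), drop = FALSE]
  Wk %*% solve(crossprod(Pk, Wk), t(Qk))
}

# test-set scores under the rotation W (P'W)^{-1}; cumulative predictions
# at every k <= fit$k are y_mean + T[, 1:k] %*% t(Q[, 1:k])
pls_scores <- function(fit, X) {
  Xc <- sweep(as.matrix(X), 2, fit$x_mean)
  Xc %*% (fit$W %*% solve(crossprod(fit$P, fit$W)))
}

#' Monte-Carlo cross-validation error trace
#'
#' Repeatedly leaves out a substantial random fraction of the training
#' samples (stratified by class by default, so no class disappears from a
#' kept set), fits a PLS2 model with `k_max` components on the remainder
#' and predicts the left-out responses at every complexity `k <= k_max`.
#' Squared errors are pooled over all response entries and splits:
#' `RMSEMCCV(k) = sqrt(pooled mean squared error at k)`.
#'
#' @param X,Y training predictors and one-hot responses.
#' @param k_max largest number of latent variables evaluated.
#' @param leave_out fraction of samples left out per split, in (0, 0.5].
#' @param n_splits number of random splits (the "sampling time").
#' @param seed RNG seed; the trace is reproducible bit-for-bit.
#' @param stratify_labels class labels for stratified resampling, or `NULL`
#'   for plain uniform sampling.
#' @return Object of class `mccv_result`: `rmse` (length `k_max`), `n_pred`
#'   (pooled prediction count per k), plus the settings. `selected_k` is
#'   filled in later by [select_k_ftest()].
#' @export
mccv_rmse <- function(X, Y, k_max, leave_out = 0.3, n_splits = 100,
                      seed = 1L, stratify_labels = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (leave_out <= 0 || leave_out > 0.5)
    stop("leave_out must be in (0, 0.5]")
  if (n_splits < 1) stop("n_splits must be >= 1")
  if (!is.null(stratify_labels)) {
    cls_idx <- split(seq_len(n), stratify_labels)
    n_out_cls <- vapply(cls_idx, function(ix)
      max(1L, as.integer(round(leave_out * length(ix)))), integer(1))
    n_out <- sum(n_out_cls)
  } else {
    n_out <- max(1L, as.integer(round(leave_out * n)))
  }
  if (n - n_out < k_max + 2)
    stop("each kept set must retain at least k_max + 2 = ", k_max + 2,
         " samples; reduce k_max or leave_out")
  set.seed(seed)
  sse <- rep(0, k_max)
  for (s in seq_len(n_splits)) {
    if (!is.null(stratify_labels)) {
      out <- unlist(mapply(function(ix, m) ix[sample.int(length(ix), m)],
                           cls_idx, n_out_cls, SIMPLIFY = FALSE),
                    use.names = FALSE)
    } else {
      out <- sample.int(n, n_out)
    }
    fit <- fit_pls2(X[-out, , drop = FALSE], Y[-out, , drop = FALSE], k_max)
    Tst <- pls_scores(fit, X[out, , drop = FALSE])
    for (k in seq_len(k_max)) {
      kk <- min(k, fit$k)
      pred <- sweep(Tst[, seq_len(kk), drop = FALSE] %*%
                      t(fit$Q[, seq_len(kk), drop = FALSE]),
                    2, fit$y_mean, "+")
      sse[k] <- sse[k] + sum((pred - Y[out, , drop = FALSE])^2)
    }
  }
  n_pred <- n_splits * n_out * ncol(Y)
  structure(list(rmse = sqrt(sse / n_pred), n_pred = n_pred,
                 k_max = k_max, leave_out = leave_out, n_splits = n_splits,
                 seed = seed, selected_k = NA_integer_, f_alpha = NA_real_),
            class = "mccv_result")
}

#' F-test selection of model complexity
#'
#' Picks the most parsimonious complexity whose cross-validated error is
#' not significantly higher than the minimum: with `k* = argmin RMSEMCCV`,
#' the statistic `F(k) = (RMSEMCCV(k) / RMSEMCCV(k*))^2` is compared to the
#' `1 - f_alpha` quantile of an F distribution with the pooled prediction
#' count as degrees of freedom on both sides; the smallest k passing is
#' selected. This deliberately errs toward fewer latent variables.
#'
#' @param mccv an [mccv_rmse()] result.
#' @param f_alpha significance level of the F-test (default 0.25).
#' @return The selected number of latent variables (integer).
#' @export
select_k_ftest <- function(mccv, f_alpha = 0.25) {
  stopifnot(inherits(mccv, "mccv_result"))
  if (f_alpha <= 0 || f_alpha > 0.5) stop("f_alpha must be in (0, 0.5]")
  rmse <- mccv$rmse
  k_star <- which.min(rmse)
  if (rmse[k_star] == 0) {
    return(as.integer(which(rmse == 0)[1]))
  }
  fq <- stats::qf(1 - f_alpha, mccv$n_pred, mccv$n_pred)
  fstat <- (rmse / rmse[k_star])^2
  as.integer(which(fstat <= fq)[1])
}

#' @export
print.mccv_result <- function(x, ...) {
  cat("Monte-Carlo cross-validation:", x$n_splits, "splits, leave-out",
      x$leave_out, "\n")
  cat("  RMSEMCCV:", signif(x$rmse, 4), "\n")
  if (!is.na(x$selected_k))
    cat("  selected k =", x$selected_k, "(F-test, alpha =", x$f_alpha, ")\n")
  invisible(x)
}

#' Multiclass PLS discriminant analysis
#'
#' Fits a PLSDA classifier: the class labels are one-hot encoded into an
#' N x B response matrix and a PLS2 regression of the responses on the
#' (mean-centered) spectra is fitted. The number of latent variables is
#' selected by Monte-Carlo cross-validation followed by an F-test on the
#' RMSEMCCV trace ([mccv_rmse()], [select_k_ftest()]), unless `ncomp` fixes
#' it directly. Prediction assigns each sample to the class whose predicted
#' response is nearest to 1.
#'
#' @param x a [spectra_set()] (its labels are used unless `labels` is
#'   given) or a numeric matrix of predictors.
#' @param labels class labels, one per row of `x`.
#' @param ncomp fixed number of latent variables; `NULL` (default) selects
#'   it by MCCV + F-test.
#' @param k_max largest complexity evaluated (capped so every resampled
#'   training set keeps at least `k_max + 2` samples).
#' @param n_splits MCCV sampling time (default 100).
#' @param leave_out MCCV leave-out fraction (default 0.3).
#' @param f_alpha F-test significance level (default 0.25).
#' @param stratify stratify the MCCV resampling by class (default TRUE).
#' @param seed RNG seed for the MCCV splits.
#' @param classes optional explicit class order; defaults to order of first
#'   appearance in the labels.
#' @return Object of class `plsda` with components `classes`, `fit` (the
#'   [fit_pls2()] path), `coefficients` (p x B at the selected complexity),
#'   `k`, and `mccv` (the trace, or `NULL` when `ncomp` was fixed).
#' @seealso [predict.plsda()], [plot.plsda()]
#' @export
plsda <- function(x, labels = NULL, ncomp = NULL, k_max = 15,
                  n_splits = 100, leave_out = 0.3, f_alpha = 0.25,
                  stratify = TRUE, seed = 1L, classes = NULL) {
  if (inherits(x, "spectra_set")) {
    if (is.null(labels)) labels <- x$labels
    wavenumbers <- x$wavenumbers
    X <- x$absorbance
  } else {
    X <- as.matrix(x)
    wavenumbers <- NULL
  }
  if (is.null(labels) || length(labels) != nrow(X))
    stop("need one class label per sample row")
  if (is.null(classes)) classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes")
  enc <- encode_onehot(labels, classes)
  n <- nrow(X)
  mccv <- NULL
  if (is.null(ncomp)) {
    n_out <- if (stratify) {
      sum(vapply(split(seq_len(n), labels), function(ix)
        max(1L, as.integer(round(leave_out * length(ix)))), integer(1)))
    } else max(1L, as.integer(round(leave_out * n)))
    k_max <- min(k_max, n - n_out - 2, ncol(X))
    if (k_max < 1) stop("too few samples for cross-validation")
    mccv <- mccv_rmse(X, enc$Y, k_max, leave_out, n_splits, seed,
                      stratify_labels = if (stratify) labels else NULL)
    k <- select_k_ftest(mccv, f_alpha)
    mccv$selected_k <- k
    mccv$f_alpha <- f_alpha
  } else {
    k <- as.integer(ncomp)
  }
  fit <- fit_pls2(X, enc$Y, k)
  if (fit$k < k) k <- fit$k
  structure(
    list(classes = classes, fit = fit,
         coefficients = pls_coefficients(fit, k), k = k,
         mccv = mccv, wavenumbers = wavenumbers,
         labels = labels, call = match.call()),
    class = "plsda"
  )
}

#' Predicted responses of a PLSDA model
#'
#' `Y_hat = (X - x_mean) B + y_mean` at the model's selected complexity.
#'
#' @param model a [plsda()] model.
#' @param x matrix or [spectra_set()] with the model's channels.
#' @return N x B matrix of predicted responses (columns named by class).
#' @export
predict_response <- function(model, x) {
  stopifnot(inherits(model, "plsda"))
  X <- if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
  if (ncol(X) != length(model$fit$x_mean))
    stop("newdata has ", ncol(X), " channels; model expects ",
         length(model$fit$x_mean))
  out <- sweep(sweep(X, 2, model$fit$x_mean) %*% model$coefficients,
               2, model$fit$y_mean, "+")
  colnames(out) <- model$classes
  out
}

#' Class assignment from predicted responses
#'
#' Assigns each sample to the class whose predicted response is nearest
#' to 1 (`argmin_j |y_hat_j - 1|`). Exact ties go to the lowest class
#' index, with a warning.
#'
#' @param model a [plsda()] model.
#' @param x matrix or [spectra_set()].
#' @return Character vector of predicted class labels.
#' @export
predict_class <- function(model, x) {
  yhat <- predict_response(model, x)
  dev <- abs(yhat - 1)
  pick <- apply(dev, 1, which.min)
  ties <- apply(dev, 1, function(r) sum(r == min(r)) > 1)
  if (any(ties))
    warning(sum(ties), " tied prediction(s) resolved to the lowest class index")
  model$classes[pick]
}

#' Predict method for PLSDA models
#'
#' @param object a [plsda()] model.
#' @param newdata matrix or [spectra_set()]; defaults to nothing (error).
#' @param type `"class"` for labels, `"response"` for the raw N x B
#'   predicted response matrix.
#' @param ... ignored.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("class", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") predict_response(object, newdata)
  else predict_class(object, newdata)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' @export
print.plsda <- function(x, ...) {
  cat("PLSDA model:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "),", x$k, "latent variables\n")
  if (!is.null(x$mccv))
    cat("  complexity by MCCV (", x$mccv$n_splits, " splits) + F-test (alpha = ",
        x$mccv$f_alpha, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  print(object)
  if (!is.null(object$mccv)) {
    cat("  RMSEMCCV by k:\n")
    print(signif(object$mccv$rmse, 4))
  }
  invisible(object)
}

#' RMSEMCCV trace plot
#'
#' Cross-validated error against model complexity, with the selected number
#' of latent variables marked.
#'
#' @param x a [plsda()] model fitted with MCCV selection.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, ...) {
  if (is.null(x$mccv)) stop("model was fitted with a fixed ncomp; no trace")
  graphics::plot(seq_along(x$mccv$rmse), x$mccv$rmse, type = "b",
                 xlab = "Latent variables", ylab = "RMSEMCCV", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}
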