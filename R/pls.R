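# NIPALS PLS1 on pre-centered data. For a single response the per-component
# iteration is closed-form: w = X'y (normalized), t = Xw, p = X't/t't,
# q = y't/t't, then X is deflated by t p'. Stops early (returning fewer
# components) when the residual covariance vanishes, i.e. the requested
# count exceeds the effective rank.
nipals_pls1 <- function(xc, yc, ncomp, tol = 1e-12) {
  p <- ncol(xc)
  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  scores <- matrix(0, nrow(xc), ncomp)
  ref <- NULL
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(xc, yc)
    wn <- sqrt(sum(w^2))
    if (is.null(ref)) ref <- wn
    if (wn <= tol * ref || wn == 0) break
    w <- w / wn
    t_ <- xc %*% w
    tt <- sum(t_^2)
    if (tt <= (tol * ref)^2) break
    pl <- crossprod(xc, t_) / tt
    q[k] <- sum(t_ * yc) / tt
    xc <- xc - t_ %*% t(pl)
    w_mat[, k] <- w
    p_mat[, k] <- pl
    scores[, k] <- t_
    a <- k
  }
  list(weights = w_mat[, seq_len(a), drop = FALSE],
       x_loadings = p_mat[, seq_len(a), drop = FALSE],
       y_loadings = q[seq_len(a)],
       scores = scores[, seq_len(a), drop = FALSE],
       ncomp = a)
}

# Regression-vector path: column a is the coefficient vector of the
# a-component model, b_a = W_a (P_a' W_a)^{-1} q_a.
coef_path <- function(fit) {
  r <- crossprod(fit$x_loadings, fit$weights)
  matrix(vapply(seq_len(fit$ncomp), function(a) {
    drop(fit$weights[, seq_len(a), drop = FALSE] %*%
           solve(r[seq_len(a), seq_len(a), drop = FALSE],
                 fit$y_loadings[seq_len(a)]))
  }, numeric(nrow(fit$weights))), nrow = nrow(fit$weights))
}

# Predictions of every nested model 1..ncomp for one centered row, via the
# same deflation the fit used: O(ncomp * p), no coefficient solve needed.
prefix_predictions <- function(fit, xrow_centered, y_mean) {
  r <- xrow_centered
  t_ <- numeric(fit$ncomp)
  for (k in seq_len(fit$ncomp)) {
    t_[k] <- sum(r * fit$weights[, k])
    r <- r - t_[k] * fit$x_loadings[, k]
  }
  y_mean + cumsum(t_ * fit$y_loadings)
}

resolve_mask <- function(mask, p) {
  if (is.null(mask)) return(seq_len(p))
  if (is.logical(mask)) {
    if (length(mask) != p) stop("logical mask length must equal P")
    mask <- which(mask)
  }
  mask <- as.integer(mask)
  if (length(mask) == 0) stop("mask selects no variables")
  if (any(mask < 1 | mask > p)) stop("mask indices out of range")
  mask
}

#' Fit a NIPALS PLS1 regression model
#'
#' Mean-centers `x` (optionally restricted to a variable mask) and `y` —
#' no variance scaling — and runs the NIPALS algorithm for `ncomp` latent
#' factors. The stored regression vector reproduces the sequential
#' algorithm's training predictions exactly.
#'
#' @param x calibration spectra: [spectra_set()] or numeric matrix.
#' @param y numeric response (analyte concentration, mg/mL), length N.
#' @param ncomp number of latent factors, `1 <= ncomp <= min(N - 1, P)`.
#' @param mask optional variable subset: integer indices or logical vector
#'   over the full wavelength axis (used by interval models). `NULL` means
#'   all variables.
#' @param analyte optional analyte name carried in the model.
#' @return Object of class `pls_model` with weights `W`, x/y loadings,
#'   scores, centering statistics, the coefficient path for 1..`ncomp`
#'   factors and the final regression vector `coef`.
#' @export
fit_pls <- function(x, y, ncomp, mask = NULL, analyte = NULL) {
  xm <- spectra_matrix(x)
  y <- as.numeric(y)
  if (nrow(xm) != length(y)) stop("x and y disagree on the number of samples")
  if (stats::var(y) == 0) stop("response has zero variance")
  p_full <- ncol(xm)
  mask <- resolve_mask(mask, p_full)
  xs <- xm[, mask, drop = FALSE]
  n <- nrow(xs)
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (ncomp > min(n - 1, length(mask))) {
    stop("ncomp exceeds min(N - 1, number of variables)")
  }
  x_mean <- colMeans(xs)
  y_mean <- mean(y)
  fit <- nipals_pls1(sweep(xs, 2, x_mean), y - y_mean, ncomp)
  if (fit$ncomp < ncomp) {
    stop(sprintf("ncomp = %d exceeds the effective rank (%d components)",
                 ncomp, fit$ncomp))
  }
  bp <- coef_path(fit)
  structure(list(analyte = analyte, ncomp = as.integer(ncomp),
                 weights = fit$weights, x_loadings = fit$x_loadings,
                 y_loadings = fit$y_loadings, scores = fit$scores,
                 x_mean = x_mean, y_mean = y_mean,
                 coef = bp[, ncomp], coef_path = bp,
                 mask = mask, p_full = p_full,
                 wavelengths = if (inherits(x, "spectra_set"))
                   x$grid$values else NULL),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model>%s %d latent factor(s), %d/%d variables\n",
              if (is.null(x$analyte)) "" else paste0(" ", x$analyte, ","),
              x$ncomp, length(x$mask), x$p_full))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata [spectra_set()] or matrix with the model's full number of
#'   wavelengths (the stored mask is applied internally).
#' @param ncomp predict with the first `ncomp` factors (default: all).
#' @param ... unused.
#' @return numeric vector of predicted concentrations.
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  xm <- spectra_matrix(newdata)
  if (inherits(newdata, "spectra_set") && !is.null(object$wavelengths)) {
    if (newdata$grid$n != length(object$wavelengths) ||
        any(abs(newdata$grid$values - object$wavelengths) > 1e-9)) {
      stop("wavelength grid of newdata does not match the model")
    }
  }
  if (ncol(xm) != object$p_full) {
    stop(sprintf("newdata has %d variables; model expects %d",
                 ncol(xm), object$p_full))
  }
  ncomp <- ncomp %||% object$ncomp
  if (ncomp < 1 || ncomp > object$ncomp) stop("invalid ncomp")
  b <- object$coef_path[, ncomp]
  drop(xm[, object$mask, drop = FALSE] %*% b) -
    sum(object$x_mean * b) + object$y_mean
}

#' Leave-one-out PRESS curve and latent-factor selection
#'
#' For each left-out sample the model is refit from scratch on the
#' remaining N-1 samples and the sample is predicted with every nested
#' factor count `a = 1..a_max`. `PRESS(a)` is the sum of squared
#' leave-one-out errors; the selected factor count is its global minimizer,
#' with ties going to the smaller `a`. Folds whose effective rank is below
#' `a_max` contribute their saturated (highest available) prediction to the
#' larger factor counts.
#'
#' @inheritParams fit_pls
#' @param a_max largest candidate factor count (default 10); silently
#'   capped at `min(N - 2, P)` with a warning when it exceeds `N - 2`.
#' @return Object of class `cv_curve`: `press` (length `a_max`),
#'   `rmsecv = sqrt(press / N)`, `selected`, `n`.
#' @export
loo_press <- function(x, y, a_max = 10, mask = NULL) {
  xm <- spectra_matrix(x)
  y <- as.numeric(y)
  n <- nrow(xm)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 samples")
  mask <- resolve_mask(mask, ncol(xm))
  xs <- xm[, mask, drop = FALSE]
  cap <- min(n - 2L, length(mask))
  if (a_max > cap) {
    warning(sprintf("a_max = %d capped at %d (= min(N - 2, P))", a_max, cap))
    a_max <- cap
  }
  press <- numeric(a_max)
  for (i in seq_len(n)) {
    xtr <- xs[-i, , drop = FALSE]
    ytr <- y[-i]
    x_mean <- colMeans(xtr)
    y_mean <- mean(ytr)
    fit <- nipals_pls1(sweep(xtr, 2, x_mean), ytr - y_mean, a_max)
    if (fit$ncomp == 0) {
      pred <- rep(y_mean, a_max)              # degenerate fold: null model
    } else {
      pred <- prefix_predictions(fit, xs[i, ] - x_mean, y_mean)
      if (fit$ncomp < a_max) {
        pred <- c(pred, rep(pred[fit$ncomp], a_max - fit$ncomp))
      }
    }
    press <- press + (y[i] - pred)^2
  }
  structure(list(press = press, rmsecv = sqrt(press / n),
                 selected = which.min(press), a_max = a_max, n = n),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve> selected %d factor(s); RMSECV = %.6g\n",
              x$selected, x$rmsecv[x$selected]))
  invisible(x)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Evaluate a calibration pipeline on a fixed split
#'
#' Runs one preprocessing method, latent-factor selection and a final PLS
#' fit on the calibration samples of a Kennard-Stone split, then scores the
#' standard metric triple: RMSEC and R2 on the calibration fit, RMSECV and
#' R2 from leave-one-out within the calibration set, RMSEP and R2 on the
#' held-out prediction set. Preprocessing statistics (the MSC reference)
#' are learned on the calibration set and frozen before the prediction set
#' is transformed.
#'
#' @param spectra full-dataset [spectra_set()].
#' @param reference full-dataset [reference_set()].
#' @param analyte analyte column to model.
#' @param split a [kennard_stone()] `split_result`.
#' @param method preprocessing method name (see [preprocess_methods()]).
#' @param mask optional variable mask (interval models).
#' @param ncomp fixed factor count, or `NULL` to select by LOO PRESS.
#' @param a_max PRESS search limit when `ncomp` is `NULL`.
#' @return Object of class `pls_evaluation`: `metrics` (one-row data.frame:
#'   method, ncomp, rmsec, r2_cal, rmsecv, r2_cv, rmsep, r2_pre), `model`,
#'   `cv` (the PRESS curve), and the frozen preprocessing `state`. RMSEP
#'   and R2_pre are `NA` when the prediction set is empty.
#' @export
evaluate_pipeline <- function(spectra, reference, analyte, split,
                              method = "RAW", mask = NULL, ncomp = NULL,
                              a_max = 10) {
  stopifnot(inherits(split, "split_result"))
  n <- nrow(spectra$x)
  if (max(c(split$calibration, split$prediction)) > n) {
    stop("split refers to samples beyond the dataset")
  }
  cal <- spectra[split$calibration]
  pp <- apply_preprocess(cal, method)
  y_cal <- reference_vector(reference, analyte, rownames(cal$x))
  cv <- loo_press(pp$spectra, y_cal, a_max = a_max, mask = mask)
  ncomp <- ncomp %||% cv$selected
  model <- fit_pls(pp$spectra, y_cal, ncomp, mask = mask, analyte = analyte)
  fitted_cal <- predict(model, pp$spectra)
  out <- data.frame(
    method = method, ncomp = ncomp,
    rmsec = rmse(y_cal, fitted_cal),
    r2_cal = r_squared(y_cal, fitted_cal),
    rmsecv = cv$rmsecv[ncomp],
    r2_cv = 1 - cv$press[ncomp] / sum((y_cal - mean(y_cal))^2),
    rmsep = NA_real_, r2_pre = NA_real_,
    stringsAsFactors = FALSE
  )
  if (length(split$prediction) > 0) {
    prd <- spectra[split$prediction]
    prd_pp <- apply_preprocess(prd, method, state = pp$state)
    y_prd <- reference_vector(reference, analyte, rownames(prd$x))
    pred <- predict(model, prd_pp$spectra)
    out$rmsep <- rmse(y_prd, pred)
    out$r2_pre <- r_squared(y_prd, pred)
  }
  structure(list(metrics = out, model = model, cv = cv, state = pp$state,
                 analyte = analyte),
            class = "pls_evaluation")
}

#' @export
print.pls_evaluation <- function(x, ...) {
  cat(sprintf("<pls_evaluation> %s, %s, %d factor(s)\n",
              x$analyte %||% "?", x$metrics$method, x$metrics$ncomp))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
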