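#' Fit a bagging-PLS ensemble
#'
#' Bootstrap-aggregated PLS: `B` member models are fit on bootstrap
#' resamples (size N, with replacement) of the calibration set, each via the
#' same NIPALS core as [fit_pls()], on the full spectrum or on a
#' variable mask (e.g. a SiPLS-selected subset). The member factor count is
#' fixed — normally the PRESS-selected count of the base model on the full
#' calibration set — so the ensemble isolates the effect of resampling.
#' Resamples whose response happens to be constant are redrawn (counted in
#' `redraws`). A master seed deterministically spawns per-member seeds, so
#' the ensemble, and every prefix of it, is reproducible.
#'
#' @inheritParams fit_pls
#' @param b number of bootstrap members (default 500).
#' @param ncomp latent factors per member.
#' @param seed master seed (required).
#' @param aggregate aggregation rule for predictions: "mean" (default) or
#'   "median".
#' @return Object of class `bagging_ensemble`: per-member coefficient
#'   vectors and intercepts, bootstrap index matrix (`b` x N), out-of-bag
#'   RMSE (`oob_rmse`), the mask, aggregation rule and seeds.
#' @export
fit_bagging <- function(x, y, b = 500, ncomp, mask = NULL, seed,
                        aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  xm <- spectra_matrix(x)
  y <- as.numeric(y)
  n <- nrow(xm)
  if (b < 1) stop("b must be >= 1")
  if (ncomp < 1 || ncomp > n - 1) stop("invalid member factor count")
  mask <- resolve_mask(mask, ncol(xm))
  xs <- xm[, mask, drop = FALSE]
  member_seeds <- spawn_seeds(seed, b)
  coefs <- matrix(0, length(mask), b)
  intercepts <- numeric(b)
  idx_mat <- matrix(0L, b, n)
  redraws <- 0L
  for (m in seq_len(b)) {
    idx <- with_seed(member_seeds[m], {
      repeat {
        cand <- sample.int(n, n, replace = TRUE)
        if (stats::var(y[cand]) > 0) break
        redraws <- redraws + 1L
      }
      cand
    })
    idx_mat[m, ] <- idx
    xb <- xs[idx, , drop = FALSE]
    yb <- y[idx]
    x_mean <- colMeans(xb)
    y_mean <- mean(yb)
    fit <- nipals_pls1(sweep(xb, 2, x_mean), yb - y_mean,
                       min(ncomp, n - 1L))
    a <- min(ncomp, fit$ncomp)                 # rank-deficient resample guard
    bvec <- coef_path(fit)[, a]
    coefs[, m] <- bvec
    intercepts[m] <- y_mean - sum(x_mean * bvec)
  }
  member_pred <- xs %*% coefs + matrix(intercepts, n, b, byrow = TRUE)
  # out-of-bag prediction: average members whose bootstrap missed sample i
  oob <- vapply(seq_len(n), function(i) {
    m_out <- which(rowSums(idx_mat == i) == 0)
    if (length(m_out) == 0) return(NA_real_)
    mean(member_pred[i, m_out])
  }, numeric(1))
  oob_rmse <- sqrt(mean((y - oob)^2, na.rm = TRUE))
  structure(list(b = as.integer(b), ncomp = as.integer(ncomp),
                 coefs = coefs, intercepts = intercepts,
                 bootstrap_indices = idx_mat, mask = mask,
                 p_full = ncol(xm), aggregate = aggregate,
                 seed = seed, member_seeds = member_seeds,
                 redraws = redraws, oob_rmse = oob_rmse),
            class = "bagging_ensemble")
}

#' @export
print.bagging_ensemble <- function(x, ...) {
  cat(sprintf(
    "<bagging_ensemble> %d members, %d factor(s), %d/%d variables, %s aggregation\n",
    x$b, x$ncomp, length(x$mask), x$p_full, x$aggregate))
  cat(sprintf("  out-of-bag RMSE: %.6g; degenerate resamples redrawn: %d\n",
              x$oob_rmse, x$redraws))
  invisible(x)
}

member_predictions <- function(ensemble, x) {
  xm <- spectra_matrix(x)
  if (ncol(xm) != ensemble$p_full) {
    stop(sprintf("newdata has %d variables; ensemble expects %d",
                 ncol(xm), ensemble$p_full))
  }
  xm[, ensemble$mask, drop = FALSE] %*% ensemble$coefs +
    matrix(ensemble$intercepts, nrow(xm), ensemble$b, byrow = TRUE)
}

#' Aggregated ensemble prediction
#'
#' @param ensemble a [fit_bagging()] ensemble.
#' @param x new spectra (full wavelength axis; the mask is applied
#'   internally).
#' @param first_b aggregate only the first `first_b` members (default: all),
#'   matching how an iteration-convergence curve is read.
#' @return numeric vector of aggregated predictions.
#' @export
predict_bagging <- function(ensemble, x, first_b = NULL) {
  stopifnot(inherits(ensemble, "bagging_ensemble"))
  first_b <- first_b %||% ensemble$b
  if (first_b < 1 || first_b > ensemble$b) stop("first_b out of range")
  mp <- member_predictions(ensemble, x)[, seq_len(first_b), drop = FALSE]
  if (ensemble$aggregate == "mean") rowMeans(mp) else
    apply(mp, 1, stats::median)
}

#' RMSEP convergence curve of a bagging ensemble
#'
#' RMSEP of the aggregated prediction as a function of the number of
#' members included, evaluated for every prefix `1..B`. With increasing
#' iterations the curve stabilizes; its tail is the ensemble's RMSEP.
#'
#' @param ensemble a [fit_bagging()] ensemble.
#' @param x test spectra.
#' @param y test concentrations (mg/mL).
#' @return numeric vector of length `B`; element `b` is the RMSEP using the
#'   first `b` members.
#' @export
rmsep_curve <- function(ensemble, x, y) {
  y <- as.numeric(y)
  if (length(y) == 0) stop("test set is empty")
  mp <- member_predictions(ensemble, x)
  if (nrow(mp) != length(y)) stop("x and y disagree on the number of samples")
  if (ensemble$aggregate == "mean") {
    cum <- t(apply(mp, 1, cumsum)) /
      matrix(seq_len(ensemble$b), length(y), ensemble$b, byrow = TRUE)
  } else {
    cum <- vapply(seq_len(ensemble$b), function(b) {
      apply(mp[, seq_len(b), drop = FALSE], 1, stats::median)
    }, numeric(length(y)))
    cum <- matrix(cum, nrow = length(y))
  }
  sqrt(colMeans((cum - y)^2))
}
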