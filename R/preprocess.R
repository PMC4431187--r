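#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a Savitzky-Golay filter to every spectrum (row). Edge points are
#' handled by fitting the same local polynomial to the asymmetric end
#' windows, so the wavelength grid keeps its full length and interval
#' bookkeeping stays exact. Derivatives are reported per grid step (i.e. per
#' 0.5 nm on the default grid); the scaling is constant across a dataset, so
#' it cancels in any regression on the filtered spectra.
#'
#' @param spectra a [spectra_set()] or numeric matrix (samples x variables).
#' @param window filter window length in points; odd, and > `polyorder`.
#' @param polyorder local polynomial order (default 2, the usual
#'   chemometrics choice).
#' @param deriv derivative order: 0 (smoothing), 1 or 2.
#' @return The filtered spectra, same class and shape as the input.
#' @export
savitzky_golay <- function(spectra, window = 11, polyorder = 2, deriv = 0) {
  x <- spectra_matrix(spectra)
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  if (ncol(x) < window) stop("spectra have fewer points than the filter window")
  out <- t(apply(x, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = deriv, ts = 1))
  dimnames(out) <- dimnames(x)
  replace_matrix(spectra, out)
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum to mean 0 and unit sample standard
#' deviation (the n-1 convention), removing per-sample offset and
#' multiplicative scatter.
#'
#' @inheritParams savitzky_golay
#' @return Transformed spectra, same class and shape.
#' @export
snv <- function(spectra) {
  x <- spectra_matrix(spectra)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0)) {
    stop("SNV undefined for constant spectrum: sample ",
         rownames(x)[which(s == 0)[1]] %||% which(s == 0)[1])
  }
  out <- (x - rowMeans(x)) / s
  dimnames(out) <- dimnames(x)
  replace_matrix(spectra, out)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum,
#' `x = a + b * reference + e`, and returns `(x - a) / b`. The reference
#' defaults to the mean spectrum of the data being corrected; when
#' correcting prediction data, pass the reference learned on the
#' calibration set so no test information leaks into the model.
#'
#' @inheritParams savitzky_golay
#' @param reference numeric vector of length P, or `NULL` to use the mean
#'   spectrum of `spectra`.
#' @return list with `spectra` (corrected, same class as input) and
#'   `reference` (the reference spectrum used).
#' @export
msc <- function(spectra, reference = NULL) {
  x <- spectra_matrix(spectra)
  if (is.null(reference)) reference <- colMeans(x)
  if (length(reference) != ncol(x)) {
    stop("MSC reference length does not match the number of wavelengths")
  }
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("MSC reference is constant")
  b <- as.vector(x %*% rc) / denom            # per-row slope
  if (any(b == 0)) {
    stop("MSC fitted slope is zero for sample ",
         rownames(x)[which(b == 0)[1]] %||% which(b == 0)[1])
  }
  a <- rowMeans(x) - b * mean(reference)      # per-row intercept
  out <- (x - a) / b
  dimnames(out) <- dimnames(x)
  list(spectra = replace_matrix(spectra, out), reference = reference)
}

#' Row normalization to unit Euclidean norm
#'
#' @inheritParams savitzky_golay
#' @return Transformed spectra with each row scaled to L2 norm 1.
#' @export
normalize_rows <- function(spectra) {
  x <- spectra_matrix(spectra)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    stop("cannot normalize all-zero spectrum: sample ",
         rownames(x)[which(nrm == 0)[1]] %||% which(nrm == 0)[1])
  }
  out <- x / nrm
  dimnames(out) <- dimnames(x)
  replace_matrix(spectra, out)
}

replace_matrix <- function(template, x) {
  if (inherits(template, "spectra_set")) {
    spectra_set(x, template$grid, template$meta)
  } else {
    x
  }
}

#' The preprocessing menu
#'
#' @return Character vector of the supported method names, in canonical
#'   comparison order: RAW, SG9, SG11, SG11+1D, SG11+2D, Normalize, MSC, SNV.
#' @export
preprocess_methods <- function() {
  c("RAW", "SG9", "SG11", "SG11+1D", "SG11+2D", "Normalize", "MSC", "SNV")
}

#' Apply a named preprocessing method
#'
#' Dispatches on the standard method names (case-insensitive): `RAW`
#' (identity), `SG9`/`SG11` (Savitzky-Golay smoothing, 9 or 11 points,
#' order 2), `SG11+1D`/`SG11+2D` (11-point filter with embedded first or
#' second derivative), `Normalize` (unit L2 row norm), `MSC` and `SNV`.
#'
#' MSC is the one stateful method: on calibration data (`state = NULL`) the
#' reference is the calibration mean spectrum and is returned in `state`;
#' on prediction data pass that state back in so the stored reference is
#' reused.
#'
#' @inheritParams savitzky_golay
#' @param method method name, one of [preprocess_methods()].
#' @param state `NULL` for calibration data, or the `state` returned by a
#'   previous call, for prediction data.
#' @return list with `spectra` (transformed) and `state` (frozen statistics
#'   for reuse on prediction data; `NULL` for stateless methods).
#' @export
apply_preprocess <- function(spectra, method, state = NULL) {
  key <- toupper(gsub("\\s", "", method))
  valid <- preprocess_methods()
  pos <- match(key, toupper(valid))
  if (is.na(pos)) {
    stop("unknown preprocessing method '", method, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  switch(valid[pos],
    "RAW" = list(spectra = spectra, state = NULL),
    "SG9" = list(spectra = savitzky_golay(spectra, window = 9), state = NULL),
    "SG11" = list(spectra = savitzky_golay(spectra, window = 11), state = NULL),
    "SG11+1D" = list(spectra = savitzky_golay(spectra, window = 11, deriv = 1),
                     state = NULL),
    "SG11+2D" = list(spectra = savitzky_golay(spectra, window = 11, deriv = 2),
                     state = NULL),
    "Normalize" = list(spectra = normalize_rows(spectra), state = NULL),
    "SNV" = list(spectra = snv(spectra), state = NULL),
    "MSC" = {
      res <- msc(spectra, reference = state$msc_reference)
      list(spectra = res$spectra, state = list(msc_reference = res$reference))
    }
  )
}
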