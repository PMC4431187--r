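#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min sample selection in Euclidean distance on the raw
#' spectra: the first two calibration samples are the most distant pair;
#' each subsequent sample maximizes its minimal distance to the set already
#' selected. The remaining samples form the prediction set. Ties (e.g.
#' duplicated spectra) are broken by the lowest sample index, so the split
#' is fully deterministic.
#'
#' @param spectra a [spectra_set()] or numeric matrix (samples x variables).
#' @param n_calibration number of calibration samples, between 2 and N
#'   (default 50, for the standard 50/25 split of a 75-sample run).
#' @return Object of class `split_result`: list with `calibration` (indices
#'   in selection order), `prediction` (remaining indices, ascending),
#'   `sample_ids` and `n_calibration`.
#' @export
kennard_stone <- function(spectra, n_calibration = 50) {
  x <- spectra_matrix(spectra)
  n <- nrow(x)
  if (n_calibration < 2 || n_calibration > n) {
    stop("n_calibration must be between 2 and the number of samples (", n, ")")
  }
  d <- as.matrix(stats::dist(x))
  # seed pair: maximal distance, ties -> smallest (i, j)
  up <- which(upper.tri(d), arr.ind = TRUE)
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  dv <- d[up]
  best <- which.max(dv)                       # first index among exact ties
  sel <- as.integer(up[best, ])
  mind <- pmin(d[, sel[1]], d[, sel[2]])      # distance to selected set
  mind[sel] <- -Inf
  names(mind) <- NULL
  while (length(sel) < n_calibration) {
    nxt <- which.max(mind)                    # ties -> lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  sel <- as.integer(unname(sel))
  ids <- rownames(x) %||% as.character(seq_len(n))
  structure(list(calibration = sel,
                 prediction = setdiff(seq_len(n), sel),
                 sample_ids = ids,
                 n_calibration = as.integer(n_calibration)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d prediction samples\n",
              length(x$calibration), length(x$prediction)))
  invisible(x)
}
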