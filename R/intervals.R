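#' Split the wavelength axis into equidistant intervals
#'
#' Partitions the variable indices `1..P` into `n_intervals` contiguous
#' blocks whose sizes differ by at most one; any remainder is distributed to
#' the leading intervals. On the default grid (P = 2800, 20 intervals) every
#' interval holds exactly 140 variables (70 nm), and interval 2 spans
#' 870.0--939.5 nm — the block conventionally labelled "870--940 nm".
#'
#' @param p number of variables.
#' @param n_intervals number of intervals (default 20).
#' @param grid optional [wavelength_grid()]; adds nm spans and display labels.
#' @return data.frame of class `interval_set` with columns `interval`,
#'   `start`, `end` (1-based, inclusive), `size`, and — when `grid` is
#'   given — `start_nm`, `end_nm` (last wavelength in the block) and `label`
#'   (integer-nm display form such as "870-940 nm").
#' @export
make_intervals <- function(p, n_intervals = 20, grid = NULL) {
  if (n_intervals < 1 || n_intervals > p) {
    stop("n_intervals must be between 1 and P")
  }
  base <- p %/% n_intervals
  extra <- p %% n_intervals
  size <- rep(base, n_intervals) + c(rep(1L, extra), rep(0L, n_intervals - extra))
  end <- cumsum(size)
  start <- end - size + 1L
  out <- data.frame(interval = seq_len(n_intervals), start = start,
                    end = end, size = size)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "wavelength_grid"), grid$n == p)
    out$start_nm <- grid$values[start]
    out$end_nm <- grid$values[end]
    out$label <- sprintf("%.0f–%.0f nm", out$start_nm,
                         out$start_nm + size * grid$step_nm)
  }
  class(out) <- c("interval_set", "data.frame")
  out
}

interval_columns <- function(intervals, which) {
  unlist(lapply(which, function(i) {
    seq.int(intervals$start[i], intervals$end[i])
  }), use.names = FALSE)
}

combo_label <- function(intervals, which) {
  if ("label" %in% names(intervals)) {
    paste(intervals$label[which], collapse = ", ")
  } else {
    paste(which, collapse = "+")
  }
}

#' Synergy-interval PLS (SiPLS) search
#'
#' Exhaustively evaluates every combination of `combo_size` out of
#' `n_intervals` equidistant spectral intervals: the combination's variables
#' are concatenated, the latent-factor count is chosen by leave-one-out
#' PRESS (capped at `a_max`), and the combination is scored by its RMSECV.
#' Results are ranked ascending by RMSECV (ties broken lexicographically by
#' interval indices) and compared against the full-spectrum baseline model.
#'
#' @inheritParams fit_pls
#' @param n_intervals number of equidistant intervals (default 20).
#' @param combo_size intervals per combination (default 3, i.e. the
#'   C(20, 3) = 1140-combination search).
#' @param a_max latent-factor search limit per combination.
#' @param grid optional [wavelength_grid()] for nm labels.
#' @return Object of class `sipls_result`: `table` (one row per
#'   combination: rank, interval indices, label, ncomp, rmsecv), `best`
#'   (integer indices of the winning combination), `baseline` (full-spectrum
#'   ncomp and rmsecv), `intervals`, `n_intervals`, `combo_size`.
#' @export
sipls_search <- function(x, y, n_intervals = 20, combo_size = 3, a_max = 10,
                         grid = NULL) {
  xm <- spectra_matrix(x)
  if (is.null(grid) && inherits(x, "spectra_set")) grid <- x$grid
  if (combo_size < 1 || combo_size > n_intervals) {
    stop("combo_size must be between 1 and n_intervals")
  }
  intervals <- make_intervals(ncol(xm), n_intervals, grid = grid)
  combos <- utils::combn(n_intervals, combo_size)
  nc <- ncol(combos)
  rmsecv <- numeric(nc)
  ncomp <- integer(nc)
  for (j in seq_len(nc)) {
    cols <- interval_columns(intervals, combos[, j])
    cv <- loo_press(xm, y, a_max = a_max, mask = cols)
    rmsecv[j] <- cv$rmsecv[cv$selected]
    ncomp[j] <- cv$selected
  }
  ord <- order(rmsecv, apply(combos, 2, paste, collapse = ","))
  tab <- data.frame(
    rank = seq_len(nc),
    combination = apply(combos[, ord, drop = FALSE], 2, paste, collapse = "+"),
    label = vapply(ord, function(j) combo_label(intervals, combos[, j]),
                   character(1)),
    ncomp = ncomp[ord], rmsecv = rmsecv[ord],
    stringsAsFactors = FALSE
  )
  base_cv <- loo_press(xm, y, a_max = a_max)
  structure(list(table = tab, best = combos[, ord[1]],
                 baseline = list(ncomp = base_cv$selected,
                                 rmsecv = base_cv$rmsecv[base_cv$selected]),
                 intervals = intervals, n_intervals = n_intervals,
                 combo_size = combo_size),
            class = "sipls_result")
}

#' @export
print.sipls_result <- function(x, n = 10, ...) {
  cat(sprintf("<sipls_result> %d combinations of %d/%d intervals\n",
              nrow(x$table), x$combo_size, x$n_intervals))
  cat(sprintf("  full-spectrum RMSECV %.6g (%d factors)\n",
              x$baseline$rmsecv, x$baseline$ncomp))
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}

#' Variable mask of a SiPLS combination
#'
#' @param result a [sipls_search()] result.
#' @param rank which ranked combination to take (default 1, the winner).
#' @return integer vector of variable indices.
#' @export
sipls_mask <- function(result, rank = 1) {
  stopifnot(inherits(result, "sipls_result"))
  which_iv <- as.integer(strsplit(result$table$combination[rank], "+",
                                  fixed = TRUE)[[1]])
  interval_columns(result$intervals, which_iv)
}

#' Moving-window PLS (MWPLS) scan
#'
#' Slides a contiguous window of each size `H` across the spectrum; at every
#' start position a PLS model is fit on the window's variables with the
#' latent-factor count selected by leave-one-out PRESS (capped at `a_max`
#' and `H - 1`), and its RMSECV is recorded. The scan reports the best
#' window per size and whether any window beats the full-spectrum RMSECV —
#' on broad, overlapping NIR bands it often does not.
#'
#' @inheritParams fit_pls
#' @param window_sizes vector of window sizes `H` in variables (default the
#'   odd sizes 13, 15, ..., 41).
#' @param a_max latent-factor search limit.
#' @param stride step between window start positions (default 1; larger
#'   strides trade resolution for speed).
#' @param grid optional [wavelength_grid()] for nm annotation.
#' @return Object of class `mwpls_result`: `map` (long data.frame: window
#'   size, start, center_nm, ncomp, rmsecv), `best_per_size`, `baseline`
#'   (full-spectrum ncomp and rmsecv), and `any_window_beats_full`.
#' @export
mwpls_scan <- function(x, y, window_sizes = seq(13, 41, by = 2), a_max = 10,
                       stride = 1, grid = NULL) {
  xm <- spectra_matrix(x)
  if (is.null(grid) && inherits(x, "spectra_set")) grid <- x$grid
  p <- ncol(xm)
  if (any(window_sizes < 3)) stop("window sizes must be >= 3")
  if (any(window_sizes > p)) stop("window size exceeds the number of variables")
  rows <- list()
  for (h in window_sizes) {
    starts <- seq.int(1L, p - h + 1L, by = stride)
    rv <- numeric(length(starts))
    nc <- integer(length(starts))
    for (s in seq_along(starts)) {
      cols <- seq.int(starts[s], starts[s] + h - 1L)
      cv <- loo_press(xm, y, a_max = min(a_max, h - 1L), mask = cols)
      rv[s] <- cv$rmsecv[cv$selected]
      nc[s] <- cv$selected
    }
    rows[[length(rows) + 1L]] <- data.frame(
      window = h, start = starts,
      center_nm = if (!is.null(grid))
        grid$values[starts + (h - 1L) %/% 2L] else NA_real_,
      ncomp = nc, rmsecv = rv
    )
  }
  map <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(map, map$window), function(d) {
    d[which.min(d$rmsecv), , drop = FALSE]
  }))
  rownames(best) <- NULL
  base_cv <- loo_press(xm, y, a_max = a_max)
  baseline <- list(ncomp = base_cv$selected,
                   rmsecv = base_cv$rmsecv[base_cv$selected])
  structure(list(map = map, best_per_size = best, baseline = baseline,
                 any_window_beats_full = any(map$rmsecv < baseline$rmsecv)),
            class = "mwpls_result")
}

#' @export
print.mwpls_result <- function(x, ...) {
  cat(sprintf("<mwpls_result> %d windows scanned; full-spectrum RMSECV %.6g\n",
              nrow(x$map), x$baseline$rmsecv))
  cat(sprintf("  any window beats the full spectrum: %s\n",
              x$any_window_beats_full))
  print(x$best_per_size, row.names = FALSE)
  invisible(x)
}
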