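#' Wavelength grid for NIR spectra
#'
#' Defines the uniform wavelength axis on which all spectra in a dataset
#' live. The grid is half-open: it covers `[start_nm, stop_nm)` in steps of
#' `step_nm`, so the default 800--2200 nm axis at 0.5 nm increment has
#' exactly 2800 variables (800.0, 800.5, ..., 2199.5 nm).
#'
#' @param start_nm first wavelength, in nm.
#' @param stop_nm exclusive upper wavelength bound, in nm.
#' @param step_nm wavelength increment, in nm; must divide
#'   `stop_nm - start_nm` evenly.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm`, `values` (the wavelength vector) and `n` (number
#'   of variables).
#' @examples
#' g <- wavelength_grid()
#' g$n          # 2800
#' head(g$values)
#' @export
wavelength_grid <- function(start_nm = 800, stop_nm = 2200, step_nm = 0.5) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (start_nm >= stop_nm) stop("start_nm must be < stop_nm")
  n <- (stop_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-9) {
    stop("step_nm must divide (stop_nm - start_nm) evenly")
  }
  n <- as.integer(round(n))
  structure(
    list(
      start_nm = start_nm,
      stop_nm = stop_nm,
      step_nm = step_nm,
      values = start_nm + step_nm * (seq_len(n) - 1),
      n = n
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> [%g, %g) nm, step %g nm, %d variables\n",
    x$start_nm, x$stop_nm, x$step_nm, x$n
  ))
  invisible(x)
}

# Reconstruct a grid from a vector of wavelengths (used when reading files).
# Requires a strictly increasing, uniform axis.
grid_from_values <- function(values, tol = 1e-9) {
  if (length(values) < 2) stop("need at least two wavelengths to infer a grid")
  d <- diff(values)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  step <- d[1]
  if (any(abs(d - step) > tol)) {
    stop("wavelength grid is irregular: step varies by more than ", tol, " nm")
  }
  wavelength_grid(values[1], values[length(values)] + step, step)
}
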