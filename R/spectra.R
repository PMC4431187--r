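#' Spectra container
#'
#' Bundles an N x P absorbance matrix with its wavelength grid and per-sample
#' metadata (batch, sampling time). Rows are samples, columns are wavelengths.
#'
#' @param x numeric matrix, N samples x P wavelengths (absorbance units).
#' @param grid a [wavelength_grid()] whose length matches `ncol(x)`.
#' @param meta optional `data.frame` with one row per sample; a `sample_id`
#'   column is added from `rownames(x)` if absent. Conventional columns are
#'   `batch` (extraction batch index) and `time_min` (minutes relative to
#'   reaching the boil; heating-phase samples have negative times).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(x, grid, meta = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("spectra must be numeric")
  if (!inherits(grid, "wavelength_grid")) grid <- grid_from_values(grid)
  if (ncol(x) != grid$n) {
    stop(sprintf("spectra have %d columns but grid has %d wavelengths",
                 ncol(x), grid$n))
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  colnames(x) <- format_wavelength(grid$values)
  if (is.null(meta)) {
    meta <- data.frame(sample_id = rownames(x), stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta)
    if (is.null(meta$sample_id)) meta$sample_id <- rownames(x)
    if (nrow(meta) != nrow(x)) stop("meta must have one row per sample")
  }
  structure(list(x = x, grid = grid, meta = meta), class = "spectra_set")
}

format_wavelength <- function(w) sprintf("%.1f", w)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%g-%g nm, step %g)\n",
              nrow(x$x), x$grid$n, x$grid$start_nm, x$grid$stop_nm,
              x$grid$step_nm))
  extra <- setdiff(names(x$meta), "sample_id")
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$x)

#' @export
as.matrix.spectra_set <- function(x, ...) x$x

#' Subset a spectra_set by sample
#'
#' @param x a `spectra_set`.
#' @param i sample indices (integer, logical or sample ids).
#' @param ... unused.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, rownames(x$x))
  spectra_set(x$x[i, , drop = FALSE], x$grid, x$meta[i, , drop = FALSE])
}

# Accept either a spectra_set or a bare matrix everywhere downstream.
spectra_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$x else as.matrix(x)
}

#' Reference concentration container
#'
#' Per-sample analyte concentrations (mg/mL) from the reference assay; these
#' are the regression targets for calibration.
#'
#' @param conc numeric matrix or data.frame, one column per analyte.
#' @param sample_ids character vector of sample ids; defaults to the row
#'   names of `conc`.
#' @return A `data.frame` of class `reference_set` with a `sample_id` column
#'   followed by one numeric column per analyte.
#' @export
reference_set <- function(conc, sample_ids = rownames(conc)) {
  conc <- as.data.frame(conc)
  if (!all(vapply(conc, is.numeric, logical(1)))) {
    stop("concentrations must be numeric")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(conc)))
  out <- cbind(data.frame(sample_id = as.character(sample_ids),
                          stringsAsFactors = FALSE), conc)
  rownames(out) <- NULL
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Analyte names of a reference set
#' @param ref a [reference_set()].
#' @return character vector of analyte column names.
#' @export
analytes <- function(ref) setdiff(names(ref), "sample_id")

# Pull one analyte's concentrations aligned to the samples of a spectra_set.
reference_vector <- function(ref, analyte, ids) {
  if (!analyte %in% analytes(ref)) {
    stop("unknown analyte '", analyte, "'; available: ",
         paste(analytes(ref), collapse = ", "))
  }
  m <- match(ids, ref$sample_id)
  if (anyNA(m)) {
    stop("reference values missing for sample(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  }
  ref[[analyte]][m]
}
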