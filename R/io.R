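# Delimited-text IO. Numeric values are written with 17 significant digits
# so a write-then-read round trip is bit-identical.

num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read a spectra CSV
#'
#' The package-standard spectra file is comma-delimited with a header row of
#' `sample_id`, optional metadata columns prefixed `meta_`, then one column
#' per wavelength (nm, one decimal). One row per sample.
#'
#' @param spectra a [spectra_set()].
#' @param path output file.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns
#'   a [spectra_set()].
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  meta <- spectra$meta
  meta_cols <- setdiff(names(meta), "sample_id")
  header <- c("sample_id", paste0("meta_", meta_cols),
              format_wavelength(spectra$grid$values))
  body <- cbind(meta$sample_id,
                do.call(cbind, c(lapply(meta_cols, function(c) {
                  v <- meta[[c]]
                  if (is.numeric(v)) num_chr(v) else as.character(v)
                }), list(matrix(num_chr(spectra$x), nrow(spectra$x))))))
  writeLines(c(paste(header, collapse = ","),
               apply(body, 1, paste, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = "sample_id"))
  nm <- names(dt)
  if (nm[1] != "sample_id") stop("first column must be 'sample_id'")
  ids <- dt$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta_cols <- grep("^meta_", nm, value = TRUE)
  wl_cols <- setdiff(nm, c("sample_id", meta_cols))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) stop("non-numeric wavelength column name(s) in header")
  grid <- grid_from_values(wl)
  x <- as.matrix(dt[, wl_cols, with = FALSE])
  rownames(x) <- ids
  meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (mc in meta_cols) meta[[sub("^meta_", "", mc)]] <- dt[[mc]]
  spectra_set(x, grid, meta)
}

#' Write / read a reference-concentration CSV
#'
#' Comma-delimited: `sample_id` then one numeric column per analyte
#' (mg/mL). Row order is immaterial; data are aligned to spectra by id.
#'
#' @param reference a [reference_set()].
#' @param path file path.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns a [reference_set()].
#' @export
write_reference <- function(reference, path) {
  an <- analytes(reference)
  body <- cbind(reference$sample_id,
                do.call(cbind, lapply(an, function(a) num_chr(reference[[a]]))))
  writeLines(c(paste(c("sample_id", an), collapse = ","),
               apply(body, 1, paste, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = "sample_id"))
  if (names(dt)[1] != "sample_id") stop("first column must be 'sample_id'")
  if (anyDuplicated(dt$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(dt$sample_id[duplicated(dt$sample_id)]), collapse = ", "))
  }
  conc <- as.data.frame(dt[, -1, with = FALSE])
  reference_set(conc, sample_ids = dt$sample_id)
}

#' Align a reference set to the samples of a spectra set
#'
#' @param spectra a [spectra_set()].
#' @param reference a [reference_set()].
#' @return The reference set reordered to the spectra's sample order.
#' @export
align_reference <- function(spectra, reference) {
  ids <- rownames(spectra$x)
  m <- match(ids, reference$sample_id)
  if (anyNA(m)) {
    stop("reference values missing for sample(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  }
  out <- reference[m, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(reference)
  out
}

#' Write / read a calibration split file
#'
#' Two-column comma-delimited file (`sample_id`, `set` with values
#' `calibration`/`prediction`), so every downstream run can reuse an
#' identical split. Calibration rows appear in selection order.
#'
#' @param split a [kennard_stone()] `split_result`.
#' @param path file path.
#' @param spectra the [spectra_set()] the split indices refer to (needed by
#'   `read_split` to map ids back to row indices).
#' @return `write_split` returns `path` invisibly; `read_split` a
#'   `split_result`.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  ids <- split$sample_ids
  lines <- c("sample_id,set",
             paste0(ids[split$calibration], ",calibration"),
             paste0(ids[split$prediction], ",prediction"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path, spectra) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = "character")
  if (!all(c("sample_id", "set") %in% names(dt))) {
    stop("split file must have columns sample_id, set")
  }
  ids <- rownames(spectra$x)
  m <- match(dt$sample_id, ids)
  if (anyNA(m)) {
    stop("split refers to unknown sample(s): ",
         paste(dt$sample_id[is.na(m)], collapse = ", "))
  }
  cal <- m[dt$set == "calibration"]
  prd <- sort(m[dt$set == "prediction"])
  structure(list(calibration = cal, prediction = prd, sample_ids = ids,
                 n_calibration = length(cal)),
            class = "split_result")
}

#' Write a simulated dataset to a directory
#'
#' Emits `spectra.csv`, `references.csv` and a `truth.yaml` sidecar holding
#' the generator's seed, band model, kinetics draws and per-sample latent
#' draws (scatter factor, baseline offset and slope).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "nir_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(sim$spectra, file.path(dir, "spectra.csv"))
  write_reference(sim$reference, file.path(dir, "references.csv"))
  tr <- sim$truth
  sidecar <- list(
    seed = tr$seed,
    grid = list(start_nm = tr$grid$start_nm, stop_nm = tr$grid$stop_nm,
                step_nm = tr$grid$step_nm),
    bands = lapply(tr$bands, function(b) as.list(as.data.frame(b))),
    kinetics_draws = list(c_inf = as.vector(tr$kinetic_draws$c_inf),
                          k = tr$kinetic_draws$k),
    additive_sd = tr$additive_sd,
    samples = list(id = rownames(sim$spectra$x),
                   scatter = tr$scatter, offset = tr$offset,
                   slope = tr$slope)
  )
  yaml::write_yaml(sidecar, file.path(dir, "truth.yaml"), precision = 15)
  invisible(dir)
}
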