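#' Pure-component band model
#'
#' Synthetic pure-component NIR spectra are modelled as sums of Gaussian
#' absorption bands. Each analyte gets a small set of bands
#' `(center_nm, width_nm, amplitude)`; `amplitude` is absorbance per mg/mL at
#' the band centre and `width_nm` is the Gaussian sigma.
#'
#' The default placement puts each flavonoid's dominant bands inside the
#' spectral regions where interval selection locates them on real extraction
#' data (hesperidin near 870--940, 1430--1500 and 1570--1640 nm; naringin
#' near 1290--1360, 1570--1640 and 1640--1710 nm; neohesperidin near
#' 940--1010, 1290--1360 and 1640--1710 nm), so interval-selection methods
#' have a recoverable, localized truth. Bands of different analytes overlap
#' in shared regions, as real NIR bands do.
#'
#' @return Named list (one element per analyte) of data.frames with columns
#'   `center_nm`, `width_nm`, `amplitude`.
#' @export
default_component_bands <- function() {
  list(
    hesperidin = data.frame(
      center_nm = c(905, 1465, 1600),
      width_nm = c(10, 10, 10),
      amplitude = c(1.8, 1.4, 1.1)
    ),
    naringin = data.frame(
      center_nm = c(1325, 1610, 1672),
      width_nm = c(10, 10, 10),
      amplitude = c(0.14, 0.11, 0.13)
    ),
    neohesperidin = data.frame(
      center_nm = c(975, 1335, 1682),
      width_nm = c(10, 10, 10),
      amplitude = c(0.17, 0.12, 0.14)
    )
  )
}

#' Evaluate pure-component spectra on a wavelength grid
#'
#' @param bands named list of band tables as in [default_component_bands()].
#' @param grid a [wavelength_grid()].
#' @return numeric matrix, analytes x P, all values >= 0.
#' @export
pure_component_spectra <- function(bands, grid) {
  if (!inherits(grid, "wavelength_grid")) stop("grid must be a wavelength_grid")
  if (length(bands) == 0 || is.null(names(bands))) {
    stop("bands must be a non-empty named list (one element per analyte)")
  }
  out <- matrix(0, length(bands), grid$n,
                dimnames = list(names(bands), format_wavelength(grid$values)))
  for (a in names(bands)) {
    b <- as.data.frame(bands[[a]])
    if (nrow(b) == 0) stop("analyte '", a, "' has no bands")
    if (any(b$width_nm <= 0)) stop("band widths must be > 0 (analyte '", a, "')")
    if (any(!is.finite(b$amplitude))) stop("band amplitudes must be finite")
    bad <- b$center_nm < grid$start_nm | b$center_nm >= grid$stop_nm
    if (any(bad)) {
      stop(sprintf(
        "band center %g nm of analyte '%s' lies outside the grid [%g, %g)",
        b$center_nm[which(bad)[1]], a, grid$start_nm, grid$stop_nm))
    }
    for (j in seq_len(nrow(b))) {
      out[a, ] <- out[a, ] + b$amplitude[j] *
        exp(-(grid$values - b$center_nm[j])^2 / (2 * b$width_nm[j]^2))
    }
  }
  out
}

gaussian_band <- function(values, center, width, amplitude) {
  amplitude * exp(-(values - center)^2 / (2 * width^2))
}

#' First-order extraction kinetics specification
#'
#' Describes a three-batch sequential water extraction: within each batch the
#' dissolved concentration follows first-order mass-transfer kinetics
#' `C(t) = C_inf * (1 - exp(-k * t))`, where `t` is minutes since the solvent
#' contacted the herb. Each successive re-extraction of the same material
#' starts from a lower plateau `C_inf` (less analyte remains), and later
#' batches equilibrate more slowly. Spectra are sampled on a per-batch
#' schedule: frequently while heating to the boil (when concentrations change
#' fastest), then at wider intervals over the first hour at the boil and the
#' final half hour.
#'
#' Default plateaus keep every simulated concentration inside the reference
#' ranges observed for the three flavonoids (hesperidin 0.0146--0.1889,
#' naringin 0.2303--2.5504, neohesperidin 0.1893--2.0272 mg/mL), and the
#' default schedule yields exactly 75 samples (32 + 24 + 19 across batches).
#'
#' @param c_inf plateau concentration matrix, batches x analytes (mg/mL),
#'   non-increasing down each column.
#' @param k per-batch rate constants (1/min), all > 0.
#' @param lag_min per-batch heating duration (min); the batch reaches the
#'   boil at kinetic time `lag_min`, which is reported as `time_min = 0`.
#' @param intervals_min batches x 3 matrix of sampling intervals (min) for
#'   the heating, first-hour and last-half-hour phases.
#' @param c_inf_jitter,k_jitter half-widths of the uniform multiplicative
#'   batch-level jitter applied to `c_inf` and `k` when profiles are drawn.
#' @return Object of class `kinetics_spec`.
#' @export
extraction_kinetics <- function(
    c_inf = rbind(`1` = c(hesperidin = 0.180, naringin = 2.45, neohesperidin = 1.95),
                  `2` = c(hesperidin = 0.100, naringin = 1.35, neohesperidin = 1.08),
                  `3` = c(hesperidin = 0.055, naringin = 0.75, neohesperidin = 0.62)),
    k = c(0.12, 0.10, 0.08),
    lag_min = c(30, 30, 30),
    intervals_min = rbind(c(3, 4, 4), c(5, 5, 5), c(5, 6, 10)),
    c_inf_jitter = 0.02,
    k_jitter = 0.03) {
  c_inf <- as.matrix(c_inf)
  intervals_min <- as.matrix(intervals_min)
  nb <- nrow(c_inf)
  stopifnot(length(k) == nb, length(lag_min) == nb, nrow(intervals_min) == nb,
            ncol(intervals_min) == 3)
  if (any(c_inf < 0)) stop("plateau concentrations must be nonnegative")
  if (any(k <= 0)) stop("rate constants must be positive")
  if (any(intervals_min <= 0)) stop("sampling intervals must be positive")
  if (nb > 1 && any(apply(c_inf, 2, diff) > 1e-12)) {
    stop("plateau concentrations must not increase across batches")
  }
  structure(list(c_inf = c_inf, k = k, lag_min = lag_min,
                 intervals_min = intervals_min,
                 c_inf_jitter = c_inf_jitter, k_jitter = k_jitter,
                 analytes = colnames(c_inf)),
            class = "kinetics_spec")
}

#' First-order extraction concentration curve
#'
#' @param t time since solvent contact (min), `t >= 0`.
#' @param c_inf plateau concentration (mg/mL).
#' @param k rate constant (1/min), must be nonnegative.
#' @return `c_inf * (1 - exp(-k * t))`.
#' @export
extraction_concentration <- function(t, c_inf, k) {
  if (any(k < 0)) stop("rate constant k must be nonnegative")
  c_inf * (1 - exp(-k * t))
}

# Kinetic sampling times for one batch: heating-phase samples, the moment the
# boil is reached, then the two timed extraction phases (0-60 and 60-90 min
# at the boil).
batch_sample_times <- function(lag, iv) {
  heating <- seq(iv[1], lag - 1e-9, by = iv[1])
  first_hour <- lag + seq(iv[2], 60, by = iv[2])
  last_half <- lag + 60 + seq(iv[3], 30, by = iv[3])
  c(heating, lag, first_hour, last_half)
}

#' Simulate per-sample extraction concentration profiles
#'
#' Draws batch-level jitter on the plateaus and rate constants (bounded
#' uniform multipliers), then evaluates the first-order kinetics at every
#' scheduled sampling time.
#'
#' @param kinetics a [extraction_kinetics()] specification.
#' @param seed integer seed; identical seeds give identical profiles.
#' @return list with `concentrations` (N x analytes matrix, mg/mL),
#'   `time_min` (minutes relative to reaching the boil; negative while
#'   heating), `batch` (integer batch labels), and `draws` (the jittered
#'   `c_inf` and `k` actually used).
#' @export
extraction_profiles <- function(kinetics = extraction_kinetics(), seed) {
  stopifnot(inherits(kinetics, "kinetics_spec"))
  nb <- nrow(kinetics$c_inf)
  na <- ncol(kinetics$c_inf)
  times <- lapply(seq_len(nb), function(b) {
    batch_sample_times(kinetics$lag_min[b], kinetics$intervals_min[b, ])
  })
  if (length(unlist(times)) == 0) stop("sampling schedule is empty")
  draws <- with_seed(seed, {
    list(
      c_inf = kinetics$c_inf *
        matrix(stats::runif(nb * na, 1 - kinetics$c_inf_jitter,
                            1 + kinetics$c_inf_jitter), nb, na),
      k = kinetics$k * stats::runif(nb, 1 - kinetics$k_jitter,
                                    1 + kinetics$k_jitter)
    )
  })
  conc <- do.call(rbind, lapply(seq_len(nb), function(b) {
    outer(times[[b]], seq_len(na), function(t, a) {
      extraction_concentration(t, draws$c_inf[b, a], draws$k[b])
    })
  }))
  colnames(conc) <- kinetics$analytes
  batch <- rep(seq_len(nb), vapply(times, length, integer(1)))
  time_min <- unlist(times) - kinetics$lag_min[batch]
  rownames(conc) <- sprintf("B%d_T%+04.0f_%02d", batch, time_min,
                            seq_along(batch))
  list(concentrations = conc, time_min = time_min, batch = batch,
       draws = draws)
}

#' Unquantified co-extracted interferent compounds
#'
#' A crude herbal extract contains far more absorbing species than the few
#' analytes that get reference values: sugars, pectins, phenolic acids and
#' minor flavonoids all co-extract and absorb throughout the NIR region.
#' The generator therefore simulates a set of interferent compounds with
#' broad overlapping bands and their own first-order extraction kinetics
#' (different rate constants and batch-depletion ratios than the analytes,
#' so their time courses are correlated with — but not collinear to — the
#' analyte concentrations). They enter the Beer-Lambert mixture exactly
#' like the analytes but never appear in the reference set, which is what
#' forces realistic model complexity: a calibration model must separate the
#' analyte signal from several unmodelled, time-varying chemical
#' directions.
#'
#' @param bands named list of band tables (see [default_component_bands()]).
#' @param c_inf batches x interferents plateau matrix (mg/mL-equivalent).
#' @param k per-interferent rate constants (1/min).
#' @param c_inf_jitter,k_jitter half-widths of the uniform multiplicative
#'   jitter drawn per simulation.
#' @return Object of class `interferent_spec`, or use `NULL` in
#'   [simulate_dataset()] for an interferent-free (pure three-component)
#'   system.
#' @export
interferent_spec <- function(
    bands = list(
      sugar = data.frame(center_nm = c(1000, 1400, 1900),
                         width_nm = c(40, 50, 60),
                         amplitude = c(0.06, 0.08, 0.05)),
      pectin = data.frame(center_nm = c(1180, 1620, 2050),
                          width_nm = c(35, 30, 45),
                          amplitude = c(0.12, 0.10, 0.12)),
      phenolic = data.frame(center_nm = c(900, 1330, 1700),
                            width_nm = c(45, 35, 40),
                            amplitude = c(0.07, 0.09, 0.08)),
      minor_flavonoid = data.frame(center_nm = c(1100, 1530, 2100),
                                   width_nm = c(50, 40, 50),
                                   amplitude = c(0.10, 0.07, 0.11))),
    c_inf = rbind(c(3.0, 1.2, 2.0, 0.8),
                  c(2.4, 0.4, 1.5, 0.7),
                  c(1.2, 0.25, 0.5, 0.6)),
    k = c(0.05, 0.25, 0.15, 0.04),
    c_inf_jitter = 0.05, k_jitter = 0.1) {
  c_inf <- as.matrix(c_inf)
  if (ncol(c_inf) != length(bands) || length(k) != length(bands)) {
    stop("bands, c_inf columns and k must describe the same interferents")
  }
  if (any(k <= 0)) stop("interferent rate constants must be positive")
  colnames(c_inf) <- names(bands)
  structure(list(bands = bands, c_inf = c_inf, k = k,
                 c_inf_jitter = c_inf_jitter, k_jitter = k_jitter),
            class = "interferent_spec")
}

# Interferent concentrations at the analyte sampling times.
interferent_profiles <- function(spec, batch, kinetic_time, seed) {
  ni <- length(spec$k)
  nb <- nrow(spec$c_inf)
  draws <- with_seed(seed, list(
    c_inf = spec$c_inf *
      matrix(stats::runif(nb * ni, 1 - spec$c_inf_jitter,
                          1 + spec$c_inf_jitter), nb, ni),
    k = spec$k * stats::runif(ni, 1 - spec$k_jitter, 1 + spec$k_jitter)
  ))
  conc <- vapply(seq_len(ni), function(j) {
    draws$c_inf[batch, j] * (1 - exp(-draws$k[j] * kinetic_time))
  }, numeric(length(batch)))
  colnames(conc) <- names(spec$bands)
  list(concentrations = conc, draws = draws)
}

#' Measurement-artefact specification for simulated spectra
#'
#' Controls the non-chemical structure layered on top of the Beer-Lambert
#' mixture: a dominant water absorption band near 1950 nm (the solvent
#' background), per-sample multiplicative scatter, a per-sample linear
#' baseline, additive Gaussian detector noise, and occasional "bubble"
#' events — samples whose spectrum is distorted by a large extra scatter
#' excursion, as happens when bubbles or suspended particles cross an
#' online probe despite in-line filtering. The bubble mechanism makes the
#' overall noise heteroscedastic: a few samples are far noisier than the
#' rest.
#'
#' @param additive_sd additive noise standard deviation in absorbance units;
#'   `NULL` (default) means `additive_sd_frac` times the median noiseless
#'   absorbance of the dataset being simulated.
#' @param additive_sd_frac fraction used when `additive_sd` is `NULL`.
#' @param scatter_range range of the per-sample multiplicative scatter
#'   factor; both ends must be > 0.
#' @param offset_range range of the per-sample baseline offset (AU).
#' @param slope_range range of the per-sample baseline slope (AU per nm,
#'   applied to wavelength minus the grid midpoint).
#' @param bubble_count number of samples per dataset affected by a bubble
#'   event (default 6 of the 75, drawn without replacement).
#' @param bubble_sd log-scale standard deviation of the extra lognormal
#'   scatter factor applied to bubble-affected samples.
#' @param water_amplitude,water_center_nm,water_width_nm Gaussian water-band
#'   background added to every sample with constant amplitude.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(additive_sd = NULL, additive_sd_frac = 0.005,
                       scatter_range = c(0.95, 1.05),
                       offset_range = c(-0.02, 0.02),
                       slope_range = c(-2e-5, 2e-5),
                       bubble_count = 6, bubble_sd = 0.3,
                       water_amplitude = 1.2, water_center_nm = 1950,
                       water_width_nm = 80) {
  if (!is.null(additive_sd) && additive_sd < 0) stop("additive_sd must be >= 0")
  if (additive_sd_frac < 0) stop("additive_sd_frac must be >= 0")
  if (any(scatter_range <= 0)) stop("multiplicative scatter factors must be > 0")
  if (bubble_count < 0) stop("bubble_count must be >= 0")
  if (bubble_sd < 0) stop("bubble_sd must be >= 0")
  structure(list(additive_sd = additive_sd,
                 additive_sd_frac = additive_sd_frac,
                 scatter_range = scatter_range, offset_range = offset_range,
                 slope_range = slope_range,
                 bubble_count = as.integer(bubble_count),
                 bubble_sd = bubble_sd,
                 water_amplitude = water_amplitude,
                 water_center_nm = water_center_nm,
                 water_width_nm = water_width_nm),
            class = "noise_spec")
}

#' Simulate a complete extraction-monitoring NIR dataset
#'
#' Builds spectra as
#' `x_i = m_i * (sum_a conc[i,a] * pure_a + water) + offset_i + slope_i * (lambda - lambda_mid) + eps_i`
#' where the component sum runs over the reference analytes *and* any
#' unquantified interferents, `m_i` is the per-sample multiplicative
#' scatter factor (bubble-affected samples carry an extra lognormal
#' excursion), the baseline is linear in wavelength and `eps_i` is iid
#' Gaussian noise. Reference concentrations are the exact simulated analyte
#' values. Every latent draw is kept in the returned ground-truth record,
#' so downstream methods can be tested against a known answer.
#'
#' @param grid a [wavelength_grid()].
#' @param bands pure-component band list, as [default_component_bands()].
#' @param kinetics an [extraction_kinetics()] spec.
#' @param noise a [noise_spec()].
#' @param interferents an [interferent_spec()], or `NULL` for a pure
#'   analytes-plus-water system.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return Object of class `nir_simulation`: a list with `spectra`
#'   (a [spectra_set()]), `reference` (a [reference_set()]) and `truth`
#'   (seed, specs, per-sample latent draws, the noiseless mixture matrix).
#' @export
simulate_dataset <- function(grid = wavelength_grid(),
                             bands = default_component_bands(),
                             kinetics = extraction_kinetics(),
                             noise = noise_spec(),
                             interferents = interferent_spec(), seed) {
  stopifnot(inherits(noise, "noise_spec"))
  if (!setequal(names(bands), kinetics$analytes)) {
    stop("band list and kinetics describe different analytes")
  }
  bands <- bands[kinetics$analytes]
  seeds <- spawn_seeds(seed, 3)
  prof <- extraction_profiles(kinetics, seeds[1])
  pure <- pure_component_spectra(bands, grid)
  water <- gaussian_band(grid$values, noise$water_center_nm,
                         noise$water_width_nm, noise$water_amplitude)
  noiseless <- prof$concentrations %*% pure +
    matrix(water, nrow(prof$concentrations), grid$n, byrow = TRUE)
  int_conc <- NULL
  int_draws <- NULL
  if (!is.null(interferents)) {
    stopifnot(inherits(interferents, "interferent_spec"))
    kinetic_time <- prof$time_min + kinetics$lag_min[prof$batch]
    ip <- interferent_profiles(interferents, prof$batch, kinetic_time,
                               seeds[2])
    int_conc <- ip$concentrations
    int_draws <- ip$draws
    noiseless <- noiseless +
      int_conc %*% pure_component_spectra(interferents$bands, grid)
  }
  n <- nrow(noiseless)
  sd_add <- noise$additive_sd %||%
    (noise$additive_sd_frac * stats::median(noiseless))
  draw <- with_seed(seeds[3], {
    scatter <- stats::runif(n, noise$scatter_range[1], noise$scatter_range[2])
    bubbles <- integer(0)
    if (noise$bubble_count > 0) {
      bubbles <- sort(sample.int(n, min(noise$bubble_count, n)))
      scatter[bubbles] <- scatter[bubbles] *
        exp(stats::rnorm(length(bubbles), sd = noise$bubble_sd))
    }
    list(
      scatter = scatter, bubbles = bubbles,
      offset = stats::runif(n, noise$offset_range[1], noise$offset_range[2]),
      slope = stats::runif(n, noise$slope_range[1], noise$slope_range[2]),
      eps = matrix(stats::rnorm(n * grid$n, sd = sd_add), n, grid$n)
    )
  })
  lam <- grid$values - mean(grid$values)
  x <- noiseless * draw$scatter +
    outer(draw$offset, rep(1, grid$n)) + outer(draw$slope, lam) + draw$eps
  rownames(x) <- rownames(prof$concentrations)
  meta <- data.frame(sample_id = rownames(x), batch = prof$batch,
                     time_min = prof$time_min, stringsAsFactors = FALSE)
  spectra <- spectra_set(x, grid, meta)
  reference <- reference_set(prof$concentrations)
  truth <- list(seed = seed, grid = grid, bands = bands, kinetics = kinetics,
                noise = noise, interferents = interferents,
                kinetic_draws = prof$draws,
                interferent_concentrations = int_conc,
                interferent_draws = int_draws,
                scatter = draw$scatter, bubbles = draw$bubbles,
                offset = draw$offset,
                slope = draw$slope, additive_sd = sd_add,
                concentrations = prof$concentrations,
                noiseless = noiseless, water = water)
  structure(list(spectra = spectra, reference = reference, truth = truth),
            class = "nir_simulation")
}

#' @export
print.nir_simulation <- function(x, ...) {
  cat(sprintf("<nir_simulation> %d samples x %d wavelengths, analytes: %s\n",
              nrow(x$spectra$x), x$spectra$grid$n,
              paste(analytes(x$reference), collapse = ", ")))
  cat("  seed:", x$truth$seed, "\n")
  invisible(x)
}

#' Default 75-sample extraction fixture
#'
#' The packaged study-scale dataset: three sequential extraction batches,
#' 75 samples in total, 2800 wavelengths (800--2200 nm at 0.5 nm), three
#' flavonoid analytes with interval-localized bands, water background,
#' scatter/baseline artefacts and additive noise at their defaults. The
#' documented default seed is 8749; pass `grid` with a coarser step for
#' reduced-resolution runs of the same experiment.
#'
#' @param seed integer seed (default 8749).
#' @param grid wavelength grid (default full 0.5 nm resolution).
#' @return A [simulate_dataset()] result.
#' @export
default_fixture <- function(seed = 8749L, grid = wavelength_grid()) {
  simulate_dataset(grid = grid, seed = seed)
}

#' Ground-truth informative intervals of a band model
#'
#' Maps each analyte's band centres to the equidistant spectral intervals
#' that contain them — the intervals a variable-selection method should
#' recover on data simulated from those bands.
#'
#' @param bands band list as in [default_component_bands()].
#' @param grid a [wavelength_grid()].
#' @param n_intervals number of equidistant intervals (default 20).
#' @return named list of sorted integer interval indices (1-based).
#' @export
informative_intervals <- function(bands, grid, n_intervals = 20) {
  iv <- make_intervals(grid$n, n_intervals, grid = grid)
  starts_nm <- grid$values[iv$start]
  lapply(bands, function(b) {
    idx <- findInterval(b$center_nm, starts_nm)
    sort(unique(idx))
  })
}
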