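# Shared fixtures and independent reference implementations used across
# the test files. Everything here is built in code at test time.

# A noise spec that switches off every measurement artefact.
quiet_noise <- function() {
  noise_spec(additive_sd = 0, scatter_range = c(1, 1),
             offset_range = c(0, 0), slope_range = c(0, 0),
             bubble_count = 0)
}

# Noiseless pure three-analyte fixture (no interferents): spectra are an
# exact Beer-Lambert mixture plus the constant water band.
noiseless_fixture <- function(seed = 1, grid = wavelength_grid()) {
  simulate_dataset(grid = grid, noise = quiet_noise(), interferents = NULL,
                   seed = seed)
}

# Two-analyte fixture for interval-selection truth recovery: analyte "a"
# has a single band in one known interval, analyte "b" in another, and the
# modelled response is their sum (total flavonoid content). The per-batch
# a:b plateau ratios differ, so neither band alone carries the response.
# Bubble events are disabled: they make a scatter-reference region (the
# water band) genuinely informative, which would break the premise that
# all signal sits in the two band intervals.
confined_signal_fixture <- function(seed, n_intervals = 8,
                                    grid = wavelength_grid(step_nm = 5)) {
  iv <- make_intervals(grid$n, n_intervals, grid = grid)
  mid_nm <- function(i) grid$values[iv$start[i]] + iv$size[i] * grid$step_nm / 2
  truth_iv <- c(2L, 4L)
  bands <- list(
    a = data.frame(center_nm = mid_nm(truth_iv[1]), width_nm = 12,
                   amplitude = 0.20),
    b = data.frame(center_nm = mid_nm(truth_iv[2]), width_nm = 12,
                   amplitude = 0.20)
  )
  kin <- extraction_kinetics(
    c_inf = rbind(c(a = 2.40, b = 1.80), c(a = 1.00, b = 1.50),
                  c(a = 0.45, b = 1.40)))
  sim <- simulate_dataset(grid = grid, bands = bands, kinetics = kin,
                          noise = noise_spec(bubble_count = 0),
                          interferents = NULL, seed = seed)
  y <- sim$reference$a + sim$reference$b
  list(sim = sim, y = y, informative = truth_iv, n_intervals = n_intervals)
}

# Quadratic-time Kennard-Stone reference: recomputes every candidate's
# minimal distance to the selected set from the raw distance matrix at
# every step.
ks_oracle <- function(x, n_cal) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  best <- c(1L, 2L); bv <- -Inf
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (d[i, j] > bv) { bv <- d[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    md <- vapply(cand, function(i) min(d[i, sel]), numeric(1))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

# Per-window least-squares polynomial fit, evaluated at the window centre
# (interior points) — the definitional Savitzky-Golay oracle.
sg_oracle_interior <- function(vec, window, polyorder, deriv = 0) {
  h <- (window - 1) %/% 2
  p <- length(vec)
  out <- rep(NA_real_, p)
  offs <- -h:h
  for (i in seq.int(h + 1, p - h)) {
    fit <- lm(vec[i + offs] ~ poly(offs, polyorder, raw = TRUE))
    cf <- coef(fit)
    out[i] <- if (deriv == 0) cf[1]
              else if (deriv == 1) cf[2]
              else 2 * cf[3]
  }
  out
}

# Smooth random spectra for small synthetic regression problems.
smooth_random_matrix <- function(n, p, seed) {
  set.seed(seed)
  raw <- matrix(rnorm(n * (p + 8)), n)
  t(apply(raw, 1, function(r) stats::filter(r, rep(1 / 9, 9),
                                            sides = 2)))[, 5:(p + 4)]
}
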