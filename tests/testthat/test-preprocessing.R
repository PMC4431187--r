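test_that("Savitzky-Golay reproduces polynomials and derivatives exactly", {
  i <- 0:99
  quad <- matrix(2 + 0.3 * i - 0.01 * i^2, 1)
  sm <- savitzky_golay(quad, window = 11, polyorder = 2, deriv = 0)
  expect_equal(sm, quad, tolerance = 1e-10)     # includes the edge windows

  lin <- matrix(5 + 3 * i, 1)
  d1 <- savitzky_golay(lin, window = 11, polyorder = 2, deriv = 1)
  expect_equal(as.vector(d1), rep(3, 100), tolerance = 1e-10)  # slope / step

  d2 <- savitzky_golay(quad, window = 11, polyorder = 2, deriv = 2)
  expect_equal(as.vector(d2), rep(-0.02, 100), tolerance = 1e-10)

  expect_error(savitzky_golay(quad, window = 10), "odd")
  expect_error(savitzky_golay(quad, window = 11, polyorder = 11), "polyorder")
  expect_error(savitzky_golay(matrix(1:5, 1), window = 11), "fewer points")
})

test_that("Savitzky-Golay equals the per-window least-squares fit", {
  set.seed(1)
  v <- as.vector(smooth_random_matrix(1, 80, 7)) + rnorm(80, sd = 0.1)
  for (dv in 0:2) {
    got <- as.vector(savitzky_golay(matrix(v, 1), 11, 2, dv))
    want <- sg_oracle_interior(v, 11, 2, dv)
    keep <- !is.na(want)
    expect_equal(got[keep], want[keep], tolerance = 1e-8)
  }
})

test_that("SNV standardizes rows and is affine-invariant", {
  expect_equal(as.vector(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  set.seed(2)
  x <- matrix(rnorm(60), 5)
  z <- snv(x)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_equal(snv(3 + 2 * x), z, tolerance = 1e-12)   # affine invariance
  expect_equal(snv(z), z, tolerance = 1e-10)           # idempotent
  xc <- x; xc[2, ] <- 7
  expect_error(snv(xc), "constant spectrum")
})

test_that("MSC inverts affine distortion against the reference", {
  ref <- as.vector(smooth_random_matrix(1, 50, 3)) + 2
  x <- rbind(ref, 0.5 + 2 * ref)
  out <- msc(x, reference = ref)
  expect_equal(unname(out$spectra[1, ]), unname(ref), tolerance = 1e-12)
  expect_equal(unname(out$spectra[2, ]), unname(ref), tolerance = 1e-12)

  # per-row (a, b) match an explicit normal-equations solve
  set.seed(4)
  y <- matrix(rnorm(150), 3, 50)
  got <- msc(y, reference = ref)$spectra
  for (r in 1:3) {
    cf <- coef(lm(y[r, ] ~ ref))
    expect_equal(unname(got[r, ]), unname((y[r, ] - cf[1]) / cf[2]),
                 tolerance = 1e-10)
  }
  expect_error(msc(y, reference = rep(1, 50)), "constant")
})

test_that("MSC is idempotent on affine distortions of a common shape", {
  ref <- as.vector(smooth_random_matrix(1, 40, 5)) + 1
  set.seed(6)
  x <- outer(runif(6, -0.5, 0.5), rep(1, 40)) +
    outer(runif(6, 0.7, 1.4), ref)
  once <- msc(x)
  twice <- msc(once$spectra)
  expect_lt(norm(twice$spectra - once$spectra, "F") /
              norm(once$spectra, "F"), 1e-10)
})

test_that("normalize scales rows to unit L2 norm, scale-invariantly", {
  expect_equal(as.vector(normalize_rows(matrix(c(3, 4), 1))), c(0.6, 0.8))
  set.seed(7)
  x <- matrix(rnorm(80), 4)
  z <- normalize_rows(x)
  expect_equal(sqrt(rowSums(z^2)), rep(1, 4), tolerance = 1e-12)
  expect_equal(normalize_rows(10 * x), z, tolerance = 1e-12)
  expect_equal(normalize_rows(z), z, tolerance = 1e-10)
  expect_error(normalize_rows(rbind(x, 0)), "all-zero")
})

test_that("apply_preprocess dispatches the menu and freezes MSC state", {
  set.seed(8)
  x <- smooth_random_matrix(6, 60, 9)
  expect_identical(apply_preprocess(x, "raw")$spectra, x)   # identity
  # window size is honored
  expect_false(identical(apply_preprocess(x, "SG9")$spectra,
                         apply_preprocess(x, "SG11")$spectra))
  # SG11+2D of a quadratic row is constant
  i <- 0:59
  q <- matrix(1 + 0.1 * i + 0.02 * i^2, 1)
  d2 <- apply_preprocess(q, "sg11+2d")$spectra
  expect_equal(as.vector(d2), rep(0.04, 60), tolerance = 1e-10)
  expect_error(apply_preprocess(x, "wavelet"), "RAW, SG9")

  # MSC reference learned on calibration is reused for prediction
  cal <- apply_preprocess(x[1:4, ], "MSC")
  expect_equal(cal$state$msc_reference, colMeans(x[1:4, ]))
  prd <- apply_preprocess(x[5:6, ], "MSC", state = cal$state)
  direct <- msc(x[5:6, ], reference = colMeans(x[1:4, ]))$spectra
  expect_equal(prd$spectra, direct)
})

test_that("preprocessing preserves shape, order and the spectra_set class", {
  sim <- noiseless_fixture(seed = 2, grid = wavelength_grid(step_nm = 50))
  for (m in preprocess_methods()) {
    out <- apply_preprocess(sim$spectra, m)$spectra
    expect_s3_class(out, "spectra_set")
    expect_identical(dim(out$x), dim(sim$spectra$x))
    expect_identical(rownames(out$x), rownames(sim$spectra$x))
  }
})
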