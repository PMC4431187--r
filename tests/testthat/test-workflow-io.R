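tiny_sim <- function(seed = 41) {
  default_fixture(seed = seed, grid = wavelength_grid(step_nm = 20))
}

test_that("spectra files round-trip bit-identically", {
  sim <- tiny_sim()
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sim$spectra, f)
  back <- read_spectra(f)
  expect_identical(back$x, sim$spectra$x)
  expect_equal(back$grid$values, sim$spectra$grid$values)
  expect_identical(back$meta$batch, sim$spectra$meta$batch)
  expect_equal(as.numeric(back$meta$time_min), sim$spectra$meta$time_min)
})

test_that("reference files round-trip and align by id", {
  sim <- tiny_sim()
  f <- withr::local_tempfile(fileext = ".csv")
  write_reference(sim$reference, f)
  back <- read_reference(f)
  expect_equal(back, sim$reference)
  # shuffled rows align back to the spectra order
  shuffled <- back[sample(nrow(back)), ]
  class(shuffled) <- class(back)
  aligned <- align_reference(sim$spectra, shuffled)
  expect_equal(aligned$naringin, sim$reference$naringin)
  # a missing id is reported by name
  dropped <- back[-3, ]
  class(dropped) <- class(back)
  expect_error(align_reference(sim$spectra, dropped),
               back$sample_id[3], fixed = TRUE)
})

test_that("malformed spectra files give distinct errors", {
  sim <- tiny_sim()
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sim$spectra, f)
  lines <- readLines(f)
  dup <- c(lines, lines[2])
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(dup, f2)
  expect_error(read_spectra(f2), "duplicate sample id")
  # irregular grid: drop one wavelength column
  hdr <- strsplit(lines[1], ",")[[1]]
  keep <- setdiff(seq_along(hdr), 10)
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(vapply(lines, function(l) {
    paste(strsplit(l, ",")[[1]][keep], collapse = ",")
  }, character(1)), f3)
  expect_error(read_spectra(f3), "irregular")
})

test_that("split files round-trip in selection order", {
  sim <- tiny_sim()
  s <- kennard_stone(sim$spectra, 50)
  f <- withr::local_tempfile(fileext = ".csv")
  write_split(s, f)
  back <- read_split(f, sim$spectra)
  expect_identical(back$calibration, s$calibration)
  expect_identical(back$prediction, s$prediction)
})

test_that("write_dataset emits spectra, references and the truth sidecar", {
  sim <- tiny_sim()
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  expect_true(all(file.exists(file.path(d, c("spectra.csv", "references.csv",
                                             "truth.yaml")))))
  tr <- yaml::read_yaml(file.path(d, "truth.yaml"))
  expect_equal(tr$seed, sim$truth$seed)
  expect_equal(tr$samples$scatter, sim$truth$scatter, tolerance = 1e-12)
})

test_that("run_workflow produces the full report bundle deterministically", {
  sim <- tiny_sim(seed = 42)
  out1 <- withr::local_tempdir()
  cfg <- run_config(spectra = sim$spectra, references = sim$reference,
                    out_dir = out1, seed = 77, a_max = 5,
                    sipls = list(n_intervals = 5, combo_size = 2),
                    mwpls = list(window_sizes = c(5, 9), stride = 5),
                    bagging = list(b = 30))
  rep1 <- suppressMessages(run_workflow(cfg))
  # 8 preprocessing rows for each of the 3 analytes
  for (an in c("hesperidin", "naringin", "neohesperidin")) {
    tab <- rep1$analytes[[an]]$preprocessing$table
    expect_equal(nrow(tab), 8L)
    expect_setequal(tab$method, preprocess_methods())
    # SiPLS labels use the nm-range form
    expect_match(rep1$analytes[[an]]$sipls$table$label[1], "nm")
    expect_equal(nrow(rep1$analytes[[an]]$sipls$table), choose(5, 2))
    expect_length(rep1$analytes[[an]]$bagging$curve_full, 30)
  }
  files <- list.files(out1)
  expect_true(all(c("split.csv", "summary.txt", "run.log",
                    "comparison_naringin.csv") %in% files))

  # identical config -> byte-identical numeric outputs
  out2 <- withr::local_tempdir()
  cfg$out_dir <- out2
  suppressMessages(run_workflow(cfg))
  for (f in grep("csv$", files, value = TRUE)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("workflow failures name the failing stage", {
  sim <- tiny_sim(seed = 43)
  out <- withr::local_tempdir()
  bad <- run_config(spectra = sim$spectra, references = sim$reference,
                    out_dir = out, seed = 1, analytes = "naringin",
                    sipls = list(n_intervals = 5, combo_size = 9),
                    mwpls = list(window_sizes = 5, stride = 5),
                    bagging = list(b = 5))
  expect_error(suppressMessages(run_workflow(bad)), "sipls")
  expect_error(suppressMessages(run_workflow(
    run_config(spectra = "no-such-file.csv", references = sim$reference,
               out_dir = out, seed = 1))), "not found")
})

test_that("the command-line interface drives the pipeline end to end", {
  cli <- system.file("cli", "nirpls.R", package = "nirpls")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run_cli <- function(...) {
    suppressWarnings(system2(rscript, c(cli, ...), stdout = TRUE,
                             stderr = TRUE,
                             env = paste0("R_LIBS=", libs)))
  }
  d <- withr::local_tempdir()
  out <- run_cli("simulate", "--seed", "5", "--out", d, "--step-nm", "20")
  expect_true(file.exists(file.path(d, "spectra.csv")))
  sp <- file.path(d, "spectra.csv")
  sf <- file.path(d, "split.csv")
  run_cli("split", "--spectra", sp, "--out", sf)
  expect_true(file.exists(sf))
  split <- read_split(sf, read_spectra(sp))
  expect_length(split$calibration, 50L)
  mf <- file.path(d, "metrics.csv")
  run_cli("fit", "--spectra", sp, "--references",
          file.path(d, "references.csv"), "--analyte", "naringin",
          "--split", sf, "--a-max", "5", "--out", mf)
  m <- utils::read.csv(mf)
  expect_true(m$rmsecv > 0 && m$rmsep > 0)
  # missing config is a usage error (nonzero exit)
  st <- suppressWarnings(system2(rscript, c(cli, "run"), stdout = FALSE,
                                 stderr = FALSE,
                                 env = paste0("R_LIBS=", libs)))
  expect_equal(st, 2)
})
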