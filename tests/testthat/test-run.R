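test_that("run_config enforces exactly one input source and valid weights", {
  expect_error(run_config(), "exactly one")
  expect_error(run_config(angio = "a.rds", phantom = phantom_spec()), "exactly one")
  expect_error(run_config(phantom = phantom_spec(), w1 = -1), "non-negative")
  cfg <- run_config(phantom = phantom_spec(), out_dir = tempfile())
  expect_s3_class(cfg, "run_config")
  expect_equal(c(cfg$w1, cfg$w2, cfg$w3), c(0.02, 3, 0.02))
})

test_that("YAML config round-trips and command-line overrides win", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(angio = "a.rds", structural = "s.rds",
                        method = "msa", w2 = 1.5, out_dir = "out"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$method, "msa")
  expect_equal(cfg$w2, 1.5)
  cfg2 <- read_run_config(f, overrides = list(w2 = 4, method = "sdef"))
  expect_equal(cfg2$method, "sdef")
  expect_equal(cfg2$w2, 4)
})

test_that("run_simulate writes reproducible phantom artifacts with a spec echo", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  spec <- small_phantom_spec(noise_sigma = 0.05)
  p1 <- run_simulate(run_config(phantom = spec, out_dir = out1, seed = 5L))
  p2 <- run_simulate(run_config(phantom = spec, out_dir = out2, seed = 5L))
  expect_true(all(file.exists(unlist(p1))))
  # byte-identical volumes from identical seed + spec
  expect_identical(readBin(p1$A, "raw", file.size(p1$A)),
                   readBin(p2$A, "raw", file.size(p2$A)))
  # spec echo equals the input spec (seed overridden by config)
  back <- read_phantom_spec(p1$spec)
  want <- spec; want$seed <- 5L
  expect_equal(back, want)
  # a no-flow spec yields an all-zero angiogram
  out3 <- withr::local_tempdir()
  p3 <- run_simulate(run_config(phantom = small_phantom_spec(vessels = list()),
                                out_dir = out3))
  expect_true(all(vals(load_volume(p3$A)) == 0))
})

test_that("run_correct applies the configured corrector and records provenance", {
  out <- withr::local_tempdir()
  spec <- small_phantom_spec()
  # w1 = 0 with preprocessing disabled leaves the volume unchanged
  res0 <- run_correct(run_config(phantom = spec, method = "tartes", w1 = 0,
                                 sigma = NULL, out_dir = file.path(out, "id")))
  fm <- simulate_phantom(spec)
  expect_identical(vals(res0$corrected), vals(fm$A))

  res <- run_correct(run_config(phantom = spec, method = "tartes", w1 = 0.02,
                                sigma = NULL, out_dir = file.path(out, "w")))
  prov <- jsonlite::read_json(file.path(out, "w", "provenance.json"))
  expect_equal(prov$method, "tartes")
  expect_equal(prov$weights$w1, 0.02)
  expect_true(is.numeric(prov$clipped_fraction))

  # reruns are byte-identical
  res2 <- run_correct(run_config(phantom = spec, method = "tartes", w1 = 0.02,
                                 sigma = NULL, out_dir = file.path(out, "w2")))
  f1 <- file.path(out, "w", "corrected.rds"); f2 <- file.path(out, "w2", "corrected.rds")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # outputs are never silently overwritten
  expect_error(run_correct(run_config(phantom = spec, method = "tartes",
                                      sigma = NULL, out_dir = file.path(out, "w"))),
               "overwrite")
})

test_that("TAR-TES methods require a structural volume; MSA and SDEF do not", {
  out <- withr::local_tempdir()
  fm <- simulate_phantom(small_phantom_spec())
  a_path <- file.path(out, "A.rds")
  save_volume(fm$A, a_path)
  expect_error(run_correct(run_config(angio = a_path, method = "tartes",
                                      sigma = NULL, out_dir = out)),
               "structural")
  res <- run_correct(run_config(angio = a_path, method = "msa", sigma = NULL,
                                out_dir = file.path(out, "msa")))
  expect_identical(vals(res$corrected), vals(mean_subtract_correct(fm$A, 3)))
  res2 <- run_correct(run_config(angio = a_path, method = "sdef", sigma = NULL,
                                 out_dir = file.path(out, "sdef")))
  expect_identical(vals(res2$corrected), vals(sdef_correct(fm$A, 0.02)))
})

test_that("run_compare reports all three correctors and ranks TAR-TES best on the phantom", {
  out <- withr::local_tempdir()
  report <- run_compare(run_config(phantom = small_phantom_spec(), sigma = NULL,
                                   out_dir = out, offset_mm = 0.15,
                                   make_plots = FALSE))
  expect_setequal(names(report$correctors), c("tartes", "msa", "sdef"))
  expect_true(file.exists(file.path(out, "compare.json")))
  rmse <- vapply(report$correctors, `[[`, numeric(1L), "recovery_rmse")
  expect_equal(names(which.min(rmse)), "tartes")
  # all-zero input yields all-zero (NA-residual) metrics without failure
  out2 <- withr::local_tempdir()
  rep0 <- run_compare(run_config(phantom = small_phantom_spec(vessels = list()),
                                 sigma = NULL, out_dir = out2, make_plots = FALSE))
  expect_equal(rep0$uncorrected$peak_value, 0)
})

test_that("run_compare panels and run_profile metrics are written", {
  out <- withr::local_tempdir()
  run_compare(run_config(phantom = small_phantom_spec(), sigma = NULL,
                         out_dir = out, offset_mm = 0.15, make_plots = TRUE))
  expect_true(file.exists(file.path(out, "enface_panels.png")))
  expect_true(file.exists(file.path(out, "ascan_overlay.png")))

  out2 <- withr::local_tempdir()
  res <- run_profile(run_config(phantom = small_phantom_spec(), sigma = NULL,
                                out_dir = out2, offset_mm = 0.15))
  expect_s3_class(res$profile, "depth_profile")
  m <- jsonlite::read_json(file.path(out2, "profile.json"))
  expect_equal(m$residual_fraction, res$metrics$residual_fraction)
})

test_that("the CLI dispatches simulate and compare against a spec file", {
  cli <- system.file("cli", "octa-tartes.R", package = "tartes")
  expect_true(nzchar(cli))
  out <- withr::local_tempdir()
  specfile <- file.path(out, "spec.yaml")
  write_phantom_spec(small_phantom_spec(), specfile)
  status <- system2("Rscript",
                    c(cli, "simulate", "--phantom", shQuote(specfile),
                      "--out", shQuote(file.path(out, "sim")), "--seed", "3"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "sim", "A.rds")))
  # unknown subcommand exits non-zero
  bad <- system2("Rscript", c(cli, "frobnicate"), stdout = FALSE, stderr = FALSE)
  expect_equal(bad, 2L)
})
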