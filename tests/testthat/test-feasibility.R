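example_file <- function(name) {
  system.file("extdata", "examples", name, package = "relex")
}

test_that("the extrapolation study file reproduces the 0.32 -> 0.93 example", {
  res <- run_feasibility(example_file("example1_extrapolation.json"))
  expect_equal(res$extrapolated_icc, 0.9336, tolerance = 1e-4)
  expect_equal(res$classification$koo_li, "clinical")
})

test_that("the correlation study file reproduces attenuation 0.75 and n 24 -> 44", {
  res <- run_feasibility(example_file("example2_correlation.json"))
  expect_equal(res$extrapolated_icc, 0.8, tolerance = 1e-12)
  expect_equal(res$attenuation, sqrt(0.8 * 0.7), tolerance = 1e-12)
  expect_equal(res$n_unattenuated, 24L)
  expect_equal(res$n_required, 44L)
})

test_that("the change-score study file reproduces the displacement example numbers", {
  res <- run_feasibility(example_file("example3_change_score.json"))
  expect_equal(round(res$extrapolated_icc, 2), 0.41)
  expect_equal(round(res$d_observed, 2), 0.95)
  expect_equal(round(res$sdd_individual, 1), 14.3)
  expect_equal(round(res$sdd_group, 1), 10.1)
})

test_that("the required-d study file reproduces the 1.6 / 2.4 / 4 ladder", {
  res <- run_feasibility(example_file("example5_required_d.json"))
  ds <- vapply(res$required_d, `[[`, numeric(1), "d")
  expect_equal(round(ds, 1), c(1.6, 2.4, 4.0))
  expect_equal(res$overlap$u3, pnorm(0.8), tolerance = 1e-12)
})

test_that("feasibility results serialize to JSON and are reproducible", {
  res <- run_feasibility(example_file("example4_overlap.json"))
  json <- feasibility_json(res)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$extrapolated_icc, res$extrapolated_icc, tolerance = 1e-12)
  expect_equal(parsed$overlap$ovl, 2 * pnorm(-0.4), tolerance = 1e-12)
  # identical inputs give identical outputs
  res2 <- run_feasibility(example_file("example4_overlap.json"))
  expect_identical(feasibility_json(res), feasibility_json(res2))
})

test_that("schema violations raise structured errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"trt": {"mean": 1, "sd": 1}}', bad)  # icc and n missing
  expect_error(run_feasibility(bad), class = "relex_schema_error")

  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"trt": {"mean": 1, "sd": 1, "icc": 0.5, "n": 10},
               "new": {"sd": 1, "sd_ratio": 2}}', bad2)
  expect_error(run_feasibility(bad2), class = "relex_schema_error")

  notjson <- withr::local_tempfile(fileext = ".json")
  writeLines("not json {", notjson)
  expect_error(run_feasibility(notjson), class = "relex_schema_error")

  expect_error(run_feasibility("no/such/file.json"), class = "relex_schema_error")
})

test_that("YAML study files are accepted when the yaml package is present", {
  skip_if_not_installed("yaml")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("trt:", "  mean: 1.6", "  sd: 1", "  icc: 0.32", "  n: 10",
               "new:", "  sd_ratio: 3.2"), yml)
  res <- run_feasibility(yml)
  expect_equal(res$extrapolated_icc, 1 - 0.68 / 10.24, tolerance = 1e-12)
})

test_that("the command-line wrapper emits valid JSON and signals schema errors", {
  cli <- system.file("cli", "relex.R", package = "relex")
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))

  out <- suppressWarnings(system2(rscript, c(cli, "extrapolate", "--icc", "0.32",
                            "--sd-trt", "1", "--sd-ratio", "3.2"),
                  stdout = TRUE, stderr = FALSE, env = env))
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(parsed$icc_new, 1 - 0.68 / 10.24, tolerance = 1e-10)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"new": {"sd": 1}}', bad)
  status <- suppressWarnings(system2(rscript, c(cli, "feasibility", "--study", bad),
                    stdout = FALSE, stderr = FALSE, env = env))
  expect_equal(status, 2L)
})
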