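# Config loading, validation and pipeline commands.

write_yaml_config <- function(lines) {
  f <- withr_local_tempfile(env = parent.frame())
  writeLines(lines, f)
  f
}

test_that("minimal config gets defaults and reports them", {
  f <- write_yaml_config("verbosity: 1")
  expect_message(cfg <- load_config(f), "defaults applied")
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$geometry$r_int, 3.5)
  expect_equal(cfg$params$k1, 147.29)
  expect_identical(cfg$fixed, "k4")
  expect_equal(cfg$noise[["PCT"]], 0.15)
  expect_equal(cfg$spectrum$total_photon_power, 3.36e-4, tolerance = 1e-6)
})

test_that("schema violations name the offending key", {
  expect_error(load_config(write_yaml_config("banana: 1")), "banana")
  expect_error(load_config(write_yaml_config(c("params:", "  k1: -3.0"))),
               "k1")
  expect_error(load_config(write_yaml_config(c("params:", "  k9: 1.0"))),
               "k9")
  expect_error(load_config(write_yaml_config(c("noise:", "  DOC: 0.1"))),
               "DOC")
  expect_error(load_config(write_yaml_config("design: /no/such/file.csv")),
               "not found")
  expect_error(load_config("/no/such/config.yaml"), "not found")
})

test_that("config save/load round trip is stable", {
  f <- write_yaml_config(c("params:", "  k1: 100.0", "seed: 7",
                           "verbosity: 0"))
  cfg <- load_config(f)
  f2 <- withr_local_tempfile()
  save_config(cfg, f2)
  cfg2 <- load_config(f2)
  expect_equal(cfg2$params, cfg$params)
  expect_equal(cfg2$geometry, cfg$geometry)
  expect_identical(cfg2$seed, cfg$seed)
  expect_identical(cfg2$noise, cfg$noise)
})

test_that("dose command writes the design table with the three molar ratios", {
  out_dir <- withr::local_tempdir()
  cfg <- load_config(write_yaml_config(c(paste0("output_dir: ", out_dir),
                                         "verbosity: 0")))
  art <- run_pipeline(cfg, "dose")
  d <- read.csv(art$artifact, comment.char = "#")
  expect_equal(nrow(d), 18)
  expect_equal(sort(unique(round(d$R, 1))), c(10.5, 21, 42))
  expect_equal(unique(d$stoich_dose_mg_L), 189, tolerance = 2e-3)
  # artifact header embeds the config hash
  expect_match(readLines(art$artifact, n = 1), "config_hash")
})

test_that("generate requires a seed; fit on noiseless data closes the loop", {
  out_dir <- withr::local_tempdir()
  # restrict to two dark runs to keep the fit small
  design <- design_table(canonical_design()[c("E3", "E9")])
  design_csv <- file.path(out_dir, "design.csv")
  write.csv(design, design_csv, row.names = FALSE)

  cfg_ns <- load_config(write_yaml_config(c(
    paste0("output_dir: ", out_dir), paste0("design: ", design_csv),
    "verbosity: 0")))
  expect_error(run_pipeline(cfg_ns, "generate"), "seed")

  cfg <- load_config(write_yaml_config(c(
    paste0("output_dir: ", out_dir), paste0("design: ", design_csv),
    "seed: 31",
    "noise:", "  PCT: 0.0", "  H2O2: 0.0", "  Fe2: 0.0", "  FeTOT: 0.0",
    "verbosity: 0")))
  gen <- run_pipeline(cfg, "generate")
  meas <- read.csv(gen$artifact, comment.char = "#")
  expect_setequal(unique(meas$run_id), c("E3", "E9"))

  fit <- run_pipeline(cfg, "fit", data = gen$artifact)
  res <- jsonlite::read_json(fit$artifact)
  expect_true(res$converged)
  expect_lt(res$residual_norm, 1e-8)
  expect_equal(res$params$k1, 147.29, tolerance = 1e-3)
})

test_that("unknown commands fail loudly", {
  out_dir <- withr::local_tempdir()
  cfg <- load_config(write_yaml_config(c(paste0("output_dir: ", out_dir),
                                         "verbosity: 0")))
  expect_error(run_pipeline(cfg, "frobnicate"), "unknown command")
  expect_error(run_pipeline(list(), "dose"), "run_config")
})

test_that("evaluate reports removal times and oxidant efficiency per run", {
  out_dir <- withr::local_tempdir()
  design <- design_table(canonical_design()[c("E1", "E10")])
  design_csv <- file.path(out_dir, "design.csv")
  write.csv(design, design_csv, row.names = FALSE)
  cfg <- load_config(write_yaml_config(c(
    paste0("output_dir: ", out_dir), paste0("design: ", design_csv),
    "verbosity: 0")))
  ev <- run_pipeline(cfg, "evaluate")
  d <- read.csv(ev$artifact, comment.char = "#")
  expect_equal(nrow(d), 2)
  expect_true(all(is.finite(d$pct_removal_time_min)))
  # irradiated twin removes PCT no later than its dark counterpart
  expect_lte(d$pct_removal_time_min[d$run_id == "E10"],
             d$pct_removal_time_min[d$run_id == "E1"])
  expect_true(all(d$h2o2_consumed_mg_L > 0))
})
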