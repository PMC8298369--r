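# Synthetic campaign: factorial design, schedules, noise model.

test_that("canonical design is the full 3x3x2 crossing in table order", {
  runs <- canonical_design()
  expect_length(runs, 18)
  d <- design_table(runs)
  expect_identical(d$run_id, paste0("E", 1:18))
  expect_identical(d$irradiated, rep(c(FALSE, TRUE), each = 9))
  expect_equal(sort(unique(d$c_h2o2_0_mg_L)), c(94.5, 189, 378))
  expect_equal(sort(unique(d$c_fe2_0_mg_L)), c(5, 7.5, 10))
  expect_true(all(d$c_pct_0_mg_L == 40) && all(d$duration_min == 120))
  # every oxidant/catalyst/irradiation combination appears exactly once
  expect_equal(nrow(unique(d[, 3:5])), 18)
  # E18: highest catalyst and oxidant, irradiated, R = 42
  expect_equal(d[18, "c_fe2_0_mg_L"], 10)
  expect_equal(d[18, "c_h2o2_0_mg_L"], 378)
  expect_true(d[18, "irradiated"])
  expect_equal(sort(unique(round(d$R, 1))), c(10.5, 21, 42))
})

test_that("sampling schedules follow the analytical protocol", {
  expect_equal(sampling_schedule("PCT"), c(0, 1.5, 2.5, 5, 7.5, 10, 15))
  h <- sampling_schedule("H2O2")
  expect_length(h, 13)
  expect_equal(h, c(0, 5, 10, 15, 20, 25, 30, 45, 60, 75, 90, 105, 120))
  expect_identical(sampling_schedule("Fe2"), h)
  expect_identical(sampling_schedule("FeTOT"), h)
  for (sp in c("PCT", "H2O2", "TOC")) {
    ss <- sampling_schedule(sp)
    expect_identical(ss[1], 0)
    expect_true(all(diff(ss) > 0))
  }
  expect_error(sampling_schedule("DOC"), "unknown species")
})

test_that("zero noise reproduces the simulated trajectory exactly", {
  run <- canonical_design()$E5
  p <- kinetic_params()
  meas <- generate_measurements(run, p, fix_geometry(), noise_model =
                                  zero_noise, seed = 3)
  sim <- simulate_run(run, p, fix_geometry(),
                      t_eval = sampling_schedule("H2O2"))
  h <- meas[meas$species == "H2O2", ]
  expect_equal(h$conc_mg_L, sim$c_h2o2_mg_L[match(h$time_min, sim$time_min)])
  ft <- meas[meas$species == "FeTOT", ]
  expect_equal(ft$conc_mg_L, rep(7.5, 13), tolerance = 1e-6)
})

test_that("the seed fully determines the generated noise", {
  run <- canonical_design()$E2
  p <- kinetic_params()
  m1 <- generate_measurements(run, p, fix_geometry(), seed = 11)
  m2 <- generate_measurements(run, p, fix_geometry(), seed = 11)
  m3 <- generate_measurements(run, p, fix_geometry(), seed = 12)
  expect_identical(m1, m2)
  expect_false(identical(m1$conc_mg_L, m3$conc_mg_L))
  expect_error(generate_measurements(run, p, fix_geometry()), "seed")
  # the global RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_measurements(run, p, fix_geometry(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("noise is centred: replicate mean matches the clean value (CLT bound)", {
  run <- canonical_design()$E9
  p <- kinetic_params()
  sim <- simulate_run(run, p, fix_geometry(),
                      t_eval = sort(unique(unlist(lapply(
                        c("PCT", "H2O2", "Fe2", "FeTOT"),
                        sampling_schedule)))))
  n_rep <- 1000
  # H2O2 at t = 0 sits far from the truncation boundary (378 mg/L, sd 1.43)
  draws <- vapply(seq_len(n_rep), function(s) {
    m <- generate_measurements(run, p, fix_geometry(), seed = 2000 + s,
                               species = "H2O2", sim = sim)
    m$conc_mg_L[m$time_min == 0]
  }, numeric(1))
  sd_h <- default_noise_model()[["H2O2"]]
  expect_lt(abs(mean(draws) - 378), 3 * sd_h / sqrt(n_rep))
  expect_equal(sd(draws), sd_h, tolerance = 0.1)
})

test_that("values are truncated at zero and TOC series are flagged not model-backed", {
  run <- canonical_design()$E9
  p <- kinetic_params()
  m <- generate_measurements(run, p, fix_geometry(), seed = 17,
                             emit_toc = TRUE)
  expect_true(all(m$conc_mg_L >= 0))
  expect_true(all(!m$model_backed[m$species == "TOC"]))
  expect_true(all(m$model_backed[m$species != "TOC"]))
  # late PCT samples are at zero concentration: truncation bites there
  late <- m$conc_mg_L[m$species == "PCT" & m$time_min >= 10]
  expect_true(all(late >= 0))
})

test_that("a campaign covers every run with per-run derived seeds", {
  runs <- canonical_design()[c(1, 9, 18)]
  meas <- generate_campaign(runs, kinetic_params(), fix_geometry(),
                            fix_lvrpa_table(), seed = 4)
  expect_setequal(unique(meas$run_id), c("E1", "E9", "E18"))
  expect_equal(nrow(meas), 3 * (7 + 13 * 3))
  # different runs see different noise streams
  p1 <- meas$conc_mg_L[meas$run_id == "E1" & meas$species == "PCT"][1]
  p9 <- meas$conc_mg_L[meas$run_id == "E9" & meas$species == "PCT"][1]
  expect_false(identical(p1, p9))
})
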