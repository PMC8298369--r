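# Synthetic experimental campaign: the 18-run factorial design, the
# species-specific sampling schedules, and Gaussian instrument noise at the
# documented measurement errors, so the whole pipeline is exercised without
# any external data.

#' The canonical 18-run factorial design
#'
#' Full 3 x 3 x 2 crossing of the initial oxidant level (94.5, 189,
#' 378 mg L^-1 H2O2: half, one and twice the stoichiometric mineralization
#' dose for 40 mg L^-1 PCT) with the catalyst level (5, 7.5, 10 mg L^-1
#' Fe2+) and irradiation (dark runs E1-E9, irradiated runs E10-E18).  PCT
#' starts at 40 mg L^-1 and every run lasts 120 min.
#'
#' @return A list of 18 [experiment_run()] objects named E1-E18.
#' @export
canonical_design <- function() {
  fe <- rep(c(5, 7.5, 10), each = 3)
  h2o2 <- rep(c(94.5, 189, 378), times = 3)
  runs <- lapply(1:18, function(i) {
    j <- ((i - 1) %% 9) + 1
    experiment_run(run_id = paste0("E", i), c_pct_0 = 40,
                   c_h2o2_0 = h2o2[j], c_fe2_0 = fe[j],
                   irradiated = i > 9, duration = 120)
  })
  names(runs) <- paste0("E", 1:18)
  runs
}

#' Design table as a data frame
#'
#' @param runs A list of [experiment_run()]s (default the canonical design).
#' @return Data frame with one row per run, including the molar ratio R.
#' @export
design_table <- function(runs = canonical_design()) {
  data.frame(
    run_id = vapply(runs, `[[`, character(1), "run_id"),
    c_pct_0_mg_L = vapply(runs, `[[`, numeric(1), "c_pct_0"),
    c_h2o2_0_mg_L = vapply(runs, `[[`, numeric(1), "c_h2o2_0"),
    c_fe2_0_mg_L = vapply(runs, `[[`, numeric(1), "c_fe2_0"),
    irradiated = vapply(runs, `[[`, logical(1), "irradiated"),
    duration_min = vapply(runs, `[[`, numeric(1), "duration"),
    R = vapply(runs, function(r) molar_ratio_R(r$c_h2o2_0, r$c_pct_0),
               numeric(1)),
    row.names = NULL
  )
}

#' Species sampling schedules
#'
#' PCT (HPLC, reaction quenched with methanol) is sampled densely over the
#' first 15 min; H2O2 and the iron species every 5 min to 30 min and then
#' every 15 min to the end of the 120-min run.
#'
#' @param species One of `"PCT"`, `"H2O2"`, `"Fe2"`, `"FeTOT"`, `"TOC"`.
#' @return Sampling times in min, strictly increasing from 0.
#' @export
sampling_schedule <- function(species) {
  switch(species,
         PCT = c(0, 1.5, 2.5, 5, 7.5, 10, 15),
         H2O2 = ,
         Fe2 = ,
         FeTOT = c(seq(0, 30, by = 5), seq(45, 120, by = 15)),
         TOC = seq(0, 120, by = 15),
         stop("unknown species: ", species))
}

#' Default instrument noise model
#'
#' Standard deviations of the Gaussian measurement noise, mg L^-1: PCT 0.15
#' (HPLC-DAD) and H2O2 1.43 (metavanadate spectrophotometry) are the
#' documented instrument errors; the iron phenanthroline assay error is not
#' documented and defaults to 0.05 mg L^-1 (an assumption, configurable);
#' TOC uses the total-carbon analyzer error 0.23 mg L^-1.
#'
#' @return Named numeric vector of noise sd by species.
#' @export
default_noise_model <- function() {
  c(PCT = 0.15, H2O2 = 1.43, Fe2 = 0.05, FeTOT = 0.05, TOC = 0.23)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate noisy measurement series for one run
#'
#' Simulates the run, samples each species on its schedule and adds
#' independent Gaussian noise truncated at zero (instruments report
#' near-zero readings as small non-negatives; the induced bias near zero is
#' a known property of the generator).  The seed fully determines the
#' output and the global RNG state is left untouched.
#'
#' @inheritParams simulate_run
#' @param noise_model Named sd vector as in [default_noise_model()];
#'   sd 0 yields noiseless series.
#' @param seed Integer seed (mandatory).
#' @param species Species to emit (default PCT, H2O2, Fe2, FeTOT).
#' @param emit_toc Also emit a TOC series computed as the TOC equivalent of
#'   the PCT trajectory plus noise.  TOC is *not* model-backed (the model
#'   tracks no intermediates, and real mineralization is far slower than
#'   PCT disappearance); the series is marked `model_backed = FALSE` and
#'   must never enter fitting.
#' @param sim Optional precomputed [simulate_run()] result on a grid
#'   containing all schedule times (to amortize simulation across many
#'   noise replicates).
#' @return Data frame: `run_id`, `species`, `time_min`, `conc_mg_L`,
#'   `model_backed`.
#' @export
generate_measurements <- function(run, params, geometry = default_geometry(),
                                  lvrpa_table = NULL,
                                  noise_model = default_noise_model(),
                                  seed, species = c("PCT", "H2O2", "Fe2", "FeTOT"),
                                  emit_toc = FALSE, sim = NULL) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  if (any(noise_model < 0)) stop("noise sd must be non-negative")
  if (emit_toc) species <- union(species, "TOC")
  times_all <- sort(unique(unlist(lapply(species, sampling_schedule))))
  if (is.null(sim)) {
    sim <- simulate_run(run, params, geometry, lvrpa_table, t_eval = times_all)
  }
  clean_at <- function(sp, tt) {
    i <- match(tt, sim$time_min)
    if (anyNA(i)) stop("simulation grid misses schedule times for ", sp)
    switch(sp,
           PCT = sim$c_pct_mg_L[i],
           H2O2 = sim$c_h2o2_mg_L[i],
           Fe2 = sim$c_fe2_mg_L[i],
           FeTOT = sim$c_fe2_mg_L[i] + sim$c_fe3_mg_L[i],
           TOC = toc_equivalent(sim$c_pct_mg_L[i]))
  }
  with_seed(seed, {
    parts <- lapply(species, function(sp) {
      tt <- sampling_schedule(sp)
      y <- clean_at(sp, tt)
      sd <- if (sp %in% names(noise_model)) noise_model[[sp]] else 0
      data.frame(run_id = run$run_id, species = sp, time_min = tt,
                 conc_mg_L = pmax(y + stats::rnorm(length(tt), 0, sd), 0),
                 model_backed = sp != "TOC")
    })
    do.call(rbind, parts)
  })
}

#' Generate a full synthetic campaign
#'
#' @inheritParams generate_measurements
#' @param runs List of [experiment_run()]s.
#' @return One tidy data frame of measurement series for all runs; each
#'   run's noise is drawn under a sub-seed derived deterministically from
#'   `seed`.
#' @export
generate_campaign <- function(runs, params, geometry = default_geometry(),
                              lvrpa_table = NULL,
                              noise_model = default_noise_model(),
                              seed, ...) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  out <- lapply(seq_along(runs), function(i)
    generate_measurements(runs[[i]], params, geometry, lvrpa_table,
                          noise_model, seed = seed + 7919L * i, ...))
  do.call(rbind, out)
}
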