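# Configuration and pipeline orchestration.
#
# A single YAML config drives every stage; all artifacts are plain CSV/JSON
# (the study's data objects are small tables).  Each written artifact
# embeds the config hash and seed so it can be regenerated byte-for-byte
# (modulo floating-point platform differences).

.config_keys <- c("geometry", "spectrum", "absorptivity", "params", "fixed",
                  "design", "noise", "seed", "output_dir", "verbosity")

#' Load and validate a run configuration
#'
#' Unknown keys are rejected; omitted blocks fall back to the package
#' defaults (pilot-plant geometry, the default kinetic constants, the
#' synthetic lamp spectrum and absorptivity table, instrument noise model)
#' and the applied defaults are reported via `message()`.
#'
#' @param path YAML file.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  cfg <- list()
  defaults_used <- character()
  if (is.null(raw$geometry)) {
    cfg$geometry <- default_geometry()
    defaults_used <- c(defaults_used, "geometry")
  } else {
    cfg$geometry <- do.call(reactor_geometry, raw$geometry)
  }
  if (is.null(raw$spectrum)) {
    cfg$spectrum <- synthetic_lamp_spectrum()
    defaults_used <- c(defaults_used, "spectrum")
  } else {
    if (!file.exists(raw$spectrum)) stop("spectrum file not found: ",
                                         raw$spectrum)
    cfg$spectrum <- read_spectrum_csv(raw$spectrum)
  }
  if (is.null(raw$absorptivity)) {
    cfg$absorptivity <- synthetic_absorptivity_table()
    defaults_used <- c(defaults_used, "absorptivity")
  } else {
    if (!file.exists(raw$absorptivity)) stop("absorptivity file not found: ",
                                             raw$absorptivity)
    cfg$absorptivity <- read_absorptivity_csv(raw$absorptivity)
  }
  pb <- raw$params
  if (is.null(pb)) defaults_used <- c(defaults_used, "params")
  for (k in names(pb)) {
    if (!k %in% c("k1", "k3", "k4", "k5", "phi_bar"))
      stop("unknown params key: ", k)
    if (!is.numeric(pb[[k]]) || pb[[k]] <= 0)
      stop("invalid value for ", k, ": must be a positive number")
  }
  cfg$params <- do.call(kinetic_params, as.list(pb))
  cfg$fixed <- if (is.null(raw$fixed)) "k4" else as.character(raw$fixed)
  if (!all(cfg$fixed %in% c("k1", "k3", "k4", "k5")))
    stop("fixed must name kinetic constants k1, k3, k4, k5")
  if (!is.null(raw$design) && !file.exists(raw$design))
    stop("design file not found: ", raw$design)
  cfg$design <- raw$design
  noise <- default_noise_model()
  if (!is.null(raw$noise)) {
    bad <- setdiff(names(raw$noise), names(noise))
    if (length(bad)) stop("unknown noise key(s): ", paste(bad, collapse = ", "))
    for (k in names(raw$noise)) {
      if (raw$noise[[k]] < 0) stop("invalid value for noise ", k)
      noise[[k]] <- raw$noise[[k]]
    }
  } else defaults_used <- c(defaults_used, "noise")
  cfg$noise <- noise
  cfg$seed <- raw$seed
  cfg$output_dir <- if (is.null(raw$output_dir)) "." else raw$output_dir
  cfg$verbosity <- if (is.null(raw$verbosity)) 1L else as.integer(raw$verbosity)
  if (length(defaults_used) && cfg$verbosity > 0)
    message("config defaults applied for: ",
            paste(defaults_used, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Save a configuration back to YAML
#'
#' Writes the resolved configuration (defaults filled in) such that
#' `load_config(save_config(cfg, f))` reproduces it.
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  g <- cfg$geometry
  out <- list(
    geometry = list(r_int = g$r_int, r_ext = g$r_ext, h_irr = g$h_irr,
                    lamp_length = g$lamp_length, lamp_offset = g$lamp_offset,
                    v_irr = g$v_irr, v_total = g$v_total),
    params = unclass(cfg$params),
    fixed = cfg$fixed,
    noise = as.list(cfg$noise),
    seed = cfg$seed,
    output_dir = cfg$output_dir,
    verbosity = cfg$verbosity
  )
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

config_hash <- function(cfg) {
  # order-stable structural digest (no external digest dependency)
  s <- paste(utils::capture.output(utils::str(
    cfg[order(names(cfg))], digits.d = 12)), collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

read_design_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "c_pct_0_mg_L", "c_h2o2_0_mg_L", "c_fe2_0_mg_L",
            "irradiated", "duration_min")
  if (!all(need %in% names(x)))
    stop("design CSV must have columns: ", paste(need, collapse = ", "))
  runs <- lapply(seq_len(nrow(x)), function(i)
    experiment_run(x$run_id[i], x$c_pct_0_mg_L[i], x$c_h2o2_0_mg_L[i],
                   x$c_fe2_0_mg_L[i],
                   irradiated = as.logical(x$irradiated[i]),
                   duration = x$duration_min[i]))
  names(runs) <- x$run_id
  runs
}

write_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s; seed: %s", config_hash(cfg),
                     if (is.null(cfg$seed)) "none" else cfg$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run one pipeline stage
#'
#' Commands: `dose` (design table with stoichiometric doses and molar
#' ratios), `lvrpa` (volume-averaged LVRPA table), `simulate` (trajectories
#' for every design run), `generate` (noisy synthetic measurements; needs
#' `seed`), `fit` (kinetic fit to a measurement CSV given via `data`),
#' `evaluate` (removal times and specific oxidant consumption from
#' simulated trajectories).  Artifacts are written under
#' `cfg$output_dir` with the config hash and seed embedded.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param command One of `dose`, `lvrpa`, `simulate`, `generate`, `fit`,
#'   `evaluate`.
#' @param data For `fit`: path to a tidy measurement CSV (as written by
#'   `generate`).
#' @return Named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg, command, data = NULL) {
  if (!inherits(cfg, "run_config")) stop("cfg must be a run_config")
  commands <- c("dose", "lvrpa", "simulate", "generate", "fit", "evaluate")
  if (!is.character(command) || length(command) != 1L ||
      !command %in% commands)
    stop("unknown command; use one of: ", paste(commands, collapse = ", "))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- if (is.null(cfg$design)) canonical_design() else
    read_design_csv(cfg$design)
  out <- file.path(cfg$output_dir, paste0(command, ".csv"))

  lvtab <- function() build_lvrpa_table(c(0, 2.5, 5, 7.5, 10),
                                        cfg$geometry, cfg$spectrum,
                                        cfg$absorptivity)
  art <- switch(command,
    dose = {
      d <- design_table(runs)
      d$stoich_dose_mg_L <- stoichiometric_h2o2_dose(d$c_pct_0_mg_L)
      write_artifact(d, out, cfg)
    },
    lvrpa = {
      tb <- lvtab()
      write_artifact(data.frame(fe3_mg_L = tb$fe3_mg_L, lvrpa = tb$lvrpa),
                     out, cfg)
    },
    simulate = {
      tb <- if (any(vapply(runs, `[[`, logical(1), "irradiated"))) lvtab()
      traj <- do.call(rbind, lapply(runs, function(r) {
        s <- simulate_run(r, cfg$params, cfg$geometry, tb)
        data.frame(run_id = r$run_id, time_min = s$time_min,
                   c_pct_mg_L = s$c_pct_mg_L, c_h2o2_mg_L = s$c_h2o2_mg_L,
                   c_fe2_mg_L = s$c_fe2_mg_L, c_fe3_mg_L = s$c_fe3_mg_L)
      }))
      write_artifact(traj, out, cfg)
    },
    generate = {
      if (is.null(cfg$seed)) stop("generate requires a seed in the config")
      tb <- if (any(vapply(runs, `[[`, logical(1), "irradiated"))) lvtab()
      meas <- generate_campaign(runs, cfg$params, cfg$geometry, tb,
                                cfg$noise, seed = cfg$seed)
      write_artifact(meas, out, cfg)
    },
    fit = {
      if (is.null(data)) stop("fit requires a measurement CSV via `data`")
      meas <- utils::read.csv(data, comment.char = "#")
      tb <- if (any(vapply(runs, `[[`, logical(1), "irradiated"))) lvtab()
      ctx <- model_context(runs, cfg$geometry, tb)
      fr <- fit_kinetics(meas, ctx, initial_guess = cfg$params,
                         fixed = cfg$fixed)
      outj <- file.path(cfg$output_dir, "fit.json")
      jsonlite::write_json(list(
        config_hash = config_hash(cfg), seed = cfg$seed,
        params = unclass(fr$params), fixed_mask = fr$fixed_mask,
        residual_norm = fr$residual_norm,
        rmse_by_species = as.list(fr$rmse_by_species), n_obs = fr$n_obs,
        converged = fr$converged, n_iter = fr$n_iter),
        outj, auto_unbox = TRUE, digits = NA)
      outj
    },
    evaluate = {
      tb <- if (any(vapply(runs, `[[`, logical(1), "irradiated"))) lvtab()
      ev <- do.call(rbind, lapply(runs, function(r) {
        s <- simulate_run(r, cfg$params, cfg$geometry, tb,
                          t_eval = seq(0, r$duration, by = 0.25))
        toc0 <- toc_equivalent(r$c_pct_0)
        toc_f <- toc_equivalent(s$c_pct_mg_L[nrow(s)])
        data.frame(
          run_id = r$run_id, irradiated = r$irradiated,
          pct_removal_time_min = removal_time(s$time_min, s$c_pct_mg_L, 0.15),
          h2o2_consumed_mg_L = r$c_h2o2_0 - s$c_h2o2_mg_L[nrow(s)],
          specific_oxidant_consumption = if (toc0 > toc_f)
            specific_oxidant_consumption(r$c_h2o2_0,
                                         s$c_h2o2_mg_L[nrow(s)],
                                         toc0, toc_f) else NA_real_)
      }))
      write_artifact(ev, out, cfg)
    })
  if (cfg$verbosity > 0)
    message(sprintf("[%s] wrote %s (config %s, seed %s)", command, art,
                    config_hash(cfg),
                    if (is.null(cfg$seed)) "none" else cfg$seed))
  invisible(list(command = command, artifact = art))
}
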