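#' Build a validated pipeline run configuration
#'
#' Assembles (and schema-checks) the configuration of a full synthetic-study
#' run: cohort size and variability, breath and robot-program settings, the
#' calibration targets (spontaneous reference excursion/tidal volume and the
#' assisted-effect ratio knobs), measurement noise, session layout, stage
#' toggles and output directory. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 42L,
    cohort = list(n = 8L, cv = 0.2),
    breath = list(t_total = 6, f_insp = 0.5),
    program = list(shape = "square", level_kpa = 30,
                   k_transmission = 0.1, t_inflate = 3),
    calibration = list(target_excursion = 1.14, target_vt = 0.83,
                       target_cv = 0.15, r_disp = 1.95, r_vol = 2.14),
    noise = list(disp = 0.05, flow = 0.02),
    session = list(n_breaths = 6L, fs = 100),
    stages = list(metrics = TRUE, fit = TRUE),
    fit = list(free_spont = c("a_dim", "a_rc"),
               free_assisted = c("a_dim", "a_rc", "p_rex")),
    out_dir = NULL)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  cfg <- defaults
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (is.list(cfg[[nm]]) && is.list(val)) {
      bad2 <- setdiff(names(val), names(cfg[[nm]]))
      if (length(bad2)) {
        abort(paste0("unknown config keys under `", nm, "`: ",
                     paste(bad2, collapse = ", ")))
      }
      cfg[[nm]] <- modifyList(cfg[[nm]], val)
    } else {
      cfg[[nm]] <- val
    }
  }
  structure(cfg, class = "run_config")
}

calibrated_cohort <- function(cfg) {
  cal <- cfg$calibration
  cohort <- sample_cohort(cfg$cohort$n, seed = cfg$seed, cv = cfg$cohort$cv,
                          noise_disp = cfg$noise$disp,
                          noise_flow = cfg$noise$flow)
  # one body-size factor per subject scales both targets, keeping the
  # excursion/volume pair physically consistent
  sdlog <- sqrt(log(1 + cal$target_cv^2))
  target_fac <- with_seed(cfg$seed + 1L,
                          rlnorm(cfg$cohort$n, -sdlog^2 / 2, sdlog))
  base_prog <- do.call(robot_program, cfg$program)
  purrr::imap(cohort, function(profile, i) {
    profile$pattern <- breath_pattern(profile$pattern$t_total,
                                      cfg$breath$f_insp,
                                      profile$pattern$a_rc,
                                      profile$pattern$a_dim)
    profile <- calibrate_amplitudes(
      profile,
      target_vt = cal$target_vt * target_fac[i],
      target_excursion = cal$target_excursion * target_fac[i],
      n_breaths = cfg$session$n_breaths, fs = cfg$session$fs,
      on_infeasible = "floor")
    assist <- calibrate_assistance(
      profile, program = base_prog,
      r_disp = cal$r_disp, r_vol = cal$r_vol,
      n_breaths = cfg$session$n_breaths, fs = cfg$session$fs)
    list(profile = profile, assist = assist)
  })
}

#' Generate and analyze a full synthetic cohort
#'
#' Samples a cohort, calibrates every participant's spontaneous session to
#' (participant-scaled) reference excursion/tidal-volume targets and the
#' assisted condition to the configured effect-ratio knobs, generates a
#' paired spontaneous + assisted recording per participant, and computes
#' the comparison metrics (per-subject means, paired ratio tests, pooled
#' excursion-volume correlation). Optionally fits the per-session model and
#' reports goodness of fit.
#'
#' @param cfg A [run_config()].
#' @return List with `sessions` (named list of recordings), `measures`
#'   (per-session tibble), `comparison` (excursion and volume
#'   [paired_ratio_test()] results), `correlation`, and (when enabled)
#'   `fits` (per-session [glance.resp_fit()] rows).
#' @export
analyze_cohort <- function(cfg = run_config()) {
  cal <- calibrated_cohort(cfg)
  sessions <- list()
  measures <- purrr::imap_dfr(cal, function(entry, i) {
    profile <- entry$profile
    sp <- generate_session(profile, "spontaneous",
                           n_breaths = cfg$session$n_breaths,
                           seed = cfg$seed + 10L * i, fs = cfg$session$fs)
    as_ <- generate_session(profile, "assisted",
                            program = entry$assist$program,
                            pattern = entry$assist$pattern,
                            n_breaths = cfg$session$n_breaths,
                            seed = cfg$seed + 10L * i + 5L,
                            fs = cfg$session$fs)
    sessions[[paste0(profile$id, "_spontaneous")]] <<- sp
    sessions[[paste0(profile$id, "_assisted")]] <<- as_
    dplyr::bind_rows(
      dplyr::mutate(measure_session(sp), condition = "spontaneous"),
      dplyr::mutate(measure_session(as_), condition = "assisted")) |>
      dplyr::mutate(subject = profile$id, .before = 1L)
  })
  wide <- measures |>
    dplyr::select("subject", "condition", "mean_excursion", "mean_vt") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean_excursion", "mean_vt"))
  comparison <- list(
    excursion = paired_ratio_test(wide$mean_excursion_spontaneous,
                                  wide$mean_excursion_assisted),
    volume = paired_ratio_test(wide$mean_vt_spontaneous,
                               wide$mean_vt_assisted))
  correlation <- disp_vol_correlation(measures$mean_excursion,
                                      measures$mean_vt)
  out <- list(config = cfg, sessions = sessions, measures = measures,
              comparison = comparison, correlation = correlation)
  if (isTRUE(cfg$stages$fit)) {
    out$fits <- purrr::imap_dfr(sessions, function(rec, nm) {
      free <- if (attr(rec, "condition") == "assisted") {
        cfg$fit$free_assisted
      } else cfg$fit$free_spont
      ft <- fit_mechanics(rec, spec = fit_spec(free), seed = cfg$seed)
      dplyr::mutate(glance(ft), session = nm,
                    condition = attr(rec, "condition"), .before = 1L)
    })
  }
  out
}

#' Run the full reproducible pipeline to disk
#'
#' Executes cohort generation, simulation, measurement and (optionally)
#' fitting, and writes every artifact into the output directory: the
#' resolved configuration (YAML), per-session trace CSVs, the metrics
#' report (JSON), fit results, a structured per-stage log, and a manifest
#' listing a checksum for every output file. Rerunning with the same
#' configuration reproduces all numeric outputs. Outputs are staged into a
#' temporary sibling directory and renamed into place on success; a failure
#' leaves a `FAILED` marker instead of a partial run directory.
#'
#' @param cfg A [run_config()] with a non-`NULL` `out_dir`.
#' @return The analysis list from [analyze_cohort()], invisibly, with
#'   `out_dir` attached.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.null(cfg$out_dir)) abort("`out_dir` must be set in the config")
  out_dir <- cfg$out_dir
  stage <- paste0(out_dir, ".staging")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_stage <- function(name, t0) {
    log_lines <<- c(log_lines, sprintf(
      "stage=%s seed=%d elapsed_s=%.3f version=%s", name, cfg$seed,
      as.numeric(proc.time()[["elapsed"]] - t0),
      as.character(utils::packageVersion("robovent"))))
  }
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(stage, recursive = TRUE)
      dir.create(dirname(out_dir), recursive = TRUE, showWarnings = FALSE)
      writeLines("pipeline failed", file.path(dirname(out_dir),
                                              paste0(basename(out_dir), ".FAILED")))
    }
  })
  t0 <- proc.time()[["elapsed"]]
  cfg_plain <- unclass(cfg)
  cfg_plain$out_dir <- NULL
  yaml::write_yaml(cfg_plain, file.path(stage, "config.yaml"))
  res <- analyze_cohort(cfg)
  log_stage("analyze", t0)

  for (nm in names(res$sessions)) {
    write_traces_csv(res$sessions[[nm]][c("t", "displacement", "flow")],
                     file.path(stage, paste0(nm, ".csv")))
  }
  report <- list(
    schema = "robovent-report/1",
    n_subjects = cfg$cohort$n,
    measures = res$measures,
    excursion_ratio_of_means = res$comparison$excursion$ratio_means,
    excursion_mean_ratio = res$comparison$excursion$mean_ratio,
    excursion_p = res$comparison$excursion$p_value,
    vt_ratio_of_means = res$comparison$volume$ratio_means,
    vt_mean_ratio = res$comparison$volume$mean_ratio,
    vt_p = res$comparison$volume$p_value,
    correlation_r = res$correlation$r,
    correlation_p = res$correlation$p)
  if (!is.null(res$fits)) report$fits <- res$fits
  write_report_json(report, file.path(stage, "report.json"))
  log_stage("write", t0)
  writeLines(log_lines, file.path(stage, "log.txt"))

  files <- setdiff(list.files(stage), "manifest.json")
  manifest <- purrr::map(files, function(f) {
    c(list(file = f), file_checksum(file.path(stage, f)))
  })
  write_report_json(list(files = manifest), file.path(stage, "manifest.json"))

  unlink(out_dir, recursive = TRUE)
  dir.create(dirname(out_dir), recursive = TRUE, showWarnings = FALSE)
  file.rename(stage, out_dir)
  ok <- TRUE
  attr(res, "out_dir") <- out_dir
  invisible(res)
}
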