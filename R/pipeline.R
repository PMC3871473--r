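# Orchestration of the full in-silico protocol and its analysis, plus a
# small command-line front end (simulate / analyze / report).
#
# Protocol order follows the in-vivo design: the mechanical interventions
# come first (n_sets sets of baseline, reduced preload, increased afterload,
# in that order), then the three drug blocks (dobutamine, nitroprusside,
# metoprolol), so no drug effect leaks into the mechanical sets.

#' Protocol description
#'
#' Defaults reproduce the full design: 6 animals, 10 mechanical sets of
#' (baseline, preload_reduced, afterload_increased), then 10 measurements
#' per drug, 10 cycles per measurement — 60 measurements and 600 beats per
#' animal.
#'
#' @param n_animals Number of animals.
#' @param n_sets Mechanical sets per animal (each = baseline + reduced
#'   preload + increased afterload).
#' @param n_drug_measurements Measurements per drug block.
#' @param cycles_per_measurement Cardiac cycles retained per measurement.
#' @param seed Top-level seed; every downstream random draw derives from it.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(n_animals = 6, n_sets = 10,
                          n_drug_measurements = 10,
                          cycles_per_measurement = 10, seed = 1L) {
  counts <- c(n_animals, n_sets, n_drug_measurements,
              cycles_per_measurement)
  if (any(counts < 1)) stop("protocol_spec: all counts must be >= 1")
  structure(list(n_animals = n_animals, n_sets = n_sets,
                 n_drug_measurements = n_drug_measurements,
                 cycles_per_measurement = cycles_per_measurement,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

# condition sequence for one animal, in protocol order
.protocol_conditions <- function(spec) {
  c(rep(c("baseline", "preload_reduced", "afterload_increased"),
        spec$n_sets),
    rep("dobutamine", spec$n_drug_measurements),
    rep("nitroprusside", spec$n_drug_measurements),
    rep("metoprolol", spec$n_drug_measurements))
}

# small measurement-to-measurement physiological drift: lognormal jitter on
# contractility, filling and vascular tone (3% SD), making beats within a
# condition spread as they do between stabilization periods in vivo
.jitter_animal <- function(animal, sdlog = 0.03) {
  animal$ventricle$e_max <- animal$ventricle$e_max * rlnorm(1, 0, sdlog)
  animal$circulation$p_ven <- animal$circulation$p_ven * rlnorm(1, 0, sdlog)
  animal$circulation$r_periph <-
    animal$circulation$r_periph * rlnorm(1, 0, sdlog)
  animal
}

#' Run the full synthetic protocol
#'
#' Simulates every measurement of the protocol for a seeded cohort and
#' applies the measurement model. Fully deterministic given `spec$seed`.
#'
#' @param spec A [protocol_spec()].
#' @param cfg A [sim_config()] template (its `n_cycles` is overridden by
#'   `spec$cycles_per_measurement`; its `noise_sd` applies to every
#'   measurement).
#' @param out_dir If non-`NULL`, each record is written there via
#'   [write_record()] along with a `manifest.csv`.
#' @param noise If `FALSE`, all noise SDs are forced to zero (the catheter
#'   gain/offset still applies).
#' @param measurement_jitter Lognormal SD of the between-measurement
#'   physiological drift (0 disables it).
#' @return List with `records` (list of measured [waveform_record()]s),
#'   `manifest` (a `data.table`), `cohort` and `spec`; invisibly if written
#'   to disk.
#' @export
run_protocol <- function(spec = protocol_spec(), cfg = sim_config(),
                         out_dir = NULL, noise = TRUE,
                         measurement_jitter = 0.03) {
  stopifnot(inherits(spec, "protocol_spec"), inherits(cfg, "sim_config"))
  cohort <- make_cohort(spec$n_animals, seed = spec$seed)
  conds <- .protocol_conditions(spec)
  n_meas <- length(conds)
  set.seed(spec$seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1,
                                spec$n_animals * n_meas),
                     nrow = spec$n_animals)
  noise_sd <- if (noise) cfg$noise_sd else cfg$noise_sd * 0

  records <- vector("list", spec$n_animals * n_meas)
  manifest <- vector("list", length(records))
  k <- 0L
  for (ai in seq_len(spec$n_animals)) {
    animal <- cohort[[ai]]
    for (mi in seq_len(n_meas)) {
      k <- k + 1L
      mseed <- seed_tab[ai, mi]
      set.seed(mseed)
      a_m <- if (measurement_jitter > 0)
        .jitter_animal(animal, measurement_jitter) else animal
      mcfg <- sim_config(fs = cfg$fs,
                         n_cycles = spec$cycles_per_measurement,
                         warmup_cycles = cfg$warmup_cycles,
                         noise_sd = noise_sd, seed = mseed)
      rec <- simulate_record(a_m, condition_spec(conds[mi]), mcfg)
      rec <- measurement_model(rec, animal, mcfg)
      rec$meta$measurement_index <- mi
      records[[k]] <- rec
      manifest[[k]] <- data.table::data.table(
        animal_id = animal$animal_id, condition = conds[mi],
        measurement_index = mi, seed = mseed,
        file = sprintf("%s_m%03d_%s.csv", animal$animal_id, mi, conds[mi]))
    }
  }
  manifest <- data.table::rbindlist(manifest)
  out <- list(records = records, manifest = manifest, cohort = cohort,
              spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(records)) {
      path <- file.path(out_dir, manifest$file[k])
      tryCatch(write_record(records[[k]], path),
               error = function(e) stop("run_protocol: failed writing ",
                                        path, ": ", conditionMessage(e)))
    }
    data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
    return(invisible(out))
  }
  out
}

.load_dataset <- function(dataset) {
  if (is.character(dataset)) {
    if (!dir.exists(dataset))
      stop("analyze_dataset: dataset directory not found: ", dataset)
    mpath <- file.path(dataset, "manifest.csv")
    if (!file.exists(mpath))
      stop("analyze_dataset: no manifest.csv in ", dataset)
    manifest <- data.table::fread(mpath)
    records <- lapply(manifest$file,
                      function(f) read_record(file.path(dataset, f)))
    list(records = records, manifest = manifest)
  } else if (is.list(dataset) && !is.null(dataset$records)) {
    dataset
  } else {
    stop("analyze_dataset: expected a dataset directory or run_protocol() output")
  }
}

#' Analyze a protocol dataset end to end
#'
#' Runs R-peak detection, cycle segmentation, per-animal alpha calibration
#' (baseline measurements only), the per-beat summary, per-animal
#' through-origin fits and Bland-Altman summaries, and the pooled
#' no-intercept random-slope mixed model with condition contrasts.
#'
#' @param dataset A directory written by [run_protocol()] or its in-memory
#'   return value.
#' @param reference Reference condition for the mixed model.
#' @param direction Regression direction, see [fit_mixed_slope_model()].
#' @param out_dir If non-`NULL`, writes `beats.csv`, `per_animal.csv`,
#'   `bland_altman.csv`, `condition_slopes.csv` and `run_log.txt` there.
#' @return List of class `agreement_results`: `beats`, `alphas`,
#'   `per_animal` (slope/CI/R2 per animal), `bland_altman` (per-animal
#'   summaries), `mixed` (the `mixed_fit`), `contrasts`, `log`.
#' @export
analyze_dataset <- function(dataset, reference = "baseline",
                            direction = "pwr_on_sw", out_dir = NULL) {
  ds <- .load_dataset(dataset)
  if (!length(ds$records)) stop("analyze_dataset: dataset is empty")

  raw <- data.table::rbindlist(lapply(ds$records, function(rec) {
    peaks <- detect_r_peaks(rec$ecg, rec$fs)
    spans <- segment_cycles(rec, peaks)
    beat_summary(rec, spans, alpha = NULL)
  }))

  # alpha calibration: once per animal, baseline cycles only
  animals <- unique(raw$animal_id)
  alphas <- lapply(animals, function(id) {
    b <- raw[animal_id == id & condition == "baseline"]
    if (!nrow(b))
      stop("analyze_dataset: calibration error, animal '", id,
           "' has no baseline measurements")
    alpha_calibration(b$sv_cond_raw_mL, b$sv_mL)
  })
  names(alphas) <- animals

  beats <- data.table::copy(raw)
  for (id in animals)
    beats[animal_id == id, sw_J := sw_J / alphas[[id]]$alpha]

  per_animal <- data.table::rbindlist(lapply(animals, function(id) {
    b <- beats[animal_id == id]
    fit <- through_origin_fit(b$sw_J, b$pwr_integral_J)
    data.table::data.table(
      animal_id = id, n_beats = fit$n, alpha = alphas[[id]]$alpha,
      slope_pwr_sw = fit$slope, ci95_low = fit$ci95_low,
      ci95_high = fit$ci95_high, r2_uncentered = fit$r2_uncentered,
      pearson_r = fit$pearson_r)
  }))

  ba <- data.table::rbindlist(lapply(animals, function(id) {
    b <- beats[animal_id == id]
    res <- bland_altman(b$sw_J, b$pwr_integral_J)
    data.table::data.table(
      animal_id = id, mean_diff_J = res$mean_diff, sd_diff_J = res$sd_diff,
      loa_low_J = res$loa_low, loa_high_J = res$loa_high, n = res$n)
  }))

  mixed <- NULL
  contrasts <- NULL
  if (length(animals) >= 2 && length(unique(beats$condition)) >= 1) {
    mixed <- fit_mixed_slope_model(beats, reference = reference,
                                   direction = direction)
    contrasts <- condition_contrasts(mixed)
  }

  log_lines <- c(
    sprintf("cardiopower %s analysis run: %s",
            as.character(utils::packageVersion("cardiopower")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("records: %d, beats: %d, animals: %d",
            length(ds$records), nrow(beats), length(animals)),
    sprintf("excluded records: 0 (no auto-exclusion; inspect manually)"),
    sprintf("alpha per animal: %s",
            paste(animals,
                  sprintf("%.4f", vapply(alphas, `[[`, numeric(1), "alpha")),
                  sep = "=", collapse = ", ")))

  res <- structure(list(beats = beats, alphas = alphas,
                        per_animal = per_animal, bland_altman = ba,
                        mixed = mixed, contrasts = contrasts,
                        log = log_lines),
                   class = "agreement_results")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_beat_table(beats, file.path(out_dir, "beats.csv"))
    data.table::fwrite(per_animal, file.path(out_dir, "per_animal.csv"))
    data.table::fwrite(ba, file.path(out_dir, "bland_altman.csv"))
    if (!is.null(contrasts))
      data.table::fwrite(contrasts,
                         file.path(out_dir, "condition_slopes.csv"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.agreement_results <- function(x, ...) {
  cat("<agreement_results>\n")
  cat(sprintf("  %d beats, %d animals\n", nrow(x$beats),
              nrow(x$per_animal)))
  print(x$per_animal[, .(animal_id, slope_pwr_sw, r2_uncentered)])
  if (!is.null(x$mixed)) print(x$mixed)
  invisible(x)
}

.cli_usage <- paste(
  "usage: cardiopower <command> [options]",
  "",
  "commands:",
  "  simulate --out DIR [--config FILE.json] [--seed N]",
  "  analyze  --in DIR --out DIR",
  "  report   --in DIR --out FILE",
  sep = "\n")

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) return(NULL)
    opts[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (run the protocol into a dataset directory),
#' `analyze` (dataset directory to result tables), `report` (result tables
#' to a plain-text summary). A JSON config for `simulate` may override any
#' [protocol_spec()] field plus `fs` and `noise` (logical). Errors print to
#' stderr; exit status 0 on success, 1 on runtime errors, 2 on usage errors.
#'
#' @param argv Character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  fail <- function(status, msg) {
    message(msg)
    invisible(status)
  }
  if (!length(argv)) return(fail(2L, .cli_usage))
  cmd <- argv[1]
  opts <- .cli_opts(argv[-1])
  if (is.null(opts) || !cmd %in% c("simulate", "analyze", "report"))
    return(fail(2L, .cli_usage))
  res <- tryCatch({
    if (cmd == "simulate") {
      if (is.null(opts$out)) return(fail(2L, .cli_usage))
      conf <- if (!is.null(opts$config))
        jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
      seed <- as.integer(opts$seed %||% conf$seed %||% 1L)
      spec <- protocol_spec(
        n_animals = conf$n_animals %||% 6,
        n_sets = conf$n_sets %||% 10,
        n_drug_measurements = conf$n_drug_measurements %||% 10,
        cycles_per_measurement = conf$cycles_per_measurement %||% 10,
        seed = seed)
      cfg <- sim_config(fs = conf$fs %||% 1000, seed = seed)
      message(sprintf("simulating %d animals x %d measurements ...",
                      spec$n_animals,
                      length(.protocol_conditions(spec))))
      run_protocol(spec, cfg, out_dir = opts$out,
                   noise = conf$noise %||% TRUE)
      message("dataset written to ", opts$out)
    } else if (cmd == "analyze") {
      if (is.null(opts$`in`) || is.null(opts$out))
        return(fail(2L, .cli_usage))
      res <- analyze_dataset(opts$`in`, out_dir = opts$out)
      message(paste(res$log, collapse = "\n"))
    } else {  # report
      if (is.null(opts$`in`) || is.null(opts$out))
        return(fail(2L, .cli_usage))
      pa <- file.path(opts$`in`, "per_animal.csv")
      cs <- file.path(opts$`in`, "condition_slopes.csv")
      if (!file.exists(pa))
        stop("report: no per_animal.csv under ", opts$`in`)
      t2 <- data.table::fread(pa)
      lines <- c("cardiopower report",
                 "== per-animal SW vs PWR-integral agreement ==",
                 utils::capture.output(print(t2)))
      if (file.exists(cs)) {
        lines <- c(lines, "== mixed-model condition slopes ==",
                   utils::capture.output(print(data.table::fread(cs))))
      }
      writeLines(lines, opts$out)
      message("report written to ", opts$out)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
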