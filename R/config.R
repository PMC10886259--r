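# Configuration, seeding and result-writing glue shared by the command-line
# driver (inst/cli/y90ici.R) and scripted use.

#' Default run configuration
#'
#' Nested list with every tunable of the simulator at its default: the model
#' parameter block, the cohort distributions, the Y90 and ICI treatment
#' blocks, and the trial block. A configuration file only needs the keys it
#' overrides.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  p <- model_parameters()
  list(
    model = unclass(p),
    cohort = list(n = 10000L, T0_mean = 1.07e11, T0_cv = 0.30,
                  L0_mean = baseline_from_counts(1122),
                  L0_sd = baseline_from_counts(469),
                  alphaT_mean = 0.148, alphaT_sd = 0.024,
                  q_mean = 0.12, q_sd = 0.04,
                  delta_mean = 0.12, delta_sd = 0.04),
    y90 = list(total_dose_gy = 400, n_fractions = 26L, kappa_blood = 0.05),
    ici = list(delta_durva = 0.12, interval_days = 14L,
               duration_days = 730L),
    trial = list(arm = "A", interval_days = 60, horizon_months = 120,
                 dt = 0.25, dm_threshold_cc = 0.1, dm_mode = "all",
                 pd_reference = "nadir", pd_detect_cells = 1.5e5),
    calibration = list(cr = 0.79, pr = 0.20, sd = 0.0, pd = 0.0,
                       dose = 400, cr_cell_threshold = 1e8,
                       assess_month = 6),
    seed = 1L,
    outdir = "results",
    log_level = "info"
  )
}

.check_range <- function(cfg) {
  chk <- function(val, lo, hi, name) {
    if (!is.numeric(val) || any(!is.finite(val)) || any(val < lo) ||
        any(val > hi)) {
      stop("config value '", name, "' must lie in [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  chk(cfg$cohort$q_mean, 0, 1, "cohort.q_mean")
  chk(cfg$cohort$delta_mean, 0, 1, "cohort.delta_mean")
  chk(cfg$model$q, 0, 1, "model.q")
  chk(cfg$model$delta_durva, 0, 1, "model.delta_durva")
  chk(cfg$ici$delta_durva, 0, 1, "ici.delta_durva")
  chk(cfg$y90$kappa_blood, 0, 1, "y90.kappa_blood")
  chk(cfg$trial$interval_days, 0, 300, "trial.interval_days")
  chk(cfg$cohort$n, 1, Inf, "cohort.n")
  do.call(model_parameters, cfg$model) # full parameter validation
  invisible(cfg)
}

# deep-merge user values into defaults, erroring on unknown keys
.merge_config <- function(base, user, path = character(0)) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]], c(path, nm))
    } else {
      if (!is.null(base[[nm]]) && is.numeric(base[[nm]]) &&
          !is.numeric(user[[nm]])) {
        stop("config key '", paste(c(path, nm), collapse = "."),
             "' must be numeric", call. = FALSE)
      }
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) file, fills every missing key from
#' [default_config()], rejects unknown keys by name, and range-checks the
#' values. An empty file yields the full default configuration. The loaded
#' configuration round-trips losslessly through [write_config()].
#'
#' @param path Configuration file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_config(), user)
  .check_range(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg Configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Derive a sub-stream seed from the master seed
#'
#' Deterministic map from a master seed and a purpose label to a 31-bit
#' integer seed, so every stochastic step of a run can be traced to one
#' integer.
#'
#' @param master Master seed (integer).
#' @param purpose Character label, e.g. `"cohort"`, `"calibration"`.
#' @return Integer seed.
#' @export
derive_seed <- function(master, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.double(master) * 48271 + h * 16807) %% 2147483647)
}

#' Write trial artifacts with a manifest
#'
#' Writes the CSV/JSON artifacts of a [run_trial()] result, a sweep grid or
#' a [fit_q_distribution()] fit into a directory, plus a `manifest.json`
#' recording the file list, seeds, a configuration hash and the package
#' version.
#'
#' @param result A `trial_result`, `sweep_grid`, or `q_fit`.
#' @param outdir Output directory (created if missing).
#' @param config Optional configuration list to snapshot alongside.
#' @return The manifest (invisibly).
#' @export
write_results <- function(result, outdir, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  files <- character(0)
  seeds <- list()
  put <- function(fname) file.path(outdir, fname)
  if (inherits(result, "trial_result")) {
    write_event_csv(result$events, put("events.csv"))
    utils::write.csv(result$summary, put("summary.csv"), row.names = FALSE)
    jsonlite::write_json(result$comparisons, put("comparisons.json"),
                         digits = NA)
    for (a in names(result$km)) {
      write_km_csv(result$km[[a]]$pfs, put(paste0("km_pfs_", a, ".csv")))
      write_km_csv(result$km[[a]]$dm, put(paste0("km_dm_", a, ".csv")))
    }
    files <- c("events.csv", "summary.csv", "comparisons.json",
               paste0("km_pfs_", names(result$km), ".csv"),
               paste0("km_dm_", names(result$km), ".csv"))
    seeds$cohort <- result$config$cohort_seed
    if (is.null(config)) config <- result$config
  } else if (inherits(result, "sweep_grid")) {
    utils::write.csv(result, put("grid.csv"), row.names = FALSE)
    files <- "grid.csv"
    seeds$cohort <- result$seed[1]
  } else if (inherits(result, "q_fit")) {
    write_qfit_json(result, put("qfit.json"))
    files <- "qfit.json"
    seeds$calibration <- result$seed
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  cfg_path <- put("config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  files <- c(files, "config.json")
  manifest <- list(files = files, seeds = seeds,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   package_version =
                     as.character(utils::packageVersion("y90ici")),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, put("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
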