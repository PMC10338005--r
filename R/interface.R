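# Scenario presets, config parsing and the command-line driver.

preset_table <- function() {
  list(
    # one-cell mean-flow studies (strong waviness)
    "meanflow-alpha4" = list(
      params = list(alpha = 4, beta = 0.4, Ri = 0, sigma = 1, n = 1,
                    epsilon = 0.02),
      grid = list(nx_cell = 96, neta = 97),
      ic = list(x0 = 0.5, delta = 0.2),
      run = NULL),
    "meanflow-alpha16" = list(
      params = list(alpha = 16, beta = 0.4, Ri = 0, sigma = 1, n = 1,
                    epsilon = 0.02),
      grid = list(nx_cell = 96, neta = 97),
      ic = list(x0 = 0.5, delta = 0.2),
      run = NULL),
    # neutrally buoyant bolus in a three-cell canal: closed-cell trapping
    "neutral-bolus" = list(
      params = list(alpha = 4, beta = 0.2, Ri = 0, sigma = 1, n = 3,
                    epsilon = 0.02),
      grid = list(nx_cell = 200, neta = 101),
      ic = list(x0 = 1.75, delta = 0.2),
      run = list(tau_end = 8, snap_dt = 1, cfl = 0.4)),
    # light solute (hypobaric), base buoyant case: upward draft
    "light-bolus" = list(
      params = list(alpha = 4, beta = 0.2, Ri = 1, sigma = 1, n = 3,
                    epsilon = 0.02),
      grid = list(nx_cell = 200, neta = 101),
      ic = list(x0 = 1.75, delta = 0.2),
      run = list(tau_end = 8, snap_dt = 1, cfl = 0.4))
  )
}

#' Named scenario presets
#'
#' Ready-made parameter sets for the canonical scenarios: the one-cell
#' mean-flow studies at strong waviness (`"meanflow-alpha4"`,
#' `"meanflow-alpha16"`: `beta = 0.4`), and the three-cell bolus-dispersion
#' runs (`"neutral-bolus"`: `Ri = 0`; `"light-bolus"`: `Ri = 1`; both
#' `beta = 0.2`, `alpha = 4`, `sigma = 1`, bolus at `x0 = 1.75` with width
#' `delta = 0.2`, stroke-length ratio `epsilon = 0.02` as metadata).
#'
#' @param name Preset name; with no argument, lists available presets.
#' @return A validated `"run_config"` object (see [load_config()]), or the
#'   character vector of preset names.
#' @examples
#' presets()
#' presets("light-bolus")$params$Ri # 1
#' @export
presets <- function(name = NULL) {
  tab <- preset_table()
  if (is.null(name)) return(names(tab))
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  }
  as_run_config(tab[[name]], preset = name)
}

config_defaults <- function() {
  list(params = list(alpha = 4, beta = 0.2, Ri = 0, sigma = 1, n = 3,
                     epsilon = NULL),
       grid = list(nx_cell = 200, neta = 101),
       ic = list(x0 = 1.75, delta = 0.2),
       run = list(tau_end = 8, snap_dt = 1, cfl = 0.4),
       output = list(dir = "."))
}

# merge b into a, recursively, rejecting unknown keys
merge_config <- function(a, b, path = "") {
  for (k in names(b)) {
    if (!k %in% names(a)) {
      stop("unknown config key: '", paste0(path, k), "'")
    }
    if (is.list(a[[k]]) && is.list(b[[k]])) {
      a[[k]] <- merge_config(a[[k]], b[[k]], paste0(path, k, "."))
    } else {
      a[[k]] <- b[[k]]
    }
  }
  a
}

as_run_config <- function(raw, preset = NULL) {
  cfg <- config_defaults()
  raw <- raw[!vapply(raw, is.null, logical(1L))]
  cfg <- merge_config(cfg, raw)
  problems <- character()
  p <- try(do.call(channel_params, cfg$params), silent = TRUE)
  if (inherits(p, "try-error")) {
    problems <- c(problems, conditionMessage(attr(p, "condition")))
  }
  if (cfg$grid$nx_cell < 16) problems <- c(problems, "grid.nx_cell must be >= 16")
  if (cfg$grid$neta < 9) problems <- c(problems, "grid.neta must be >= 9")
  if (cfg$run$tau_end <= 0) problems <- c(problems, "run.tau_end must be > 0")
  if (cfg$run$snap_dt <= 0) problems <- c(problems, "run.snap_dt must be > 0")
  if (cfg$ic$delta <= 0) problems <- c(problems, "ic.delta must be > 0")
  if (cfg$ic$x0 <= 0 || (is.numeric(cfg$params$n) && cfg$ic$x0 >= cfg$params$n)) {
    problems <- c(problems, "ic.x0 must lie inside (0, n)")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg$preset <- preset
  structure(cfg, class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file describing a run (sections `params`, `grid`,
#' `ic`, `run`, `output`, optional `preset`), applies preset values, then
#' file values, then any `overrides` (highest precedence), validates every
#' invariant and rejects unknown keys with an itemised error.
#'
#' @param path Path to a YAML config file, or `NULL` to start from defaults.
#' @param overrides Named list in the same nested shape, applied last
#'   (e.g. `list(params = list(Ri = 0.25))`).
#' @return A `"run_config"` object: nested list with `params`, `grid`, `ic`,
#'   `run`, `output` and `preset`.
#' @examples
#' cfg <- load_config(overrides = list(params = list(alpha = 8)))
#' cfg$params$alpha
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  preset <- raw$preset %||% overrides$preset
  raw$preset <- NULL
  overrides$preset <- NULL
  base <- if (is.null(preset)) config_defaults() else unclass(presets(preset))
  base$preset <- NULL
  base <- base[!vapply(base, is.null, logical(1L))]
  merged <- merge_config(config_defaults(), base)
  merged <- merge_config(merged, raw)
  merged <- merge_config(merged, overrides)
  as_run_config(merged, preset = preset)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", if (!is.null(x$preset)) paste0("preset: ", x$preset), "\n")
  str <- yaml::as.yaml(unclass(x)[c("params", "grid", "ic", "run", "output")])
  cat(str)
  invisible(x)
}

#' Convert slow time to fast time and oscillation count
#'
#' The slow dispersion time is `tau = epsilon^2 t` with `t` the fast
#' (radian) time of the pressure oscillation, so `t = tau / epsilon^2` and
#' the number of oscillation cycles is `t / (2 pi)`.
#'
#' @param tau Slow time(s).
#' @param epsilon Stroke-length ratio, > 0.
#' @return Tibble with columns `tau`, `t` and `cycles`.
#' @examples
#' cycles_from_tau(8, 0.02)$t # 20000
#' @export
cycles_from_tau <- function(tau, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a positive number.")
  }
  t_fast <- tau / epsilon^2
  tibble::tibble(tau = tau, t = t_fast, cycles = t_fast / (2 * pi))
}

config_params <- function(cfg) do.call(channel_params, cfg$params)

run_from_config <- function(cfg, keep_fields = FALSE, verbose = FALSE) {
  run_transport(config_params(cfg),
                nx_cell = cfg$grid$nx_cell, neta = cfg$grid$neta,
                x0 = cfg$ic$x0, delta = cfg$ic$delta,
                tau_end = cfg$run$tau_end, snap_dt = cfg$run$snap_dt,
                cfl = cfg$run$cfl, keep_fields = keep_fields,
                verbose = verbose)
}

#' Command-line driver
#'
#' Thin shell entry point over the package functions (see
#' `inst/cli/wavechannel` for the executable wrapper). Subcommands:
#' \describe{
#'   \item{meanflow}{write the mean Lagrangian drift fields, streamfunction/
#'     vorticity and converged peak table for one cell.}
#'   \item{transport}{run a full bolus-dispersion simulation and write
#'     profile, diagnostic and config-echo files.}
#'   \item{sweep}{repeat a transport run varying one parameter over a
#'     comma-separated list, writing one flow-rate series per member.}
#' }
#' Flags: `--config FILE`, `--preset NAME`, `--out DIR`, parameter overrides
#' `--alpha`, `--beta`, `--Ri`, `--sigma`, `--n`, `--nx-cell`, `--neta`,
#' `--x0`, `--delta`, `--tau-end`, `--snap-dt`; for sweep:
#' `--param NAME --values v1,v2,...`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success); artifacts on disk.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    run_cli_inner(argv)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_flags <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(argv)) stop("flag --", key, " needs a value")
    out[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

flag_num <- function(flags, key) {
  if (is.null(flags[[key]])) NULL else as.numeric(flags[[key]])
}

cli_config <- function(flags) {
  ov <- list(
    params = list(alpha = flag_num(flags, "alpha"),
                  beta = flag_num(flags, "beta"),
                  Ri = flag_num(flags, "Ri"),
                  sigma = flag_num(flags, "sigma"),
                  n = flag_num(flags, "n")),
    grid = list(nx_cell = flag_num(flags, "nx-cell"),
                neta = flag_num(flags, "neta")),
    ic = list(x0 = flag_num(flags, "x0"), delta = flag_num(flags, "delta")),
    run = list(tau_end = flag_num(flags, "tau-end"),
               snap_dt = flag_num(flags, "snap-dt")),
    output = list(dir = flags[["out"]])
  )
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, function(e) is.null(e) || (is.list(e) && !length(e)),
              logical(1L))]
  }
  ov <- drop_null(ov)
  ov$preset <- flags[["preset"]]
  load_config(flags[["config"]], overrides = ov)
}

run_cli_inner <- function(argv) {
  if (!length(argv)) {
    stop("usage: wavechannel <meanflow|transport|sweep> [flags]")
  }
  cmd <- argv[1L]
  if (!cmd %in% c("meanflow", "transport", "sweep")) {
    stop("unknown subcommand '", cmd, "'")
  }
  flags <- parse_flags(argv[-1L])
  cfg <- cli_config(flags)
  dir <- cfg$output$dir %||% "."
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(dir, paste0(cmd, ".log"))
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) {
    line <- sprintf(...)
    cat(line, "\n")
    writeLines(line, logcon)
  }
  say("wavechannel %s | %s", cmd,
      paste(deparse(unclass(cfg)[c("params", "grid")]), collapse = ""))

  if (cmd == "meanflow") {
    p <- config_params(cfg)
    md <- mean_drift(p, cfg$grid$nx_cell, cfg$grid$neta)
    utils::write.csv(tidy(md), file.path(dir, "drift_fields.csv"),
                     row.names = FALSE)
    pk <- drift_peaks(p, nx_cell = cfg$grid$nx_cell, neta = cfg$grid$neta)
    utils::write.csv(pk, file.path(dir, "drift_peaks.csv"), row.names = FALSE)
    say("peak table:")
    say("%s", paste(utils::capture.output(print(as.data.frame(pk))),
                    collapse = "\n"))
  } else if (cmd == "transport") {
    run <- run_from_config(cfg, verbose = FALSE)
    export_transport_run(run, dir, config = cfg)
    d <- run$diagnostics
    say("tau_end = %g, steps = %d, mass drift = %.3e, Q_b(final) = %.6g",
        run$tau_end, run$n_steps,
        abs(d$M[nrow(d)] / d$M[1L] - 1), d$Q_b[nrow(d)])
    cm <- run$cell_mass[run$cell_mass$tau == max(run$cell_mass$tau), ]
    say("per-cell mass at tau = %g: %s", max(cm$tau),
        paste(sprintf("cell %d: %.6f", cm$cell, cm$mass), collapse = "; "))
  } else if (cmd == "sweep") {
    pname <- flags[["param"]] %||% stop("sweep needs --param")
    values <- as.numeric(strsplit(flags[["values"]] %||%
                                    stop("sweep needs --values"), ",")[[1L]])
    for (v in values) {
      raw <- unclass(cfg)[c("params", "grid", "ic", "run", "output")]
      raw$params[[pname]] <- v
      cfg_v <- as_run_config(raw, preset = cfg$preset)
      run <- run_from_config(cfg_v)
      series <- run$diagnostics[, c("tau", "Q_b")]
      fn <- file.path(dir, sprintf("qb_series_%s_%g.csv", pname, v))
      utils::write.csv(series, fn, row.names = FALSE)
      say("%s = %g: Q_b(final) = %.6g -> %s", pname, v,
          series$Q_b[nrow(series)], fn)
    }
  }
  invisible(0L)
}

#' Export a transport run as columnar text with a config echo
#'
#' Writes `profiles.csv` (tau, x, C, phi), `diagnostics.csv`,
#' `cell_mass.csv`, `qb_series.csv` and `config.json` (exact echo of the
#' run's configuration for provenance) into `dir`.
#'
#' @param run A [run_transport()] result.
#' @param dir Output directory (created if missing).
#' @param config Optional `"run_config"` echoed to `config.json`; defaults
#'   to the settings stored in the run.
#' @return `dir`, invisibly.
#' @export
export_transport_run <- function(run, dir, config = NULL) {
  stopifnot(inherits(run, "transport_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(run$diagnostics, file.path(dir, "diagnostics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$cell_mass, file.path(dir, "cell_mass.csv"),
                   row.names = FALSE)
  utils::write.csv(run$diagnostics[, c("tau", "Q_b")],
                   file.path(dir, "qb_series.csv"), row.names = FALSE)
  echo <- if (is.null(config)) {
    c(run$params[c("alpha", "beta", "Ri", "sigma", "n", "epsilon")],
      run$settings)
  } else unclass(config)
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
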