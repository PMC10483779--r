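#' Run one pipeline stage with a validated configuration
#'
#' The reproducible entry point tying the stages together. Each command
#' validates its configuration against a schema (unknown keys are
#' rejected), runs the corresponding package functions, writes its outputs
#' plus the resolved configuration (`config.yaml`) and a plain-text log
#' (`run.log`, capturing seed, config hash and package version) into
#' `out_dir`. All randomness flows from the single `seed` entry of the
#' configuration.
#'
#' Commands and their main outputs:
#' \describe{
#'   \item{`capacity`}{`capacity.csv` - batch/generation capacity report.}
#'   \item{`simulate-rbale`}{`timeseries.csv`, `events.csv`, `layout.csv`,
#'     `truth.json` - synthetic repetitive-batch dataset.}
#'   \item{`simulate-bioreactor`}{`bioreactor.csv`, `truth.json`.}
#'   \item{`fit-rbale`}{`batch_rates.csv` (`group,batch,mu_est,ci_lo,ci_hi,
#'     n_points`), `fit.json`.}
#'   \item{`fit-monod`}{`monod_fit.json`.}
#'   \item{`report`}{`summary.csv`, `summary.json` - see [rbale_report()].}
#' }
#'
#' @param command One of `"capacity"`, `"simulate-rbale"`,
#'   `"simulate-bioreactor"`, `"fit-rbale"`, `"fit-monod"`, `"report"`.
#' @param config Named list of command options; see the schemas in
#'   `rbale:::command_schemas`.
#' @param out_dir Output directory (created).
#'
#' @return The command's main result, invisibly.
#' @examples
#' dir <- tempfile()
#' rbale_run("capacity", list(wells_per_group = 8, groups = 6,
#'                            recycle = FALSE, gens_per_batch = 3), dir)
#' @export
rbale_run <- function(command, config = list(), out_dir) {
  command <- match.arg(command, names(command_schemas))
  schema <- command_schemas[[command]]
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s) for ", command, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- modifyList(schema, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- switch(command,
    "capacity" = {
      cap <- plan_capacity(cfg$wells_per_group, cfg$groups,
                           recycle = cfg$recycle,
                           gens_per_batch = cfg$gens_per_batch)
      readr::write_csv(cap, file.path(out_dir, "capacity.csv"))
      cap
    },
    "simulate-rbale" = {
      d <- gen_rbale_dataset(scenario = cfg$scenario,
                             n_batches = cfg$n_batches,
                             noise = noise_model(cv = cfg$cv),
                             seed = cfg$seed, blank_bs = cfg$blank_bs)
      write_fixtures(d, out_dir)
      d
    },
    "simulate-bioreactor" = {
      d <- gen_bioreactor_dataset(n_reactors = cfg$n_reactors,
                                  sample_interval_h = cfg$sample_interval_h,
                                  t_end_h = cfg$t_end_h,
                                  noise = noise_model(cv = cfg$cv),
                                  seed = cfg$seed)
      write_fixtures(d, out_dir)
      d
    },
    "fit-rbale" = {
      fx <- read_fixtures(cfg$input)
      fit <- fit_rbale(fx$ts, fx$events, n_starts = cfg$n_starts,
                       seed = cfg$seed,
                       exclude_batches = cfg$exclude_batches %||% integer(0))
      if (isTRUE(cfg$bootstrap) && isTRUE(fit$converged)) {
        fit <- bootstrap_ci(fit, n_boot = cfg$n_boot, seed = cfg$seed)
      }
      write_batch_rates(fit, file.path(out_dir, "batch_rates.csv"))
      jsonlite::write_json(fit_result_json(fit),
                           file.path(out_dir, "fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      fit
    },
    "fit-monod" = {
      fx <- read_fixtures(cfg$input)
      fit <- fit_monod_hierarchical(fx$obs, n_starts = cfg$n_starts,
                                    seed = cfg$seed)
      jsonlite::write_json(fit_result_json(fit),
                           file.path(out_dir, "monod_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      fit
    },
    "report" = rbale_report(cfg$input %||% out_dir, out_dir)
  )
  yaml::write_yaml(c(list(command = command), cfg),
                   file.path(out_dir, "config.yaml"))
  writeLines(c(sprintf("command: %s", command),
               sprintf("seed: %s", format(cfg$seed %||% NA)),
               sprintf("config_hash: %s", rlang::hash(cfg)),
               sprintf("rbale_version: %s",
                       as.character(utils::packageVersion("rbale")))),
             file.path(out_dir, "run.log"))
  invisible(result)
}

command_schemas <- list(
  "capacity" = list(wells_per_group = 8, groups = 6, recycle = FALSE,
                    gens_per_batch = 3, seed = 1),
  "simulate-rbale" = list(scenario = "constant", n_batches = 16, cv = 0.02,
                          blank_bs = 2, seed = 1),
  "simulate-bioreactor" = list(n_reactors = 4, cv = 0.03,
                               sample_interval_h = 2, t_end_h = 24, seed = 1),
  "fit-rbale" = list(input = NULL, n_starts = 10, seed = 1,
                     exclude_batches = NULL, bootstrap = FALSE, n_boot = 100),
  "fit-monod" = list(input = NULL, n_starts = 5, seed = 1),
  "report" = list(input = NULL, seed = 1)
)

write_batch_rates <- function(fit, path) {
  d <- fit$per_batch
  d$group <- fit$slices$group[1]
  ci <- fit$ci
  if (!is.null(ci)) {
    mu_ci <- ci[grepl("^mu_", ci$term), ]
    mu_ci$batch <- as.integer(sub("^mu_", "", mu_ci$term))
    d <- dplyr::left_join(d, mu_ci[, c("batch", "conf.low", "conf.high")],
                          by = "batch")
    names(d)[names(d) == "conf.low"] <- "ci_lo"
    names(d)[names(d) == "conf.high"] <- "ci_hi"
  } else {
    d$ci_lo <- NA_real_; d$ci_hi <- NA_real_
  }
  readr::write_csv(d[, c("group", "batch", "mu_est", "ci_lo", "ci_hi",
                         "n_points")], path)
  invisible(path)
}

fit_result_json <- function(fit) {
  if (inherits(fit, "rbale_fit")) {
    list(type = "rbale_fit",
         estimates = fit$estimates, ci = fit$ci,
         objective = fit$objective, converged = fit$converged,
         n_starts = fit$n_starts, seed = fit$seed)
  } else {
    list(type = "monod_fit",
         estimates = fit$estimates, ci = fit$ci,
         objective = fit$objective, converged = fit$converged,
         n_starts = fit$n_starts, seed = fit$seed)
  }
}

#' Summarize the artifacts of a pipeline run directory
#'
#' Collects whatever pipeline outputs are present (event logs, per-batch
#' rate tables, fit results, capacity reports) into one `summary.csv` and
#' one `summary.json`. Running it twice over the same directory produces
#' byte-identical outputs. If the directory contains none of the expected
#' artifacts, the error lists what was looked for.
#'
#' @param dir Directory containing pipeline outputs.
#' @param out_dir Where to write the summary (defaults to `dir`).
#'
#' @return A tibble with one row per summary quantity (`section`, `name`,
#'   `value`), invisibly.
#' @export
rbale_report <- function(dir, out_dir = dir) {
  expected <- c("events.csv", "batch_rates.csv", "capacity.csv", "fit.json",
                "monod_fit.json")
  present <- expected[file.exists(file.path(dir, expected))]
  if (!length(present)) {
    stop("no pipeline artifacts in ", dir, "; expected any of: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  add <- function(section, name, value) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      section = section, name = name, value = value)
  }
  if ("events.csv" %in% present) {
    ev <- read_events(file.path(dir, "events.csv"))
    trig <- ev[ev$kind == "trigger", ]
    add("schedule", "n_batches", nrow(trig))
    add("schedule", "n_groups", length(unique(ev$group)))
    add("schedule", "horizon_h", max(ev$time_h[ev$kind != "dry_complete"]))
  }
  if ("batch_rates.csv" %in% present) {
    br <- readr::read_csv(file.path(dir, "batch_rates.csv"),
                          col_types = readr::cols())
    add("rates", "n_batches_fit", nrow(br))
    add("rates", "mean_mu", mean(br$mu_est))
    add("rates", "final_mu", br$mu_est[which.max(br$batch)])
  }
  if ("capacity.csv" %in% present) {
    cap <- readr::read_csv(file.path(dir, "capacity.csv"),
                           col_types = readr::cols())
    add("capacity", "batches_per_run", cap$batches_per_run[1])
    add("capacity", "total_generations", cap$total_generations[1])
  }
  for (f in intersect(c("fit.json", "monod_fit.json"), present)) {
    fj <- jsonlite::read_json(file.path(dir, f), simplifyVector = TRUE)
    add(fj$type, "objective", fj$objective)
    add(fj$type, "converged", as.numeric(fj$converged))
  }
  summary <- dplyr::bind_rows(rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Command-line interface to the pipeline
#'
#' A thin argv parser over [rbale_run()]: the first argument is the
#' command, `--config <file>` loads a YAML configuration, and any
#' `--key value` pair overrides it (precedence: flag > config file >
#' default). `--out <dir>` selects the output directory. Designed to be
#' called from the wrapper script installed at
#' `system.file("cli", "rbale.R", package = "rbale")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @examples
#' rbale_cli(c("capacity", "--wells_per_group", "8", "--groups", "6",
#'             "--out", tempfile()))
#' @export
rbale_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: rbale <command> [--config file.yaml] [--key value ...] --out <dir>")
    command <- args[[1]]
    args <- args[-1]
    if (length(args) %% 2 != 0) stop("flags must come in --key value pairs")
    keys <- args[c(TRUE, FALSE)]
    vals <- args[c(FALSE, TRUE)]
    if (!all(startsWith(keys, "--"))) stop("malformed flags: ",
                                           paste(keys, collapse = " "))
    keys <- sub("^--", "", keys)
    flags <- stats::setNames(as.list(vals), keys)
    out_dir <- flags$out %||% stop("--out <dir> is required")
    flags$out <- NULL
    config <- list()
    if (!is.null(flags$config)) {
      if (!file.exists(flags$config)) stop("config file not found: ", flags$config)
      config <- yaml::read_yaml(flags$config)
      flags$config <- NULL
    }
    flags <- lapply(flags, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else if (v %in% c("true", "false")) v == "true" else v
    })
    config <- modifyList(config, flags)
    rbale_run(command, config, out_dir)
    0L
  }, error = function(e) {
    message("rbale: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
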