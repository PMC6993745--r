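## End-to-end workflow: simulate -> derive -> grid -> fit -> bootstrap ->
## summarize -> plot, with a JSON run manifest and a CLI dispatcher.

write_results_csv <- function(curve, path) {
  res <- curve$results
  for (col in c("ci_lower", "ci_upper"))
    if (is.null(res[[col]])) res[[col]] <- NA_real_
  cols <- c("spec_id", "day_type", "sleep_measure", "tech_measure",
            "control_set", "beta", "se", "p", "n", "r2", "significant",
            "ci_lower", "ci_upper", "status")
  write.csv(res[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the complete pipeline
#'
#' Executes every stage (simulate, derive, grid, fit, bootstrap, summarize,
#' plot) and writes all tables, figures and a JSON run manifest to
#' `out_dir`. Idempotent for a fixed configuration seed: re-running
#' reproduces the CSV outputs bitwise. A stage failure is recorded in the
#' manifest rather than aborting the run.
#'
#' @param config An [generator_config()] (give it a `seed` for
#'   reproducibility).
#' @param out_dir Output directory (created if needed).
#' @param n_reps Bootstrap replicates (default 500, the full-run setting;
#'   lower it for quick passes).
#' @param alpha Significance level.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config, out_dir, n_reps = 500, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  outputs <- character(0)
  note <- function(stage, expr) {
    r <- tryCatch(list(value = expr, error = NULL),
                  error = function(e) list(value = NULL,
                                           error = conditionMessage(e)))
    stages[[stage]] <<- if (is.null(r$error)) "ok" else
      paste("error:", r$error)
    r$value
  }
  path <- function(f) file.path(out_dir, f)

  sim <- note("simulate", generate_cohort(config))
  if (!is.null(sim)) {
    outputs <- c(outputs, write_cohort_csv(sim$cohort, path("cohort.csv")),
                 write_diaries_csv(sim$diaries, path("diaries.csv")))
  }
  derived <- if (!is.null(sim))
    note("derive", {
      d <- derive_measures(sim, fallback = config$fallback_score)
      write.csv(d, path("derived.csv"), row.names = FALSE, na = "")
      outputs <- c(outputs, path("derived.csv"))
      d
    })
  grid <- note("grid", {
    g <- build_grid()
    write.csv(g, path("grid.csv"), row.names = FALSE)
    outputs <- c(outputs, path("grid.csv"))
    g
  })
  curve <- if (!is.null(derived) && !is.null(grid))
    note("fit", run_sca(derived, grid, alpha))
  boot <- if (!is.null(curve))
    note("bootstrap", bootstrap_sca(derived, grid, n_reps = n_reps,
                                    seed = (config$seed %||% 0) + 1,
                                    alpha = alpha))
  if (!is.null(curve)) {
    if (!is.null(boot)) curve <- add_bootstrap(curve, boot)
    outputs <- c(outputs, write_results_csv(curve, path("results.csv")))
  }
  if (!is.null(curve))
    note("summarize", {
      summaries <- do.call(rbind, lapply(
        c("day_type", "sleep_measure", "tech_measure", "control_set"),
        function(by) {
          s <- summarize_curve(curve, by)
          data.frame(decision = by, option = s[[1]], s[-1],
                     stringsAsFactors = FALSE)
        }))
      write.csv(summaries, path("summary.csv"), row.names = FALSE)
      outputs <- c(outputs, path("summary.csv"))
      summaries
    })
  if (!is.null(curve))
    note("plot", {
      outputs <- c(outputs,
                   save_figure(plot_curve(curve), path("curve")),
                   save_figure(plot_n_per_spec(curve), path("n_per_spec"),
                               height = 3.5))
      NULL
    })

  manifest <- list(
    package = "sleepsca",
    version = as.character(packageVersion("sleepsca")),
    r_version = R.version.string,
    seed = config$seed,
    n_reps = n_reps,
    alpha = alpha,
    config = config_snapshot(config),
    stages = stages,
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# serialisable view of the configuration (drops solved internals)
config_snapshot <- function(config) {
  keep <- c("n_participants", "diary_fraction", "seed", "true_effects",
            "participation_prob", "digital_hours", "bedtime_use_prob",
            "sleep_onset", "item_targets", "missingness_rates",
            "wake_diary", "fallback_score")
  lapply(unclass(config)[keep], function(x)
    if (is.list(x)) lapply(x, as.list) else as.list(x))
}

## Command line ------------------------------------------------------------

cli_options <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "flat key=value configuration file"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n", type = "integer", default = NULL,
                          help = "cohort size override"),
    optparse::make_option("--out", type = "character", default = "sca_out"),
    optparse::make_option("--data", type = "character", default = NULL,
                          help = "directory with cohort.csv/diaries.csv"),
    optparse::make_option("--reps", type = "integer", default = 500L),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--by", type = "character", default = "day_type")
  )
}

cli_config <- function(opts) {
  overrides <- if (!is.null(opts$config)) read_flat_config(opts$config)
    else list()
  if (!is.null(opts$n)) overrides$n_participants <- opts$n
  overrides$seed <- opts$seed
  config_from_list(overrides)
}

cli_derived <- function(opts) {
  dir <- opts$data %||% opts$out
  sim <- list(cohort = read_cohort_csv(file.path(dir, "cohort.csv")),
              diaries = read_diaries_csv(file.path(dir, "diaries.csv")))
  sim$cohort$has_diary <- sim$cohort$has_diary %in% c(TRUE, "TRUE", "true")
  derive_measures(sim)
}

#' Command-line entry point
#'
#' Dispatches the verbs `simulate`, `derive`, `grid`, `run`, `bootstrap`,
#' `summarize`, `plot` and `all` with `--config`, `--seed`, `--n`, `--out`,
#' `--data`, `--reps`, `--alpha`, `--by` flags. Installed alongside the
#' package as the `inst/cli/sleepsca` launcher.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the main object produced by the verb.
#' @export
sca_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verbs <- c("simulate", "derive", "grid", "run", "bootstrap", "summarize",
             "plot", "all")
  if (length(args) == 0 || !args[1] %in% verbs)
    config_error(paste("usage: sleepsca <verb> [options]; verbs:",
                       paste(verbs, collapse = ", ")))
  verb <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = cli_options()),
    args = args[-1])
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    verb,
    simulate = {
      sim <- generate_cohort(cli_config(opts))
      write_cohort_csv(sim$cohort, file.path(opts$out, "cohort.csv"))
      write_diaries_csv(sim$diaries, file.path(opts$out, "diaries.csv"))
      sim
    },
    derive = {
      d <- cli_derived(opts)
      write.csv(d, file.path(opts$out, "derived.csv"), row.names = FALSE,
                na = "")
      d
    },
    grid = {
      g <- build_grid()
      write.csv(g, file.path(opts$out, "grid.csv"), row.names = FALSE)
      g
    },
    run = {
      d <- read.csv(file.path(opts$data %||% opts$out, "derived.csv"),
                    stringsAsFactors = FALSE)
      d$nvq <- factor(d$nvq, levels = 1:5)
      curve <- run_sca(d, build_grid(), alpha = opts$alpha)
      write_results_csv(curve, file.path(opts$out, "results.csv"))
      curve
    },
    bootstrap = {
      d <- read.csv(file.path(opts$data %||% opts$out, "derived.csv"),
                    stringsAsFactors = FALSE)
      d$nvq <- factor(d$nvq, levels = 1:5)
      boot <- bootstrap_sca(d, build_grid(), n_reps = opts$reps,
                            seed = opts$seed, alpha = opts$alpha)
      write.csv(boot$ci, file.path(opts$out, "boot_ci.csv"),
                row.names = FALSE)
      boot
    },
    summarize = {
      res <- read.csv(file.path(opts$data %||% opts$out, "results.csv"),
                      stringsAsFactors = FALSE)
      curve <- structure(list(results = res, alpha = opts$alpha),
                         class = "sca_curve")
      s <- summarize_curve(curve, by = opts$by)
      print(s)
      s
    },
    plot = {
      res <- read.csv(file.path(opts$data %||% opts$out, "results.csv"),
                      stringsAsFactors = FALSE)
      curve <- structure(list(results = res, alpha = opts$alpha),
                         class = "sca_curve")
      save_figure(plot_curve(curve), file.path(opts$out, "curve"))
      save_figure(plot_n_per_spec(curve), file.path(opts$out, "n_per_spec"),
                  height = 3.5)
      curve
    },
    all = run_all(cli_config(opts), opts$out, n_reps = opts$reps,
                  alpha = opts$alpha)
  )
  invisible(out)
}
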