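# Reproducible run orchestration: each command takes a config (a named
# list, typically read from YAML), writes its outputs under one run
# directory with fixed file names, and records the merged config
# (run.yaml) plus an append-only log (run.log). A saved run directory
# re-runs to identical seeded results.

.merge_config <- function(config, defaults, command) {
  config <- as.list(config)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s) for ", command, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- defaults
  out[names(config)] <- config
  out
}

.init_run_dir <- function(out) {
  if (is.null(out)) stop("config needs an `out` directory", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out,
                             call. = FALSE)
  out
}

.run_log <- function(out, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  cat(line, "\n", file = file.path(out, "run.log"), append = TRUE, sep = "")
  invisible(line)
}

.write_run_meta <- function(out, command, config) {
  meta <- c(list(command = command,
                 package_version = as.character(utils::packageVersion("bindmem"))),
            config)
  yaml::write_yaml(meta, file.path(out, "run.yaml"))
  .run_log(out, "command=", command, " seed=", config$seed,
           " config_hash=", substr(.config_hash(config), 1, 12))
}

.config_hash <- function(config) {
  s <- yaml::as.yaml(config[order(names(config))])
  # small rolling hash; stable across sessions, only used for log labels
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%d", h)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of one of the `run_*` commands.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

.truth_from_config <- function(cfg, conditions) {
  generator_truth(cfg$model, conditions,
                  pb = unlist(cfg$pb), pi = unlist(cfg$pi),
                  a = unlist(cfg$a), c_bind = unlist(cfg$c_bind),
                  sd_binding = cfg$sd_binding, sd_item = cfg$sd_item,
                  b = cfg$b, seed = cfg$seed)
}

#' Simulate a synthetic experiment to disk
#'
#' Wraps [simulate_dataset()]: builds the preset and generator truth from
#' the config, simulates, and writes `trials.csv`, `truth.csv` (subject
#' sidecar), `run.yaml` and `run.log` into the run directory.
#'
#' @param config named list (or path handled by [read_run_config()]) with
#'   fields `out` (run directory, required), `preset` (`"exp1"` ..
#'   `"exp4"`), `model` (`"mpt"`/`"mmm"`), `seed`, truth fields (`pb`,
#'   `pi`, `a`, `c_bind`, per-condition vectors or scalars; `sd_binding`,
#'   `sd_item`, `b`), and optional `n_trials`.
#' @return invisible list of written paths.
#' @export
run_simulate <- function(config) {
  defaults <- list(out = NULL, preset = "exp1", model = "mmm", seed = 1L,
                   pb = 0.5, pi = 0.5, a = 0.3, c_bind = 0.5,
                   sd_binding = 0.5, sd_item = 0.5, b = 0.1,
                   n_trials = NULL)
  cfg <- .merge_config(config, defaults, "simulate")
  out <- .init_run_dir(cfg$out)
  preset <- design_preset(cfg$preset, n_trials = cfg$n_trials)
  truth <- .truth_from_config(cfg, preset$conditions)
  sim <- simulate_dataset(preset, truth, seed = cfg$seed)
  write_trials(sim$trials, file.path(out, "trials.csv"))
  write.csv(sim$subject_truth, file.path(out, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  .write_run_meta(out, "simulate", cfg)
  .run_log(out, "wrote trials.csv (", nrow(sim$trials), " rows), truth.csv (",
           nrow(sim$subject_truth), " rows), category resamples=",
           sim$n_category_resamples)
  invisible(list(trials = file.path(out, "trials.csv"),
                 truth = file.path(out, "truth.csv")))
}

#' Score a trial table to disk
#'
#' Wraps [read_trials()], [apply_exclusions()] and [score_trials()]:
#' writes per-trial scores (`scores.csv`), per subject-by-condition mean
#' free and serial scores (`score_summary.csv`), and the exclusion report
#' (`exclusions.csv`) when a flag table is supplied.
#'
#' @param config named list with fields `out` (required), `trials` (path,
#'   required), `flags` (optional path to an exclusion-flag CSV), `seed`
#'   (recorded for provenance only; scoring is deterministic).
#' @return invisible list of written paths.
#' @export
run_score <- function(config) {
  defaults <- list(out = NULL, trials = NULL, flags = NULL, seed = 1L)
  cfg <- .merge_config(config, defaults, "score")
  if (is.null(cfg$trials)) stop("config needs a `trials` path", call. = FALSE)
  out <- .init_run_dir(cfg$out)
  trials <- read_trials(cfg$trials)
  paths <- list()
  if (!is.null(cfg$flags)) {
    flags <- read.csv(cfg$flags, stringsAsFactors = FALSE)
    excl <- apply_exclusions(trials, flags)
    trials <- excl$data
    write.csv(excl$report, file.path(out, "exclusions.csv"),
              row.names = FALSE, quote = FALSE)
    paths$exclusions <- file.path(out, "exclusions.csv")
    .run_log(out, "exclusions: retained ", length(excl$retained),
             " subjects")
  }
  if (nrow(trials) == 0) {
    warning("no trials left to score after exclusions", call. = FALSE)
    scores <- score_trials(trials[0, , drop = FALSE])
    summary <- data.frame(subject_id = character(0), condition = character(0),
                          free_score = numeric(0), serial_score = numeric(0))
  } else {
    scores <- score_trials(trials)
    cond <- condition_label(scores)
    summary <- aggregate(cbind(free_score, serial_score) ~ subject_id + cond,
                         data = cbind(scores, cond = cond), FUN = mean)
    names(summary)[names(summary) == "cond"] <- "condition"
    summary <- summary[order(summary$subject_id, summary$condition), ]
  }
  write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(summary, file.path(out, "score_summary.csv"), row.names = FALSE,
            quote = FALSE)
  .write_run_meta(out, "score", cfg)
  .run_log(out, "wrote scores.csv (", nrow(scores),
           " trials), score_summary.csv (", nrow(summary), " cells)")
  invisible(c(paths, list(scores = file.path(out, "scores.csv"),
                          summary = file.path(out, "score_summary.csv"))))
}

.canonical_cond_order <- function(conds) {
  # order by time (short < medium < long), then none < arithmetic,
  # then immediate-test suffix; unknown labels keep their sorted position
  task <- sub(":.*$", "", conds)
  rank <- match(task, c("simple", "medium", "slow", "complex"))
  rank[is.na(rank)] <- 99L
  conds[order(rank, conds)]
}

#' Fit a measurement model to a trial table on disk
#'
#' Wraps [aggregate_counts()], [fit_mpt()]/[fit_mmm()] and [contrast()]:
#' writes long-format posterior draws (`draws.csv`), convergence
#' diagnostics (`diagnostics.csv`) and all later-minus-earlier
#' time-condition contrasts of the binding and item parameters
#' (`contrasts.csv`). Convergence problems are reported in the
#' diagnostics table and the log, not as an error.
#'
#' @param config named list with fields `out`, `trials` (path), `model`
#'   (`"mpt"`/`"mmm"`), `encoding_group` (optional filter), `b`, and
#'   sampler fields `chains`, `adapt`, `warmup`, `draws`, `seed`,
#'   `rhat_threshold`.
#' @return invisible list of written paths.
#' @export
run_fit <- function(config) {
  defaults <- list(out = NULL, trials = NULL, model = "mmm",
                   encoding_group = NULL, b = 0.1, chains = 4L,
                   adapt = 500L, warmup = 1000L, draws = 1000L, seed = 1L,
                   rhat_threshold = 1.01)
  cfg <- .merge_config(config, defaults, "fit")
  if (is.null(cfg$trials)) stop("config needs a `trials` path", call. = FALSE)
  out <- .init_run_dir(cfg$out)
  trials <- read_trials(cfg$trials)
  if (!is.null(cfg$encoding_group)) {
    trials <- trials[trials$encoding_group %in% cfg$encoding_group, ,
                     drop = FALSE]
  }
  counts <- aggregate_counts(trials)
  sc <- sampler_config(chains = cfg$chains, adapt = cfg$adapt,
                       warmup = cfg$warmup, draws = cfg$draws,
                       seed = cfg$seed, rhat_threshold = cfg$rhat_threshold)
  fit <- withCallingHandlers(
    if (cfg$model == "mpt") fit_mpt(counts, sc)
    else fit_mmm(counts, sc, b = cfg$b),
    warning = function(w) {
      .run_log(out, "WARNING: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conds <- .canonical_cond_order(fit$conditions)
  pars <- if (cfg$model == "mpt") c("Pb", "Pi") else c("C", "A")
  ctr <- list()
  if (length(conds) > 1) {
    for (p in pars) {
      for (i in seq_along(conds)[-1]) {
        for (j in seq_len(i - 1)) {
          ctr[[length(ctr) + 1L]] <- contrast(fit, p, conds[i], conds[j])
        }
      }
    }
  }
  contrasts <- if (length(ctr)) do.call(rbind, ctr) else
    data.frame(model = character(0), parameter = character(0),
               contrast = character(0), mean = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               credible = logical(0))
  write.csv(fit$draws, file.path(out, "draws.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(fit$diagnostics, file.path(out, "diagnostics.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(contrasts, file.path(out, "contrasts.csv"), row.names = FALSE,
            quote = FALSE)
  .write_run_meta(out, "fit", cfg)
  .run_log(out, "wrote draws.csv, diagnostics.csv, contrasts.csv; flagged=",
           length(fit$flagged))
  invisible(list(draws = file.path(out, "draws.csv"),
                 diagnostics = file.path(out, "diagnostics.csv"),
                 contrasts = file.path(out, "contrasts.csv")))
}

#' Run a parameter-recovery study to disk
#'
#' Wraps [recovery_study()]: writes the per-replication table
#' (`replications.csv`) and its summary (`report.csv`).
#'
#' @param config named list with fields `out`, `preset`, `model`, truth
#'   fields as in [run_simulate()], `n_replications`, `parameter`,
#'   `cond_a`, `cond_b`, `encoding_group`, and the sampler fields of
#'   [run_fit()].
#' @return invisible list of written paths.
#' @export
run_recover <- function(config) {
  defaults <- list(out = NULL, preset = "exp1", model = "mmm", seed = 1L,
                   pb = 0.5, pi = 0.5, a = 0.3, c_bind = 0.5,
                   sd_binding = 0.5, sd_item = 0.5, b = 0.1,
                   n_trials = NULL, n_replications = 10L, parameter = NULL,
                   cond_a = NULL, cond_b = NULL, encoding_group = NULL,
                   chains = 2L, adapt = 300L, warmup = 300L, draws = 400L,
                   rhat_threshold = 1.01)
  cfg <- .merge_config(config, defaults, "recover")
  out <- .init_run_dir(cfg$out)
  preset <- design_preset(cfg$preset, n_trials = cfg$n_trials)
  truth <- .truth_from_config(cfg, preset$conditions)
  sc <- sampler_config(chains = cfg$chains, adapt = cfg$adapt,
                       warmup = cfg$warmup, draws = cfg$draws,
                       seed = cfg$seed, rhat_threshold = cfg$rhat_threshold)
  rep <- recovery_study(preset, truth, n_replications = cfg$n_replications,
                        config = sc, parameter = cfg$parameter,
                        cond_a = cfg$cond_a, cond_b = cfg$cond_b,
                        encoding_group = cfg$encoding_group)
  write.csv(rep$replications, file.path(out, "replications.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(rep$summary, file.path(out, "report.csv"), row.names = FALSE,
            quote = FALSE)
  .write_run_meta(out, "recover", cfg)
  .run_log(out, "wrote replications.csv (", nrow(rep$replications),
           " rows), report.csv")
  invisible(list(replications = file.path(out, "replications.csv"),
                 report = file.path(out, "report.csv")))
}
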