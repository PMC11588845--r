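# Synthetic experiment generator: design presets for the four span-task
# experiments, generator truths for either measurement model, trial-level
# simulation honoring the reconstruction task's distinct-selection rule,
# and seeded parameter-recovery studies.

#' Design presets for the span-task experiments
#'
#' Returns the structure of one of the four experiments: encoding groups
#' with their final sample sizes, the time-by-distraction conditions, the
#' immediate test ending each trial, and trials per cell. Experiments 1
#' and 2 cross simple/complex/slow span (10 trials each) with
#' intentional (serial recall) vs. incidental (no recall) encoding
#' between subjects; Experiment 3 replaces complex span with a medium
#' uninterrupted interval; Experiment 4 crosses short/long time with the
#' immediate test within subjects (9 trials per cell), all under
#' intentional encoding.
#'
#' @param experiment `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`, or
#'   `"custom"` (then supply `subjects` and `cells`).
#' @param n_subjects optional named vector overriding the per-group
#'   subject counts, e.g. `c(intentional = 10)` drops groups not named.
#' @param n_trials optional scalar overriding trials per cell.
#' @param subjects,cells for `experiment = "custom"`: a data frame
#'   `subjects(encoding_group, n_subjects)` and a data frame
#'   `cells(encoding_group, time_condition, distraction, immediate_test,
#'   n_trials)`.
#' @return list of class `design_preset` with elements `experiment`,
#'   `subjects`, `cells`, and `conditions` (the condition labels used by
#'   [aggregate_counts()]).
#' @export
design_preset <- function(experiment = c("exp1", "exp2", "exp3", "exp4",
                                         "custom"),
                          n_subjects = NULL, n_trials = NULL,
                          subjects = NULL, cells = NULL) {
  experiment <- match.arg(experiment)
  tasks3 <- data.frame(
    time_condition = c("short", "long", "long"),
    distraction = c("none", "none", "arithmetic"),
    stringsAsFactors = FALSE)
  times3 <- data.frame(
    time_condition = c("short", "medium", "long"),
    distraction = "none", stringsAsFactors = FALSE)
  build <- function(subj, per_group_cells, trials) {
    cells <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
      cc <- per_group_cells[[subj$encoding_group[i]]]
      cc$encoding_group <- subj$encoding_group[i]
      cc$n_trials <- trials
      cc
    }))
    rownames(cells) <- NULL
    cells[, c("encoding_group", "time_condition", "distraction",
              "immediate_test", "n_trials")]
  }
  if (experiment %in% c("exp1", "exp2")) {
    subj <- data.frame(encoding_group = c("intentional", "incidental"),
                       n_subjects = if (experiment == "exp1") c(43L, 40L)
                                    else c(43L, 44L),
                       stringsAsFactors = FALSE)
    int_cells <- tasks3; int_cells$immediate_test <- "serial_recall"
    inc_cells <- tasks3; inc_cells$immediate_test <- "no_recall"
    cells <- build(subj, list(intentional = int_cells,
                              incidental = inc_cells), 10L)
  } else if (experiment == "exp3") {
    subj <- data.frame(encoding_group = c("intentional", "incidental"),
                       n_subjects = c(59L, 51L), stringsAsFactors = FALSE)
    int_cells <- times3; int_cells$immediate_test <- "serial_recall"
    inc_cells <- times3; inc_cells$immediate_test <- "no_recall"
    cells <- build(subj, list(intentional = int_cells,
                              incidental = inc_cells), 10L)
  } else if (experiment == "exp4") {
    subj <- data.frame(encoding_group = "intentional", n_subjects = 61L,
                       stringsAsFactors = FALSE)
    g <- expand.grid(time_condition = c("short", "long"),
                     immediate_test = c("serial_recall", "no_recall"),
                     stringsAsFactors = FALSE)
    g$distraction <- "none"
    cells <- build(subj, list(intentional = g), 9L)
  } else {
    if (is.null(subjects) || is.null(cells)) {
      stop("custom presets need `subjects` and `cells`", call. = FALSE)
    }
    subj <- subjects
    need <- c("encoding_group", "time_condition", "distraction",
              "immediate_test", "n_trials")
    missing_cols <- setdiff(need, names(cells))
    if (length(missing_cols)) {
      stop("custom cells are missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    cells <- cells[, need]
  }
  if (!is.null(n_subjects)) {
    subj <- subj[subj$encoding_group %in% names(n_subjects), , drop = FALSE]
    if (nrow(subj) == 0) stop("n_subjects names match no group", call. = FALSE)
    subj$n_subjects <- as.integer(n_subjects[subj$encoding_group])
    cells <- cells[cells$encoding_group %in% subj$encoding_group, ,
                   drop = FALSE]
  }
  if (!is.null(n_trials)) cells$n_trials <- as.integer(n_trials)
  task_label(cells$time_condition, cells$distraction)  # validates pairs
  structure(list(experiment = experiment, subjects = subj, cells = cells,
                 conditions = unique(condition_label(cells))),
            class = "design_preset")
}

#' Generator truth for a recovery simulation
#'
#' Fixes the data-generating parameters of one measurement model:
#' per-condition group-level values on the natural scale, between-subject
#' SDs on the latent scale (probit for the MPT, softplus for the MMM),
#' and the seed. Subject-level parameters are drawn as
#' `link_inverse(link(group value) + N(0, sd))`, so the group value is the
#' parameter of a typical (median) subject.
#'
#' @param model `"mpt"` or `"mmm"`.
#' @param conditions character vector of condition labels (normally
#'   `preset$conditions`).
#' @param pb,pi MPT group probabilities per condition (recycled).
#' @param a,c_bind MMM group activations per condition (recycled).
#' @param sd_binding,sd_item latent-scale between-subject SDs (>= 0) for
#'   the binding and item parameter respectively.
#' @param b fixed MMM baseline activation.
#' @param seed integer seed; fully determines [simulate_dataset()] output.
#' @return list of class `generator_truth` with a `group` data frame of
#'   per-condition true values.
#' @examples
#' pr <- design_preset("exp1")
#' generator_truth("mmm", pr$conditions, a = 0.3, c_bind = c(0.5, 0.5, 0.5))
#' @export
generator_truth <- function(model = c("mpt", "mmm"), conditions,
                            pb = 0.5, pi = 0.5, a = 0.3, c_bind = 0.5,
                            sd_binding = 0.5, sd_item = 0.5, b = 0.1,
                            seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(conditions) >= 1, sd_binding >= 0, sd_item >= 0, b > 0)
  n <- length(conditions)
  if (model == "mpt") {
    pb <- rep_len(pb, n); pi <- rep_len(pi, n)
    if (any(pb < 0 | pb > 1 | pi < 0 | pi > 1)) {
      stop("pb and pi must be in [0, 1]", call. = FALSE)
    }
    group <- data.frame(condition = conditions, Pb = pb, Pi = pi,
                        stringsAsFactors = FALSE)
  } else {
    a <- rep_len(a, n); c_bind <- rep_len(c_bind, n)
    if (any(a < 0 | c_bind < 0)) {
      stop("a and c_bind must be >= 0", call. = FALSE)
    }
    group <- data.frame(condition = conditions, A = a, C = c_bind,
                        stringsAsFactors = FALSE)
  }
  structure(list(model = model, conditions = conditions, group = group,
                 sd_binding = sd_binding, sd_item = sd_item, b = b,
                 seed = as.integer(seed)),
            class = "generator_truth")
}

.latent_binding <- function(truth) {
  if (truth$model == "mpt") qnorm(truth$group$Pb)
  else ifelse(truth$group$C == 0, -Inf, inv_softplus(truth$group$C))
}
.latent_item <- function(truth) {
  if (truth$model == "mpt") qnorm(truth$group$Pi)
  else ifelse(truth$group$A == 0, -Inf, inv_softplus(truth$group$A))
}
.natural <- function(truth, latent) {
  if (truth$model == "mpt") pnorm(latent) else softplus(latent)
}

.resample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Simulate a complete synthetic experiment
#'
#' Generates trial-level reconstruction data with the statistical
#' structure the measurement models assume. Per subject, latent parameters
#' are drawn from the hierarchy in `truth`; per trial, 4 target words and
#' 4 never-presented lures are sampled from a synthetic lexicon; per
#' output position, a response category is drawn independently from the
#' model's analytic probabilities, and categories are then mapped to
#' concrete tokens without replacement within class (Correct: the
#' position's target; Other: uniform over valid assignments of unused
#' other targets; New: uniform over unused lures), respecting the task's
#' distinct-selection rule. The one token-infeasible pattern (three
#' Corrects plus one Other, which exhausts the Other pick's class) is
#' resolved by resampling that position's category from the renormalized
#' remaining probabilities; the events are counted in
#' `n_category_resamples`.
#'
#' @param preset a [design_preset()].
#' @param truth a [generator_truth()] whose conditions cover
#'   `preset$conditions`.
#' @param seed integer seed (default `truth$seed`); the output is fully
#'   reproducible from it.
#' @param lexicon_size number of distinct word tokens available per
#'   subject.
#' @return list of class `sim_data`: `trials` (trial table in the
#'   [read_trials()] schema), `subject_truth` (sidecar table of true
#'   subject-level parameters per condition), `truth`, `preset`, `seed`,
#'   `n_category_resamples`.
#' @export
simulate_dataset <- function(preset, truth, seed = truth$seed,
                             lexicon_size = 360L) {
  if (!inherits(preset, "design_preset")) {
    stop("`preset` must come from design_preset()", call. = FALSE)
  }
  if (!inherits(truth, "generator_truth")) {
    stop("`truth` must come from generator_truth()", call. = FALSE)
  }
  missing_conds <- setdiff(preset$conditions, truth$conditions)
  if (length(missing_conds)) {
    stop("truth lacks condition(s): ",
         paste(missing_conds, collapse = ", "), call. = FALSE)
  }
  stopifnot(lexicon_size >= 8)
  set.seed(seed)
  lexicon <- sprintf("w%03d", seq_len(lexicon_size))
  mu_b <- setNames(.latent_binding(truth), truth$conditions)
  mu_i <- setNames(.latent_item(truth), truth$conditions)
  bind_name <- if (truth$model == "mpt") "Pb" else "C"
  item_name <- if (truth$model == "mpt") "Pi" else "A"

  trial_rows <- list()
  truth_rows <- list()
  n_resample <- 0L
  for (gi in seq_len(nrow(preset$subjects))) {
    grp <- preset$subjects$encoding_group[gi]
    cells <- preset$cells[preset$cells$encoding_group == grp, , drop = FALSE]
    cond_of_cell <- condition_label(preset$cells)[
      preset$cells$encoding_group == grp]
    for (si in seq_len(preset$subjects$n_subjects[gi])) {
      sid <- sprintf("%s_%s_%02d", preset$experiment, substr(grp, 1, 3), si)
      u_b <- rnorm(1, 0, truth$sd_binding)
      u_i <- rnorm(1, 0, truth$sd_item)
      subj_bind <- .natural(truth, mu_b + u_b)
      subj_item <- .natural(truth, mu_i + u_i)
      st <- data.frame(subject_id = sid, encoding_group = grp,
                       condition = truth$conditions,
                       stringsAsFactors = FALSE)
      st[[bind_name]] <- unname(subj_bind)
      st[[item_name]] <- unname(subj_item)
      truth_rows[[length(truth_rows) + 1L]] <- st
      trial_counter <- 0L
      for (ci in seq_len(nrow(cells))) {
        cond <- cond_of_cell[ci]
        probs <- if (truth$model == "mpt") {
          mpt_category_probs(subj_bind[cond], subj_item[cond])
        } else {
          mmm_category_probs(subj_item[cond], subj_bind[cond], b = truth$b)
        }
        probs <- as.numeric(probs[1, ])
        for (tr in seq_len(cells$n_trials[ci])) {
          trial_counter <- trial_counter + 1L
          toks <- sample(lexicon, 8L)
          targets <- toks[1:4]
          lures <- toks[5:8]
          cand <- sample(toks)  # display order
          # categories first (independent per position, full-set probs),
          # then tokens without replacement within class
          cats <- sample.int(3L, 4L, replace = TRUE, prob = probs)
          # the one token-infeasible pattern: three Corrects consume all
          # targets the remaining Other pick could use except its own
          if (sum(cats == 1L) == 3L && sum(cats == 2L) == 1L) {
            n_resample <- n_resample + 1L
            pos_o <- which(cats == 2L)
            p2 <- probs[c(1L, 3L)] / sum(probs[c(1L, 3L)])
            cats[pos_o] <- c(1L, 3L)[sample.int(2L, 1L, prob = p2)]
          }
          resp <- character(4)
          resp[cats == 1L] <- targets[cats == 1L]
          pos_o <- which(cats == 2L)
          if (length(pos_o)) {
            pool <- setdiff(targets, targets[cats == 1L])
            # uniform over injective assignments avoiding each position's
            # own target; one always exists after the resampling above
            repeat {
              pick <- if (length(pool) == 1L) pool else
                sample(pool, length(pos_o))
              if (!any(pick == targets[pos_o])) break
            }
            resp[pos_o] <- pick
          }
          pos_n <- which(cats == 3L)
          if (length(pos_n)) {
            resp[pos_n] <- if (length(pos_n) == 1L) .resample1(lures) else
              sample(lures, length(pos_n))
          }
          trial_rows[[length(trial_rows) + 1L]] <- data.frame(
            subject_id = sid, experiment = preset$experiment,
            encoding_group = grp,
            time_condition = cells$time_condition[ci],
            distraction = cells$distraction[ci],
            immediate_test = cells$immediate_test[ci],
            trial_index = trial_counter, output_position = 1:4,
            target_id = targets,
            candidate_ids = paste(cand, collapse = "|"),
            response_id = resp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  subject_truth <- do.call(rbind, truth_rows)
  rownames(subject_truth) <- NULL
  structure(list(trials = trials, subject_truth = subject_truth,
                 truth = truth, preset = preset, seed = as.integer(seed),
                 n_category_resamples = n_resample),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Synthetic span-task dataset (", x$preset$experiment, ")\n", sep = "")
  cat("  model:", x$truth$model, " seed:", x$seed, "\n")
  cat("  subjects:", length(unique(x$trials$subject_id)),
      " rows:", nrow(x$trials),
      " category resamples:", x$n_category_resamples, "\n")
  invisible(x)
}

#' Parameter-recovery study
#'
#' Repeatedly simulates a dataset from a known truth, fits the matching
#' hierarchical model, and summarizes the headline condition contrast:
#' bias and RMSE of the posterior mean, coverage of the true value by the
#' 95% CI, and sign agreement of the posterior mean with the true effect.
#'
#' @param preset a [design_preset()].
#' @param truth a [generator_truth()].
#' @param n_replications number of simulate-fit-contrast replications.
#' @param config a [sampler_config()]; replication `r` offsets both the
#'   generator seed (`truth$seed + r`) and the sampler seed.
#' @param parameter group-level parameter to contrast (default: the
#'   model's binding parameter, `"Pb"` or `"C"`).
#' @param cond_a,cond_b conditions contrasted (`A - B`); defaults to the
#'   last vs. first condition label of the preset.
#' @param encoding_group group whose data are fitted (default: the
#'   preset's first group).
#' @return list of class `recovery_report`: `replications` (one row per
#'   replication: estimate, CI, credible flag, number of flagged
#'   parameters) and `summary` (true value, mean estimate, bias, RMSE,
#'   coverage, sign agreement, credible rate).
#' @export
recovery_study <- function(preset, truth, n_replications = 10L,
                           config = sampler_config(),
                           parameter = NULL, cond_a = NULL, cond_b = NULL,
                           encoding_group = NULL) {
  stopifnot(n_replications >= 1)
  if (is.null(parameter)) parameter <- if (truth$model == "mpt") "Pb" else "C"
  conds <- preset$conditions
  if (is.null(cond_a)) cond_a <- conds[length(conds)]
  if (is.null(cond_b)) cond_b <- conds[1]
  if (is.null(encoding_group)) encoding_group <- preset$subjects$encoding_group[1]
  g <- truth$group
  true_value <- g[[parameter]][match(cond_a, g$condition)] -
    g[[parameter]][match(cond_b, g$condition)]
  rows <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    sim <- simulate_dataset(preset, truth, seed = truth$seed + r)
    trials <- sim$trials[sim$trials$encoding_group == encoding_group, ,
                         drop = FALSE]
    counts <- aggregate_counts(trials)
    cfg <- config
    cfg$seed <- config$seed + r * 100L
    fit <- suppressWarnings(
      if (truth$model == "mpt") fit_mpt(counts, cfg)
      else fit_mmm(counts, cfg, b = truth$b))
    ct <- contrast(fit, parameter, cond_a, cond_b)
    rows[[r]] <- data.frame(replication = r, estimate = ct$mean,
                            ci_low = ct$ci_low, ci_high = ct$ci_high,
                            credible = ct$credible,
                            n_flagged = length(fit$flagged),
                            stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  err <- reps$estimate - true_value
  summary <- data.frame(
    parameter = parameter, contrast = paste(cond_a, "-", cond_b),
    true_value = true_value,
    mean_estimate = mean(reps$estimate),
    bias = mean(err), rmse = sqrt(mean(err^2)),
    coverage = mean(reps$ci_low <= true_value & true_value <= reps$ci_high),
    sign_agreement = if (true_value == 0) NA_real_
                     else mean(sign(reps$estimate) == sign(true_value)),
    credible_rate = mean(reps$credible),
    n_replications = n_replications, stringsAsFactors = FALSE)
  structure(list(replications = reps, summary = summary,
                 truth = truth, preset = preset),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery study (", x$truth$model, ", ",
      x$summary$contrast, " on ", x$summary$parameter, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
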