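# Shared fixture builders. Everything is generated in code; no files.

# A single 4-position trial as a schema-conforming data frame.
make_trial <- function(subject_id = "s1", trial_index = 1L,
                       targets = c("t1", "t2", "t3", "t4"),
                       lures = c("l1", "l2", "l3", "l4"),
                       responses = targets,
                       time_condition = "short", distraction = "none",
                       immediate_test = "serial_recall",
                       encoding_group = "intentional",
                       experiment = "custom") {
  data.frame(subject_id = subject_id, experiment = experiment,
             encoding_group = encoding_group,
             time_condition = time_condition, distraction = distraction,
             immediate_test = immediate_test, trial_index = trial_index,
             output_position = 1:4, target_id = targets,
             candidate_ids = paste(c(targets, lures), collapse = "|"),
             response_id = responses, stringsAsFactors = FALSE)
}

# All-FALSE exclusion flags for a set of subjects.
make_flags <- function(subject_ids) {
  out <- data.frame(subject_id = subject_ids, stringsAsFactors = FALSE)
  for (f in c("quit_midway", "technical_issues", "nonconforming_encoding",
              "expected_final_test", "restarted", "cheated")) {
    out[[f]] <- FALSE
  }
  out
}

# Category counts simulated directly from a hierarchical truth: the data
# model the fitters assume, with no reconstruction-task constraints.
simulate_counts <- function(model, n_subjects, n_per_cell, group_values,
                            sd_latent = 0.5, b = 0.1, seed = 1L) {
  set.seed(seed)
  conds <- names(group_values$binding)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    u_b <- rnorm(1, 0, sd_latent)
    u_i <- rnorm(1, 0, sd_latent)
    for (cc in conds) {
      if (model == "mpt") {
        pb <- pnorm(qnorm(group_values$binding[[cc]]) + u_b)
        pi <- pnorm(qnorm(group_values$item[[cc]]) + u_i)
        p <- as.numeric(mpt_category_probs(pb, pi))
      } else {
        cb <- softplus(inv_softplus(group_values$binding[[cc]]) + u_b)
        aa <- softplus(inv_softplus(group_values$item[[cc]]) + u_i)
        p <- as.numeric(mmm_category_probs(aa, cb, b))
      }
      y <- rmultinom(1, n_per_cell, p)[, 1]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("s%02d", s), condition = cc,
        n_correct = y[1], n_other = y[2], n_new = y[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Short-chain sampler settings for tests.
quick_config <- function(seed = 1L, chains = 2L) {
  sampler_config(chains = chains, adapt = 300L, warmup = 300L,
                 draws = 400L, seed = seed)
}

# A synthetic draws table with specified per-(parameter, condition) values;
# values is a named list: name "param|condition" -> numeric vector that is
# split evenly over `chains`.
make_draws <- function(values, model = "mmm", chains = 2L,
                       level = "group") {
  rows <- list()
  for (nm in names(values)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    v <- values[[nm]]
    per <- length(v) / chains
    stopifnot(per == round(per))
    rows[[nm]] <- data.frame(
      chain = rep(seq_len(chains), each = per),
      draw = rep(seq_len(per), times = chains),
      model = model, parameter = parts[1], level = level,
      condition = if (length(parts) > 1) parts[2] else NA_character_,
      subject = NA_character_, value = v, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
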