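# Hierarchical Bayesian estimation of the two measurement models.
#
# Both models share the same hierarchy: per-condition group means on an
# unconstrained latent scale, subject-level normal deviations shared across
# conditions, and weakly informative priors (normal on group means,
# half-normal on group SDs). The MPT maps the latent scale to probabilities
# through a probit link; the MMM maps it to non-negative activations
# through a softplus. JAGS is used as the MCMC engine; the model
# likelihoods are defined here.

#' Sampler configuration
#'
#' @param chains number of MCMC chains (>= 2 for convergence diagnostics).
#' @param adapt adaptation iterations for JAGS.
#' @param warmup burn-in iterations discarded after adaptation.
#' @param draws retained posterior draws per chain.
#' @param seed integer seed; chain `k` uses `seed + k`.
#' @param rhat_threshold split-R-hat threshold above which a parameter is
#'   flagged as non-converged (default 1.01).
#' @param prior_mu_mean,prior_mu_sd normal prior on latent group means.
#' @param prior_sigma_sd scale of the half-normal prior on latent group
#'   SDs.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, adapt = 500L, warmup = 1000L,
                           draws = 1000L, seed = 1L, rhat_threshold = 1.01,
                           prior_mu_mean = 0, prior_mu_sd = 1,
                           prior_sigma_sd = 1) {
  stopifnot(chains >= 1, adapt >= 100, warmup >= 0, draws >= 1,
            prior_mu_sd > 0, prior_sigma_sd > 0)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold,
                 prior_mu_mean = prior_mu_mean, prior_mu_sd = prior_mu_sd,
                 prior_sigma_sd = prior_sigma_sd),
            class = "sampler_config")
}

.mpt_jags <- "
model {
  for (j in 1:nObs) {
    Pb[j] <- phi(muPb[cond[j]] + uPb[subj[j]])
    Pi[j] <- phi(muPi[cond[j]] + uPi[subj[j]])
    po[j] <- (1 - Pb[j]) * Pi[j] / 4 + (1 - Pb[j]) * (1 - Pi[j]) / 8
    pr[j,1] <- Pb[j] + po[j]
    pr[j,2] <- 3 * po[j]
    pr[j,3] <- (1 - Pb[j]) * (1 - Pi[j]) / 2
    # epsilon floor keeps every category probability positive even when an
    # extreme latent draw pushes phi() to exactly 0 or 1
    for (k in 1:3) { p[j,k] <- (1 - 3.0E-6) * pr[j,k] + 1.0E-6 }
    y[j,1:3] ~ dmulti(p[j,1:3], N[j])
  }
  for (s in 1:nSubj) {
    uPb[s] ~ dnorm(0, tauPb)
    uPi[s] ~ dnorm(0, tauPi)
  }
  for (c in 1:nCond) {
    muPb[c] ~ dnorm(muMean, muPrec)
    muPi[c] ~ dnorm(muMean, muPrec)
    groupPb[c] <- phi(muPb[c])
    groupPi[c] <- phi(muPi[c])
  }
  sigmaPb ~ dnorm(0, sigPrec) T(0,)
  sigmaPi ~ dnorm(0, sigPrec) T(0,)
  tauPb <- 1 / pow(sigmaPb, 2)
  tauPi <- 1 / pow(sigmaPi, 2)
}"

.mmm_jags <- "
model {
  for (j in 1:nObs) {
    A[j] <- log(1 + exp(muA[cond[j]] + uA[subj[j]]))
    C[j] <- log(1 + exp(muC[cond[j]] + uC[subj[j]]))
    D[j] <- 8 * B + 4 * A[j] + C[j]
    p[j,1] <- (B + A[j] + C[j]) / D[j]
    p[j,2] <- 3 * (B + A[j]) / D[j]
    p[j,3] <- 4 * B / D[j]
    y[j,1:3] ~ dmulti(p[j,1:3], N[j])
  }
  for (s in 1:nSubj) {
    uA[s] ~ dnorm(0, tauA)
    uC[s] ~ dnorm(0, tauC)
  }
  for (c in 1:nCond) {
    muA[c] ~ dnorm(muMean, muPrec)
    muC[c] ~ dnorm(muMean, muPrec)
    groupA[c] <- log(1 + exp(muA[c]))
    groupC[c] <- log(1 + exp(muC[c]))
  }
  sigmaA ~ dnorm(0, sigPrec) T(0,)
  sigmaC ~ dnorm(0, sigPrec) T(0,)
  tauA <- 1 / pow(sigmaA, 2)
  tauC <- 1 / pow(sigmaC, 2)
}"

.prepare_fit_data <- function(counts) {
  m <- .check_counts(counts)
  if (!all(c("subject_id", "condition") %in% names(counts))) {
    stop("counts need subject_id and condition columns", call. = FALSE)
  }
  subj_levels <- sort(unique(as.character(counts$subject_id)))
  cond_levels <- sort(unique(as.character(counts$condition)))
  if (length(subj_levels) < 2) {
    stop("hierarchical fitting requires at least 2 subjects", call. = FALSE)
  }
  key <- paste(counts$subject_id, counts$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("more than one counts row per subject x condition cell", call. = FALSE)
  }
  list(y = m,
       N = as.integer(rowSums(m)),
       cond = match(as.character(counts$condition), cond_levels),
       subj = match(as.character(counts$subject_id), subj_levels),
       subj_levels = subj_levels, cond_levels = cond_levels)
}

# Map a JAGS variable name to the canonical draws labelling.
.label_map <- list(
  mpt = list(groupPb = c("Pb", "group"),    groupPi = c("Pi", "group"),
             muPb    = c("mu_Pb", "hyper"), muPi    = c("mu_Pi", "hyper"),
             sigmaPb = c("sigma_Pb", "hyper"), sigmaPi = c("sigma_Pi", "hyper"),
             uPb     = c("u_Pb", "subject"), uPi    = c("u_Pi", "subject")),
  mmm = list(groupA = c("A", "group"),     groupC = c("C", "group"),
             muA    = c("mu_A", "hyper"),  muC    = c("mu_C", "hyper"),
             sigmaA = c("sigma_A", "hyper"), sigmaC = c("sigma_C", "hyper"),
             uA     = c("u_A", "subject"), uC     = c("u_C", "subject"))
)

.samples_to_draws <- function(samples, model, subj_levels, cond_levels) {
  lmap <- .label_map[[model]]
  out <- vector("list", length(samples))
  for (ch in seq_along(samples)) {
    mat <- as.matrix(samples[[ch]])
    vn <- colnames(mat)
    base <- sub("\\[.*$", "", vn)
    idx <- suppressWarnings(as.integer(sub("^.*\\[(\\d+)\\]$", "\\1", vn)))
    info <- lmap[base]
    param <- vapply(info, `[`, "", 1L)
    level <- vapply(info, `[`, "", 2L)
    condition <- ifelse(level %in% c("group", "hyper") & !is.na(idx),
                        cond_levels[idx], NA_character_)
    subject <- ifelse(level == "subject", subj_levels[idx], NA_character_)
    n_draw <- nrow(mat)
    out[[ch]] <- data.frame(
      chain = rep(ch, n_draw * ncol(mat)),
      draw = rep(seq_len(n_draw), times = ncol(mat)),
      model = model,
      parameter = rep(param, each = n_draw),
      level = rep(level, each = n_draw),
      condition = rep(condition, each = n_draw),
      subject = rep(subject, each = n_draw),
      value = as.vector(mat),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

.fit_jags <- function(model, counts, config, b = NULL) {
  if (!inherits(config, "sampler_config")) {
    stop("`config` must be created by sampler_config()", call. = FALSE)
  }
  prep <- .prepare_fit_data(counts)
  data <- list(y = prep$y, N = prep$N, cond = prep$cond, subj = prep$subj,
               nObs = nrow(prep$y), nSubj = length(prep$subj_levels),
               nCond = length(prep$cond_levels),
               muMean = config$prior_mu_mean,
               muPrec = 1 / config$prior_mu_sd^2,
               sigPrec = 1 / config$prior_sigma_sd^2)
  if (model == "mmm") data$B <- b
  code <- if (model == "mpt") .mpt_jags else .mmm_jags
  monitors <- names(.label_map[[model]])
  inits <- lapply(seq_len(config$chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + k)
  })
  jm <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                          n.chains = config$chains, n.adapt = config$adapt,
                          quiet = TRUE)
  if (config$warmup > 0) update(jm, config$warmup, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitors, n.iter = config$draws,
                                 progress.bar = "none")
  draws <- .samples_to_draws(samples, model, prep$subj_levels, prep$cond_levels)
  diag <- diagnostics(draws, rhat_threshold = config$rhat_threshold)
  fit <- structure(list(model = model, draws = draws,
                        diagnostics = diag$table, flagged = diag$flagged,
                        conditions = prep$cond_levels,
                        subjects = prep$subj_levels,
                        config = config, b = b, counts = counts),
                   class = "memfit")
  if (length(diag$flagged)) {
    warning("possible non-convergence (split R-hat > ",
            config$rhat_threshold, ") for: ",
            paste(diag$flagged, collapse = ", "), call. = FALSE)
  }
  fit
}

#' Fit the hierarchical MPT model
#'
#' Estimates binding memory (`Pb`) and item memory (`Pi`) per condition
#' from per-subject category counts with a hierarchical Bayesian
#' multinomial processing tree. Latent scale: probit; per-condition group
#' means with subject deviations shared across conditions; normal priors
#' on group means and half-normal priors on group SDs. Group-level
#' probabilities (`Pb`, `Pi` at the group mean) are monitored on the
#' natural scale, along with latent means, SDs and subject effects.
#'
#' @param counts data frame from [aggregate_counts()]: one row per subject
#'   x condition with `n_correct`, `n_other`, `n_new`. At least 2 subjects.
#' @param config a [sampler_config()].
#' @return object of class `memfit` with elements `draws` (long-format
#'   posterior draws: chain, draw, model, parameter, level, condition,
#'   subject, value), `diagnostics` (split-R-hat and bulk effective sample
#'   size per parameter), `flagged` (parameters exceeding the R-hat
#'   threshold; also raised as a warning), `conditions`, `subjects`,
#'   `config`. Seeded runs are reproducible.
#' @seealso [fit_mmm()], [contrast()], [summarize_draws()]
#' @export
fit_mpt <- function(counts, config = sampler_config()) {
  .fit_jags("mpt", counts, config)
}

#' Fit the hierarchical memory measurement model
#'
#' Estimates item activation (`A`) and context/binding activation (`C`)
#' per condition with the continuous activation model. The baseline
#' activation `b` is fixed (default 0.1) to anchor the scale, since Luce
#' choice probabilities are invariant to common scaling of activations.
#' `A` and `C` are kept non-negative by a softplus transform of latent
#' normal hierarchies, so the truncation of `C` at zero holds in the prior
#' and the posterior. Group-level activations reported on the natural
#' scale are `softplus(mu)`, the activation of a typical subject.
#'
#' @inheritParams fit_mpt
#' @param b fixed baseline activation (> 0).
#' @return object of class `memfit`; see [fit_mpt()].
#' @export
fit_mmm <- function(counts, config = sampler_config(), b = 0.1) {
  stopifnot(is.numeric(b), length(b) == 1, b > 0)
  .fit_jags("mmm", counts, config, b = b)
}

#' @export
print.memfit <- function(x, ...) {
  cat("Hierarchical", toupper(x$model), "fit\n")
  cat("  subjects:", length(x$subjects),
      " conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  chains:", x$config$chains, " draws/chain:", x$config$draws, "\n")
  if (length(x$flagged)) {
    cat("  NOT CONVERGED (R-hat >", x$config$rhat_threshold, "):",
        paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("  all split R-hat <=", x$config$rhat_threshold, "\n")
  }
  s <- summarize_draws(x, level = "group")
  print(s, row.names = FALSE)
  invisible(x)
}
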