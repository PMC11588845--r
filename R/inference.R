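# Posterior summaries, condition contrasts, posterior-predictive
# simulation and convergence diagnostics on long-format draws tables.
#
# Reported intervals are 95% equal-tailed credibility intervals computed
# with type-7 quantiles; an effect is "credible" exactly when its interval
# excludes zero. Both conventions are recorded in output attributes.

.draws_of <- function(x) {
  if (inherits(x, "memfit")) return(x$draws)
  if (is.data.frame(x)) return(x)
  stop("expected a memfit object or a draws data frame", call. = FALSE)
}

.param_key <- function(draws) {
  suffix <- ifelse(!is.na(draws$condition), paste0("[", draws$condition, "]"),
            ifelse(!is.na(draws$subject), paste0("[", draws$subject, "]"), ""))
  paste0(draws$parameter, suffix)
}

#' Validate a long-format draws table
#'
#' Checks the draws invariants: required columns, equal numbers of draws
#' per chain, and every parameter present in every chain.
#'
#' @param draws long-format draws data frame (see [fit_mpt()]).
#' @return the draws table, invisibly.
#' @export
validate_draws <- function(draws) {
  draws <- .draws_of(draws)
  need <- c("chain", "draw", "model", "parameter", "level", "condition",
            "subject", "value")
  missing_cols <- setdiff(need, names(draws))
  if (length(missing_cols)) {
    stop("draws table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(draws) == 0) stop("draws table is empty", call. = FALSE)
  key <- .param_key(draws)
  chains <- sort(unique(draws$chain))
  per <- table(key, draws$chain)
  if (any(per == 0)) {
    bad <- rownames(per)[which(rowSums(per == 0) > 0)[1]]
    stop("parameter '", bad, "' is missing from at least one chain",
         call. = FALSE)
  }
  if (length(unique(as.vector(per))) != 1) {
    stop("unequal draw counts across chains/parameters", call. = FALSE)
  }
  invisible(draws)
}

.select_draws <- function(draws, parameter = NULL, level = NULL,
                          condition = NULL, subject = NULL) {
  keep <- rep(TRUE, nrow(draws))
  if (!is.null(parameter)) keep <- keep & draws$parameter %in% parameter
  if (!is.null(level)) keep <- keep & draws$level %in% level
  if (!is.null(condition)) keep <- keep & draws$condition %in% condition
  if (!is.null(subject)) keep <- keep & draws$subject %in% subject
  if (!any(keep)) {
    sel <- paste(c(if (!is.null(parameter)) paste0("parameter=", paste(parameter, collapse = "/")),
                   if (!is.null(level)) paste0("level=", paste(level, collapse = "/")),
                   if (!is.null(condition)) paste0("condition=", paste(condition, collapse = "/")),
                   if (!is.null(subject)) paste0("subject=", paste(subject, collapse = "/"))),
                 collapse = ", ")
    stop("no draws match selector (", sel, ")", call. = FALSE)
  }
  draws[keep, , drop = FALSE]
}

#' Summarize posterior draws
#'
#' Posterior mean and 95% equal-tailed credibility interval (2.5% and
#' 97.5% type-7 quantiles) per selected parameter. Deterministic given the
#' draws.
#'
#' @param x a `memfit` object or a long-format draws data frame.
#' @param parameter,level,condition,subject optional selectors; `NULL`
#'   keeps everything at that slot. Group-level natural-scale parameters
#'   are `Pb`/`Pi` (MPT) and `A`/`C` (MMM).
#' @return data frame with one row per parameter label and columns
#'   `model`, `parameter`, `level`, `condition`, `subject`, `mean`,
#'   `ci_low`, `ci_high`. Attributes `ci_type` and `quantile_type` record
#'   the interval conventions.
#' @export
summarize_draws <- function(x, parameter = NULL, level = NULL,
                            condition = NULL, subject = NULL) {
  draws <- validate_draws(.draws_of(x))
  sel <- .select_draws(draws, parameter, level, condition, subject)
  key <- .param_key(sel)
  idx <- split(seq_len(nrow(sel)), key)
  rows <- lapply(idx, function(k) {
    v <- sel$value[k]
    q <- quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(model = sel$model[k[1]], parameter = sel$parameter[k[1]],
               level = sel$level[k[1]], condition = sel$condition[k[1]],
               subject = sel$subject[k[1]], mean = mean(v),
               ci_low = q[1], ci_high = q[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ci_type") <- "95% equal-tailed quantile interval"
  attr(out, "quantile_type") <- 7L
  out
}

#' Posterior condition contrast
#'
#' Computes the draw-wise difference `cond_a - cond_b` of a group-level
#' parameter and summarizes it with mean and 95% equal-tailed CI. The
#' effect is flagged `credible` exactly when the interval excludes zero.
#' By convention the later/longer condition is `cond_a` (e.g. slow minus
#' simple), so positive contrasts are advantages of more time.
#'
#' @param x a `memfit` object or draws data frame.
#' @param parameter group-level parameter name (`"Pb"`, `"Pi"`, `"A"`,
#'   `"C"`).
#' @param cond_a,cond_b condition labels; the contrast is `A - B`.
#' @return one-row data frame: `model`, `parameter`, `contrast`, `mean`,
#'   `ci_low`, `ci_high`, `credible`.
#' @examples
#' \dontrun{
#' contrast(fit, "C", "slow", "simple")
#' }
#' @export
contrast <- function(x, parameter, cond_a, cond_b) {
  draws <- validate_draws(.draws_of(x))
  conds <- unique(draws$condition[!is.na(draws$condition)])
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% conds) {
      stop("unknown condition '", cc, "'; available: ",
           paste(sort(conds), collapse = ", "), call. = FALSE)
    }
  }
  a <- .select_draws(draws, parameter = parameter, level = "group",
                     condition = cond_a)
  b <- .select_draws(draws, parameter = parameter, level = "group",
                     condition = cond_b)
  a <- a[order(a$chain, a$draw), ]
  b <- b[order(b$chain, b$draw), ]
  if (nrow(a) != nrow(b)) stop("misaligned draws for the two conditions",
                               call. = FALSE)
  d <- a$value - b$value
  q <- quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
  out <- data.frame(model = a$model[1], parameter = parameter,
                    contrast = paste(cond_a, "-", cond_b),
                    mean = mean(d), ci_low = q[1], ci_high = q[2],
                    credible = q[1] > 0 | q[2] < 0,
                    stringsAsFactors = FALSE)
  attr(out, "ci_type") <- "95% equal-tailed quantile interval"
  attr(out, "quantile_type") <- 7L
  out
}

#' Posterior-predictive category counts
#'
#' Simulates response-category counts from the joint posterior of the
#' fitted hierarchy: for each retained draw, each subject's parameters are
#' reconstructed from the group means and that subject's deviation, mapped
#' to category probabilities, and used to draw multinomial counts for the
#' requested number of trials. Frequencies are then averaged over draws.
#'
#' @param fit a `memfit` object.
#' @param design data frame with columns `condition` and `n_trials` (one
#'   row per condition cell; every condition must be in the fit).
#' @param n_draws number of posterior draws used (subsampled evenly).
#' @param seed integer seed for the predictive simulation.
#' @return data frame with one row per subject x condition x category:
#'   `subject_id`, `condition`, `category`, `predicted` (mean predicted
#'   proportion over draws), `n_trials`. Empty design gives an empty
#'   frame.
#' @export
posterior_predict <- function(fit, design, n_draws = 200L, seed = 1L) {
  if (!inherits(fit, "memfit")) stop("`fit` must be a memfit object",
                                     call. = FALSE)
  out_empty <- data.frame(subject_id = character(0), condition = character(0),
                          category = character(0), predicted = numeric(0),
                          n_trials = integer(0), stringsAsFactors = FALSE)
  if (!is.data.frame(design) ||
      !all(c("condition", "n_trials") %in% names(design))) {
    stop("`design` needs condition and n_trials columns", call. = FALSE)
  }
  if (nrow(design) == 0) return(out_empty)
  bad <- setdiff(as.character(design$condition), fit$conditions)
  if (length(bad)) {
    stop("design condition(s) not in the fit: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  draws <- fit$draws
  hyper <- if (fit$model == "mpt") c("mu_Pb", "mu_Pi") else c("mu_A", "mu_C")
  subj_par <- if (fit$model == "mpt") c("u_Pb", "u_Pi") else c("u_A", "u_C")
  # wide matrices: rows = (chain, draw), cols = condition or subject
  wide <- function(par, by, levels) {
    d <- .select_draws(draws, parameter = par)
    d <- d[order(d$chain, d$draw), ]
    m <- matrix(NA_real_, nrow = sum(d[[by]] == levels[1]),
                ncol = length(levels), dimnames = list(NULL, levels))
    for (lv in levels) m[, lv] <- d$value[d[[by]] == lv]
    m
  }
  mu1 <- wide(hyper[1], "condition", fit$conditions)
  mu2 <- wide(hyper[2], "condition", fit$conditions)
  u1 <- wide(subj_par[1], "subject", fit$subjects)
  u2 <- wide(subj_par[2], "subject", fit$subjects)
  total <- nrow(mu1)
  pick <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(design))) {
    cc <- as.character(design$condition[i])
    n_resp <- 4L * as.integer(design$n_trials[i])
    for (s in fit$subjects) {
      acc <- c(Correct = 0, Other = 0, New = 0)
      for (d in pick) {
        if (fit$model == "mpt") {
          p <- mpt_category_probs(pnorm(mu1[d, cc] + u1[d, s]),
                                  pnorm(mu2[d, cc] + u2[d, s]))
        } else {
          p <- mmm_category_probs(softplus(mu1[d, cc] + u1[d, s]),
                                  softplus(mu2[d, cc] + u2[d, s]),
                                  b = fit$b)
        }
        acc <- acc + rmultinom(1, n_resp, as.numeric(p))[, 1] / n_resp
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, condition = cc, category = .category_levels,
        predicted = as.numeric(acc) / length(pick),
        n_trials = as.integer(design$n_trials[i]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- convergence diagnostics -------------------------------------------

#' Split R-hat of a draws matrix
#'
#' Potential scale reduction factor computed on split chains: each chain
#' is halved, and the classic between/within variance ratio is applied to
#' the resulting `2m` sequences, so within-chain trends inflate the
#' statistic.
#'
#' @param mat numeric matrix, iterations x chains.
#' @return scalar split R-hat (1 for well-mixed stationary chains).
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  half <- floor(n / 2)
  sp <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[(n - half + 1):n, j])
  }))
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) return(if (B == 0 || is.na(B)) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Bulk effective sample size of a draws matrix
#'
#' Multi-chain effective sample size computed from split chains: chain
#' autocovariances are combined with the between-chain variance, and the
#' autocorrelation sum is truncated by Geyer's initial monotone positive
#' sequence.
#'
#' @param mat numeric matrix, iterations x chains.
#' @return scalar effective sample size (close to the total number of
#'   draws for independent samples).
#' @export
ess_bulk <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  half <- floor(n / 2)
  sp <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[(n - half + 1):n, j])
  }))
  m <- ncol(sp); nn <- nrow(sp)
  total <- m * nn
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- nn * var(colMeans(sp))
  var_plus <- (nn - 1) / nn * W + B / nn
  if (!is.finite(var_plus) || var_plus == 0) return(total)
  max_lag <- nn - 1
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(sp[, j], lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus   # rho[1] is lag 0
  # Geyer initial monotone positive sequence over paired autocorrelations
  max_pairs <- floor((length(rho) - 1) / 2)
  pair_sums <- numeric(0)
  for (k in seq_len(max_pairs)) {
    s <- rho[2 * k] + rho[2 * k + 1]
    if (s < 0) break
    pair_sums <- c(pair_sums, s)
  }
  if (length(pair_sums)) pair_sums <- cummin(pair_sums)
  tau <- -1 + 2 * sum(c(rho[1], pair_sums))
  total / max(tau, 1 / total)
}

#' Convergence diagnostics for posterior draws
#'
#' Split R-hat and bulk effective sample size per parameter, plus the
#' list of parameters exceeding the R-hat threshold. Requires at least two
#' chains.
#'
#' @param x a `memfit` object or long-format draws data frame.
#' @param rhat_threshold flagging threshold (default 1.01).
#' @return list with `table` (data frame: parameter label, `rhat`, `ess`)
#'   and `flagged` (character vector of parameter labels with
#'   `rhat > rhat_threshold`).
#' @export
diagnostics <- function(x, rhat_threshold = 1.01) {
  draws <- validate_draws(.draws_of(x))
  chains <- sort(unique(draws$chain))
  if (length(chains) < 2) {
    stop("convergence diagnostics require at least 2 chains", call. = FALSE)
  }
  key <- .param_key(draws)
  labels <- unique(key)
  rows <- lapply(labels, function(lb) {
    d <- draws[key == lb, ]
    mat <- do.call(cbind, lapply(chains, function(ch) {
      d$value[d$chain == ch][order(d$draw[d$chain == ch])]
    }))
    data.frame(parameter = lb, rhat = split_rhat(mat), ess = ess_bulk(mat),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       flagged = tab$parameter[is.finite(tab$rhat) &
                                 tab$rhat > rhat_threshold |
                                 is.infinite(tab$rhat)])
}
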