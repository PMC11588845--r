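# Analytic cores of the two measurement models for set size 4 with a
# response set of 8 (4 targets + 4 lures): response-category probabilities,
# multinomial log-likelihoods, and plain Monte-Carlo simulators of the
# discrete branch process and the activation-based choice process.

#' MPT response-category probabilities
#'
#' Discrete-state multinomial processing tree for one output position.
#' With probability `pb` the item-position binding is intact and the
#' correct target is selected. Otherwise, with probability `pi` item
#' memory supports a guess among the four presented words (each 1/4), and
#' failing that the selection is a uniform guess over all eight options
#' (each 1/8). `pOther` aggregates the three other presented words and
#' `pNew` the four lures.
#'
#' @param pb binding-memory probability in \[0, 1\] (recycled).
#' @param pi item-memory probability in \[0, 1\] (recycled).
#' @return data frame with columns `pCorrect`, `pOther`, `pNew`; the rows
#'   sum to 1 exactly.
#' @examples
#' mpt_category_probs(0.4, 0.6)   # 0.52, 0.36, 0.12
#' mpt_category_probs(0, 0)       # pure guessing: 1/8, 3/8, 4/8
#' @export
mpt_category_probs <- function(pb, pi) {
  if (!is.numeric(pb) || !is.numeric(pi) || anyNA(pb) || anyNA(pi) ||
      any(pb < 0 | pb > 1) || any(pi < 0 | pi > 1)) {
    stop("pb and pi must be probabilities in [0, 1]", call. = FALSE)
  }
  n <- max(length(pb), length(pi))
  pb <- rep_len(pb, n); pi <- rep_len(pi, n)
  per_other <- (1 - pb) * pi / 4 + (1 - pb) * (1 - pi) / 8
  data.frame(pCorrect = pb + per_other,
             pOther   = 3 * per_other,
             pNew     = 4 * (1 - pb) * (1 - pi) / 8)
}

#' MMM response-category probabilities
#'
#' Continuous activation model (Luce choice rule) for one output position.
#' All eight options carry a baseline activation `b`; the four presented
#' words carry additional item activation `a`; the position's own target
#' carries additional context (binding) activation `c`. A selection
#' follows normalized activations, so with denominator
#' `D = 8 b + 4 a + c`: `pCorrect = (b + a + c) / D`,
#' `pOther = 3 (b + a) / D`, `pNew = 4 b / D`. Probabilities are invariant
#' to scaling all three activations by a common positive factor.
#'
#' @param a item activation, `>= 0` (recycled).
#' @param c_bind context/binding activation, `>= 0` (truncated at zero by
#'   construction; recycled).
#' @param b baseline activation, `> 0`; fixed to 0.1 by default to anchor
#'   the activation scale.
#' @return data frame with columns `pCorrect`, `pOther`, `pNew`.
#' @examples
#' mmm_category_probs(0.3, 0.5)   # 0.36, 0.48, 0.16
#' mmm_category_probs(0, 0)       # all options equal: 1/8, 3/8, 4/8
#' @export
mmm_category_probs <- function(a, c_bind, b = 0.1) {
  if (!is.numeric(a) || !is.numeric(c_bind) || !is.numeric(b) ||
      anyNA(a) || anyNA(c_bind) || anyNA(b) ||
      any(a < 0) || any(c_bind < 0) || any(b <= 0)) {
    stop("require a >= 0, c_bind >= 0 and b > 0", call. = FALSE)
  }
  n <- max(length(a), length(c_bind), length(b))
  a <- rep_len(a, n); c_bind <- rep_len(c_bind, n); b <- rep_len(b, n)
  d <- 8 * b + 4 * a + c_bind
  data.frame(pCorrect = (b + a + c_bind) / d,
             pOther   = 3 * (b + a) / d,
             pNew     = 4 * b / d)
}

.check_counts <- function(counts) {
  need <- c("n_correct", "n_other", "n_new")
  if (is.data.frame(counts)) {
    missing_cols <- setdiff(need, names(counts))
    if (length(missing_cols)) {
      stop("counts are missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(counts[, need])
  } else {
    m <- matrix(as.numeric(counts), ncol = 3)
    colnames(m) <- need
  }
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m
}

.multinom_loglik <- function(m, p) {
  # Sum of multinomial log-pmfs; -Inf (not an error) when a zero-probability
  # category has a nonzero count.
  tot <- 0
  for (i in seq_len(nrow(m))) {
    pi_row <- as.numeric(p[i, ])
    yi <- m[i, ]
    if (any(pi_row == 0 & yi > 0)) return(-Inf)
    tot <- tot + dmultinom(yi, prob = pi_row, log = TRUE)
  }
  tot
}

#' MPT multinomial log-likelihood
#'
#' Log-probability of observed `(n_correct, n_other, n_new)` category
#' counts under the MPT category probabilities.
#'
#' @param counts data frame with columns `n_correct`, `n_other`, `n_new`
#'   (one or more rows), or a length-3 vector.
#' @param pb,pi scalar MPT parameters.
#' @return scalar log-likelihood; `-Inf` when a zero-probability category
#'   has a nonzero count.
#' @export
mpt_loglik <- function(counts, pb, pi) {
  stopifnot(length(pb) == 1, length(pi) == 1)
  m <- .check_counts(counts)
  p <- mpt_category_probs(rep(pb, nrow(m)), rep(pi, nrow(m)))
  .multinom_loglik(m, p)
}

#' MMM multinomial log-likelihood
#'
#' @inheritParams mpt_loglik
#' @param a,c_bind,b scalar MMM activations (see [mmm_category_probs()]).
#' @return scalar log-likelihood.
#' @export
mmm_loglik <- function(counts, a, c_bind, b = 0.1) {
  stopifnot(length(a) == 1, length(c_bind) == 1, length(b) == 1)
  m <- .check_counts(counts)
  p <- mmm_category_probs(rep(a, nrow(m)), rep(c_bind, nrow(m)), b)
  .multinom_loglik(m, p)
}

#' Simulate the MPT branch process
#'
#' Draws response categories by simulating the tree literally: a binding
#' coin with probability `pb`, then an item-memory coin with probability
#' `pi`, then uniform guessing among 4 presented words or all 8 options.
#' Used to cross-check [mpt_category_probs()] by Monte Carlo.
#'
#' @param n number of simulated selections.
#' @param pb,pi scalar MPT parameters.
#' @param seed integer seed.
#' @return factor of categories with levels `Correct`, `Other`, `New`.
#' @export
simulate_mpt_branches <- function(n, pb, pi, seed = 1L) {
  mpt_category_probs(pb, pi)  # validates
  set.seed(seed)
  bound <- runif(n) < pb
  item <- runif(n) < pi
  # uniform guess among 4 targets (index 1 = position's target) or 8 options
  guess4 <- sample.int(4L, n, replace = TRUE)
  guess8 <- sample.int(8L, n, replace = TRUE)
  out <- ifelse(bound, "Correct",
         ifelse(item, ifelse(guess4 == 1L, "Correct", "Other"),
                ifelse(guess8 == 1L, "Correct",
                       ifelse(guess8 <= 4L, "Other", "New"))))
  factor(out, levels = .category_levels)
}

#' Simulate the MMM choice process
#'
#' Draws response categories by sampling one of the eight options with
#' probability proportional to its activation (baseline `b` everywhere,
#' `+ a` for the four presented words, `+ c_bind` for the position's own
#' target). Used to cross-check [mmm_category_probs()] by Monte Carlo.
#'
#' @param n number of simulated selections.
#' @param a,c_bind,b scalar MMM activations.
#' @param seed integer seed.
#' @return factor of categories with levels `Correct`, `Other`, `New`.
#' @export
simulate_mmm_choices <- function(n, a, c_bind, b = 0.1, seed = 1L) {
  mmm_category_probs(a, c_bind, b)  # validates
  set.seed(seed)
  act <- c(b + a + c_bind, rep(b + a, 3), rep(b, 4))
  pick <- sample.int(8L, n, replace = TRUE, prob = act)
  out <- ifelse(pick == 1L, "Correct", ifelse(pick <= 4L, "Other", "New"))
  factor(out, levels = .category_levels)
}

# Latent-scale transforms shared by the generator and the samplers --------

#' Softplus and its inverse
#'
#' `softplus(x) = log(1 + exp(x))` maps the latent real line to the
#' positive activations of the MMM; `inv_softplus` is its inverse on
#' positive values. The hierarchical MMM places normal distributions on
#' the latent scale, which keeps `A` and `C` non-negative in the prior and
#' posterior (the truncation at zero holds by construction).
#'
#' @param x real vector (latent scale).
#' @return transformed vector.
#' @export
softplus <- function(x) {
  # numerically stable: log1p(exp(x)) for x <= 0, x + log1p(exp(-x)) above
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

#' @rdname softplus
#' @param y positive vector (activation scale).
#' @export
inv_softplus <- function(y) {
  if (any(y <= 0)) stop("inv_softplus requires positive input", call. = FALSE)
  ifelse(y > 30, y, log(expm1(y)))
}
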