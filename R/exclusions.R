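# Participant-level exclusion filtering in the style of preregistered
# screening: a subject is retained iff every exclusion flag is FALSE.

#' Apply participant exclusion flags
#'
#' Filters a trial (or counts) table to the subjects whose exclusion flags
#' are all `FALSE`, and reports how many subjects each flag removed. The
#' flags mirror the usual preregistered reasons: quitting midway, technical
#' issues, not conforming to the encoding-group assignment, expecting the
#' final memory test, restarting the experiment, and reported cheating.
#'
#' @param data data frame with a `subject_id` column (trial records,
#'   scores, or category counts).
#' @param flags data frame with `subject_id` and logical columns
#'   `quit_midway`, `technical_issues`, `nonconforming_encoding`,
#'   `expected_final_test`, `restarted`, `cheated`. Every subject in
#'   `data` must be present.
#' @return list with elements `data` (retained rows of `data`),
#'   `retained` (character vector of retained subject ids), and `report`
#'   (data frame, one row per flag with the count of flagged subjects,
#'   plus `any_flag` and `retained` summary rows).
#' @examples
#' flags <- data.frame(subject_id = c("s1", "s2"),
#'                     quit_midway = c(FALSE, TRUE),
#'                     technical_issues = FALSE,
#'                     nonconforming_encoding = FALSE,
#'                     expected_final_test = FALSE,
#'                     restarted = FALSE, cheated = FALSE)
#' dat <- data.frame(subject_id = c("s1", "s1", "s2"), x = 1:3)
#' apply_exclusions(dat, flags)$retained
#' @export
apply_exclusions <- function(data, flags) {
  if (!is.data.frame(data) || !"subject_id" %in% names(data)) {
    stop("`data` must be a data frame with a subject_id column", call. = FALSE)
  }
  missing_cols <- setdiff(c("subject_id", .flag_names), names(flags))
  if (length(missing_cols)) {
    stop("flag table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  flags$subject_id <- as.character(flags$subject_id)
  if (anyDuplicated(flags$subject_id)) {
    stop("duplicated subject_id in flag table: ",
         flags$subject_id[anyDuplicated(flags$subject_id)], call. = FALSE)
  }
  subjects <- unique(as.character(data$subject_id))
  unknown <- setdiff(subjects, flags$subject_id)
  if (length(unknown)) {
    stop("no exclusion flags for subject(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (f in .flag_names) {
    flags[[f]] <- as.logical(flags[[f]])
    if (anyNA(flags[[f]])) stop("flag '", f, "' contains NA", call. = FALSE)
  }
  fl <- flags[flags$subject_id %in% subjects, , drop = FALSE]
  flag_mat <- as.matrix(fl[, .flag_names])
  excluded <- rowSums(flag_mat) > 0
  retained <- fl$subject_id[!excluded]
  report <- data.frame(
    reason = c(.flag_names, "any_flag", "retained"),
    n = c(colSums(flag_mat), sum(excluded), sum(!excluded)),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(data = data[as.character(data$subject_id) %in% retained, , drop = FALSE],
       retained = retained,
       report = report)
}

#' Simulate participant exclusion flags
#'
#' Draws independent Bernoulli exclusion flags per subject, e.g. to emulate
#' the screening arithmetic of a recruitment pipeline.
#'
#' @param n_subjects number of subjects.
#' @param rates named numeric vector or list of per-flag probabilities in
#'   \[0, 1\]; unnamed flags default to 0. Valid names are the six flag
#'   columns of [apply_exclusions()].
#' @param seed integer seed; the output is fully determined by it.
#' @param subject_ids optional character vector of ids (default
#'   `"s1".."sN"`).
#' @return data frame of subject ids and logical flag columns.
#' @export
simulate_exclusion_flags <- function(n_subjects, rates = list(), seed = 1L,
                                     subject_ids = NULL) {
  stopifnot(n_subjects >= 0)
  rates <- as.list(rates)
  unknown <- setdiff(names(rates), .flag_names)
  if (length(unknown)) {
    stop("unknown flag name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- setNames(rep(0, length(.flag_names)), .flag_names)
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1) {
      stop("rate for '", nm, "' must be a probability in [0, 1]", call. = FALSE)
    }
    full[nm] <- r
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("s%d", seq_len(n_subjects))
  stopifnot(length(subject_ids) == n_subjects)
  set.seed(seed)
  out <- data.frame(subject_id = as.character(subject_ids),
                    stringsAsFactors = FALSE)
  for (nm in .flag_names) {
    out[[nm]] <- as.logical(rbinom(n_subjects, 1L, full[nm]))
  }
  out
}
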