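# Trial-level data: schema, validation, delimited I/O, categorization,
# free/serial scoring, and aggregation to the models' sufficient statistic.

.trial_columns <- c("subject_id", "experiment", "encoding_group",
                    "time_condition", "distraction", "immediate_test",
                    "trial_index", "output_position", "target_id",
                    "candidate_ids", "response_id")

.split_candidates <- function(x) strsplit(as.character(x), "|", fixed = TRUE)

#' Validate a trial table
#'
#' Checks a data frame of output-position observations against the trial
#' schema: one row per output position, eight pipe-joined candidate tokens
#' per row (the four presented targets plus four never-presented lures),
#' the position's target among the candidates, four distinct targets per
#' trial, and distinct responses within a trial (selection without
#' replacement).
#'
#' @param trials data frame with columns `subject_id`, `experiment`,
#'   `encoding_group`, `time_condition`, `distraction`, `immediate_test`,
#'   `trial_index`, `output_position`, `target_id`, `candidate_ids`
#'   (pipe-joined, 8 tokens), `response_id` (may be `NA` for a missing
#'   response).
#' @return the validated data frame, invisibly, with `trial_index` and
#'   `output_position` coerced to integer.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("`trials` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0) return(invisible(trials))
  trials$trial_index <- as.integer(trials$trial_index)
  trials$output_position <- as.integer(trials$output_position)

  check_enum <- function(col, levels) {
    bad <- !(as.character(trials[[col]]) %in% levels)
    if (any(bad)) {
      stop(sprintf("invalid value '%s' in column '%s' at row %d",
                   as.character(trials[[col]])[which(bad)[1]], col,
                   which(bad)[1]), call. = FALSE)
    }
  }
  check_enum("experiment", .experiment_levels)
  check_enum("encoding_group", .group_levels)
  check_enum("time_condition", .time_levels)
  check_enum("distraction", .distraction_levels)
  check_enum("immediate_test", .test_levels)
  task_label(trials$time_condition, trials$distraction)

  if (any(is.na(trials$trial_index) | trials$trial_index < 1L)) {
    stop("trial_index must be a positive integer (row ",
         which(is.na(trials$trial_index) | trials$trial_index < 1L)[1], ")",
         call. = FALSE)
  }
  bad_pos <- is.na(trials$output_position) |
    trials$output_position < 1L | trials$output_position > 4L
  if (any(bad_pos)) {
    stop("output_position must be in 1..4 (row ", which(bad_pos)[1], ")",
         call. = FALSE)
  }

  cand <- .split_candidates(trials$candidate_ids)
  n_cand <- lengths(cand)
  if (any(n_cand != 8L)) {
    i <- which(n_cand != 8L)[1]
    stop(sprintf("candidate set must contain exactly 8 tokens, found %d at row %d",
                 n_cand[i], i), call. = FALSE)
  }
  dup_cand <- vapply(cand, anyDuplicated, 0L) > 0L
  if (any(dup_cand)) {
    stop("duplicated candidate token at row ", which(dup_cand)[1], call. = FALSE)
  }
  in_cand <- mapply(function(t, cc) t %in% cc, trials$target_id, cand)
  if (!all(in_cand)) {
    stop("target_id not among candidate_ids at row ", which(!in_cand)[1],
         call. = FALSE)
  }
  resp_ok <- is.na(trials$response_id) |
    mapply(function(r, cc) r %in% cc, trials$response_id, cand)
  if (!all(resp_ok)) {
    stop("response_id not among candidate_ids at row ", which(!resp_ok)[1],
         call. = FALSE)
  }

  # Per-trial invariants: positions 1..4 once each, a common candidate set,
  # four distinct targets inside it, distinct observed responses.
  key <- paste(trials$subject_id, trials$trial_index, sep = "\r")
  for (k in split(seq_len(nrow(trials)), key)) {
    pos <- trials$output_position[k]
    if (anyDuplicated(pos)) {
      stop("duplicated output_position within trial starting at row ", k[1],
           call. = FALSE)
    }
    sets <- unique(vapply(cand[k], function(cc) paste(sort(cc), collapse = "|"), ""))
    if (length(sets) != 1L) {
      stop("candidate set differs across positions of the trial starting at row ",
           k[1], call. = FALSE)
    }
    tg <- unique(as.character(trials$target_id[k]))
    if (length(tg) != length(k)) {
      stop("targets are not distinct within the trial starting at row ", k[1],
           call. = FALSE)
    }
    if (length(k) == 4L && length(tg) != 4L) {
      stop("a complete trial must have 4 distinct targets (row ", k[1], ")",
           call. = FALSE)
    }
    resp <- trials$response_id[k]
    resp <- resp[!is.na(resp)]
    if (anyDuplicated(resp)) {
      stop("responses are not distinct within the trial starting at row ", k[1],
           call. = FALSE)
    }
  }
  invisible(trials)
}

#' Read a trial table from a delimited file
#'
#' Reads a comma-separated, UTF-8, header-row file with one row per output
#' position and validates it against the trial schema
#' (see [validate_trials()]). The candidate set is stored pipe-joined in a
#' single `candidate_ids` column. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @return validated data frame of trial records.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trials <- read.csv(path, colClasses = "character",
                     na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- trials[, .trial_columns]
  validate_trials(trials)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$output_position <- as.integer(trials$output_position)
  trials
}

#' Write a trial table to a delimited file
#'
#' @param trials validated trial data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials[, .trial_columns], path, row.names = FALSE,
            fileEncoding = "UTF-8", quote = FALSE, na = "NA")
  invisible(path)
}

.trial_targets <- function(trials) {
  key <- paste(trials$subject_id, trials$trial_index, sep = "\r")
  tg <- split(as.character(trials$target_id), key)
  tg[key]
}

#' Categorize reconstruction responses
#'
#' Each selection is the position's own target (`Correct`), one of the
#' trial's three other presented words (`Other`), or one of the four
#' never-presented lures (`New`).
#'
#' @param trials validated trial data frame; rows with a missing
#'   `response_id` get an `NA` category.
#' @return character vector of categories, one per row.
#' @export
categorize_responses <- function(trials) {
  validate_trials(trials)
  if (nrow(trials) == 0) return(character(0))
  targets <- .trial_targets(trials)
  resp <- as.character(trials$response_id)
  tgt <- as.character(trials$target_id)
  out <- rep(NA_character_, nrow(trials))
  hit <- !is.na(resp)
  out[hit & resp == tgt] <- "Correct"
  is_other <- hit & resp != tgt &
    mapply(function(r, tg) r %in% tg, resp, targets)
  out[is_other] <- "Other"
  out[hit & is.na(out)] <- "New"
  out
}

#' Score trials with free and serial scoring
#'
#' Serial scoring counts a selection as correct only when it matches that
#' output position's target; free scoring counts any selection of a
#' presented word as correct, regardless of position. Both are proportions
#' over the four output positions of a trial, so chance is 12.5% for serial
#' scoring (1 of 8) and 50% for free scoring (4 of 8). Positions with a
#' missing response are dropped from the denominator and their count is
#' reported in the `n_missing` column.
#'
#' @param trials validated trial data frame.
#' @return data frame with one row per trial: `subject_id`, `trial_index`,
#'   condition columns, `free_score`, `serial_score`, `n_scored`,
#'   `n_missing`. `free_score >= serial_score` always.
#' @export
score_trials <- function(trials) {
  validate_trials(trials)
  if (nrow(trials) == 0) {
    return(data.frame(subject_id = character(0), experiment = character(0),
                      encoding_group = character(0),
                      time_condition = character(0),
                      distraction = character(0),
                      immediate_test = character(0),
                      trial_index = integer(0), free_score = numeric(0),
                      serial_score = numeric(0), n_scored = integer(0),
                      n_missing = integer(0), stringsAsFactors = FALSE))
  }
  cat <- categorize_responses(trials)
  key <- paste(trials$subject_id, trials$trial_index, sep = "\r")
  idx <- split(seq_len(nrow(trials)), key)
  rows <- lapply(idx, function(k) {
    ck <- cat[k]
    scored <- sum(!is.na(ck))
    data.frame(
      subject_id = trials$subject_id[k[1]],
      experiment = trials$experiment[k[1]],
      encoding_group = trials$encoding_group[k[1]],
      time_condition = trials$time_condition[k[1]],
      distraction = trials$distraction[k[1]],
      immediate_test = trials$immediate_test[k[1]],
      trial_index = trials$trial_index[k[1]],
      free_score = if (scored) sum(ck %in% c("Correct", "Other")) / scored else NA_real_,
      serial_score = if (scored) sum(ck == "Correct", na.rm = TRUE) / scored else NA_real_,
      n_scored = scored,
      n_missing = sum(is.na(ck)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$trial_index), ]
  rownames(out) <- NULL
  out
}

#' Condition label used for counting and fitting
#'
#' Conditions are labelled by span-task name (`simple`, `medium`, `slow`,
#' `complex`). When the immediate test varies within an encoding group
#' (the within-subject testing design), the label is suffixed with the
#' immediate-test level, e.g. `"simple:serial_recall"`; a between-group
#' difference in immediate test (intentional vs. incidental encoding)
#' does not trigger the suffix.
#'
#' @param trials validated trial data frame (or any data frame with
#'   `time_condition`, `distraction`, `immediate_test` and optionally
#'   `encoding_group` columns).
#' @return character vector of condition labels.
#' @export
condition_label <- function(trials) {
  task <- task_label(trials$time_condition, trials$distraction)
  test <- as.character(trials$immediate_test)
  varies <- if ("encoding_group" %in% names(trials)) {
    any(vapply(split(test, as.character(trials$encoding_group)),
               function(x) length(unique(x)) > 1L, TRUE))
  } else {
    length(unique(test)) > 1L
  }
  if (varies) paste(task, test, sep = ":") else task
}

#' Aggregate responses to category counts
#'
#' Builds the sufficient statistic of both measurement models: per subject
#' and condition, the number of `Correct`, `Other` and `New` selections.
#' Rows with missing responses are dropped (their count is logged as an
#' attribute `n_dropped`). Counts conserve the number of scored responses
#' exactly: `n_correct + n_other + n_new` equals 4 times the number of
#' fully scored trials in the cell.
#'
#' @param trials validated trial data frame.
#' @return data frame with columns `subject_id`, `encoding_group`,
#'   `condition`, `n_correct`, `n_other`, `n_new`; attribute `n_dropped`
#'   holds the number of unscored positions.
#' @export
aggregate_counts <- function(trials) {
  validate_trials(trials)
  empty <- data.frame(subject_id = character(0), encoding_group = character(0),
                      condition = character(0), n_correct = integer(0),
                      n_other = integer(0), n_new = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(trials) == 0) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  cat <- categorize_responses(trials)
  cond <- condition_label(trials)
  keep <- !is.na(cat)
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    attr(empty, "n_dropped") <- n_dropped
    return(empty)
  }
  df <- data.frame(subject_id = as.character(trials$subject_id)[keep],
                   encoding_group = as.character(trials$encoding_group)[keep],
                   condition = cond[keep], category = cat[keep],
                   stringsAsFactors = FALSE)
  tab <- table(df$subject_id, df$condition, factor(df$category, .category_levels))
  cells <- which(apply(tab, c(1, 2), sum) > 0, arr.ind = TRUE)
  out <- data.frame(
    subject_id = rownames(tab)[cells[, 1]],
    condition = colnames(tab)[cells[, 2]],
    n_correct = as.integer(tab[cbind(cells, 1L)]),
    n_other = as.integer(tab[cbind(cells, 2L)]),
    n_new = as.integer(tab[cbind(cells, 3L)]),
    stringsAsFactors = FALSE
  )
  grp <- unique(df[, c("subject_id", "encoding_group")])
  out$encoding_group <- grp$encoding_group[match(out$subject_id, grp$subject_id)]
  out <- out[order(out$subject_id, out$condition),
             c("subject_id", "encoding_group", "condition",
               "n_correct", "n_other", "n_new")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
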