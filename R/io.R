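# Session-log and measures CSV formats.
#
# All tabular artifacts are plain CSV (comma, UTF-8, "." decimal): one row
# per trial in the session log, one row per participant in the measures
# table, missing values as empty cells.

SESSION_LOG_COLUMNS <- c(
  "participant_id", "trial", "target_color", "target_shape",
  "target_number", "rule", "response_key", "chosen_keycard",
  "matched_dimension", "feedback", "rule_switch_before", "opportunity_tag",
  "label", "pe_occasion", "sle_occasion", "ie_occasion"
)

#' Write sessions to a session-log CSV
#'
#' @param sessions a `wcst_session` or list of them.
#' @param path output file path.
#' @param include_labels attach scorer labels/occasion flags (default TRUE;
#'   when FALSE the label columns are written empty and a reader's scorer
#'   regenerates them).
#' @return `path`, invisibly.
#' @export
write_session_log <- function(sessions, path, include_labels = TRUE) {
  if (inherits(sessions, "wcst_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    tr <- s$trials
    lb <- if (include_labels) label_trials(s) else
      data.frame(label = NA_character_, pe_occasion = NA_character_,
                 sle_occasion = NA, ie_occasion = NA)[rep(1, nrow(tr)), ]
    data.frame(
      participant_id = s$participant_id,
      trial = tr$trial,
      target_color = tr$target_color,
      target_shape = tr$target_shape,
      target_number = tr$target_number,
      rule = tr$rule,
      response_key = tr$response_key,
      chosen_keycard = tr$chosen_keycard,
      matched_dimension = tr$matched_dimension,
      feedback = tr$feedback,
      rule_switch_before = ifelse(tr$rule_switch_before, "true", "false"),
      opportunity_tag = tr$opportunity_tag,
      label = lb$label,
      pe_occasion = lb$pe_occasion,
      sle_occasion = ifelse(is.na(lb$sle_occasion), NA,
                            ifelse(lb$sle_occasion, "true", "false")),
      ie_occasion = ifelse(is.na(lb$ie_occasion), NA,
                           ifelse(lb$ie_occasion, "true", "false")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out[, SESSION_LOG_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

stop_at <- function(row, col, msg) {
  stop(sprintf("session log row %d, column '%s': %s", row, col, msg),
       call. = FALSE)
}

#' Read sessions back from a session-log CSV
#'
#' Validates every row (index ranges, unambiguous targets, feedback
#' consistency, contiguous trial numbering) and reports the first offending
#' row and column. The label columns are ignored on input: the scorer
#' regenerates them. The session configuration is not serialized; supply it
#' via `config`.
#'
#' @param path session-log CSV path.
#' @param config the [session_config()] to attach to each session.
#' @return a list of `wcst_session` objects, in file order.
#' @export
read_session_log <- function(path, config = session_config()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(SESSION_LOG_COLUMNS, names(raw))
  if (length(miss))
    stop("session log lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(raw)
  int_col <- function(col, lo, hi) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) | v < lo | v > hi)
    if (length(bad))
      stop_at(bad[1], col, sprintf("value '%s' outside %d..%d",
                                   raw[[col]][bad[1]], lo, hi))
    v
  }
  trial <- int_col("trial", 1L, .Machine$integer.max)
  tc <- int_col("target_color", 1L, 4L)
  ts <- int_col("target_shape", 1L, 4L)
  tn <- int_col("target_number", 1L, 4L)
  kc <- int_col("chosen_keycard", 1L, 4L)
  fb <- int_col("feedback", 0L, 1L)
  amb <- which(tc == ts | tc == tn | ts == tn)
  if (length(amb)) stop_at(amb[1], "target_color", "ambiguous target card")
  bad_rule <- which(!(raw$rule %in% DIMENSIONS))
  if (length(bad_rule))
    stop_at(bad_rule[1], "rule", paste("unknown dimension", raw$rule[bad_rule[1]]))
  bad_m <- which(!(raw$matched_dimension %in% c(DIMENSIONS, "ODD")))
  if (length(bad_m))
    stop_at(bad_m[1], "matched_dimension", "unknown value")
  rsb <- raw$rule_switch_before %in% "true"
  bad_b <- which(!(raw$rule_switch_before %in% c("true", "false")))
  if (length(bad_b))
    stop_at(bad_b[1], "rule_switch_before", "expected true/false")
  bad_tag <- which(!(raw$opportunity_tag %in%
                       c("NEUTRAL", "REPETITIVE", "NON_REPETITIVE")))
  if (length(bad_tag)) stop_at(bad_tag[1], "opportunity_tag", "unknown tag")

  ids <- raw$participant_id
  split_idx <- split(seq_len(n), factor(ids, levels = unique(ids)))
  lapply(names(split_idx), function(id) {
    i <- split_idx[[id]]
    if (!identical(trial[i], seq_along(i)))
      stop_at(i[which(trial[i] != seq_along(i))[1]], "trial",
              "trials not contiguous from 1")
    tr <- data.frame(
      trial = trial[i], target_color = tc[i], target_shape = ts[i],
      target_number = tn[i], rule = raw$rule[i],
      response_key = raw$response_key[i], chosen_keycard = kc[i],
      matched_dimension = raw$matched_dimension[i], feedback = fb[i],
      rule_switch_before = rsb[i], opportunity_tag = raw$opportunity_tag[i],
      stringsAsFactors = FALSE
    )
    # feedback/matched/rule consistency, located
    bad <- which((tr$feedback == 1L) != (tr$matched_dimension == tr$rule))
    if (length(bad)) stop_at(i[bad[1]], "feedback",
                             "inconsistent with matched_dimension and rule")
    structure(list(
      participant_id = id, config = config, trials = tr,
      n_categories = compute_measures_categories(tr$feedback,
                                                 config$category_length),
      termination_reason = if (nrow(tr) >= config$max_trials)
        "MAX_TRIALS" else "OCCASIONS_REACHED"
    ), class = "wcst_session")
  })
}

compute_measures_categories <- function(feedback, L) {
  run <- 0L; n_cat <- 0L
  for (f in feedback) {
    if (f == 1L) { run <- run + 1L
      if (run == L) { n_cat <- n_cat + 1L; run <- 0L }
    } else run <- 0L
  }
  n_cat
}

#' Write a cohort measures table to CSV
#'
#' @param measures data.frame from [score_cohort()].
#' @param path output path. Missing (undefined) values become empty cells.
#' @return `path`, invisibly.
#' @export
write_measures_csv <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort measures table
#' @param path CSV path written by [write_measures_csv()].
#' @return data.frame with empty cells restored as `NA`.
#' @export
read_measures_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
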