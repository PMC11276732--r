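# Trial labelling, occasion counting, per-participant measures, and cohort
# aggregation with exclusion rules.
#
# Error taxonomy (one label per trial; errors only on incorrect trials):
#   PE  -- repeating the dimension disconfirmed by error feedback on the
#          *immediately preceding* trial; the occasion is repetitive when
#          the action-relevant feature on that dimension repeats between
#          the two trials, non-repetitive when it changes.
#   IE  -- after informative errors on two *distinct* dimensions on the two
#          preceding trials, re-choosing the first-excluded dimension
#          instead of the remaining third.
#   SLE -- an error following confirmed-correct feedback with the rule
#          unchanged (the first trial after a covert switch is excluded:
#          the old-rule response there is an unavoidable switch-signal
#          error, not a set loss).
#   OE  -- choosing the keycard sharing no feature with the target.
# Precedence on conflicts: OE > PE > IE > SLE > SWITCH_SIGNAL_ERROR >
# UNCLASSIFIED_ERROR. Odd responses are never informative about a
# dimension and never create or extend PE/IE occasion chains.

TRIAL_LABELS <- c("CORRECT", "PE_REP", "PE_NONREP", "SLE", "IE", "OE",
                  "SWITCH_SIGNAL_ERROR", "UNCLASSIFIED_ERROR")

#' Dimension disconfirmed by a trial's feedback, if any
#'
#' @param matched_dimension character vector of matched dimensions
#'   (`"COLOR"`/`"SHAPE"`/`"NUMBER"`/`"ODD"`).
#' @param feedback integer vector (1 correct, 0 incorrect).
#' @return character vector: the disconfirmed dimension, or `NA` when the
#'   trial was correct or the response odd.
#' @export
informative_error_dimension <- function(matched_dimension, feedback) {
  ifelse(feedback == 0L & matched_dimension != "ODD",
         matched_dimension, NA_character_)
}

#' Label every trial of a session and flag its occasions
#'
#' @param session a `wcst_session` (or any list with a conforming `trials`
#'   data frame).
#' @return a data.frame aligned with the trials: `label`, `pe_occasion`
#'   (`"NONE"`/`"REPETITIVE"`/`"NON_REPETITIVE"`), `sle_occasion`,
#'   `ie_occasion` (logicals), and `ie_first_excluded` (the dimension a
#'   faulty integration would revisit, `NA` off IE occasions).
#' @export
label_trials <- function(session) {
  tr <- session$trials
  validate_trials(tr)
  n <- nrow(tr)
  tgt <- cbind(tr$target_color, tr$target_shape, tr$target_number)
  colnames(tgt) <- DIMENSIONS
  fb <- tr$feedback
  m <- tr$matched_dimension
  rsb <- tr$rule_switch_before

  info <- informative_error_dimension(m, fb)
  d1 <- c(NA_character_, info[-n])                     # from trial t-1
  d0 <- if (n >= 2) c(NA_character_, NA_character_, info[seq_len(n - 2)])
        else rep(NA_character_, n)                     # from trial t-2

  # perseveration occasions: previous trial was an informative error
  pe_occ <- rep("NONE", n)
  has_d1 <- !is.na(d1)
  if (any(has_d1)) {
    i <- which(has_d1)
    di <- match(d1[i], DIMENSIONS)
    feat_now <- tgt[cbind(i, di)]
    feat_prev <- tgt[cbind(i - 1L, di)]
    pe_occ[i] <- ifelse(feat_now == feat_prev, "REPETITIVE", "NON_REPETITIVE")
  }

  ie_occ <- !is.na(d0) & !is.na(d1) & d0 != d1
  prev_fb <- c(NA_integer_, fb[-n])
  sle_occ <- !is.na(prev_fb) & prev_fb == 1L & !rsb
  prev_rule <- c(NA_character_, tr$rule[-n])

  label <- rep("UNCLASSIFIED_ERROR", n)
  label[fb == 1L] <- "CORRECT"
  err <- fb == 0L
  is_odd <- err & m == "ODD"
  is_pe <- err & !is_odd & has_d1 & m == d1
  is_ie <- err & !is_odd & !is_pe & ie_occ & m == d0
  is_sle <- err & !is_odd & !is_pe & !is_ie & sle_occ
  is_sws <- err & !is_odd & !is_pe & !is_ie & !is_sle & rsb &
    !is.na(prev_rule) & m == prev_rule
  label[is_odd] <- "OE"
  label[is_pe] <- ifelse(pe_occ[is_pe] == "REPETITIVE", "PE_REP", "PE_NONREP")
  label[is_ie] <- "IE"
  label[is_sle] <- "SLE"
  label[is_sws] <- "SWITCH_SIGNAL_ERROR"

  data.frame(label = label, pe_occasion = pe_occ, sle_occasion = sle_occ,
             ie_occasion = ie_occ,
             ie_first_excluded = ifelse(ie_occ, d0, NA_character_),
             stringsAsFactors = FALSE)
}

validate_trials <- function(tr) {
  needed <- c("target_color", "target_shape", "target_number", "rule",
              "chosen_keycard", "matched_dimension", "feedback",
              "rule_switch_before")
  miss <- setdiff(needed, names(tr))
  if (length(miss))
    stop("trials table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  idx <- cbind(tr$target_color, tr$target_shape, tr$target_number)
  if (any(idx < 1L | idx > 4L) ||
      any(idx[, 1] == idx[, 2] | idx[, 1] == idx[, 3] | idx[, 2] == idx[, 3]))
    stop("trials contain ambiguous or out-of-range target cards",
         call. = FALSE)
  ok_fb <- (tr$feedback == 1L) == (tr$matched_dimension == tr$rule)
  if (any(!ok_fb))
    stop("feedback inconsistent with matched dimension and rule at trial ",
         which(!ok_fb)[1], call. = FALSE)
  invisible(tr)
}

#' Per-participant measures from a labelled session
#'
#' Percentages are per-occasion: e.g. `npe_pct` is 100 * committed
#' non-repetitive perseverations / non-repetitive occasions. The error
#' suppression effect is `ese = npe_pct - rpe_pct`, and its normalized form
#' `ese_sum = (npe_pct - rpe_pct) / (npe_pct + rpe_pct)`, defined only for
#' participants committing at least one perseveration. Percentages with a
#' zero denominator are `NA` (explicitly undefined, never 0).
#'
#' @param session a `wcst_session`.
#' @param labels optional result of [label_trials()] (recomputed if omitted).
#' @return a one-row data.frame with all measure columns.
#' @export
compute_measures <- function(session, labels = NULL) {
  if (is.null(labels)) labels <- label_trials(session)
  tr <- session$trials
  n <- nrow(tr)
  lab <- labels$label

  # categories recomputed from feedback alone so CSV-loaded sessions score
  # identically to engine output; the final partial run is not counted
  L <- session$config$category_length %||% 6L
  run <- 0L; n_cat <- 0L
  for (f in tr$feedback) {
    if (f == 1L) { run <- run + 1L
      if (run == L) { n_cat <- n_cat + 1L; run <- 0L }
    } else run <- 0L
  }

  n_occ_npe <- sum(labels$pe_occasion == "NON_REPETITIVE")
  n_occ_rpe <- sum(labels$pe_occasion == "REPETITIVE")
  n_npe <- sum(lab == "PE_NONREP")
  n_rpe <- sum(lab == "PE_REP")
  n_occ_sle <- sum(labels$sle_occasion)
  n_sle <- sum(lab == "SLE")
  n_occ_ie <- sum(labels$ie_occasion)
  n_ie <- sum(lab == "IE")

  pct <- function(k, occ) if (occ > 0) 100 * k / occ else NA_real_
  npe_pct <- pct(n_npe, n_occ_npe)
  rpe_pct <- pct(n_rpe, n_occ_rpe)
  ese <- npe_pct - rpe_pct
  ese_sum <- if (n_npe + n_rpe > 0 && !is.na(ese))
    (npe_pct - rpe_pct) / (npe_pct + rpe_pct) else NA_real_

  data.frame(
    participant_id = session$participant_id,
    n_total_trials = n,
    n_categories = n_cat,
    categories_pct = 100 * n_cat / n,
    n_occ_pe = n_occ_npe + n_occ_rpe,
    n_pe = n_npe + n_rpe,
    n_occ_npe = n_occ_npe, n_npe = n_npe,
    n_occ_rpe = n_occ_rpe, n_rpe = n_rpe,
    npe_pct = npe_pct, rpe_pct = rpe_pct,
    ese = ese, ese_sum = ese_sum,
    n_occ_sle = n_occ_sle, n_sle = n_sle,
    sle_pct = pct(n_sle, n_occ_sle),
    n_occ_ie = n_occ_ie, n_ie = n_ie,
    ie_pct = pct(n_ie, n_occ_ie),
    n_oe = sum(lab == "OE"),
    stringsAsFactors = FALSE
  )
}

#' Score a cohort of sessions
#'
#' @param sessions a list of `wcst_session` objects.
#' @return a data.frame, one [compute_measures()] row per session.
#' @export
score_cohort <- function(sessions) {
  do.call(rbind, lapply(sessions, compute_measures))
}

#' Apply cohort-level exclusion rules and summarize
#'
#' Excludes participants (a) more than `sd_mult` SD below the cohort mean
#' number of categories, (b) more than `sd_mult` SD above the cohort mean
#' number of odd errors, or (c) with fewer than `min_occasions` occasions of
#' either perseveration type. Undefined percentages propagate as `NA` into
#' the descriptive statistics (pairwise deletion).
#'
#' @param measures cohort measures data.frame from [score_cohort()].
#' @param min_occasions minimum occasions of each perseveration type
#'   (default 8).
#' @param sd_mult SD multiplier for rules (a) and (b) (default 3).
#' @return a list: `retained` (measures rows kept), `excluded` (data.frame
#'   of `participant_id` and `reason`), `descriptives` (per-measure n,
#'   mean, sd, median, q1, q3, min, max over the retained rows).
#' @export
aggregate_and_exclude <- function(measures, min_occasions = 8L,
                                  sd_mult = 3) {
  if (nrow(measures) < 2L)
    stop("cohort must contain at least 2 participants (SD undefined)",
         call. = FALSE)
  mu_cat <- mean(measures$n_categories); sd_cat <- sd(measures$n_categories)
  mu_oe <- mean(measures$n_oe); sd_oe <- sd(measures$n_oe)
  low_cat <- measures$n_categories < mu_cat - sd_mult * sd_cat
  high_oe <- measures$n_oe > mu_oe + sd_mult * sd_oe
  few_occ <- measures$n_occ_npe < min_occasions |
    measures$n_occ_rpe < min_occasions

  reason <- character(nrow(measures))
  reason[few_occ] <- "fewer_than_min_pe_occasions"
  reason[high_oe] <- "oe_above_3sd"
  reason[low_cat] <- "categories_below_3sd"
  drop <- low_cat | high_oe | few_occ

  num_cols <- setdiff(names(measures), "participant_id")
  kept <- measures[!drop, , drop = FALSE]
  desc <- do.call(rbind, lapply(num_cols, function(v) {
    x <- kept[[v]]
    x <- x[!is.na(x)]
    data.frame(measure = v, n = length(x), mean = mean(x), sd = sd(x),
               median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  list(retained = kept,
       excluded = data.frame(participant_id = measures$participant_id[drop],
                             reason = reason[drop],
                             stringsAsFactors = FALSE),
       descriptives = desc)
}
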