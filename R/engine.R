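# The session state machine.
#
# A covert sorting rule cycles COLOR -> SHAPE -> NUMBER -> COLOR ... and
# advances after `category_length` consecutive correct sorts (a *category*).
# Feedback is CORRECT iff the chosen keycard matches the target on the
# current rule dimension. The session ends at `max_trials` trials, or early
# once the participant has encountered `occasion_target` potential
# non-repetitive AND `occasion_target` potential repetitive perseveration
# errors.

#' Session configuration
#'
#' Defaults encode the task as administered: 240-trial cap, early stop at 20
#' occasions of each perseveration type, categories of six consecutive
#' correct sorts, rules cycling COLOR/SHAPE/NUMBER, 1200 ms feedback and
#' 800 ms inter-trial interval (timing recorded, not simulated).
#'
#' @param max_trials maximum number of trials (default 240).
#' @param occasion_target early-termination threshold on each perseveration
#'   occasion counter (default 20).
#' @param category_length consecutive correct sorts per category (default 6).
#' @param dimension_order cyclic rule order; the first element is the first
#'   rule in force.
#' @param feedback_ms,iti_ms display timing constants in milliseconds.
#' @param seed integer master seed for the session.
#' @return a list of class `wcst_config`.
#' @export
session_config <- function(max_trials = 240L, occasion_target = 20L,
                           category_length = 6L,
                           dimension_order = DIMENSIONS,
                           feedback_ms = 1200L, iti_ms = 800L, seed = 1L) {
  stopifnot(max_trials >= 1, occasion_target >= 1, category_length >= 1,
            length(seed) == 1, is.finite(seed))
  if (!setequal(dimension_order, DIMENSIONS) || length(dimension_order) != 3L)
    stop("dimension_order must be a permutation of COLOR, SHAPE, NUMBER",
         call. = FALSE)
  structure(list(
    max_trials = as.integer(max_trials),
    occasion_target = as.integer(occasion_target),
    category_length = as.integer(category_length),
    dimension_order = as.character(dimension_order),
    feedback_ms = as.integer(feedback_ms),
    iti_ms = as.integer(iti_ms),
    seed = as.integer(seed)
  ), class = "wcst_config")
}

#' Create a fresh in-progress session state
#'
#' Low-level interface: tests and custom drivers can present targets and
#' play trials one at a time. [run_session()] wraps the same primitives.
#'
#' @param config a [session_config()].
#' @param participant_id identifier recorded in the session log.
#' @return an environment of class `wcst_session_state`.
#' @export
new_session_state <- function(config = session_config(),
                              participant_id = "p1") {
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$participant_id <- as.character(participant_id)
  e$seq <- new_sequencer_state(derive_seed(config$seed, 1L))
  e$rule_ids <- match(config$dimension_order, DIMENSIONS)
  e$rule_pos <- 1L
  e$consecutive <- 0L
  e$categories <- 0L
  e$switch_next <- FALSE    # next trial is the first after a covert switch
  e$nocc_rep <- 0L
  e$nocc_nonrep <- 0L
  e$t <- 0L
  e$pending <- NULL
  e$termination <- NULL
  n <- config$max_trials
  e$rec <- list(
    target = matrix(NA_integer_, n, 3),
    rule = integer(n), chosen = integer(n), matched = integer(n),
    feedback = integer(n), rsb = logical(n), tag = character(n)
  )
  class(e) <- "wcst_session_state"
  e
}

#' Present the next target card
#'
#' Draws the constrained pseudo-random target for the upcoming trial and
#' counts the perseveration opportunity it realizes, if any.
#'
#' @param state a `wcst_session_state`.
#' @return list with `card`, `opportunity_tag`, `trial`.
#' @export
present_next_target <- function(state) {
  if (!is.null(state$termination)) stop("session already terminated")
  if (!is.null(state$pending)) stop("a target is already awaiting a response")
  drawn <- draw_next_target(state$seq)
  if (drawn$opportunity_tag == "REPETITIVE") {
    state$nocc_rep <- state$nocc_rep + 1L
  } else if (drawn$opportunity_tag == "NON_REPETITIVE") {
    state$nocc_nonrep <- state$nocc_nonrep + 1L
  }
  state$pending <- drawn
  list(card = drawn$card, opportunity_tag = drawn$opportunity_tag,
       trial = state$t + 1L)
}

#' Play one trial against the presented target
#'
#' Applies feedback, updates the consecutive-correct counter and the covert
#' rule (advancing the rule and flagging the next trial after a completed
#' category), updates the sequencer's critical dimension, and checks
#' termination.
#'
#' @param state a `wcst_session_state` with a pending target.
#' @param chosen_keycard integer 1..4.
#' @return the trial record as a one-row list (invisibly mutates `state`).
#' @export
play_trial <- function(state, chosen_keycard) {
  if (is.null(state$pending))
    stop("no target presented; call present_next_target() first")
  if (length(chosen_keycard) != 1L || is.na(chosen_keycard) ||
      !(chosen_keycard %in% 1:4))
    stop("chosen_keycard must be a single integer in 1..4", call. = FALSE)
  t <- state$t + 1L
  tgt <- state$pending$card
  tag <- state$pending$opportunity_tag
  rule_id <- state$rule_ids[state$rule_pos]
  matched <- classify_fast(tgt, as.integer(chosen_keycard))
  correct <- matched == rule_id
  rsb <- state$switch_next

  r <- state$rec
  r$target[t, ] <- tgt
  r$rule[t] <- rule_id
  r$chosen[t] <- as.integer(chosen_keycard)
  r$matched[t] <- matched
  r$feedback[t] <- as.integer(correct)
  r$rsb[t] <- rsb
  r$tag[t] <- tag
  state$rec <- r

  # rule-state update
  state$switch_next <- FALSE
  if (correct) {
    state$consecutive <- state$consecutive + 1L
    if (state$consecutive == state$config$category_length) {
      state$categories <- state$categories + 1L
      state$rule_pos <- (state$rule_pos %% 3L) + 1L
      state$consecutive <- 0L
      state$switch_next <- TRUE
    }
  } else {
    state$consecutive <- 0L
  }
  sequencer_observe_feedback(state$seq, matched, correct)
  state$pending <- NULL
  state$t <- t

  verdict <- check_termination(state$nocc_nonrep, state$nocc_rep, t,
                               state$config)
  if (verdict != "CONTINUE") state$termination <- verdict
  invisible(list(trial = t, target = tgt, rule = DIMENSIONS[rule_id],
                 chosen_keycard = as.integer(chosen_keycard),
                 matched = if (matched == 0L) "ODD" else DIMENSIONS[matched],
                 feedback = as.integer(correct), rule_switch_before = rsb,
                 opportunity_tag = tag))
}

#' Termination verdict for a session in progress
#'
#' Early termination fires once both perseveration-occasion counters reach
#' the occasion target; otherwise the trial cap binds. Checked after each
#' completed trial.
#'
#' @param n_occ_npe,n_occ_rpe occasion counters so far.
#' @param n_trials completed trials so far.
#' @param config a [session_config()].
#' @return `"CONTINUE"`, `"OCCASIONS_REACHED"` or `"MAX_TRIALS"`.
#' @export
check_termination <- function(n_occ_npe, n_occ_rpe, n_trials,
                              config = session_config()) {
  if (n_occ_npe >= config$occasion_target &&
      n_occ_rpe >= config$occasion_target) return("OCCASIONS_REACHED")
  if (n_trials >= config$max_trials) return("MAX_TRIALS")
  "CONTINUE"
}

# assemble the completed-session record from the preallocated buffers
finalize_session <- function(state) {
  t <- state$t
  r <- state$rec
  matched <- ifelse(r$matched[seq_len(t)] == 0L, "ODD",
                    DIMENSIONS[pmax(r$matched[seq_len(t)], 1L)])
  trials <- data.frame(
    trial = seq_len(t),
    target_color = r$target[seq_len(t), 1],
    target_shape = r$target[seq_len(t), 2],
    target_number = r$target[seq_len(t), 3],
    rule = DIMENSIONS[r$rule[seq_len(t)]],
    response_key = RESPONSE_KEYS[r$chosen[seq_len(t)]],
    chosen_keycard = r$chosen[seq_len(t)],
    matched_dimension = matched,
    feedback = r$feedback[seq_len(t)],
    rule_switch_before = r$rsb[seq_len(t)],
    opportunity_tag = r$tag[seq_len(t)],
    stringsAsFactors = FALSE
  )
  structure(list(
    participant_id = state$participant_id,
    config = state$config,
    trials = trials,
    n_categories = state$categories,
    termination_reason = state$termination %||% "MAX_TRIALS"
  ), class = "wcst_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a complete session under a response policy
#'
#' @param policy a function `(target, ctx) -> keycard position 1..4`; `ctx`
#'   carries `trial`, `rule` (the covert rule's dimension id -- honest
#'   policies must ignore it; the omniscient fixture uses it),
#'   `prev_feedback` and `prev_matched` (dimension id, 0 for odd, `NA` on
#'   the first trial).
#' @param config a [session_config()]; its `seed` fully determines the
#'   session given the policy.
#' @param participant_id identifier recorded in the output.
#' @return a `wcst_session` object.
#' @export
run_session <- function(policy, config = session_config(),
                        participant_id = "p1") {
  state <- new_session_state(config, participant_id)
  prev_feedback <- NA
  prev_matched <- NA_integer_
  while (is.null(state$termination)) {
    pres <- present_next_target(state)
    ctx <- list(trial = pres$trial,
                rule = state$rule_ids[state$rule_pos],
                prev_feedback = prev_feedback,
                prev_matched = prev_matched)
    choice <- tryCatch(policy(pres$card, ctx), error = function(e)
      stop(sprintf("policy failed on trial %d: %s", pres$trial,
                   conditionMessage(e)), call. = FALSE))
    rec <- play_trial(state, choice)
    prev_feedback <- rec$feedback == 1L
    prev_matched <- if (rec$matched == "ODD") 0L else
      match(rec$matched, DIMENSIONS)
  }
  finalize_session(state)
}

#' @export
print.wcst_session <- function(x, ...) {
  cat(sprintf("<wcst_session> %s: %d trials, %d categories, %s\n",
              x$participant_id, nrow(x$trials), x$n_categories,
              x$termination_reason))
  invisible(x)
}
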