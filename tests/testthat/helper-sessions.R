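# Fixture sessions built in code.

# wrap a hand-written trials table as a session object
fixture_session <- function(trials, id = "fixture",
                            config = iwcst::session_config()) {
  structure(list(participant_id = id, config = config, trials = trials,
                 n_categories = 0L, termination_reason = "MAX_TRIALS"),
            class = "wcst_session")
}

fixture_trial_row <- function(trial, target, rule, chosen, rsb) {
  matched <- iwcst::classify_response(target, chosen)
  data.frame(
    trial = trial,
    target_color = target[1], target_shape = target[2],
    target_number = target[3],
    rule = rule,
    response_key = c("Y", "C", "B", "M")[chosen],
    chosen_keycard = chosen,
    matched_dimension = matched,
    feedback = as.integer(matched == rule),
    rule_switch_before = rsb,
    opportunity_tag = "NEUTRAL",
    stringsAsFactors = FALSE
  )
}

make_fixture <- function(rows) {
  tr <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    fixture_trial_row(i, r$target, r$rule, r$chosen, isTRUE(r$rsb))
  }))
  fixture_session(tr)
}

# worked example A: covert switch away from SHAPE, then a repetitive and a
# non-repetitive perseveration (the two-pathway contrast)
fixture_pe_sequence <- function() {
  make_fixture(list(
    # sort by SHAPE while SHAPE is the rule: correct
    list(target = c(2, 1, 3), rule = "SHAPE", chosen = 1),
    # covert switch to COLOR; sorting by SHAPE again is the switch signal
    list(target = c(3, 2, 4), rule = "COLOR", chosen = 2, rsb = TRUE),
    # asterisk (shape 2) repeats: repetitive PE occasion, SHAPE chosen
    list(target = c(4, 2, 1), rule = "COLOR", chosen = 2),
    # shape feature changes 2 -> 4: non-repetitive occasion, SHAPE chosen
    list(target = c(1, 4, 2), rule = "COLOR", chosen = 4)
  ))
}

# worked example B: two consecutive informative errors on distinct
# dimensions, a faulty integration, a successful sort, then a set loss
fixture_ie_sle_sequence <- function() {
  make_fixture(list(
    list(target = c(2, 1, 3), rule = "SHAPE", chosen = 1),             # correct
    list(target = c(3, 2, 4), rule = "NUMBER", chosen = 2, rsb = TRUE),# SHAPE err
    list(target = c(4, 3, 1), rule = "NUMBER", chosen = 4),            # COLOR err
    list(target = c(2, 4, 3), rule = "NUMBER", chosen = 4),            # SHAPE: IE
    list(target = c(1, 2, 4), rule = "NUMBER", chosen = 4),            # correct
    list(target = c(3, 1, 2), rule = "NUMBER", chosen = 1)             # SHAPE: SLE
  ))
}

# a cohort of sessions driven by a uniformly random policy (exercises every
# label branch, including odd errors)
random_policy_sessions <- function(n_sessions, seed, max_trials = 40L) {
  lapply(seq_len(n_sessions), function(i) {
    stream <- iwcst::new_rng_stream(iwcst::derive_seed(seed, 1000L + i))
    policy <- function(target, ctx) {
      u <- iwcst:::stream_runif(stream)
      1L + (u >= 0.25) + (u >= 0.5) + (u >= 0.75)
    }
    cfg <- iwcst::session_config(max_trials = max_trials,
                                 seed = iwcst::derive_seed(seed, 2000L + i))
    iwcst::run_session(policy, cfg, participant_id = sprintf("rand_%d", i))
  })
}
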