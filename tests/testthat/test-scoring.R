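test_that("the perseveration worked example labels as rPE then nPE", {
  s <- fixture_pe_sequence()
  lb <- label_trials(s)
  expect_equal(lb$label,
               c("CORRECT", "SWITCH_SIGNAL_ERROR", "PE_REP", "PE_NONREP"))
  expect_equal(lb$pe_occasion,
               c("NONE", "NONE", "REPETITIVE", "NON_REPETITIVE"))
})

test_that("the integration/set-loss worked example labels IE and SLE", {
  s <- fixture_ie_sle_sequence()
  lb <- label_trials(s)
  expect_equal(lb$label,
               c("CORRECT", "SWITCH_SIGNAL_ERROR", "UNCLASSIFIED_ERROR",
                 "IE", "CORRECT", "SLE"))
  expect_equal(lb$ie_occasion, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(lb$ie_first_excluded[4], "SHAPE")
  expect_equal(lb$sle_occasion, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("informative_error_dimension ignores correct and odd trials", {
  expect_equal(informative_error_dimension(c("SHAPE", "COLOR", "ODD"),
                                           c(0L, 1L, 0L)),
               c("SHAPE", NA, NA))
})

test_that("an all-correct session has only CORRECT labels and SLE occasions", {
  s <- run_session(omniscient_policy(), session_config(seed = 5))
  lb <- label_trials(s)
  expect_true(all(lb$label == "CORRECT"))
  expect_true(all(lb$pe_occasion == "NONE"))
  expect_false(any(lb$ie_occasion))
  # every trial after a correct non-switch trial is a set-loss occasion
  expect_equal(sum(lb$sle_occasion), 240L - 1L - 39L)
  m <- compute_measures(s, lb)
  expect_equal(m$n_pe + m$n_sle + m$n_ie + m$n_oe, 0L)
  expect_true(is.na(m$npe_pct) && is.na(m$ese) && is.na(m$ese_sum))
  expect_true(is.na(m$ie_pct))
})

test_that("labels partition trials and occasion identities hold", {
  sessions <- c(
    random_policy_sessions(30, seed = 61),
    simulate_cohort(agent_params(p_pers_nonrep = 0.3, p_pers_rep = 0.2,
                                 p_sle = 0.15, p_oe = 0.05),
                    10, session_config(max_trials = 120), master_seed = 62)
  )
  for (s in sessions) {
    lb <- label_trials(s)
    n <- nrow(s$trials)
    expect_equal(sum(lb$label == "CORRECT"), sum(s$trials$feedback))
    expect_equal(sum(lb$label != "CORRECT"), sum(s$trials$feedback == 0L))
    # PE and SLE occasions are mutually exclusive; IE implies a PE occasion
    expect_false(any(lb$pe_occasion != "NONE" & lb$sle_occasion))
    expect_true(all(lb$pe_occasion[lb$ie_occasion] != "NONE"))
    # scorer occasions agree with the sequencer's opportunity tags
    has_occ <- lb$pe_occasion != "NONE"
    expect_equal(lb$pe_occasion[has_occ], s$trials$opportunity_tag[has_occ])
    m <- compute_measures(s, lb)
    expect_equal(m$n_occ_pe, m$n_occ_npe + m$n_occ_rpe)
    expect_lte(m$n_npe, m$n_occ_npe)
    expect_lte(m$n_rpe, m$n_occ_rpe)
    if (!is.na(m$ese)) expect_equal(m$ese, m$npe_pct - m$rpe_pct)
  }
})

test_that("the vectorized scorer agrees with the naive oracle", {
  sessions <- c(
    random_policy_sessions(60, seed = 71, max_trials = 40),
    simulate_cohort(agent_params(p_pers_nonrep = 0.35, p_pers_rep = 0.15,
                                 p_sle = 0.2, p_ie = 0.4, p_oe = 0.08),
                    20, session_config(max_trials = 60), master_seed = 72)
  )
  for (s in sessions) {
    got <- label_trials(s)
    want <- oracle_label_trials(s)
    expect_equal(got$label, want$label)
    expect_equal(got$pe_occasion, want$pe_occasion)
    expect_equal(got$sle_occasion, want$sle_occasion)
    expect_equal(got$ie_occasion, want$ie_occasion)
  }
})

test_that("measure arithmetic and domain restrictions are honored", {
  # 2 committed of 20 occasions -> 10%
  expect_equal(100 * 2 / 20, 10)
  s <- fixture_pe_sequence()
  m <- compute_measures(s)
  expect_equal(m$n_occ_rpe, 1L)
  expect_equal(m$n_rpe, 1L)
  expect_equal(m$rpe_pct, 100)
  expect_equal(m$npe_pct, 100)
  expect_equal(m$ese, 0)
  expect_equal(m$ese_sum, 0)

  # ese_sum is +1 when only non-repetitive PE occur, undefined when none
  s2 <- fixture_ie_sle_sequence()
  m2 <- compute_measures(s2)
  expect_equal(m2$n_pe, 0L)
  expect_true(is.na(m2$ese_sum))
  expect_equal(m2$n_ie, 1L)
  expect_equal(m2$n_sle, 1L)
})

test_that("cohort exclusion flags each rule and refuses tiny cohorts", {
  base <- compute_measures(run_session(
    make_agent_policy(agent_params(), new_rng_stream(8)),
    session_config(seed = 8)))
  cohort <- do.call(rbind, replicate(100, base, simplify = FALSE))
  cohort$participant_id <- sprintf("p%03d", seq_len(nrow(cohort)))
  # plant one zero-category outlier, one OE outlier, one occasion-poor row
  cohort$n_categories[5] <- 0L
  cohort$n_oe[9] <- 50L
  cohort$n_occ_rpe[14] <- 7L
  agg <- aggregate_and_exclude(cohort)
  expect_setequal(agg$excluded$participant_id, c("p005", "p009", "p014"))
  expect_equal(agg$excluded$reason[agg$excluded$participant_id == "p005"],
               "categories_below_3sd")
  expect_equal(agg$excluded$reason[agg$excluded$participant_id == "p009"],
               "oe_above_3sd")
  expect_equal(agg$excluded$reason[agg$excluded$participant_id == "p014"],
               "fewer_than_min_pe_occasions")
  expect_equal(nrow(agg$retained), 97L)

  # homogeneous cohort: SD = 0, nobody excluded
  hom <- do.call(rbind, replicate(10, base, simplify = FALSE))
  expect_equal(nrow(aggregate_and_exclude(hom)$excluded), 0L)
  expect_error(aggregate_and_exclude(base), "at least 2")

  # descriptive table covers every measure with the standard statistics
  expect_true(all(c("mean", "sd", "median", "q1", "q3", "min", "max")
                  %in% names(agg$descriptives)))
  expect_true("ese" %in% agg$descriptives$measure)
})
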