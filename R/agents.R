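# Parametric synthetic participants.
#
# The agent is a descriptive probabilistic policy, not a cognitive-process
# model: each error pathway of the scoring taxonomy has its own generating
# probability, so every downstream measure is non-degenerate and scored
# per-occasion error rates converge to the generating parameters. The
# two-pathway account of the error suppression effect is captured by
# separate post-error perseveration probabilities for repetitive
# (feature-repeat) versus non-repetitive contexts: p_pers_rep <
# p_pers_nonrep produces a positive ESE (goal-directed instrumental
# control regime), the reverse ordering a negative ESE (supervisory
# attentional system regime).

#' Parameters of a synthetic participant
#'
#' Defaults emulate the cohort-level error rates observed with the task in
#' neurotypical adults: non-repetitive perseveration ~9.2% of occasions,
#' repetitive ~3.9%, set loss ~5.1%, integration failure ~14.9% of
#' integration occasions, and odd responses on ~0.45% of trials.
#'
#' @param p_pers_nonrep probability of repeating the just-disconfirmed
#'   dimension when its action-relevant feature changed.
#' @param p_pers_rep same, when the feature repeated.
#' @param p_sle probability of abandoning a just-confirmed set.
#' @param p_ie probability of re-choosing the first-excluded dimension after
#'   two consecutive informative errors on distinct dimensions.
#' @param p_oe probability of an odd response on any trial.
#' @param omniscient if `TRUE`, always sort by the true rule (test fixture;
#'   overrides all other parameters).
#' @return a list of class `wcst_agent_params`.
#' @export
agent_params <- function(p_pers_nonrep = 0.092, p_pers_rep = 0.039,
                         p_sle = 0.051, p_ie = 0.149, p_oe = 0.0045,
                         omniscient = FALSE) {
  p <- c(p_pers_nonrep, p_pers_rep, p_sle, p_ie, p_oe)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("all agent probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(p_pers_nonrep = p_pers_nonrep, p_pers_rep = p_pers_rep,
                 p_sle = p_sle, p_ie = p_ie, p_oe = p_oe,
                 omniscient = isTRUE(omniscient)),
            class = "wcst_agent_params")
}

#' Build a response policy from agent parameters
#'
#' The returned closure tracks the agent's candidate dimension, the previous
#' target, and the informative-error dimensions of the last two trials. On
#' each trial it first updates the candidate set given the latest feedback
#' (keep after correct with prob `1 - p_sle`; after an informative error on
#' d, perseverate on d with the context-appropriate probability, otherwise
#' switch -- to the remaining third dimension after two distinct-dimension
#' errors (integration, failed with prob `p_ie`), to the still-valid
#' confirmed set when the error was a lapse from one, or else uniformly
#' between the two alternatives), then with probability `p_oe` overrides
#' the response with the odd keycard. Reinstating a confirmed set after a
#' lapse keeps the rate of integration-error occasions in the range
#' observed empirically; a uniform re-choice there would inflate it.
#'
#' @param params an [agent_params()] object.
#' @param stream a `wcst_rng` stream supplying the agent's randomness.
#' @return a policy function suitable for [run_session()].
#' @export
make_agent_policy <- function(params, stream) {
  stopifnot(inherits(params, "wcst_agent_params"),
            inherits(stream, "wcst_rng"))
  st <- new.env(parent = emptyenv())
  st$candidate <- NA_integer_
  st$prev_target <- NULL
  st$d1 <- NA_integer_  # informative-error dimension, previous trial
  st$d0 <- NA_integer_  # informative-error dimension, trial before that
  st$confirmed <- NA_integer_  # set confirmed by the latest correct feedback

  function(target, ctx) {
    if (params$omniscient) return(target[ctx$rule])
    u <- stream_runif(stream, 3L)
    if (ctx$trial == 1L || is.na(st$candidate)) {
      st$candidate <- 1L + (u[1] >= 1 / 3) + (u[1] >= 2 / 3)
    } else if (isTRUE(ctx$prev_feedback)) {
      # set confirmed; lose it with probability p_sle
      st$d0 <- NA_integer_; st$d1 <- NA_integer_
      st$confirmed <- st$candidate
      if (u[1] < params$p_sle) {
        others <- which(seq_len(3L) != st$candidate)
        st$candidate <- others[1L + (u[2] >= 0.5)]
      }
    } else if (!is.na(ctx$prev_matched) && ctx$prev_matched == 0L) {
      # odd feedback disconfirms no dimension: keep candidate, break chains
      st$d0 <- NA_integer_; st$d1 <- NA_integer_
    } else if (!is.na(ctx$prev_matched)) {
      d <- ctx$prev_matched   # dimension disconfirmed on the previous trial
      st$d0 <- st$d1; st$d1 <- d
      if (!is.na(st$confirmed) && st$confirmed == d)
        st$confirmed <- NA_integer_
      repeated <- !is.null(st$prev_target) && target[d] == st$prev_target[d]
      p_pers <- if (repeated) params$p_pers_rep else params$p_pers_nonrep
      if (u[1] < p_pers) {
        st$candidate <- d
      } else if (!is.na(st$d0) && st$d0 != d) {
        third <- which(seq_len(3L) != st$d0 & seq_len(3L) != d)
        st$candidate <- if (u[2] < params$p_ie) st$d0 else third
      } else if (!is.na(st$confirmed)) {
        # the error was a lapse from a still-valid confirmed set: reinstate
        st$candidate <- st$confirmed
      } else {
        others <- which(seq_len(3L) != d)
        st$candidate <- others[1L + (u[2] >= 0.5)]
      }
    }
    st$prev_target <- target
    if (u[3] < params$p_oe) {
      return(setdiff(1:4, target)) # the keycard sharing no feature
    }
    target[st$candidate]
  }
}

#' The always-correct policy fixture
#'
#' Sorts by the covert rule on every trial; never errs, so the session can
#' only end at the trial cap.
#' @return a policy function.
#' @export
omniscient_policy <- function() {
  function(target, ctx) target[ctx$rule]
}

#' Simulate an independent cohort of synthetic participants
#'
#' Each agent receives its own session seed and agent-stream seed derived
#' deterministically from `master_seed`, so the cohort is reproducible and
#' agents are mutually independent.
#'
#' @param params an [agent_params()] object (shared by all agents).
#' @param n_agents cohort size.
#' @param config a [session_config()]; its `seed` field is overridden per
#'   agent.
#' @param master_seed integer master seed.
#' @param id_prefix participant-id prefix.
#' @return a list of `wcst_session` objects.
#' @export
simulate_cohort <- function(params, n_agents, config = session_config(),
                            master_seed = 1L, id_prefix = "agent") {
  stopifnot(n_agents >= 1)
  lapply(seq_len(n_agents), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, 2L * i)
    policy <- if (params$omniscient) omniscient_policy() else
      make_agent_policy(params,
                        new_rng_stream(derive_seed(master_seed, 2L * i + 1L)))
    run_session(policy, cfg,
                participant_id = sprintf("%s_%04d", id_prefix, i))
  })
}
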