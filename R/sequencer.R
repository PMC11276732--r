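# Constrained pseudo-random target sequencing.
#
# The next target card is drawn from the 24-card unambiguous deck subject to
# two constraints: (i) the same target never appears on two consecutive
# trials, and (ii) on any trial that follows an informative error -- error
# feedback that disconfirmed a specific dimension d -- a fair coin first
# selects whether the action-relevant feature on d repeats (a *repetitive*
# perseveration opportunity) or changes (*non-repetitive*), and the card is
# then drawn uniformly within the chosen stratum. This is the only mechanism
# that guarantees the 50/50 balance of the two opportunity types regardless
# of the participant's behavior. On all other trials the draw is uniform
# over the 23 legal cards.

#' Create a fresh sequencer state
#'
#' @param seed integer seed for the sequencer's private random stream.
#' @return an environment of class `wcst_sequencer`.
#' @export
new_sequencer_state <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$stream <- new_rng_stream(seed)
  e$prev_idx <- NA_integer_       # row index of previous card in the deck
  e$critical_dim <- NA_integer_   # dimension disconfirmed on previous trial
  class(e) <- "wcst_sequencer"
  e
}

#' Draw the next target card
#'
#' @param state a `wcst_sequencer` state (mutated in place).
#' @return a list with `card` (length-3 integer vector), `card_row` (deck row
#'   index) and `opportunity_tag` (`"REPETITIVE"`, `"NON_REPETITIVE"` or
#'   `"NEUTRAL"`).
#' @export
draw_next_target <- function(state) {
  deck <- the_deck()
  n <- nrow(deck)
  if (is.na(state$prev_idx)) {
    row <- stream_sample(state$stream, seq_len(n))
    tag <- "NEUTRAL"
  } else {
    if (state$prev_idx < 1L || state$prev_idx > n)
      stop("previous card is not a deck card", call. = FALSE)
    if (is.na(state$critical_dim)) {
      elig <- setdiff(seq_len(n), state$prev_idx)
      row <- stream_sample(state$stream, elig)
      tag <- "NEUTRAL"
    } else {
      d <- state$critical_dim
      prev_feat <- deck[state$prev_idx, d]
      repeat_stratum <- stream_runif(state$stream) < 0.5
      if (repeat_stratum) {
        elig <- setdiff(which(deck[, d] == prev_feat), state$prev_idx)
        tag <- "REPETITIVE"
      } else {
        elig <- which(deck[, d] != prev_feat)
        tag <- "NON_REPETITIVE"
      }
      row <- stream_sample(state$stream, elig)
    }
  }
  state$prev_idx <- row
  list(card = deck[row, ], card_row = row, opportunity_tag = tag)
}

#' Update the sequencer after feedback
#'
#' Sets the critical (disconfirmed) dimension when the completed trial was an
#' informative error; clears it after correct feedback or an odd response,
#' which disconfirm no single dimension.
#'
#' @param state a `wcst_sequencer` state (mutated in place).
#' @param matched_dim integer dimension id 1..3, or 0 for an odd response.
#' @param correct logical feedback of the completed trial.
#' @export
sequencer_observe_feedback <- function(state, matched_dim, correct) {
  state$critical_dim <-
    if (!correct && matched_dim >= 1L) as.integer(matched_dim) else NA_integer_
  invisible(state)
}
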