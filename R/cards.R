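# Card and keycard combinatorics.
#
# A card lives in a three-dimensional feature space (COLOR, SHAPE, NUMBER),
# each dimension instantiated by one of four features, encoded as indices
# 1..4. Keycard k carries index k on every dimension, so a card matches
# keycard k on dimension d iff its index on d equals k. A card is
# "unambiguous" iff its three indices are pairwise distinct: it then matches
# three different keycards (one per dimension) and shares no feature with
# the fourth, whose selection is an odd error.

#' The three sorting dimensions, in fixed order
#' @export
DIMENSIONS <- c("COLOR", "SHAPE", "NUMBER")

#' Response keys, left to right, mapped to keycard positions 1..4
#' @export
RESPONSE_KEYS <- c("Y", "C", "B", "M")

# presentation-layer feature labels; task logic uses indices only
FEATURE_LABELS <- list(
  COLOR  = c("red", "green", "yellow", "blue"),
  SHAPE  = c("triangle", "asterisk", "cross", "circle"),
  NUMBER = c("1", "2", "3", "4")
)

#' Construct a card from its three feature indices
#'
#' @param color_index,shape_index,number_index integers in 1..4.
#' @return integer vector of length 3 named by dimension, class `wcst_card`.
#' @export
wcst_card <- function(color_index, shape_index, number_index) {
  idx <- c(color_index, shape_index, number_index)
  if (length(idx) != 3L || anyNA(idx) || any(idx != as.integer(idx)) ||
      any(idx < 1L | idx > 4L))
    stop("card indices must be integers in 1..4", call. = FALSE)
  structure(setNames(as.integer(idx), DIMENSIONS), class = "wcst_card")
}

#' Is a card unambiguous (pairwise-distinct feature indices)?
#' @param card a card (integer vector of length 3).
#' @return logical scalar.
#' @export
is_unambiguous <- function(card) {
  length(unique(as.integer(card))) == 3L
}

#' The fixed panel of four keycards
#'
#' Keycard k bears the k-th feature on every dimension and sits under
#' response key Y, C, B or M (left to right).
#'
#' @return a data.frame with one row per keycard position.
#' @export
build_keycard_panel <- function() {
  structure(
    data.frame(
      position = 1:4,
      key = RESPONSE_KEYS,
      color_index = 1:4,
      shape_index = 1:4,
      number_index = 1:4,
      label = vapply(1:4, function(k) {
        shape <- FEATURE_LABELS$SHAPE[k]
        if (k > 1) shape <- paste0(shape, "s")
        paste(FEATURE_LABELS$NUMBER[k], FEATURE_LABELS$COLOR[k], shape)
      }, ""),
      stringsAsFactors = FALSE
    ),
    class = c("wcst_panel", "data.frame")
  )
}

#' Enumerate the deck of unambiguous target cards
#'
#' Exhausts all 4 x 4 x 4 index triples and keeps those with pairwise
#' distinct indices; exactly 24 such cards exist.
#'
#' @return an integer matrix with 24 rows and columns COLOR, SHAPE, NUMBER.
#' @export
enumerate_unambiguous_deck <- function() {
  g <- as.matrix(expand.grid(COLOR = 1:4, SHAPE = 1:4, NUMBER = 1:4))
  keep <- g[, 1] != g[, 2] & g[, 1] != g[, 3] & g[, 2] != g[, 3]
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# deck cached once; row order is the canonical card enumeration
.deck_cache <- new.env(parent = emptyenv())
the_deck <- function() {
  if (is.null(.deck_cache$deck)) .deck_cache$deck <- enumerate_unambiguous_deck()
  .deck_cache$deck
}

#' Classify a keycard choice against a target card
#'
#' @param target an unambiguous card (length-3 integer vector of indices).
#' @param keycard_position integer 1..4.
#' @return `"COLOR"`, `"SHAPE"`, `"NUMBER"`, or `"ODD"` when the chosen
#'   keycard shares no feature with the target.
#' @export
classify_response <- function(target, keycard_position) {
  tgt <- as.integer(target)
  if (length(tgt) != 3L || anyNA(tgt) || any(tgt < 1L | tgt > 4L))
    stop("target must be three feature indices in 1..4", call. = FALSE)
  if (!is_unambiguous(tgt))
    stop("ambiguous target card (two equal feature indices): corrupt input",
         call. = FALSE)
  if (length(keycard_position) != 1L || is.na(keycard_position) ||
      !(keycard_position %in% 1:4))
    stop("keycard_position must be a single integer in 1..4", call. = FALSE)
  hit <- which(tgt == as.integer(keycard_position))
  if (length(hit) == 0L) "ODD" else DIMENSIONS[hit]
}

# fast internal variant: returns dimension id 1..3 or 0L for ODD,
# assuming valid unambiguous target
classify_fast <- function(tgt, pos) {
  hit <- which(tgt == pos)
  if (length(hit) == 0L) 0L else hit
}
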