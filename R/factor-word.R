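## Constructors and plumbing for factor words (ordered lists of prime
## generators).

#' Build a factor word
#'
#' @param n Monoid parameter N shared by all factors.
#' @param kind Character vector of \code{"T"} / \code{"U"} kinds (recycled
#'   against \code{index} only when a scalar).
#' @param index Integer vector of generator indices in 1..N-1.
#' @return A [FactorList-class].
#' @examples
#' factorList(5, c("T", "T", "U"), c(3, 4, 2))
#' @export
factorList <- function(n, kind = character(0), index = integer(0)) {
  if (length(kind) == 1L && length(index) > 1L)
    kind <- rep(kind, length(index))
  x <- new("FactorList", n = as.integer(n), kind = as.character(kind),
           index = as.integer(index))
  validObject(x)
  x
}

#' Format a factor word as text
#'
#' Serializes a word as e.g. \code{"T3*T4*U2"}; [parseWord()] is the inverse.
#'
#' @param f A [FactorList-class].
#' @return A character scalar (\code{""} for the identity word).
#' @export
formatWord <- function(f) {
  stopifnot(is(f, "FactorList"))
  paste(paste0(f@kind, f@index), collapse = "*")
}

#' Parse a factor word from text
#'
#' @param text Word string such as \code{"T3*T4*U2"} (an empty string gives
#'   the identity word).
#' @param n Monoid parameter; inferred as \code{max(index) + 1} when
#'   \code{NULL}.
#' @return A [FactorList-class].
#' @export
parseWord <- function(text, n = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text))
    return(factorList(if (is.null(n)) 1L else n))
  tokens <- strsplit(text, "*", fixed = TRUE)[[1L]]
  ok <- grepl("^[TU][0-9]+$", tokens)
  if (!all(ok))
    stop(sprintf("malformed factor token '%s'", tokens[!ok][1L]))
  kind <- substr(tokens, 1L, 1L)
  index <- as.integer(substring(tokens, 2L))
  if (is.null(n)) n <- max(index) + 1L
  factorList(n, kind, index)
}

#' Concatenate factor words
#'
#' @param ... [FactorList-class] objects over the same N.
#' @return The concatenated [FactorList-class].
#' @export
concatWords <- function(...) {
  words <- list(...)
  stopifnot(length(words) > 0L, all(vapply(words, is, logical(1), "FactorList")))
  ns <- unique(vapply(words, function(w) w@n, integer(1)))
  if (length(ns) != 1L)
    stop("cannot concatenate words over different n")
  factorList(ns, unlist(lapply(words, function(w) w@kind)),
             unlist(lapply(words, function(w) w@index)))
}

#' Reverse a factor word
#'
#' The reverse \eqn{F^{-1}} of a word \eqn{P_{x_1} \circ \cdots \circ
#' P_{x_m}} is \eqn{P_{x_m} \circ \cdots \circ P_{x_1}}; for a word of
#' T-primes it composes to the inverse permutation, which is how the
#' big-hook heuristic records the factors it used for shrinking.
#'
#' @param f A [FactorList-class].
#' @return The reversed [FactorList-class].
#' @export
reverseWord <- function(f) {
  stopifnot(is(f, "FactorList"))
  factorList(f@n, rev(f@kind), rev(f@index))
}

#' Extract a subword
#'
#' @param f A [FactorList-class].
#' @param idx Integer positions to keep, in order.
#' @return A [FactorList-class].
#' @export
subWord <- function(f, idx) {
  stopifnot(is(f, "FactorList"))
  factorList(f@n, f@kind[idx], f@index[idx])
}

## number of T symbols in a word
.tCount <- function(f) sum(f@kind == "T")

.wordKey <- function(f) paste(paste0(f@kind, f@index), collapse = " ")
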