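## Native term-rewriting engine over the thirteen prime-tangle identities:
## delete rules R1-R10 strictly shorten a word, move rules R11-R13 preserve
## its length.  Minimization alternates exhaustive greedy deletion with a
## bounded breadth-first search of the move-closure for a state where a
## delete rule applies.

## Each rule: lhs length, a matcher over (kind, index) rows, and a rewriter
## returning the replacement rows.  i and j denote the indices of the first
## and second distinct factors of the matched span.
.ruleDefs <- list(
  R1  = list(kind = "delete", len = 2L,
             match = function(k, x) k[1L] == "T" && k[2L] == "T" && x[1L] == x[2L],
             rhs = function(k, x) list(kind = character(0), index = integer(0))),
  R2  = list(kind = "delete", len = 2L,
             match = function(k, x) k[1L] == "U" && k[2L] == "U" && x[1L] == x[2L],
             rhs = function(k, x) list(kind = "U", index = x[1L])),
  R3  = list(kind = "delete", len = 2L,
             match = function(k, x) k[1L] == "T" && k[2L] == "U" && x[1L] == x[2L],
             rhs = function(k, x) list(kind = "U", index = x[1L])),
  R4  = list(kind = "delete", len = 2L,
             match = function(k, x) k[1L] == "U" && k[2L] == "T" && x[1L] == x[2L],
             rhs = function(k, x) list(kind = "U", index = x[1L])),
  R5  = list(kind = "delete", len = 3L,
             match = function(k, x) all(k == c("U", "U", "U")) &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = "U", index = x[1L])),
  R6  = list(kind = "delete", len = 3L,
             match = function(k, x) all(k == c("U", "T", "U")) &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = "U", index = x[1L])),
  R7  = list(kind = "delete", len = 3L,
             match = function(k, x) all(k == c("T", "U", "U")) &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = c("T", "U"), index = c(x[2L], x[1L]))),
  R8  = list(kind = "delete", len = 3L,
             match = function(k, x) all(k == c("U", "U", "T")) &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = c("U", "T"), index = c(x[1L], x[2L]))),
  R9  = list(kind = "delete", len = 3L,
             match = function(k, x) all(k == c("U", "T", "T")) &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = c("U", "U"), index = c(x[1L], x[2L]))),
  R10 = list(kind = "delete", len = 3L,
             match = function(k, x) all(k == c("T", "T", "U")) &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = c("U", "U"), index = c(x[2L], x[1L]))),
  R11 = list(kind = "move", len = 3L,
             match = function(k, x) all(k == c("T", "T", "T")) &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = c("T", "T", "T"),
                                       index = c(x[2L], x[1L], x[2L]))),
  R12 = list(kind = "move", len = 3L,
             match = function(k, x) k[1L] == "T" && k[2L] == "U" && k[3L] == "T" &&
               x[1L] == x[3L] && abs(x[1L] - x[2L]) == 1L,
             rhs = function(k, x) list(kind = c("T", "U", "T"),
                                       index = c(x[2L], x[1L], x[2L]))),
  R13 = list(kind = "move", len = 2L,
             match = function(k, x) abs(x[1L] - x[2L]) > 1L,
             rhs = function(k, x) list(kind = k[2:1], index = x[2:1]))
)

#' Rewrite rules over prime factor words
#'
#' Tabulates the thirteen identities among prime tangles that the
#' minimization engine uses: ten delete rules that strictly shorten a word
#' and three move rules that preserve its length (the braid-like moves and
#' far commutation).  Every rule preserves the composed tangle.
#'
#' @return A data frame with columns \code{id}, \code{kind}, \code{length}.
#' @export
rewriteRules <- function() {
  data.frame(id = names(.ruleDefs),
             kind = vapply(.ruleDefs, `[[`, character(1), "kind"),
             length = vapply(.ruleDefs, `[[`, integer(1), "len"))
}

#' Apply one rewrite rule at a position
#'
#' @param w A [FactorList-class].
#' @param rule Rule id, \code{"R1"} .. \code{"R13"}.
#' @param pos 1-based position of the start of the matched span.
#' @return The rewritten [FactorList-class]; the composed tangle is
#'   unchanged.
#' @examples
#' applyRule(parseWord("U1*U2*U1", n = 3), "R5", 1)
#' @export
applyRule <- function(w, rule, pos) {
  stopifnot(is(w, "FactorList"))
  def <- .ruleDefs[[rule]]
  if (is.null(def)) stop(sprintf("unknown rule '%s'", rule))
  len <- def$len
  if (pos < 1L || pos + len - 1L > length(w))
    stop(sprintf("rule %s does not fit at position %d", rule, pos))
  span <- pos:(pos + len - 1L)
  k <- w@kind[span]; x <- w@index[span]
  if (!def$match(k, x))
    stop(sprintf("rule %s does not match at position %d", rule, pos))
  new <- def$rhs(k, x)
  factorList(w@n,
             c(w@kind[seq_len(pos - 1L)], new$kind,
               w@kind[seq_len(length(w) - pos - len + 1L) + pos + len - 1L]),
             c(w@index[seq_len(pos - 1L)], new$index,
               w@index[seq_len(length(w) - pos - len + 1L) + pos + len - 1L]))
}

## First applicable (pos, rule) with the given kinds, scanning positions left
## to right and rules in id order; NULL when none applies.
.findRule <- function(w, kinds) {
  ids <- names(.ruleDefs)[vapply(.ruleDefs, function(d) d$kind %in% kinds,
                                 logical(1))]
  L <- length(w)
  for (pos in seq_len(L)) {
    for (id in ids) {
      len <- .ruleDefs[[id]]$len
      if (pos + len - 1L > L) next
      span <- pos:(pos + len - 1L)
      if (.ruleDefs[[id]]$match(w@kind[span], w@index[span]))
        return(list(pos = pos, id = id))
    }
  }
  NULL
}

.allMoves <- function(w) {
  out <- list()
  L <- length(w)
  for (id in c("R11", "R12", "R13")) {
    len <- .ruleDefs[[id]]$len
    for (pos in seq_len(max(L - len + 1L, 0L))) {
      span <- pos:(pos + len - 1L)
      if (.ruleDefs[[id]]$match(w@kind[span], w@index[span]))
        out[[length(out) + 1L]] <- list(pos = pos, id = id)
    }
  }
  out
}

.traceRow <- function(rule, pos, before, after) {
  data.frame(rule = rule, pos = pos, before = before, after = after)
}

#' Put a word into commutation-canonical form
#'
#' Deterministic representative of a word's far-commutation (R13) class:
#' repeated bubble passes swap adjacent factors with \eqn{|i - j| > 1}
#' whenever the later factor sorts earlier under the (kind, index) order
#' (T before U, then by index).  Idempotent, and the composed tangle is
#' unchanged.
#'
#' @param w A [FactorList-class].
#' @return A [FactorList-class].
#' @export
commutationCanonical <- function(w) {
  stopifnot(is(w, "FactorList"))
  k <- w@kind; x <- w@index
  key <- function(kk, xx) ifelse(kk == "T", 0L, 1L) * 1000L + xx
  repeat {
    swapped <- FALSE
    for (p in seq_len(max(length(k) - 1L, 0L))) {
      if (abs(x[p] - x[p + 1L]) > 1L &&
          key(k[p + 1L], x[p + 1L]) < key(k[p], x[p])) {
        k[c(p, p + 1L)] <- k[c(p + 1L, p)]
        x[c(p, p + 1L)] <- x[c(p + 1L, p)]
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  factorList(w@n, k, x)
}

#' Minimize a factor word by rewriting
#'
#' Alternates two phases until neither makes progress: (1) greedy exhaustive
#' application of the delete rules (left-to-right, first match first), and
#' (2) a breadth-first search over words reachable by move rules alone,
#' looking for any state where a delete rule applies; when one is found the
#' moves on the path plus the delete are committed and phase 1 restarts.
#' The word is minimal-by-rewriting when no delete is reachable; if the
#' search exhausts the move-closure within the state budget this is
#' certified, otherwise \code{certified} is \code{FALSE}.  The result always
#' composes to the same tangle and is never longer than the input; a word
#' with no reachable delete is returned unchanged.
#'
#' @param w A [FactorList-class].
#' @param maxStates Maximum number of distinct words the move-closure search
#'   may visit per round.
#' @return A list with \code{word} (the minimized [FactorList-class]),
#'   \code{certified} (logical), and \code{trace} (data frame of applied
#'   steps with columns \code{rule}, \code{pos}, \code{before},
#'   \code{after}).
#' @examples
#' res <- minimizeWord(parseWord("T2*U1*U1*U2*U3*U1*U2*T4", n = 5))
#' formatWord(res$word)
#' @export
minimizeWord <- function(w, maxStates = 1e5) {
  stopifnot(is(w, "FactorList"))
  trace <- .traceRow(character(0), integer(0), character(0), character(0))
  certified <- TRUE
  repeat {
    ## phase 1: greedy deletes
    repeat {
      hit <- .findRule(w, "delete")
      if (is.null(hit)) break
      before <- formatWord(w)
      w <- applyRule(w, hit$id, hit$pos)
      trace <- rbind(trace, .traceRow(hit$id, hit$pos, before, formatWord(w)))
    }
    if (length(w) == 0L) break
    ## phase 2: BFS over the move-closure for a reachable delete
    startKey <- .wordKey(w)
    visited <- new.env(parent = emptyenv())
    assign(startKey, TRUE, envir = visited)
    queue <- list(list(word = w, path = list()))
    qhead <- 1L
    nVisited <- 1L
    foundPath <- NULL
    while (qhead <= length(queue)) {
      state <- queue[[qhead]]; qhead <- qhead + 1L
      del <- .findRule(state$word, "delete")
      if (!is.null(del)) {
        foundPath <- c(state$path, list(list(pos = del$pos, id = del$id)))
        break
      }
      if (nVisited >= maxStates) { certified <- FALSE; break }
      for (mv in .allMoves(state$word)) {
        w2 <- applyRule(state$word, mv$id, mv$pos)
        key <- .wordKey(w2)
        if (!exists(key, envir = visited, inherits = FALSE)) {
          assign(key, TRUE, envir = visited)
          nVisited <- nVisited + 1L
          queue[[length(queue) + 1L]] <-
            list(word = w2, path = c(state$path, list(mv)))
        }
      }
    }
    if (is.null(foundPath)) break
    for (stp in foundPath) {
      before <- formatWord(w)
      w <- applyRule(w, stp$id, stp$pos)
      trace <- rbind(trace, .traceRow(stp$id, stp$pos, before, formatWord(w)))
    }
  }
  list(word = w, certified = certified, trace = trace)
}
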