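## Ground-truth minimal factorizations for small N: breadth-first search
## over the Cayley graph of the Brauer monoid under right multiplication by
## the prime generators.  Used as the independent standard the heuristic
## factorizer is tested against.

.oracleCache <- new.env(parent = emptyenv())

## BFS from the identity; for every reachable tangle store the shortest
## word length together with parent pointers for reconstruction.
.cayleyIndex <- function(n) {
  key <- as.character(n)
  cached <- .oracleCache[[key]]
  if (!is.null(cached)) return(cached)
  primes <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    primes[[length(primes) + 1L]] <- list(kind = "T", i = i,
                                          tangle = primeTangle("T", i, n))
    primes[[length(primes) + 1L]] <- list(kind = "U", i = i,
                                          tangle = primeTangle("U", i, n))
  }
  dist <- new.env(parent = emptyenv())
  parent <- new.env(parent = emptyenv())
  id <- identityTangle(n)
  idKey <- formatInvariant(id)
  assign(idKey, 0L, envir = dist)
  queue <- list(id)
  qhead <- 1L
  while (qhead <= length(queue)) {
    cur <- queue[[qhead]]; qhead <- qhead + 1L
    curKey <- formatInvariant(cur)
    d <- get(curKey, envir = dist)
    for (p in primes) {
      nxt <- composeTangles(cur, p$tangle)
      nxtKey <- formatInvariant(nxt)
      if (!exists(nxtKey, envir = dist, inherits = FALSE)) {
        assign(nxtKey, d + 1L, envir = dist)
        assign(nxtKey, list(from = curKey, kind = p$kind, i = p$i),
               envir = parent)
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  out <- list(n = n, dist = dist, parent = parent)
  .oracleCache[[key]] <- out
  out
}

#' Shortest factor word by exhaustive search
#'
#' Breadth-first search over the Cayley graph of \eqn{B_n} from the identity,
#' right-multiplying by the 2(n-1) prime generators, yields a provably
#' shortest word for every tangle.  Only feasible at small n (the monoid has
#' (2n-1)!! elements; 945 at n = 5), but independent of every heuristic in
#' the package, which makes it the reference that certifies them.
#'
#' @param x A [Tangle-class] with \code{nStrands(x) <= bound}.
#' @param bound Largest n the oracle will attempt (default 5).
#' @return A shortest [FactorList-class] composing to \code{x}.
#' @examples
#' formatWord(bfsMinimalWord(parseInvariant("1:1',2:4,3:5',5:4',2':3'")))
#' @export
bfsMinimalWord <- function(x, bound = 5L) {
  stopifnot(is(x, "Tangle"))
  n <- x@n
  if (n > bound)
    stop(sprintf("n = %d exceeds the oracle bound %d ((2n-1)!! growth)", n, bound))
  if (n == 0L) return(factorList(0L))
  idx <- .cayleyIndex(n)
  key <- formatInvariant(x)
  if (!exists(key, envir = idx$dist, inherits = FALSE))
    stop("internal error: tangle not reached by the Cayley BFS")
  kinds <- character(0); is <- integer(0)
  while (key != formatInvariant(identityTangle(n))) {
    p <- get(key, envir = idx$parent)
    kinds <- c(p$kind, kinds)
    is <- c(p$i, is)
    key <- p$from
  }
  word <- factorList(n, kinds, is)
  stopifnot(.sameTangle(composeFactors(word), x))
  word
}

#' Length of the shortest factor word
#'
#' @param x A [Tangle-class].
#' @param bound Largest n the oracle will attempt.
#' @return A single integer: the minimal factorization length of \code{x}.
#' @export
minimalWordLength <- function(x, bound = 5L) {
  stopifnot(is(x, "Tangle"))
  if (x@n == 0L) return(0L)
  if (x@n > bound)
    stop(sprintf("n = %d exceeds the oracle bound %d", x@n, bound))
  idx <- .cayleyIndex(x@n)
  get(formatInvariant(x), envir = idx$dist)
}
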