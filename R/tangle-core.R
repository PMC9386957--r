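## Core Brauer-monoid operations: invariant parsing/formatting, prime
## generators, diagram composition, crossing number, classification and
## exhaustive enumeration.

.edgeLabel <- function(e) {
  lab <- function(d) if (d > 0L) as.character(d) else paste0(abs(d), "'")
  paste0(lab(e[1L]), ":", lab(e[2L]))
}

.edgeClass <- function(e) {
  a <- e[1L]; b <- e[2L]
  if (a > 0L && b > 0L) return("upper hook")
  if (a < 0L && b < 0L) return("lower hook")
  top <- abs(if (a > 0L) a else b)
  bot <- abs(if (a > 0L) b else a)
  if (top > bot) "positive transversal"
  else if (top < bot) "negative transversal"
  else "zero transversal"
}

.newTangle <- function(n, edges) {
  new("Tangle", n = as.integer(n),
      edges = .canonicalEdges(matrix(as.integer(edges), ncol = 2L)))
}

#' Construct a tangle from explicit edges
#'
#' Low-level constructor.  Edges are given as a two-column matrix (or a
#' flat vector of pairs) in the signed dot encoding: top dot i is \code{i},
#' bottom dot i' is \code{-i}.
#'
#' @param n Dots per row.
#' @param edges Two-column integer matrix (or length-2n vector) of edges.
#' @return A validated [Tangle-class].
#' @examples
#' newTangle(2, rbind(c(1, 2), c(-1, -2)))  # the hook prime U_1
#' @export
newTangle <- function(n, edges) {
  x <- .newTangle(n, edges)
  validObject(x)
  x
}

#' Parse a tangle invariant string
#'
#' Reads the textual edge enumeration of a tangle, e.g.
#' \code{"1:2,3:2',4:3',1':4'"}: edges are comma-separated, the two dots of
#' an edge are colon-separated, and an ASCII apostrophe marks a bottom-row
#' dot.
#'
#' @param text Invariant string.
#' @param n Dots per row; inferred as the largest index when \code{NULL}.
#' @return A [Tangle-class].
#' @examples
#' parseInvariant("1:1',2:2',3:3',4:4'")  # the identity of B_4
#' @export
parseInvariant <- function(text, n = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) {
    if (is.null(n)) n <- 0L
    if (n != 0L) stop("empty invariant only denotes the empty tangle (n = 0)")
    return(.newTangle(0L, integer(0)))
  }
  tokens <- strsplit(text, ",", fixed = TRUE)[[1L]]
  parseDot <- function(s, token) {
    m <- regmatches(s, regexec("^([0-9]+)(')?$", s))[[1L]]
    if (length(m) == 0L || m[2L] == "")
      stop(sprintf("malformed token '%s' in invariant", token))
    idx <- as.integer(m[2L])
    if (idx < 1L) stop(sprintf("index out of range in token '%s'", token))
    if (m[3L] == "'") -idx else idx
  }
  edges <- matrix(0L, nrow = length(tokens), ncol = 2L)
  for (k in seq_along(tokens)) {
    parts <- strsplit(tokens[k], ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed token '%s' in invariant", tokens[k]))
    a <- parseDot(parts[1L], tokens[k])
    b <- parseDot(parts[2L], tokens[k])
    if (a == b)
      stop(sprintf("dot %s repeated within edge '%s'", parts[1L], tokens[k]))
    edges[k, ] <- c(a, b)
  }
  inferred <- max(abs(edges))
  if (is.null(n)) n <- inferred
  if (inferred > n)
    stop(sprintf("index %d out of range for n = %d", inferred, n))
  dotLabel <- function(d) if (d > 0L) as.character(d) else paste0(abs(d), "'")
  dots <- as.vector(edges)
  dup <- dots[duplicated(dots)]
  if (length(dup))
    stop(sprintf("dot %s occurs in more than one edge", dotLabel(dup[1L])))
  missing <- setdiff(c(seq_len(n), -seq_len(n)), dots)
  if (length(missing))
    stop(sprintf("dot %s is missing from the invariant", dotLabel(missing[1L])))
  x <- .newTangle(n, edges)
  validObject(x)
  x
}

#' Format a tangle as its canonical invariant string
#'
#' The inverse of [parseInvariant()]: edges are emitted in canonical order
#' (top dots before bottom dots, ascending index), so
#' \code{parseInvariant(formatInvariant(x))} reproduces \code{x} exactly.
#'
#' @param x A [Tangle-class].
#' @return A character scalar.
#' @export
formatInvariant <- function(x) {
  stopifnot(is(x, "Tangle"))
  if (x@n == 0L) return("")
  paste(apply(x@edges, 1L, .edgeLabel), collapse = ",")
}

#' Identity tangle
#'
#' @param n Dots per row.
#' @return The identity of \eqn{B_n}: all zero transversals i:i'.
#' @export
identityTangle <- function(n) {
  n <- as.integer(n)
  .newTangle(n, cbind(seq_len(n), -seq_len(n)))
}

#' Prime generator tangles
#'
#' The two families of prime tangles generating the Brauer monoid:
#' \eqn{T_i} crosses strands i and i+1 (edges i:(i+1)' and (i+1):i'), and
#' \eqn{U_i} breaks them into an adjacent upper hook i:(i+1) and lower hook
#' i':(i+1)'.  All other strands pass straight through.
#'
#' @param kind \code{"T"} or \code{"U"}.
#' @param i Generator index, 1 <= i <= n-1.
#' @param n Dots per row.
#' @return A [Tangle-class].
#' @examples
#' formatInvariant(primeTangle("U", 5, 6))
#' @export
primeTangle <- function(kind, i, n) {
  kind <- match.arg(kind, c("T", "U"))
  i <- as.integer(i); n <- as.integer(n)
  if (i < 1L || i > n - 1L)
    stop(sprintf("prime index %d out of range 1..%d", i, n - 1L))
  others <- setdiff(seq_len(n), c(i, i + 1L))
  straight <- cbind(others, -others)
  special <- if (kind == "T") {
    rbind(c(i, -(i + 1L)), c(i + 1L, -i))
  } else {
    rbind(c(i, i + 1L), c(-i, -(i + 1L)))
  }
  .newTangle(n, rbind(straight, special))
}

#' Compose two tangles
#'
#' Stacks \code{x} on top of \code{y}, identifies the bottom row of \code{x}
#' with the top row of \code{y}, and reads off the resulting matching on the
#' outer boundary.  Closed loops formed entirely in the identified middle row
#' are discarded (the monoid quotient) but counted.
#'
#' @param x,y [Tangle-class] objects with equal \code{n}.
#' @param loops If \code{TRUE}, return \code{list(tangle =, loops =)} with the
#'   number of discarded closed loops; otherwise return the tangle alone.
#' @return A [Tangle-class], or a list when \code{loops = TRUE}.
#' @examples
#' u2 <- primeTangle("U", 2, 4)
#' composeTangles(u2, u2, loops = TRUE)  # U_2 again, one closed loop
#' @export
composeTangles <- function(x, y, loops = FALSE) {
  stopifnot(is(x, "Tangle"), is(y, "Tangle"))
  n <- x@n
  if (y@n != n)
    stop(sprintf("cannot compose tangles with n = %d and n = %d", n, y@n))
  if (n == 0L) {
    out <- .newTangle(0L, integer(0))
    return(if (loops) list(tangle = out, loops = 0L) else out)
  }
  ## node ids: top boundary 1..n, bottom boundary n+1..2n, middle 2n+1..3n
  nodeOf <- function(d, fromX) {
    if (fromX) { if (d > 0L) d else 2L * n + abs(d) }
    else { if (d > 0L) 2L * n + d else n + abs(d) }
  }
  m <- 2L * n                          # total number of diagram edges
  eu <- integer(m); ev <- integer(m)
  for (k in seq_len(n)) {
    eu[k] <- nodeOf(x@edges[k, 1L], TRUE)
    ev[k] <- nodeOf(x@edges[k, 2L], TRUE)
    eu[n + k] <- nodeOf(y@edges[k, 1L], FALSE)
    ev[n + k] <- nodeOf(y@edges[k, 2L], FALSE)
  }
  incident <- vector("list", 3L * n)
  for (k in seq_len(m)) {
    incident[[eu[k]]] <- c(incident[[eu[k]]], k)
    incident[[ev[k]]] <- c(incident[[ev[k]]], k)
  }
  used <- logical(m)
  newEdges <- matrix(0L, nrow = n, ncol = 2L)
  found <- 0L
  boundaryDot <- function(node) if (node <= n) node else -(node - n)
  for (start in seq_len(2L * n)) {
    k <- incident[[start]][1L]
    if (used[k]) next
    cur <- start
    repeat {
      used[k] <- TRUE
      nxt <- if (eu[k] == cur) ev[k] else eu[k]
      if (nxt <= 2L * n) break
      inc <- incident[[nxt]]
      k <- if (used[inc[1L]]) inc[2L] else inc[1L]
      cur <- nxt
    }
    found <- found + 1L
    newEdges[found, ] <- c(boundaryDot(start), boundaryDot(nxt))
  }
  nloops <- 0L
  for (k in seq_len(m)) {
    if (used[k]) next
    nloops <- nloops + 1L
    j <- k
    cur <- eu[k]
    repeat {
      used[j] <- TRUE
      nxt <- if (eu[j] == cur) ev[j] else eu[j]
      inc <- incident[[nxt]]
      inc <- inc[!used[inc]]
      if (length(inc) == 0L) break
      j <- inc[1L]
      cur <- nxt
    }
  }
  out <- .newTangle(n, newEdges)
  if (loops) list(tangle = out, loops = nloops) else out
}

#' Compose a factor word into a tangle
#'
#' Left-to-right fold of [composeTangles()] over the prime tangles of a word.
#' The empty word gives the identity.
#'
#' @param f A [FactorList-class].
#' @return A [Tangle-class].
#' @export
composeFactors <- function(f) {
  stopifnot(is(f, "FactorList"))
  x <- identityTangle(f@n)
  for (k in seq_along(f@kind))
    x <- composeTangles(x, primeTangle(f@kind[k], f@index[k], f@n))
  x
}

## Cyclic boundary position of a signed dot: top dots 1..n left to right,
## then bottom dots n'..1' continuing clockwise, so i -> i and j' -> 2n-j+1.
.cyclicPos <- function(d, n) ifelse(d > 0L, d, 2L * n - abs(d) + 1L)

.interleaves <- function(p1, q1, p2, q2) {
  if (p1 > q1) { t <- p1; p1 <- q1; q1 <- t }
  if (p2 > q2) { t <- p2; p2 <- q2; q2 <- t }
  (p1 < p2 & p2 < q1 & q1 < q2) | (p2 < p1 & p1 < q2 & q2 < q1)
}

#' Crossing number of a tangle
#'
#' The number of unordered edge pairs whose endpoints interleave in the
#' cyclic boundary order 1, ..., N, N', (N-1)', ..., 1'.  This is the number
#' of crossings in a minimally drawn diagram; crossings are introduced only
#' by \eqn{T}-primes, so it equals the number of T factors in any minimal
#' factor word.
#'
#' @param x A [Tangle-class].
#' @return A single non-negative integer.
#' @export
crossingNumber <- function(x) {
  stopifnot(is(x, "Tangle"))
  n <- x@n
  if (n < 2L) return(0L)
  p <- .cyclicPos(x@edges[, 1L], n)
  q <- .cyclicPos(x@edges[, 2L], n)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (.interleaves(p[i], q[i], p[j], q[j])) count <- count + 1L
    }
  }
  count
}

#' Classify a tangle
#'
#' Assigns one of the four classes steering the factorization dispatcher,
#' with precedence T, TL, U, H (the classes overlap; e.g. every TL-tangle
#' has a size-1 lower hook, so it would also qualify as U):
#' \describe{
#'   \item{T}{all edges are transversals; factorizable by T-primes alone.}
#'   \item{TL}{crossing-free (Temperley-Lieb); factorizable by U-primes
#'     alone.}
#'   \item{U}{has a lower hook of size 1, so a \eqn{U_i} can be peeled off
#'     the right.}
#'   \item{H}{everything else; always has a lower hook of size > 1 that must
#'     first be shrunk.}
#' }
#'
#' @param x A [Tangle-class].
#' @return One of \code{"T"}, \code{"TL"}, \code{"U"}, \code{"H"}.
#' @export
classifyTangle <- function(x) {
  stopifnot(is(x, "Tangle"))
  e <- x@edges
  if (x@n == 0L || all((e[, 1L] > 0L) != (e[, 2L] > 0L))) return("T")
  if (crossingNumber(x) == 0L) return("TL")
  lower <- e[, 1L] < 0L & e[, 2L] < 0L
  if (any(abs(abs(e[lower, 1L]) - abs(e[lower, 2L])) == 1L)) return("U")
  "H"
}

#' Enumerate all tangles of a small Brauer monoid
#'
#' Generates every perfect matching on the 2n dots exactly once; there are
#' \eqn{(2n-1)!!} of them, of which the crossing-free ones number the Catalan
#' number \eqn{C_n}.
#'
#' @param n Dots per row.
#' @param bound Refuse to enumerate beyond this n (double factorial growth).
#' @return A list of [Tangle-class] objects.
#' @examples
#' length(enumerateTangles(3))  # 15
#' @export
enumerateTangles <- function(n, bound = 5L) {
  n <- as.integer(n)
  if (n > bound)
    stop(sprintf("n = %d exceeds the enumeration bound %d", n, bound))
  if (n == 0L) return(list(.newTangle(0L, integer(0))))
  dots <- c(seq_len(n), -seq_len(n))
  out <- list()
  recurse <- function(remaining, acc) {
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- .newTangle(n, do.call(rbind, acc))
      return(invisible())
    }
    a <- remaining[1L]
    for (k in seq_along(remaining)[-1L]) {
      recurse(remaining[-c(1L, k)], c(acc, list(c(a, remaining[k]))))
    }
  }
  recurse(dots, list())
  out
}

#' Serialize / deserialize a tangle as JSON
#'
#' The JSON form is \code{{"n": int, "edges": [[a, b], ...]}} with bottom
#' dots encoded as negative integers, matching the internal representation.
#'
#' @param x A [Tangle-class].
#' @param text JSON string.
#' @return \code{tangleToJSON}: a JSON character scalar;
#'   \code{tangleFromJSON}: a [Tangle-class].
#' @export
tangleToJSON <- function(x) {
  stopifnot(is(x, "Tangle"))
  as.character(jsonlite::toJSON(
    list(n = x@n, edges = unname(apply(x@edges, 1L, identity, simplify = FALSE))),
    auto_unbox = TRUE))
}

#' @rdname tangleToJSON
#' @export
tangleFromJSON <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyMatrix = TRUE)
  e <- obj$edges
  edges <- if (is.matrix(e)) {
    matrix(as.integer(e), ncol = 2L)
  } else if (is.list(e)) {
    do.call(rbind, lapply(e, as.integer))
  } else {
    matrix(as.integer(e), ncol = 2L, byrow = TRUE)
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  newTangle(obj$n, edges)
}
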