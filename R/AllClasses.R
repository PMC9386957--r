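#' @import methods
NULL

## Internal dot encoding: a dot on the top row with index i is stored as +i,
## a dot on the bottom row (primed, i') as -i.  Edge rows are kept in canonical
## order (top dots before bottom dots, ascending index) and the edge matrix is
## sorted by that order, so identical tangles have identical representations.

.dotKey <- function(d) ifelse(d > 0L, abs(d), 1e6 + abs(d))

.canonicalEdges <- function(edges) {
  if (nrow(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  swap <- .dotKey(edges[, 1L]) > .dotKey(edges[, 2L])
  tmp <- edges[swap, 1L]
  edges[swap, 1L] <- edges[swap, 2L]
  edges[swap, 2L] <- tmp
  ord <- order(.dotKey(edges[, 1L]), .dotKey(edges[, 2L]))
  edges <- edges[ord, , drop = FALSE]
  dimnames(edges) <- list(NULL, c("a", "b"))
  edges
}

#' Tangle of the Brauer monoid
#'
#' A tangle in the Brauer monoid \eqn{B_N} is a perfect matching on 2N dots
#' arranged in two rows of N: a top row labelled 1..N and a bottom row
#' labelled 1'..N'.  Each matched pair is an edge; edges joining the two rows
#' are transversals, edges within a row are hooks.  Internally the top dot i
#' is stored as the integer \code{i} and the bottom dot i' as \code{-i}.
#'
#' @slot n Number of dots per row (a single non-negative integer; \code{n = 0}
#'   gives the empty tangle, used for structures without base pairs).
#' @slot edges Integer matrix with \code{n} rows and two columns holding the
#'   signed dot encoding of each edge, in canonical order.
#'
#' @seealso [parseInvariant()], [primeTangle()], [composeTangles()]
#' @export
setClass("Tangle", representation(n = "integer", edges = "matrix"))

setValidity("Tangle", function(object) {
  n <- object@n
  e <- object@edges
  if (length(n) != 1L || is.na(n) || n < 0L)
    return("'n' must be a single non-negative integer")
  if (!is.integer(e) || ncol(e) != 2L)
    return("'edges' must be a two-column integer matrix")
  if (nrow(e) != n)
    return(sprintf("a tangle in B_%d must have exactly %d edges", n, n))
  dots <- as.vector(e)
  if (any(dots == 0L) || any(abs(dots) > n))
    return("edge endpoints must be non-zero and within 1..n in absolute value")
  expected <- c(seq_len(n), -seq_len(n))
  if (n > 0L && !setequal(dots, expected))
    return("every one of the 2n dots must occur in exactly one edge")
  if (anyDuplicated(dots))
    return("a dot occurs in more than one edge")
  TRUE
})

#' Word of prime tangle factors
#'
#' An ordered word of prime generators of the Brauer monoid \eqn{B_N}.  The
#' generators are the crossing primes \eqn{T_i} (an adjacent transposition of
#' strands i, i+1) and the hook primes \eqn{U_i} (an adjacent upper and lower
#' hook at i, i+1), for \eqn{1 \le i \le N-1}.  The empty word denotes the
#' identity tangle.
#'
#' @slot n The monoid parameter N shared by every factor.
#' @slot kind Character vector of factor kinds, each \code{"T"} or \code{"U"}.
#' @slot index Integer vector of factor indices, each in 1..N-1.
#'
#' @seealso [factorList()], [composeFactors()], [minimizeWord()]
#' @export
setClass("FactorList",
         representation(n = "integer", kind = "character", index = "integer"))

setValidity("FactorList", function(object) {
  if (length(object@n) != 1L || is.na(object@n) || object@n < 0L)
    return("'n' must be a single non-negative integer")
  if (length(object@kind) != length(object@index))
    return("'kind' and 'index' must have equal length")
  if (!all(object@kind %in% c("T", "U")))
    return("factor kinds must be 'T' or 'U'")
  if (length(object@index) &&
      (any(object@index < 1L) || any(object@index > object@n - 1L)))
    return("factor indices must lie in 1..n-1")
  TRUE
})

#' RNA secondary structure
#'
#' Base-paired positions of an RNA molecule of a given length.  Each position
#' takes part in at most one pair and pairs are stored with i < j.  Crossing
#' pairs (pseudoknots) are allowed.
#'
#' @slot length Number of nucleotide positions.
#' @slot pairs Two-column integer matrix of paired positions (i < j).
#' @slot sequence Optional nucleotide string of the same length
#'   (\code{NA_character_} when absent).
#'
#' @seealso [parseDotBracket()], [parseBpseq()], [toArcDiagram()]
#' @export
setClass("SecondaryStructure",
         representation(length = "integer", pairs = "matrix",
                        sequence = "character"))

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  if (!is.integer(p) || ncol(p) != 2L)
    return("'pairs' must be a two-column integer matrix")
  if (nrow(p)) {
    if (any(p < 1L) || any(p > object@length))
      return("paired positions must lie within 1..length")
    if (any(p[, 1L] >= p[, 2L]))
      return("pairs must satisfy i < j")
    if (anyDuplicated(as.vector(p)))
      return("a position occurs in more than one pair")
  }
  if (!is.na(object@sequence) && nchar(object@sequence) != object@length)
    return("'sequence' must match 'length'")
  TRUE
})

#' Arc diagram over paired positions
#'
#' A flattened diagram: 2N dots on a line joined by N arcs in the upper half
#' plane.  Produced from a [SecondaryStructure-class] by dropping unpaired
#' positions, and reduced to a shape by collapsing stacked arcs.  The
#' \code{origins} list records, per arc, the original position pairs it
#' abbreviates.
#'
#' @slot numDots Number of dots (always even, 2N).
#' @slot arcs Two-column integer matrix of arcs (p < q) forming a perfect
#'   matching on 1..numDots.
#' @slot origins List of two-column integer matrices, one per arc row, holding
#'   the original (i, j) sequence positions the arc stands for.
#'
#' @seealso [toArcDiagram()], [reduceToShape()], [foldToTangle()]
#' @export
setClass("ArcDiagram",
         representation(numDots = "integer", arcs = "matrix",
                        origins = "list"))

setValidity("ArcDiagram", function(object) {
  a <- object@arcs
  if (!is.integer(a) || ncol(a) != 2L)
    return("'arcs' must be a two-column integer matrix")
  if (object@numDots %% 2L != 0L)
    return("'numDots' must be even")
  if (nrow(a) * 2L != object@numDots)
    return("every dot must lie on exactly one arc")
  if (nrow(a)) {
    if (any(a[, 1L] >= a[, 2L]))
      return("arcs must satisfy p < q")
    if (!setequal(as.vector(a), seq_len(object@numDots)))
      return("arcs must form a perfect matching on 1..numDots")
  }
  if (length(object@origins) != nrow(a))
    return("'origins' must have one entry per arc")
  TRUE
})

#' Pipeline report
#'
#' The assembled result of running the full analysis on one input: the parsed
#' structure, its shape, the folded tangle, its class, the raw and minimized
#' factor words, the crossing number, and the per-edge generator map.
#'
#' @slot input Character scalar echo of the input.
#' @slot format Input format that was parsed.
#' @slot structure The [SecondaryStructure-class], or \code{NULL} when the
#'   input was a raw tangle invariant.
#' @slot shape The reduced [ArcDiagram-class], or \code{NULL}.
#' @slot positionMap Data frame linking tangle dots to original sequence
#'   positions (empty for invariant input).
#' @slot tangle The [Tangle-class].
#' @slot tangleClass One of \code{"T"}, \code{"TL"}, \code{"U"}, \code{"H"}.
#' @slot rawWord,minimizedWord [FactorList-class] before and after rewriting.
#' @slot certifiedMinimal Logical: was the move-closure search exhausted?
#' @slot crossingNumber Crossing number of the tangle.
#' @slot generators Named list mapping edge labels to data frames of the
#'   factors that generate them.
#' @slot trace Data frame of rewrite steps (empty unless tracing was on).
#'
#' @seealso [runPipeline()]
#' @export
setClass("TangleReport",
         representation(input = "character", format = "character",
                        structure = "ANY", shape = "ANY",
                        positionMap = "data.frame", tangle = "Tangle",
                        tangleClass = "character", rawWord = "FactorList",
                        minimizedWord = "FactorList",
                        certifiedMinimal = "logical",
                        crossingNumber = "integer", generators = "list",
                        trace = "data.frame"))
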