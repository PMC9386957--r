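#' Number of strands (dots per row)
#'
#' The monoid parameter N of a tangle, factor word, or report.
#'
#' @param x A [Tangle-class], [FactorList-class], or [TangleReport-class].
#' @return A single integer.
#' @export
setGeneric("nStrands", function(x) standardGeneric("nStrands"))

#' @rdname nStrands
#' @export
setMethod("nStrands", "Tangle", function(x) x@n)

#' @rdname nStrands
#' @export
setMethod("nStrands", "FactorList", function(x) x@n)

#' @rdname nStrands
#' @export
setMethod("nStrands", "TangleReport", function(x) x@tangle@n)

#' Edge table of a tangle
#'
#' Tabulates the edges of a tangle with their labels, derived class
#' (positive/negative/zero transversal, upper/lower hook) and size
#' \eqn{|a - b|}.
#'
#' @param x A [Tangle-class].
#' @return A data frame with columns \code{a}, \code{b} (signed dot encoding,
#'   bottom dots negative), \code{label}, \code{class} and \code{size}.
#' @examples
#' edgeTable(parseInvariant("1:2,3:2',4:3',1':4'"))
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "Tangle", function(x) {
  e <- x@edges
  data.frame(a = e[, 1L], b = e[, 2L],
             label = apply(e, 1L, .edgeLabel),
             class = apply(e, 1L, .edgeClass),
             size = abs(abs(e[, 1L]) - abs(e[, 2L])))
})

#' @describeIn FactorList-class Word length (number of prime factors).
#' @param x A \code{FactorList}.
#' @export
setMethod("length", "FactorList", function(x) length(x@kind))

setMethod("show", "Tangle", function(object) {
  cat(sprintf("Tangle in B_%d: %s\n", object@n,
              if (object@n) formatInvariant(object) else "(empty)"))
  invisible(object)
})

setMethod("show", "FactorList", function(object) {
  cat(sprintf("FactorList over B_%d (length %d): %s\n", object@n,
              length(object),
              if (length(object)) formatWord(object) else "(identity)"))
  invisible(object)
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d nt, %d base pairs%s\n",
              object@length, nrow(object@pairs),
              if (.hasCrossingPairs(object@pairs)) " (pseudoknotted)" else ""))
  invisible(object)
})

setMethod("show", "ArcDiagram", function(object) {
  cat(sprintf("ArcDiagram: %d dots, %d arcs\n", object@numDots,
              nrow(object@arcs)))
  invisible(object)
})

setMethod("show", "TangleReport", function(object) {
  cat("RNA tangle factorization report\n")
  cat(sprintf("  input (%s): %s\n", object@format,
              .truncateEcho(object@input)))
  cat(sprintf("  tangle:  %s\n",
              if (object@tangle@n) formatInvariant(object@tangle) else "(empty)"))
  cat(sprintf("  class:   %s-tangle   crossings: %d\n", object@tangleClass,
              object@crossingNumber))
  cat(sprintf("  raw word:       %s\n",
              if (length(object@rawWord)) formatWord(object@rawWord) else "(identity)"))
  cat(sprintf("  minimized word: %s%s\n",
              if (length(object@minimizedWord)) formatWord(object@minimizedWord) else "(identity)",
              if (object@certifiedMinimal) "  [certified minimal]" else ""))
  invisible(object)
})

.truncateEcho <- function(x) {
  x <- gsub("\n", " / ", x)
  if (nchar(x) > 60) paste0(substr(x, 1, 57), "...") else x
}
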