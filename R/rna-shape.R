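## The secondary-structure-to-tangle mapping: dot-bracket and BPSEQ parsing,
## flattening to an arc diagram, shape reduction (collapse stacked arcs), and
## the book-fold into a Brauer tangle.

.bracketPages <- local({
  openers <- c("(", "[", "{", "<", LETTERS)
  closers <- c(")", "]", "}", ">", letters)
  list(openers = openers, closers = closers)
})

.hasCrossingPairs <- function(pairs) {
  m <- nrow(pairs)
  if (m < 2L) return(FALSE)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (.interleaves(pairs[i, 1L], pairs[i, 2L], pairs[j, 1L], pairs[j, 2L]))
        return(TRUE)
    }
  }
  FALSE
}

#' Parse extended dot-bracket notation
#'
#' Reads a secondary structure from Vienna-style dot-bracket text.  Dots are
#' unpaired positions; each bracket page -- \code{()}, \code{[]}, \code{\{\}},
#' \code{<>} and the letter pairs \code{Aa}..\code{Zz} -- is matched
#' independently by stack discipline, so crossing pairs (pseudoknots) are
#' expressed by putting the crossing arcs on different pages.
#'
#' @param text Structure string.
#' @param sequence Optional nucleotide string of the same length.
#' @return A [SecondaryStructure-class].
#' @examples
#' parseDotBracket("([)]")  # a minimal pseudoknot: pairs (1,3) and (2,4)
#' @export
parseDotBracket <- function(text, sequence = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  stacks <- vector("list", length(.bracketPages$openers))
  pairs <- list()
  for (pos in seq_len(L)) {
    ch <- chars[pos]
    if (ch %in% c(".", "-", "_")) next
    op <- match(ch, .bracketPages$openers)
    if (!is.na(op)) {
      stacks[[op]] <- c(stacks[[op]], pos)
      next
    }
    cl <- match(ch, .bracketPages$closers)
    if (is.na(cl))
      stop(sprintf("invalid character '%s' at position %d", ch, pos))
    st <- stacks[[cl]]
    if (length(st) == 0L)
      stop(sprintf("unmatched '%s' at position %d", ch, pos))
    pairs[[length(pairs) + 1L]] <- c(st[length(st)], pos)
    stacks[[cl]] <- st[-length(st)]
  }
  for (pg in seq_along(stacks)) {
    if (length(stacks[[pg]]))
      stop(sprintf("unclosed '%s' at position %d",
                   .bracketPages$openers[pg], stacks[[pg]][1L]))
  }
  pm <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), ncol = 2L)
  pm <- pm[order(pm[, 1L]), , drop = FALSE]
  new("SecondaryStructure", length = L,
      pairs = matrix(as.integer(pm), ncol = 2L),
      sequence = if (is.null(sequence)) NA_character_ else sequence)
}

#' Parse a BPSEQ file
#'
#' BPSEQ lists one position per line as \code{index base partner}, 1-based,
#' with partner 0 meaning unpaired.  The pairing must be symmetric.
#'
#' @param lines Character vector of lines, or a file path of length 1 naming
#'   an existing file.
#' @return A [SecondaryStructure-class].
#' @export
parseBpseq <- function(lines) {
  stopifnot(is.character(lines))
  if (length(lines) == 1L && file.exists(lines) && !grepl("[\n ]", lines))
    lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(new("SecondaryStructure", length = 0L,
               pairs = matrix(integer(0), ncol = 2L),
               sequence = NA_character_))
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop(sprintf("malformed BPSEQ line %d: '%s'", bad[1L], lines[bad[1L]]))
  idx <- as.integer(vapply(fields, `[`, character(1), 1L))
  base <- vapply(fields, `[`, character(1), 2L)
  partner <- as.integer(vapply(fields, `[`, character(1), 3L))
  L <- length(idx)
  if (anyDuplicated(idx))
    stop(sprintf("duplicate index %d in BPSEQ input", idx[duplicated(idx)][1L]))
  if (!setequal(idx, seq_len(L)))
    stop("BPSEQ indices must cover 1..length exactly once")
  ord <- order(idx)
  base <- base[ord]; partner <- partner[ord]
  if (any(partner < 0L | partner > L))
    stop("BPSEQ partner index out of range")
  for (i in seq_len(L)) {
    j <- partner[i]
    if (j != 0L && partner[j] != i)
      stop(sprintf("asymmetric pairing: partner(%d) = %d but partner(%d) = %d",
                   i, j, j, partner[j]))
    if (j == i) stop(sprintf("position %d paired with itself", i))
  }
  sel <- which(partner > seq_len(L))
  pm <- cbind(sel, partner[sel])
  new("SecondaryStructure", length = L,
      pairs = matrix(as.integer(pm), ncol = 2L),
      sequence = paste(base, collapse = ""))
}

#' Flatten a structure to its arc diagram
#'
#' Discards the unpaired positions and re-indexes the 2N paired positions as
#' 1..2N in sequence order; each base pair becomes one arc.  The origin of
#' every arc (its original position pair) is recorded.
#'
#' @param s A [SecondaryStructure-class].
#' @return An [ArcDiagram-class].
#' @export
toArcDiagram <- function(s) {
  stopifnot(is(s, "SecondaryStructure"))
  paired <- sort(as.vector(s@pairs))
  rank <- integer(s@length)
  rank[paired] <- seq_along(paired)
  m <- nrow(s@pairs)
  arcs <- matrix(integer(0), ncol = 2L)
  origins <- list()
  if (m) {
    arcs <- cbind(rank[s@pairs[, 1L]], rank[s@pairs[, 2L]])
    ord <- order(arcs[, 1L])
    arcs <- arcs[ord, , drop = FALSE]
    origins <- lapply(ord, function(k) s@pairs[k, , drop = FALSE])
  }
  new("ArcDiagram", numDots = 2L * m,
      arcs = matrix(as.integer(arcs), ncol = 2L), origins = origins)
}

#' Reduce an arc diagram to its shape
#'
#' Repeatedly merges any stacked pair of arcs -- arcs (p, q) and (p+1, q-1)
#' in the paired-only index space -- into a single arc, re-indexing after
#' each merge, until no stack remains.  Because unpaired positions were
#' already discarded, bulges and interior loops never block stacking, so
#' each helix of the original structure collapses to one arc.  Merged arcs
#' accumulate their origins.  The operation is idempotent.
#'
#' @param d An [ArcDiagram-class].
#' @return A stack-free [ArcDiagram-class] (the shape).
#' @export
reduceToShape <- function(d) {
  stopifnot(is(d, "ArcDiagram"))
  arcs <- d@arcs
  origins <- d@origins
  repeat {
    nd <- 2L * nrow(arcs)
    if (nd == 0L) break
    partner <- integer(nd)
    arcOf <- integer(nd)
    for (k in seq_len(nrow(arcs))) {
      p <- arcs[k, 1L]; q <- arcs[k, 2L]
      partner[p] <- q; partner[q] <- p
      arcOf[p] <- k; arcOf[q] <- k
    }
    hit <- 0L
    for (p in seq_len(nd - 1L)) {
      q <- partner[p]
      if (q > p + 1L && partner[p + 1L] == q - 1L) { hit <- p; break }
    }
    if (hit == 0L) break
    p <- hit; q <- partner[p]
    keep <- arcOf[p]; drop <- arcOf[p + 1L]
    origins[[keep]] <- rbind(origins[[keep]], origins[[drop]])
    arcs <- arcs[-drop, , drop = FALSE]
    origins <- origins[-drop]
    ## dots p+1 and q-1 disappear; renumber the survivors
    removed <- c(p + 1L, q - 1L)
    arcs <- apply(arcs, c(1L, 2L), function(x) x - sum(removed < x))
    arcs <- matrix(as.integer(arcs), ncol = 2L)
  }
  ord <- order(arcs[, 1L])
  new("ArcDiagram", numDots = 2L * nrow(arcs),
      arcs = matrix(as.integer(arcs[ord, , drop = FALSE]), ncol = 2L),
      origins = origins[ord])
}

#' Fold a shape diagram into a tangle
#'
#' Folds the line of 2N dots at its centre like closing a book: dot k with
#' k <= N becomes top dot k, and dot N+m becomes bottom dot (N-m+1)'.  Arcs
#' become tangle edges.  In cyclic boundary coordinates the fold is the
#' identity, so arcs cross in the diagram exactly when their edges cross in
#' the tangle.
#'
#' @param d A (preferably stack-free) [ArcDiagram-class].
#' @return A list with elements \code{tangle} (a [Tangle-class]),
#'   \code{positionMap} (data frame linking tangle dots to the original
#'   sequence positions they represent) and \code{origins} (named list, per
#'   edge label, of the original position pairs it abbreviates).
#' @export
foldToTangle <- function(d) {
  stopifnot(is(d, "ArcDiagram"))
  n <- d@numDots %/% 2L
  foldDot <- function(k) if (k <= n) k else -(2L * n - k + 1L)
  m <- nrow(d@arcs)
  edges <- matrix(integer(0), ncol = 2L)
  if (m) {
    edges <- cbind(vapply(d@arcs[, 1L], foldDot, integer(1)),
                   vapply(d@arcs[, 2L], foldDot, integer(1)))
  }
  tangle <- .newTangle(n, edges)
  validObject(tangle)
  posMap <- data.frame(dot = character(0), position = integer(0))
  origins <- list()
  if (m) {
    dotLab <- function(dd) if (dd > 0L) as.character(dd) else paste0(abs(dd), "'")
    for (k in seq_len(m)) {
      e <- c(foldDot(d@arcs[k, 1L]), foldDot(d@arcs[k, 2L]))
      lab <- .edgeLabel(.canonicalEdges(matrix(e, ncol = 2L))[1L, ])
      origins[[lab]] <- d@origins[[k]]
      posMap <- rbind(posMap,
                      data.frame(dot = dotLab(e[1L]),
                                 position = d@origins[[k]][1L, 1L]),
                      data.frame(dot = dotLab(e[2L]),
                                 position = d@origins[[k]][1L, 2L]))
    }
  }
  list(tangle = tangle, positionMap = posMap, origins = origins)
}

#' Write a structure in extended dot-bracket notation
#'
#' Assigns each pair greedily to the first bracket page on which it does not
#' cross any pair already assigned there, in order of opening position, then
#' renders the string.  Nested structures use \code{()} only; each additional
#' "layer" of pseudoknot crossings moves to the next page.
#'
#' @param s A [SecondaryStructure-class].
#' @return A character scalar.
#' @export
formatDotBracket <- function(s) {
  stopifnot(is(s, "SecondaryStructure"))
  out <- rep(".", s@length)
  m <- nrow(s@pairs)
  if (m) {
    pageOf <- integer(m)
    ord <- order(s@pairs[, 1L])
    for (k in ord) {
      pg <- 1L
      repeat {
        clash <- FALSE
        for (k2 in ord[pageOf[ord] == pg]) {
          if (.interleaves(s@pairs[k, 1L], s@pairs[k, 2L],
                           s@pairs[k2, 1L], s@pairs[k2, 2L])) { clash <- TRUE; break }
        }
        if (!clash) break
        pg <- pg + 1L
        if (pg > length(.bracketPages$openers))
          stop("structure needs more bracket pages than are available")
      }
      pageOf[k] <- pg
      out[s@pairs[k, 1L]] <- .bracketPages$openers[pg]
      out[s@pairs[k, 2L]] <- .bracketPages$closers[pg]
    }
  }
  paste(out, collapse = "")
}

#' Read a dot-bracket file
#'
#' Accepts Vienna-style files: an optional FASTA-style \code{>} header line,
#' an optional sequence line, and the structure line.
#'
#' @param lines Character vector of lines, or a path to a file.
#' @return A [SecondaryStructure-class].
#' @export
readDotBracket <- function(lines) {
  stopifnot(is.character(lines))
  if (length(lines) == 1L && file.exists(lines) && !grepl("\n", lines))
    lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) == 0L) stop("no structure line found")
  ## note: a structure drawn purely with letter pages and no dots is
  ## indistinguishable from a sequence; dots or brackets mark it as structure
  isSeq <- grepl("^[ACGUTNacgutn]+$", lines)
  structLine <- lines[!isSeq]
  if (length(structLine) == 0L) stop("no structure line found")
  seqLine <- if (any(isSeq)) lines[isSeq][1L] else NULL
  parseDotBracket(structLine[1L], sequence = seqLine)
}
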