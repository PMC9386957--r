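## Class-specific factorization algorithms and the dispatcher that peels
## prime factors from the right of a tangle until the identity is reached.

.sameTangle <- function(a, b) a@n == b@n && identical(a@edges, b@edges)

.heuristicFailure <- function(msg, x) {
  stop(structure(class = c("rnatangles_heuristic_failure", "error", "condition"),
                 list(message = sprintf("%s [tangle %s]", msg, formatInvariant(x)),
                      call = sys.call(-1L))))
}

.findEdgeRow <- function(x, e) {
  if (is.character(e)) {
    parts <- strsplit(gsub("[[:space:]]", "", e), ":", fixed = TRUE)[[1L]]
    toDot <- function(s) {
      primed <- endsWith(s, "'")
      idx <- as.integer(sub("'$", "", s))
      if (primed) -idx else idx
    }
    e <- c(toDot(parts[1L]), toDot(parts[2L]))
  }
  e <- .canonicalEdges(matrix(as.integer(e), ncol = 2L))[1L, ]
  row <- which(x@edges[, 1L] == e[1L] & x@edges[, 2L] == e[2L])
  if (length(row) != 1L)
    stop(sprintf("edge %s is not in the tangle", .edgeLabel(e)))
  row
}

#' Merge a size-1 lower hook with another edge
#'
#' The elementary move behind U-tangle factorization.  Removing the prime
#' \eqn{U_i} from the right of \eqn{X = X' \circ U_i} amounts to merging the
#' lower hook h = i':(i+1)' with a second edge e = e1:e2: both are removed
#' and replaced by edges a and b, where for a hook or a negative (or zero)
#' transversal a = e1:i' and b = (i+1)':e2, while for a positive transversal
#' a = e1:(i+1)' and b = e2:i'.  Hook endpoints are taken in ascending order
#' and transversal endpoints as (top, bottom).
#'
#' @param x A [Tangle-class].
#' @param h The size-1 lower hook, as a signed integer pair or a label such
#'   as \code{"2':3'"}.
#' @param e The edge to merge with, in the same forms.
#' @return The merged [Tangle-class].
#' @examples
#' x <- parseInvariant("1:1',2:4,3:5',5:4',2':3'")
#' formatInvariant(mergeHook(x, "2':3'", "2:4"))
#' @export
mergeHook <- function(x, h, e) {
  stopifnot(is(x, "Tangle"))
  hRow <- .findEdgeRow(x, h)
  eRow <- .findEdgeRow(x, e)
  if (hRow == eRow) stop("'h' and 'e' must be distinct edges")
  hEdge <- x@edges[hRow, ]
  if (!(hEdge[1L] < 0L && hEdge[2L] < 0L &&
        abs(abs(hEdge[1L]) - abs(hEdge[2L])) == 1L))
    stop(sprintf("edge %s is not a size-1 lower hook", .edgeLabel(hEdge)))
  i <- min(abs(hEdge))
  eEdge <- x@edges[eRow, ]
  cls <- .edgeClass(eEdge)
  ## endpoint roles: hooks ascending, transversals (top, bottom); canonical
  ## storage already provides both
  e1 <- eEdge[1L]; e2 <- eEdge[2L]
  if (cls == "positive transversal") {
    a <- c(e1, -(i + 1L)); b <- c(e2, -i)
  } else {
    a <- c(e1, -i); b <- c(-(i + 1L), e2)
  }
  edges <- x@edges[-c(hRow, eRow), , drop = FALSE]
  out <- .newTangle(x@n, rbind(edges, a, b))
  validObject(out)
  out
}

#' One step of the small-hook (U-tangle) heuristic
#'
#' Writes a U-tangle as \eqn{X = X' \circ U_i} by merging its leftmost
#' size-1 lower hook h = i':(i+1)' with a partner edge.  Candidate partners
#' are the edges that intersect both imaginary vertical edges I = \{i:i',
#' (i+1):(i+1)'\} (sharing a dot with an I edge counts as intersecting it);
#' among candidates whose merge preserves the crossing number, the edge with
#' the fewest intersections in X is chosen (ties: smallest canonical edge).
#'
#' @param x A U-class [Tangle-class].
#' @return A list with \code{tangle} (the merged tangle X'), \code{yielded}
#'   (a one-factor [FactorList-class] holding \eqn{U_i}) and \code{merged}
#'   (the label of the partner edge).
#' @export
heuristic1Step <- function(x) {
  stopifnot(is(x, "Tangle"))
  n <- x@n
  e <- x@edges
  lower <- which(e[, 1L] < 0L & e[, 2L] < 0L &
                 abs(abs(e[, 1L]) - abs(e[, 2L])) == 1L)
  if (length(lower) == 0L)
    .heuristicFailure("no size-1 lower hook found", x)
  hRow <- lower[which.min(pmin(abs(e[lower, 1L]), abs(e[lower, 2L])))]
  i <- min(abs(e[hRow, ]))
  cTarget <- crossingNumber(x)
  iEdges <- list(c(i, -i), c(i + 1L, -(i + 1L)))
  interCount <- function(row) {
    ep <- e[row, ]
    p1 <- .cyclicPos(ep[1L], n); q1 <- .cyclicPos(ep[2L], n)
    total <- 0L
    for (ie in iEdges) {
      if (any(ep %in% ie)) { total <- total + 1L; next }
      if (.interleaves(p1, q1, .cyclicPos(ie[1L], n), .cyclicPos(ie[2L], n)))
        total <- total + 1L
    }
    total
  }
  S <- setdiff(which(vapply(seq_len(n), interCount, integer(1)) == 2L), hRow)
  if (length(S) == 0L)
    .heuristicFailure(sprintf("no edge intersects both imaginary edges at hook %s",
                              .edgeLabel(e[hRow, ])), x)
  keep <- S[vapply(S, function(row) {
    crossingNumber(mergeHook(x, e[hRow, ], e[row, ])) == cTarget
  }, logical(1))]
  if (length(keep) == 0L)
    .heuristicFailure(sprintf("no crossing-preserving merge partner for hook %s",
                              .edgeLabel(e[hRow, ])), x)
  crossesInX <- function(row) {
    p1 <- .cyclicPos(e[row, 1L], n); q1 <- .cyclicPos(e[row, 2L], n)
    sum(vapply(seq_len(n)[-row], function(r2) {
      .interleaves(p1, q1, .cyclicPos(e[r2, 1L], n), .cyclicPos(e[r2, 2L], n))
    }, logical(1)))
  }
  nInter <- vapply(keep, crossesInX, integer(1))
  keep <- keep[nInter == min(nInter)]
  best <- keep[order(.dotKey(e[keep, 1L]), .dotKey(e[keep, 2L]))][1L]
  xPrime <- mergeHook(x, e[hRow, ], e[best, ])
  yielded <- factorList(n, "U", i)
  stopifnot(.sameTangle(composeTangles(xPrime, primeTangle("U", i, n)), x))
  list(tangle = xPrime, yielded = yielded, merged = .edgeLabel(e[best, ]))
}

.smallestBigLowerHook <- function(x) {
  e <- x@edges
  lower <- which(e[, 1L] < 0L & e[, 2L] < 0L)
  sizes <- abs(abs(e[lower, 1L]) - abs(e[lower, 2L]))
  big <- lower[sizes > 1L]
  if (length(big) == 0L) return(NULL)
  sz <- sizes[sizes > 1L]
  big <- big[sz == min(sz)]
  big[which.min(pmin(abs(e[big, 1L]), abs(e[big, 2L])))]
}

#' Score the shrinkage locations of a big lower hook
#'
#' A lower hook h = i':(i+k)' of size k > 1 can be shrunk to size 1 at any
#' of k locations j by composing with the T-prime word L = T_i ... T_(i+j-2)
#' (ascending) followed by R = T_(i+k-1) ... T_(i+j) (descending).  Shrinking
#' changes the sizes of the edges attached inside the hook; each location is
#' scored by the summed size change, and the big-hook heuristic picks a
#' location with minimal sum.
#'
#' @param x An H-class [Tangle-class].
#' @param h The big lower hook (signed pair or label); defaults to the
#'   smallest (leftmost on ties) lower hook of size > 1.
#' @return A data frame with one row per location: \code{location},
#'   \code{sum}, \code{factors} (the L,R word as text), and list columns
#'   \code{word} (the [FactorList-class]) and \code{deltas} (named integer
#'   vector of per-edge size changes, keyed by the original edge labels).
#' @examples
#' x <- parseInvariant("1:2,4:1',3:3',7:4',6:5',5:6',2':7'")
#' scoreShrinkLocations(x)[, c("location", "sum", "factors")]
#' @export
scoreShrinkLocations <- function(x, h = NULL) {
  stopifnot(is(x, "Tangle"))
  n <- x@n
  hRow <- if (is.null(h)) .smallestBigLowerHook(x) else .findEdgeRow(x, h)
  if (is.null(hRow)) stop("tangle has no lower hook of size > 1")
  hEdge <- x@edges[hRow, ]
  if (!(hEdge[1L] < 0L && hEdge[2L] < 0L))
    stop(sprintf("edge %s is not a lower hook", .edgeLabel(hEdge)))
  i <- min(abs(hEdge)); k <- abs(abs(hEdge[1L]) - abs(hEdge[2L]))
  if (k <= 1L) stop(sprintf("lower hook %s has size %d, need size > 1",
                            .edgeLabel(hEdge), k))
  inside <- (i + 1L):(i + k - 1L)
  e <- x@edges
  insideBottom <- function(row) {
    d <- e[row, ]
    hit <- abs(d[d < 0L])
    hit <- hit[hit %in% inside]
    if (length(hit)) min(hit) else NA_integer_
  }
  anchor <- vapply(seq_len(n), insideBottom, integer(1))
  tracked <- which(!is.na(anchor) & seq_len(n) != hRow)
  tracked <- tracked[order(anchor[tracked])]
  edgeSize <- function(d) abs(abs(d[1L]) - abs(d[2L]))
  rows <- lapply(seq_len(k), function(j) {
    idxL <- if (j >= 2L) i:(i + j - 2L) else integer(0)
    idxR <- if (j <= k - 1L) (i + k - 1L):(i + j) else integer(0)
    word <- factorList(n, rep("T", length(idxL) + length(idxR)), c(idxL, idxR))
    ## composing on the right with a T word only relabels the bottom row
    sig <- seq_len(n)
    for (m in c(idxL, idxR)) {
      sig[sig == m] <- -1L
      sig[sig == m + 1L] <- m
      sig[sig == -1L] <- m + 1L
    }
    relabel <- function(d) ifelse(d < 0L, -sig[abs(d)], d)
    deltas <- vapply(tracked, function(row) {
      edgeSize(relabel(e[row, ])) - edgeSize(e[row, ])
    }, integer(1))
    names(deltas) <- apply(e[tracked, , drop = FALSE], 1L, .edgeLabel)
    list(location = j, sum = sum(deltas), word = word, deltas = deltas)
  })
  data.frame(location = vapply(rows, `[[`, integer(1), "location"),
             sum = vapply(rows, `[[`, integer(1), "sum"),
             factors = vapply(rows, function(r) formatWord(r$word), character(1)),
             word = I(lapply(rows, `[[`, "word")),
             deltas = I(lapply(rows, `[[`, "deltas")))
}

#' One step of the big-hook (H-tangle) heuristic
#'
#' Shrinks the smallest lower hook of an H-tangle to size 1 at the
#' lowest-index location with minimal score (see [scoreShrinkLocations()]),
#' by composing X with the T-word L followed by R.  The result X' satisfies
#' \eqn{X = X' \circ (L \circ R)^{-1}}, so the reversed word is what gets
#' appended to the factorization.
#'
#' @param x An H-class [Tangle-class].
#' @return A list with \code{tangle} (X'), \code{appended} (the reversed
#'   word, a [FactorList-class]), \code{location} (the chosen j) and
#'   \code{scores} (the score table).
#' @export
heuristic2Step <- function(x) {
  stopifnot(is(x, "Tangle"))
  scores <- scoreShrinkLocations(x)
  best <- scores$location[scores$sum == min(scores$sum)][1L]
  word <- scores$word[[match(best, scores$location)]]
  xPrime <- composeTangles(x, composeFactors(word))
  appended <- reverseWord(word)
  stopifnot(.sameTangle(composeTangles(xPrime, composeFactors(appended)), x))
  list(tangle = xPrime, appended = appended, location = best, scores = scores)
}

#' Factorize an all-transversal tangle by sorting
#'
#' A tangle whose edges are all transversals is a permutation: top dot k is
#' joined to bottom dot s(k)'.  Since every T-prime is an adjacent
#' transposition, an optimal T-word is obtained by bubble-sorting the bottom
#' row; the word has exactly one T per inversion, i.e. per crossing.
#'
#' @param x A T-class [Tangle-class].
#' @return A [FactorList-class] of T factors, in bubble-pass order.
#' @export
sortTransversals <- function(x) {
  stopifnot(is(x, "Tangle"))
  if (classifyTangle(x) != "T")
    stop("sortTransversals() requires an all-transversal tangle")
  n <- x@n
  s <- integer(n)
  for (r in seq_len(n)) {
    top <- x@edges[r, 1L]; bot <- x@edges[r, 2L]
    s[top] <- abs(bot)
  }
  kinds <- character(0); idx <- integer(0)
  repeat {
    swapped <- FALSE
    for (j in seq_len(max(n - 1L, 0L))) {
      if (s[j] > s[j + 1L]) {
        tmp <- s[j]; s[j] <- s[j + 1L]; s[j + 1L] <- tmp
        idx <- c(idx, j); kinds <- c(kinds, "T")
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  factorList(n, kinds, idx)
}

## --- Temperley-Lieb factorization via odd-depth regions --------------------

## Edges crossing the vertical midline of column `col` (the strip between
## dots col and col+1), ordered top to bottom.  Everything is computed from
## the cyclic boundary coordinates: the midline runs from boundary coordinate
## col+0.5 (top) to 2n-col+0.5 (bottom); a chord crosses it iff exactly one
## of those two coordinates lies strictly inside the chord's coordinate
## interval.  For two crossing chords, e lies above f iff e separates f from
## the top end of the midline.
.midlineCrossings <- function(pos, ti, bi) {
  inside <- function(coord) pmin(pos[, 1L], pos[, 2L]) < coord &
    coord < pmax(pos[, 1L], pos[, 2L])
  which(xor(inside(ti), inside(bi)))
}

.orderCrossings <- function(pos, rows, bi) {
  if (length(rows) <= 1L) return(rows)
  onBiSide <- function(f, e) {
    lo <- min(pos[e, ]); hi <- max(pos[e, ])
    fIn <- lo < pos[f, 1L] & pos[f, 1L] < hi
    biIn <- lo < bi & bi < hi
    fIn == biIn
  }
  rank <- vapply(rows, function(e) {
    sum(vapply(setdiff(rows, e), function(f) onBiSide(e, f), logical(1)))
  }, integer(1))
  rows[order(rank)]
}

#' Factorize a Temperley-Lieb tangle by its odd-depth regions
#'
#' Implements the region-based factorization of crossing-free tangles:
#' vertical lines through every dot pair divide the diagram into columns;
#' within column i, the edges crossing the column are linearly ordered top
#' to bottom, and every region at odd depth (an odd number of edges above
#' it) contributes one \eqn{U_i}.  Regions are ordered by the DAG of
#' diagonal adjacencies -- at each interior vertical line, the region above
#' a crossing edge on one side precedes the region below it on the other --
#' and read top to bottom, left to right.  The resulting word is minimal.
#'
#' @param x A crossing-free, non-identity [Tangle-class].
#' @return A [FactorList-class] of U factors.
#' @examples
#' ernstFactorize(parseInvariant("1:2,3:1',2':3'"))
#' @export
ernstFactorize <- function(x) {
  stopifnot(is(x, "Tangle"))
  if (crossingNumber(x) != 0L)
    stop("ernstFactorize() requires a crossing-free (Temperley-Lieb) tangle")
  n <- x@n
  pos <- cbind(.cyclicPos(x@edges[, 1L], n), .cyclicPos(x@edges[, 2L], n))
  cols <- vector("list", max(n - 1L, 0L))
  for (col in seq_len(max(n - 1L, 0L))) {
    ti <- col + 0.5; bi <- 2L * n - col + 0.5
    rows <- .midlineCrossings(pos, ti, bi)
    cols[[col]] <- .orderCrossings(pos, rows, bi)
  }
  ## pieces: (column, depth) for odd depth; depth g means g edges above
  pieces <- list()
  pieceId <- function(col, g) paste0(col, ".", g)
  for (col in seq_along(cols)) {
    k <- length(cols[[col]])
    for (g in seq_len(k)) {
      if (g %% 2L == 1L && g < k + 1L)
        pieces[[pieceId(col, g)]] <- list(col = col, g = g)
    }
  }
  if (length(pieces) == 0L) {
    if (!.sameTangle(x, identityTangle(n)))
      stop("internal error: no regions found for a non-identity TL tangle")
    return(factorList(n, character(0), integer(0)))
  }
  succ <- stats::setNames(vector("list", length(pieces)), names(pieces))
  indeg <- stats::setNames(integer(length(pieces)), names(pieces))
  addEdge <- function(from, to) {
    if (is.null(pieces[[from]]) || is.null(pieces[[to]])) return(invisible())
    if (to %in% succ[[from]]) return(invisible())
    succ[[from]] <<- c(succ[[from]], to)
    indeg[[to]] <<- indeg[[to]] + 1L
  }
  ## same-column regions: shallower first
  for (col in seq_along(cols)) {
    gs <- sort(vapply(pieces[vapply(pieces, function(p) p$col == col, logical(1))],
                      `[[`, integer(1), "g"))
    if (length(gs) > 1L) {
      for (a in seq_len(length(gs) - 1L))
        addEdge(pieceId(col, gs[a]), pieceId(col, gs[a + 1L]))
    }
  }
  ## diagonal adjacency across each interior vertical line
  for (line in if (n >= 3L) 2L:(n - 1L) else integer(0)) {
    a <- line; b <- 2L * n - line + 1L
    for (r in seq_len(n)) {
      lo <- min(pos[r, ]); hi <- max(pos[r, ])
      if (lo == a || hi == a || lo == b || hi == b) next
      aIn <- lo < a && a < hi; bIn <- lo < b && b < hi
      if (aIn == bIn) next
      mL <- match(r, cols[[line - 1L]])
      mR <- match(r, cols[[line]])
      if (is.na(mL) || is.na(mR))
        stop("internal error: line-crossing chord misses a flanking midline")
      addEdge(pieceId(line, mR - 1L), pieceId(line - 1L, mL))      # upper right -> lower left
      addEdge(pieceId(line - 1L, mL - 1L), pieceId(line, mR))      # upper left -> lower right
    }
  }
  ## Kahn topological sort; ties: shallower region first, then leftmost column
  remaining <- names(pieces)
  out <- integer(0)
  while (length(remaining)) {
    avail <- remaining[indeg[remaining] == 0L]
    if (length(avail) == 0L) stop("internal error: region DAG has a cycle")
    g <- vapply(avail, function(id) pieces[[id]]$g, integer(1))
    cl <- vapply(avail, function(id) pieces[[id]]$col, integer(1))
    nxt <- avail[order(g, cl)][1L]
    out <- c(out, pieces[[nxt]]$col)
    for (s in succ[[nxt]]) indeg[[s]] <- indeg[[s]] - 1L
    remaining <- setdiff(remaining, nxt)
  }
  word <- factorList(n, rep("U", length(out)), out)
  if (!.sameTangle(composeFactors(word), x))
    stop("internal error: region word does not compose to the input tangle")
  word
}

#' Factorize a tangle into prime generators
#'
#' The dispatcher: classify the tangle and peel factors from the right until
#' the identity is reached.  All-transversal tangles are finished by
#' [sortTransversals()], crossing-free tangles by [ernstFactorize()];
#' otherwise one [heuristic1Step()] (U class) or [heuristic2Step()] (H
#' class) is taken and the dispatcher recurses on the remaining tangle,
#' appending the yielded factors on the right.  Unless \code{minimize =
#' FALSE}, the raw word is then passed through [minimizeWord()].
#'
#' @param x A [Tangle-class].
#' @param minimize Apply the rewriting minimization to the raw word?
#' @param maxStates Search budget forwarded to [minimizeWord()].
#' @return A [FactorList-class] composing to \code{x}.
#' @examples
#' formatWord(factorizeTangle(parseInvariant("1:1',2:4,3:5',5:4',2':3'")))
#' @export
factorizeTangle <- function(x, minimize = TRUE, maxStates = 1e5) {
  stopifnot(is(x, "Tangle"))
  n <- x@n
  suffixKind <- character(0); suffixIdx <- integer(0)
  cur <- x
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10L * n + 10L)
      .heuristicFailure("factorization did not terminate", x)
    cls <- classifyTangle(cur)
    if (cls == "T") { front <- sortTransversals(cur); break }
    if (cls == "TL") { front <- ernstFactorize(cur); break }
    if (cls == "U") {
      step <- heuristic1Step(cur)
      suffixKind <- c(step$yielded@kind, suffixKind)
      suffixIdx <- c(step$yielded@index, suffixIdx)
      cur <- step$tangle
    } else {
      step <- heuristic2Step(cur)
      suffixKind <- c(step$appended@kind, suffixKind)
      suffixIdx <- c(step$appended@index, suffixIdx)
      cur <- step$tangle
    }
  }
  raw <- factorList(n, c(front@kind, suffixKind), c(front@index, suffixIdx))
  if (!.sameTangle(composeFactors(raw), x))
    stop("internal error: raw factorization does not compose to the input")
  if (!minimize) return(raw)
  minimizeWord(raw, maxStates = maxStates)$word
}

#' Which factors generate each edge
#'
#' Composes a factor word layer by layer and, for every edge of the
#' resulting tangle, records the factors whose non-identity strands lie on
#' that edge's path: a \eqn{T_i} contributes when the path runs through one
#' of its two crossing transversals, a \eqn{U_i} when the path runs through
#' one of its hooks.  Straight pass-through strands contribute nothing, so
#' e.g. the edge 1:1' of a word whose factors all have index >= 2 has an
#' empty generator set.
#'
#' @param f A [FactorList-class].
#' @return A named list, keyed by edge label of \code{composeFactors(f)};
#'   each element is a data frame with columns \code{position} (1-based
#'   position in the word), \code{kind} and \code{index}.
#' @examples
#' gen <- trackGenerators(factorList(5, c("T", "T", "U"), c(3, 4, 2)))
#' gen[["2:4"]]
#' @export
trackGenerators <- function(f) {
  stopifnot(is(f, "FactorList"))
  n <- f@n
  m <- length(f)
  tangle <- composeFactors(f)
  nodeId <- function(level, strand) level * n + strand
  eu <- integer(0); ev <- integer(0); layer <- integer(0); marked <- logical(0)
  addE <- function(u, v, p, mk) {
    eu <<- c(eu, u); ev <<- c(ev, v); layer <<- c(layer, p); marked <<- c(marked, mk)
  }
  for (p in seq_len(m)) {
    i <- f@index[p]
    others <- setdiff(seq_len(n), c(i, i + 1L))
    for (s in others) addE(nodeId(p - 1L, s), nodeId(p, s), p, FALSE)
    if (f@kind[p] == "T") {
      addE(nodeId(p - 1L, i), nodeId(p, i + 1L), p, TRUE)
      addE(nodeId(p - 1L, i + 1L), nodeId(p, i), p, TRUE)
    } else {
      addE(nodeId(p - 1L, i), nodeId(p - 1L, i + 1L), p, TRUE)
      addE(nodeId(p, i), nodeId(p, i + 1L), p, TRUE)
    }
  }
  gens <- stats::setNames(vector("list", n),
                          if (n) apply(tangle@edges, 1L, .edgeLabel) else character(0))
  if (m == 0L) {
    for (lab in names(gens))
      gens[[lab]] <- data.frame(position = integer(0), kind = character(0),
                                index = integer(0))
    return(gens)
  }
  nNodes <- (m + 1L) * n
  incident <- vector("list", nNodes)
  for (k in seq_along(eu)) {
    incident[[eu[k]]] <- c(incident[[eu[k]]], k)
    incident[[ev[k]]] <- c(incident[[ev[k]]], k)
  }
  boundary <- c(seq_len(n), nodeId(m, seq_len(n)))
  dotOf <- function(node) if (node <= n) node else -(node - m * n)
  used <- logical(length(eu))
  for (start in boundary) {
    k <- incident[[start]][1L]
    if (used[k]) next
    cur <- start
    layersOnPath <- integer(0)
    repeat {
      used[k] <- TRUE
      if (marked[k]) layersOnPath <- c(layersOnPath, layer[k])
      nxt <- if (eu[k] == cur) ev[k] else eu[k]
      if (nxt %in% boundary && nxt != start) break
      inc <- incident[[nxt]]
      inc <- inc[!used[inc]]
      if (length(inc) == 0L) break
      k <- inc[1L]
      cur <- nxt
    }
    edge <- .canonicalEdges(matrix(c(dotOf(start), dotOf(nxt)), ncol = 2L))[1L, ]
    lab <- .edgeLabel(edge)
    ps <- sort(unique(layersOnPath))
    gens[[lab]] <- data.frame(position = ps, kind = f@kind[ps],
                              index = f@index[ps])
  }
  gens
}
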