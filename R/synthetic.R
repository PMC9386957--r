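## Seeded generators for random tangles and random secondary structures.
## The structure generator emulates the features the mapping cares about:
## nested helices (hairpins, bulges, multiloops come for free from nesting
## and unpaired padding) plus an optional number of crossing pseudoknot
## arcs.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random tangle from a random prime word
#'
#' Composes a uniformly random word of prime generators; identical seeds
#' give identical tangles.
#'
#' @param n Dots per row.
#' @param length Word length (0 gives the identity).
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return A [Tangle-class].
#' @export
randomTangle <- function(n, length, seed = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L, length >= 0L)
  if (length > 0L && n < 2L) stop("n must be at least 2 for a non-empty word")
  .withSeed(seed, {
    word <- randomWord(n, length)
    composeFactors(word)
  })
}

#' Random factor word
#'
#' @inheritParams randomTangle
#' @return A [FactorList-class] of uniformly random prime factors.
#' @export
randomWord <- function(n, length, seed = NULL) {
  n <- as.integer(n)
  .withSeed(seed, {
    factorList(n,
               sample(c("T", "U"), length, replace = TRUE),
               if (length > 0L) sample(seq_len(n - 1L), length, replace = TRUE)
               else integer(0))
  })
}

## random noncrossing perfect matching on `m` points (m even), as a list of
## (open, close) index pairs: point 1 matches a point at even distance, the
## two sides recurse independently
.randomNoncrossing <- function(points) {
  m <- length(points)
  if (m == 0L) return(list())
  stopifnot(m %% 2L == 0L)
  gap <- sample.int(m %/% 2L, 1L)         # partner at position 2*gap
  partner <- 2L * gap
  insidePts <- if (partner > 2L) points[2L:(partner - 1L)] else integer(0)
  outsidePts <- if (partner < m) points[(partner + 1L):m] else integer(0)
  c(list(c(points[1L], points[partner])),
    .randomNoncrossing(insidePts),
    .randomNoncrossing(outsidePts))
}

#' Random secondary structure
#'
#' Generates a seeded random structure in two layers: a random noncrossing
#' set of \code{nStems} shape arcs (giving hairpins, bulges and multiloops
#' once stems and unpaired runs are materialized), then \code{pseudoknots}
#' additional arcs, each placed so that one endpoint falls strictly inside
#' a randomly chosen existing arc and the other strictly outside, which
#' forces a crossing.  Every arc is expanded into a helix of 1 to
#' \code{maxStemLength} stacked pairs and random runs of 0 to
#' \code{maxUnpaired} unpaired nucleotides are inserted between all helix
#' boundaries.  With \code{pseudoknots = 0} the pair set is strictly
#' nested, so the folded tangle is crossing-free (Temperley-Lieb); with
#' \code{pseudoknots >= 1} the tangle has at least one crossing.
#'
#' @param nStems Number of shape-level nested arcs (>= 1).
#' @param pseudoknots Number of crossing arcs to add (>= 0).
#' @param maxStemLength Largest helix length, in stacked pairs.
#' @param maxUnpaired Largest unpaired run inserted between helix ends.
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return A [SecondaryStructure-class].
#' @examples
#' s <- randomStructure(3, pseudoknots = 1, seed = 7)
#' formatDotBracket(s)
#' @export
randomStructure <- function(nStems, pseudoknots = 0L, maxStemLength = 4L,
                            maxUnpaired = 3L, seed = NULL) {
  nStems <- as.integer(nStems)
  pseudoknots <- as.integer(pseudoknots)
  stopifnot(nStems >= 1L, pseudoknots >= 0L, maxStemLength >= 1L,
            maxUnpaired >= 0L)
  .withSeed(seed, {
    ## shape arcs on a line of abstract endpoints, coordinates kept as
    ## doubles so pseudoknot endpoints can be interleaved anywhere
    arcs <- .randomNoncrossing(seq_len(2L * nStems))
    arcs <- lapply(arcs, as.numeric)
    for (p in seq_len(pseudoknots)) {
      host <- arcs[[sample.int(length(arcs), 1L)]]
      lo <- min(host); hi <- max(host)
      aCoord <- lo + stats::runif(1L) * (hi - lo)       # strictly inside host
      coords <- sort(unlist(arcs))
      after <- stats::runif(1L) < 0.5
      bCoord <- if (after) hi + stats::runif(1L)        # strictly to the right
                else lo - stats::runif(1L)              # strictly to the left
      arcs[[length(arcs) + 1L]] <- c(aCoord, bCoord)
    }
    ## materialize: each arc becomes a helix; order endpoint events and lay
    ## out pairs with unpaired padding
    events <- do.call(rbind, lapply(seq_along(arcs), function(k) {
      a <- arcs[[k]]
      data.frame(coord = c(min(a), max(a)), arc = k, open = c(TRUE, FALSE))
    }))
    events <- events[order(events$coord), ]
    stemLen <- sample.int(maxStemLength, length(arcs), replace = TRUE)
    pos <- 0L
    openStack <- vector("list", length(arcs))
    pairs <- list()
    pad <- function() {
      if (maxUnpaired > 0L) pos <<- pos + sample.int(maxUnpaired + 1L, 1L) - 1L
      invisible()
    }
    for (r in seq_len(nrow(events))) {
      pad()
      k <- events$arc[r]
      if (events$open[r]) {
        openStack[[k]] <- pos + seq_len(stemLen[k])
        pos <- pos + stemLen[k]
      } else {
        closes <- pos + seq_len(stemLen[k])
        pos <- pos + stemLen[k]
        opens <- openStack[[k]]
        for (t in seq_len(stemLen[k])) {
          ## innermost open pairs with innermost close (stacked helix)
          pairs[[length(pairs) + 1L]] <-
            c(opens[stemLen[k] - t + 1L], closes[t])
        }
      }
    }
    pad()
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 1L]), , drop = FALSE]
    new("SecondaryStructure", length = as.integer(pos),
        pairs = matrix(as.integer(pm), ncol = 2L),
        sequence = NA_character_)
  })
}
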