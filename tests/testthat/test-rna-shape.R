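test_that("dot-bracket parsing matches brackets per page by stack discipline", {
  s <- parseDotBracket("((..))")
  expect_equal(s@length, 6L)
  expect_equal(unname(s@pairs), rbind(c(1L, 6L), c(2L, 5L)))
  s <- parseDotBracket("([)]")
  expect_equal(unname(s@pairs), rbind(c(1L, 3L), c(2L, 4L)))
  s <- parseDotBracket("A.(.)a")
  expect_equal(unname(s@pairs), rbind(c(1L, 6L), c(3L, 5L)))
  expect_error(parseDotBracket("((.)"), "unclosed '\\(' at position 1")
  expect_error(parseDotBracket("..)"), "unmatched '\\)' at position 3")
  expect_error(parseDotBracket("(!)"), "invalid character")
})

test_that("BPSEQ parsing enforces symmetry and coverage", {
  s <- parseBpseq(c("1 G 4", "2 A 0", "3 A 0", "4 C 1"))
  expect_equal(unname(s@pairs), rbind(c(1L, 4L)))
  expect_equal(s@sequence, "GAAC")
  expect_error(parseBpseq(c("1 G 0", "2 A 5", "3 C 0", "4 U 0", "5 G 0")),
               "asymmetric")
  expect_error(parseBpseq(c("1 G 0", "1 A 0")), "duplicate index|cover")
  empty <- parseBpseq(character(0))
  expect_equal(empty@length, 0L)
  expect_equal(nrow(empty@pairs), 0L)
})

test_that("flattening drops unpaired positions and re-indexes arcs", {
  d <- toArcDiagram(parseDotBracket("((..))"))
  expect_equal(unname(d@arcs), rbind(c(1L, 4L), c(2L, 3L)))
  d <- toArcDiagram(parseDotBracket("([)]"))
  expect_equal(unname(d@arcs), rbind(c(1L, 3L), c(2L, 4L)))
  d <- toArcDiagram(parseDotBracket(".(.)."))
  expect_equal(unname(d@arcs), rbind(c(1L, 2L)))
  expect_equal(unname(d@origins[[1]]), matrix(c(2L, 4L), ncol = 2))
})

test_that("shape reduction collapses stacks and is idempotent", {
  d <- toArcDiagram(parseDotBracket("((..))"))
  sh <- reduceToShape(d)
  expect_equal(unname(sh@arcs), rbind(c(1L, 2L)))
  expect_equal(nrow(sh@origins[[1]]), 2L)   # both original pairs recorded
  # crossing arcs never stack
  d <- toArcDiagram(parseDotBracket("([)]"))
  expect_equal(unname(reduceToShape(d)@arcs), unname(d@arcs))
  # bulges and interior loops do not block stacking
  sh <- reduceToShape(toArcDiagram(parseDotBracket("((.((..))..))")))
  expect_equal(unname(sh@arcs), rbind(c(1L, 2L)))
  # idempotence on random shapes
  withr::with_seed(2718, {
    for (k in 1:25) {
      d <- toArcDiagram(randomStructure(4, pseudoknots = sample(0:2, 1)))
      once <- reduceToShape(d)
      expect_equal(unname(reduceToShape(once)@arcs), unname(once@arcs))
    }
  })
})

test_that("book-folding maps arcs to the expected tangle edges", {
  mkDiagram <- function(arcs) {
    new("ArcDiagram", numDots = as.integer(2L * nrow(arcs)),
        arcs = matrix(as.integer(arcs), ncol = 2),
        origins = lapply(seq_len(nrow(arcs)),
                         function(k) matrix(as.integer(arcs[k, ]), ncol = 2)))
  }
  # the worked tRNA shape: five stems, one pseudoknot pair of crossings
  f <- foldToTangle(mkDiagram(rbind(c(1, 10), c(2, 4), c(3, 6),
                                    c(5, 7), c(8, 9))))
  expect_equal(formatInvariant(f$tangle), "1:1',2:4,3:5',5:4',2':3'")
  expect_equal(formatWord(factorizeTangle(f$tangle)), "T3*T4*U2")
  f <- foldToTangle(mkDiagram(rbind(c(1, 2))))
  expect_equal(formatInvariant(f$tangle), "1:1'")
  # a stack reduces first, then folds to the trivial strand
  sh <- reduceToShape(toArcDiagram(parseDotBracket("(())")))
  expect_equal(formatInvariant(foldToTangle(sh)$tangle), "1:1'")
})

test_that("pseudoknot-free structures fold to crossing-free tangles", {
  withr::with_seed(1123, {
    for (k in 1:60) {
      s <- randomStructure(sample(2:6, 1), pseudoknots = 0)
      rep <- runPipeline(formatDotBracket(s))
      expect_equal(rep@crossingNumber, 0L)
      expect_true(rep@tangleClass %in% c("T", "TL"))
      expect_equal(sum(rep@minimizedWord@kind == "T"), 0L)
    }
  })
})

test_that("pseudoknotted structures fold to tangles with crossings", {
  withr::with_seed(3344, {
    for (k in 1:60) {
      s <- randomStructure(sample(2:5, 1), pseudoknots = sample(1:2, 1))
      rep <- runPipeline(formatDotBracket(s))
      expect_gte(rep@crossingNumber, 1L)
      expect_gte(sum(rep@minimizedWord@kind == "T"), 1L)
    }
  })
})

test_that("an arc leaving another arc's span crosses it (Jordan property)", {
  n <- 4
  # all three relative arrangements of two arcs over distinct endpoints:
  # nested, disjoint, interleaved -- only the last one crosses
  nested <- rbind(c(1, 8), c(2, 5))
  disjoint <- rbind(c(1, 3), c(5, 8))
  interleaved <- rbind(c(1, 5), c(2, 8))
  asEdges <- function(arcs) {
    foldDot <- function(k) if (k <= n) k else -(2 * n - k + 1)
    lapply(1:2, function(r) c(foldDot(arcs[r, 1]), foldDot(arcs[r, 2])))
  }
  e <- asEdges(nested);      expect_false(edgesCross(e[[1]], e[[2]], n))
  e <- asEdges(disjoint);    expect_false(edgesCross(e[[1]], e[[2]], n))
  e <- asEdges(interleaved); expect_true(edgesCross(e[[1]], e[[2]], n))
})

test_that("synonymous mutations leave shape, tangle and word unchanged", {
  withr::with_seed(5150, {
    for (k in 1:20) {
      s <- randomStructure(sample(2:4, 1), pseudoknots = sample(0:1, 1))
      db <- formatDotBracket(s)
      ref <- runPipeline(db)
      # insert an unpaired nucleotide at a random point
      db2 <- insertUnpaired(db, sample(nchar(db) + 1, 1))
      # extend a random helix by one stacked pair
      db3 <- extendStem(db, sample(nrow(s@pairs), 1))
      for (mut in c(db2, db3)) {
        got <- runPipeline(mut)
        expect_equal(formatInvariant(got@tangle), formatInvariant(ref@tangle))
        expect_equal(formatWord(got@minimizedWord),
                     formatWord(ref@minimizedWord))
      }
    }
  })
})

test_that("dot-bracket writing round-trips through parsing", {
  withr::with_seed(776, {
    for (k in 1:20) {
      s <- randomStructure(sample(2:5, 1), pseudoknots = sample(0:2, 1))
      db <- formatDotBracket(s)
      back <- parseDotBracket(db)
      expect_equal(unname(back@pairs), unname(s@pairs))
    }
  })
})

test_that("dot-bracket files with headers and sequence lines are read", {
  s <- readDotBracket(c("> example hairpin", "GGGAAACCC", "(((...)))"))
  expect_equal(s@length, 9L)
  expect_equal(s@sequence, "GGGAAACCC")
  expect_equal(nrow(s@pairs), 3L)
})
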