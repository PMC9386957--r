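test_that("invariant strings parse, canonicalize and round-trip", {
  x <- parseInvariant("1:2,3:2',4:3',1':4'")
  expect_equal(nStrands(x), 4L)
  expect_equal(formatInvariant(x), "1:2,3:2',4:3',1':4'")
  # canonicalization of a scrambled edge list
  expect_equal(formatInvariant(parseInvariant("1':4',4:3',1:2,3:2'")),
               "1:2,3:2',4:3',1':4'")
  expect_equal(formatInvariant(identityTangle(4)), "1:1',2:2',3:3',4:4'")
  # round trip over every tangle of B_4
  for (t in enumerateTangles(4)) {
    expect_true(sameTangle(parseInvariant(formatInvariant(t)), t))
  }
})

test_that("malformed invariants are rejected with the offending token", {
  expect_error(parseInvariant("1:1,2:2'"), "repeated within edge")
  expect_error(parseInvariant("1:2,1:2'"), "occurs in more than one edge")
  expect_error(parseInvariant("1:1',3:3'"), "missing", ignore.case = TRUE)
  expect_error(parseInvariant("1:x,2:2'"), "malformed token")
  expect_error(parseInvariant("1:3',2:2',3:1'", n = 2), "out of range")
})

test_that("prime tangles match their definitions", {
  expect_equal(formatInvariant(primeTangle("U", 5, 6)),
               "1:1',2:2',3:3',4:4',5:6,5':6'")
  expect_equal(formatInvariant(primeTangle("T", 3, 6)),
               "1:1',2:2',3:4',4:3',5:5',6:6'")
  expect_equal(formatInvariant(primeTangle("T", 1, 2)), "1:2',2:1'")
  expect_equal(formatInvariant(primeTangle("U", 1, 2)), "1:2,1':2'")
  expect_error(primeTangle("T", 5, 5), "out of range")
})

test_that("composition follows the diagram rules and counts loops", {
  for (i in 1:3) {
    r <- composeTangles(primeTangle("T", i, 4), primeTangle("T", i, 4),
                        loops = TRUE)
    expect_true(sameTangle(r$tangle, identityTangle(4)))
    expect_equal(r$loops, 0L)
    r <- composeTangles(primeTangle("U", i, 4), primeTangle("U", i, 4),
                        loops = TRUE)
    expect_true(sameTangle(r$tangle, primeTangle("U", i, 4)))
    expect_equal(r$loops, 1L)
  }
  # U_i o U_j o U_i = U_i for adjacent i, j
  u1 <- primeTangle("U", 1, 3); u2 <- primeTangle("U", 2, 3)
  expect_true(sameTangle(composeTangles(composeTangles(u1, u2), u1), u1))
  expect_error(composeTangles(identityTangle(3), identityTangle(4)),
               "cannot compose")
})

test_that("composition is associative and identity-neutral", {
  # exhaustive over all pairs of B_3
  b3 <- enumerateTangles(3)
  id3 <- identityTangle(3)
  for (x in b3) {
    expect_true(sameTangle(composeTangles(id3, x), x))
    expect_true(sameTangle(composeTangles(x, id3), x))
  }
  for (x in b3) for (y in b3) {
    for (z in b3[c(1, 8, 15)]) {
      expect_true(sameTangle(composeTangles(composeTangles(x, y), z),
                             composeTangles(x, composeTangles(y, z))))
    }
  }
  # random triples at N = 8
  withr::with_seed(4213, {
    for (k in 1:100) {
      x <- randomTangle(8, sample(0:10, 1))
      y <- randomTangle(8, sample(0:10, 1))
      z <- randomTangle(8, sample(0:10, 1))
      expect_true(sameTangle(composeTangles(composeTangles(x, y), z),
                             composeTangles(x, composeTangles(y, z))))
    }
  })
})

test_that("word composition folds left to right and handles the identity", {
  expect_equal(formatInvariant(composeFactors(factorList(5, c("T", "T", "U"),
                                                         c(3, 4, 2)))),
               "1:1',2:4,3:5',5:4',2':3'")
  expect_true(sameTangle(composeFactors(factorList(7)), identityTangle(7)))
  expect_true(sameTangle(
    composeFactors(parseWord("T3*T5*T6*T5*U1*U2*T3*T4*T5*T6", n = 7)),
    bigHookTangle()))
})

test_that("crossing number counts interleaving boundary chords", {
  expect_equal(crossingNumber(identityTangle(6)), 0L)
  for (i in 1:4) {
    expect_equal(crossingNumber(primeTangle("T", i, 5)), 1L)
    expect_equal(crossingNumber(primeTangle("U", i, 5)), 0L)
  }
  # the all-transversal stage of the big-hook worked example: bottom row
  # 1' 2' 4' 3' 7' 6' 5' has four inversions
  expect_equal(crossingNumber(
    parseInvariant("1:1',2:2',4:3',3:4',5:7',6:6',7:5'")), 4L)
})

test_that("crossing number is bounded by the T count of any word", {
  withr::with_seed(907, {
    for (k in 1:200) {
      w <- randomWord(6, sample(0:10, 1))
      expect_lte(crossingNumber(composeFactors(w)), sum(w@kind == "T"))
    }
  })
})

test_that("classification follows the T > TL > U > H precedence", {
  expect_equal(classifyTangle(identityTangle(4)), "T")
  expect_equal(classifyTangle(ecoliTangle()), "U")
  expect_equal(classifyTangle(bigHookTangle()), "H")
  expect_equal(classifyTangle(primeTangle("U", 2, 4)), "TL")
  expect_equal(classifyTangle(primeTangle("T", 2, 4)), "T")
  # every enumerated tangle gets exactly one of the four labels
  for (t in enumerateTangles(3)) {
    expect_true(classifyTangle(t) %in% c("T", "TL", "U", "H"))
  }
})

test_that("enumeration counts match the double factorial and Catalan laws", {
  counts <- vapply(1:5, function(n) length(enumerateTangles(n)), integer(1))
  expect_equal(counts, c(1L, 3L, 15L, 105L, 945L))  # (2n-1)!!
  catalan <- function(n) choose(2 * n, n) / (n + 1)
  for (n in 1:4) {
    tl <- sum(vapply(enumerateTangles(n),
                     function(t) crossingNumber(t) == 0L, logical(1)))
    expect_equal(tl, catalan(n))
  }
  expect_error(enumerateTangles(6), "bound")
})

test_that("JSON serialization round-trips with negative bottom dots", {
  x <- ecoliTangle()
  js <- tangleToJSON(x)
  expect_match(js, "\"n\":5")
  expect_match(js, "-3")  # bottom dots are negative in the wire format
  expect_true(sameTangle(tangleFromJSON(js), x))
})
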