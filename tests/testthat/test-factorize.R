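test_that("bubble sorting an all-transversal tangle emits one T per inversion", {
  # the all-transversal stage of the big-hook worked example
  x <- parseInvariant("1:1',2:2',4:3',3:4',5:7',6:6',7:5'")
  expect_equal(formatWord(sortTransversals(x)), "T3*T5*T6*T5")
  expect_equal(length(sortTransversals(x)), crossingNumber(x))
  expect_equal(length(sortTransversals(identityTangle(5))), 0L)
  expect_equal(formatWord(sortTransversals(parseInvariant("1:2',2:1'"))), "T1")
  expect_error(sortTransversals(primeTangle("U", 1, 3)), "all-transversal")
  # soundness + optimality on random permutation tangles
  withr::with_seed(62, {
    for (k in 1:25) {
      perm <- sample(6)
      x <- newTangle(6, cbind(1:6, -perm))
      w <- sortTransversals(x)
      expect_true(sameTangle(composeFactors(w), x))
      expect_equal(length(w), crossingNumber(x))
    }
  })
})

test_that("the region reader factorizes Temperley-Lieb tangles minimally", {
  expect_equal(formatWord(ernstFactorize(primeTangle("U", 3, 6))), "U3")
  expect_equal(formatWord(ernstFactorize(parseInvariant("1:2,3:1',2':3'"))),
               "U1*U2")
  expect_equal(formatWord(ernstFactorize(parseInvariant("1:2,1':2'"))), "U1")
  # fully nested hooks need a revisit of the middle column
  expect_equal(formatWord(ernstFactorize(parseInvariant("1:4,2:3,1':4',2':3'"))),
               "U2*U1*U3*U2")
  expect_error(ernstFactorize(primeTangle("T", 1, 3)), "crossing-free")
  # exhaustive certification against the oracle at N = 4
  for (x in enumerateTangles(4)) {
    if (crossingNumber(x) > 0L || sameTangle(x, identityTangle(4))) next
    w <- ernstFactorize(x)
    expect_true(all(w@kind == "U"))
    expect_true(sameTangle(composeFactors(w), x))
    expect_equal(length(w), minimalWordLength(x))
  }
  # soundness on larger random TL tangles
  withr::with_seed(818, {
    for (k in 1:40) {
      x <- composeFactors(factorList(9, "U", sample(8, sample(1:12, 1),
                                                    replace = TRUE)))
      w <- ernstFactorize(x)
      expect_true(sameTangle(composeFactors(w), x))
    }
  })
})

test_that("merging a size-1 lower hook follows the endpoint rules", {
  # upper hook partner (the worked tRNA step)
  x <- ecoliTangle()
  expect_equal(formatInvariant(mergeHook(x, "2':3'", "2:4")),
               "1:1',2:2',3:5',4:3',5:4'")
  # that result is exactly T_3 o T_4
  expect_true(sameTangle(mergeHook(x, "2':3'", "2:4"),
                         composeFactors(factorList(5, "T", c(3, 4)))))
  # minimal case: hook merged with its upper hook gives the identity
  expect_true(sameTangle(mergeHook(primeTangle("U", 1, 2), "1':2'", "1:2"),
                         identityTangle(2)))
  # positive transversal partner swaps the endpoint roles
  y <- parseInvariant("1:2,3:4',4:1',5:7',6:6',7:5',2':3'")
  merged <- mergeHook(y, "2':3'", "4:1'")
  expect_s4_class(merged, "Tangle")
  expect_true("1':2'" %in% edgeTable(merged)$label)
  # merging with any edge still yields a valid matching
  for (lab in setdiff(edgeTable(x)$label, "2':3'")) {
    expect_s4_class(mergeHook(x, "2':3'", lab), "Tangle")
  }
  expect_error(mergeHook(x, "1:1'", "2:4"), "not a size-1 lower hook")
})

test_that("the small-hook heuristic peels a U while preserving crossings", {
  x <- ecoliTangle()
  st <- heuristic1Step(x)
  expect_equal(st$merged, "2:4")
  expect_equal(formatWord(st$yielded), "U2")
  expect_equal(formatInvariant(st$tangle), "1:1',2:2',3:5',4:3',5:4'")
  expect_equal(crossingNumber(st$tangle), crossingNumber(x))
  expect_true(sameTangle(composeTangles(st$tangle, primeTangle("U", 2, 5)), x))
  # second worked example: hook 2':3' merges with the transversal 4:1'
  y <- parseInvariant("1:2,3:4',4:1',5:7',6:6',7:5',2':3'")
  st <- heuristic1Step(y)
  expect_equal(st$merged, "4:1'")
  expect_equal(formatWord(st$yielded), "U2")
  st <- heuristic1Step(primeTangle("U", 1, 2))
  expect_true(sameTangle(st$tangle, identityTangle(2)))
  expect_equal(formatWord(st$yielded), "U1")
})

test_that("shrink-location scoring reproduces hook-size bookkeeping", {
  x <- bigHookTangle()
  sc <- scoreShrinkLocations(x)
  expect_equal(nrow(sc), 5L)          # hook 2':7' has size 5: five locations
  expect_equal(vapply(sc$word, length, integer(1)), rep(4L, 5))  # k - 1 factors
  # every location's sum is the total of its per-edge deltas
  for (r in seq_len(nrow(sc))) {
    expect_equal(sc$sum[r], sum(sc$deltas[[r]]))
  }
  # a small case, checked by enumerating both locations by hand:
  # hook 1':3' in B_3, inside edge 3:2'; location 1 keeps it size 1,
  # location 2 grows it to size 2
  z <- parseInvariant("1:2,3:2',1':3'")
  sc <- scoreShrinkLocations(z)
  expect_equal(sc$location, c(1L, 2L))
  expect_equal(sc$sum, c(-1L, 1L))
  expect_equal(sc$factors, c("T2", "T1"))
  expect_error(scoreShrinkLocations(ecoliTangle()), "no lower hook of size > 1")
})

test_that("the big-hook heuristic shrinks to a smaller-class tangle", {
  x <- bigHookTangle()
  st <- heuristic2Step(x)
  expect_equal(st$location, 1L)
  expect_equal(formatWord(st$appended), "T3*T4*T5*T6")
  expect_true(sameTangle(composeTangles(st$tangle,
                                        composeFactors(st$appended)), x))
  expect_true(classifyTangle(st$tangle) %in% c("T", "TL", "U"))
  # B_3 big hook resolves in one step
  z <- parseInvariant("1:2,3:2',1':3'")
  st <- heuristic2Step(z)
  expect_true(sameTangle(composeTangles(st$tangle,
                                        composeFactors(st$appended)), z))
  expect_true(classifyTangle(st$tangle) %in% c("T", "TL", "U"))
})

test_that("the dispatcher factorizes soundly and minimally at small N", {
  expect_equal(formatWord(factorizeTangle(ecoliTangle())), "T3*T4*U2")
  expect_equal(formatWord(factorizeTangle(bigHookTangle())),
               "T3*T5*T6*T5*U1*U2*T3*T4*T5*T6")
  expect_equal(length(factorizeTangle(identityTangle(5))), 0L)
  # exhaustive soundness and minimality over B_3
  for (x in enumerateTangles(3)) {
    w <- factorizeTangle(x)
    expect_true(sameTangle(composeFactors(w), x))
    expect_equal(length(w), minimalWordLength(x))
    expect_equal(sum(w@kind == "T"), crossingNumber(x))
  }
  # soundness on random tangles at N = 8
  withr::with_seed(271, {
    for (k in 1:40) {
      x <- randomTangle(8, sample(0:12, 1))
      w <- factorizeTangle(x)
      expect_true(sameTangle(composeFactors(w), x))
    }
  })
})

test_that("strand 1 is untouched exactly when edge 1:1' is present", {
  # both directions of the vertical-edge proposition, exhaustive over B_4
  for (x in enumerateTangles(4)) {
    hasVertical <- "1:1'" %in% edgeTable(x)$label
    w <- factorizeTangle(x)
    allAtLeastTwo <- length(w) == 0L || all(w@index >= 2L)
    expect_equal(hasVertical, allAtLeastTwo)
  }
})

test_that("generator tracking recovers which factors make each edge", {
  gen <- trackGenerators(factorList(5, c("T", "T", "U"), c(3, 4, 2)))
  lab <- function(df) paste0(df$kind, df$index)
  expect_equal(lab(gen[["2:4"]]), c("T3", "U2"))
  expect_equal(lab(gen[["3:5'"]]), c("T3", "T4"))
  expect_equal(lab(gen[["5:4'"]]), "T4")
  expect_equal(lab(gen[["2':3'"]]), "U2")
  expect_equal(nrow(gen[["1:1'"]]), 0L)
  # identity word: every edge has an empty generator set
  gen <- trackGenerators(factorList(3))
  expect_true(all(vapply(gen, nrow, integer(1)) == 0L))
  # a single hook prime generates both of its hooks
  gen <- trackGenerators(factorList(2, "U", 1L))
  expect_equal(lab(gen[["1:2"]]), "U1")
  expect_equal(lab(gen[["1':2'"]]), "U1")
})

test_that("crossing edges share a T generator (shared-factor property)", {
  withr::with_seed(1391, {
    for (k in 1:50) {
      w <- minimizeWord(randomWord(6, sample(1:8, 1)))$word
      x <- composeFactors(w)
      gen <- trackGenerators(w)
      et <- edgeTable(x)
      for (i in seq_len(nrow(et) - 1)) {
        for (j in (i + 1):nrow(et)) {
          if (!edgesCross(c(et$a[i], et$b[i]), c(et$a[j], et$b[j]), x@n)) next
          shared <- intersect(
            gen[[et$label[i]]]$position[gen[[et$label[i]]]$kind == "T"],
            gen[[et$label[j]]]$position[gen[[et$label[j]]]$kind == "T"])
          expect_gte(length(shared), 1L)
        }
      }
    }
  })
})
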