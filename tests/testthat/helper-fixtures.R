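# Shared fixtures: the two worked tangles, plus small utilities used across
# test files.

# modified E. coli tRNA shape, folded (a U-tangle in B_5)
ecoliTangle <- function() parseInvariant("1:1',2:4,3:5',5:4',2':3'")

# big-hook worked example (an H-tangle in B_7)
bigHookTangle <- function() parseInvariant("1:2,4:1',3:3',7:4',6:5',5:6',2':7'")

sameTangle <- function(a, b) {
  nStrands(a) == nStrands(b) && formatInvariant(a) == formatInvariant(b)
}

# cyclic boundary coordinate of a signed dot (top i -> i, bottom i' -> 2n-i+1)
cyclicCoord <- function(d, n) ifelse(d > 0, d, 2 * n - abs(d) + 1)

edgesCross <- function(e1, e2, n) {
  p <- sort(cyclicCoord(e1, n)); q <- sort(cyclicCoord(e2, n))
  (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
    (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
}

# grow a helix of a structure by one stacked pair (string surgery on the
# dot-bracket rendering): duplicates the bracket characters of one pair
extendStem <- function(db, pairRow) {
  s <- parseDotBracket(db)
  i <- s@pairs[pairRow, 1]; j <- s@pairs[pairRow, 2]
  chars <- strsplit(db, "")[[1]]
  paste(c(chars[seq_len(i - 1)], chars[i], chars[i:j], chars[j],
          if (j < length(chars)) chars[(j + 1):length(chars)]),
        collapse = "")
}

insertUnpaired <- function(db, at) {
  chars <- strsplit(db, "")[[1]]
  paste(c(chars[seq_len(at - 1)], ".",
          if (at <= length(chars)) chars[at:length(chars)]),
        collapse = "")
}
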