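# RNAtangles

Prime tangle factorization of RNA secondary structures in the Brauer monoid.

## What this is for

An RNA secondary structure — including pseudoknotted ones — can be modelled
as a *tangle* of the Brauer monoid B_N: a perfect matching on 2N dots
arranged in two rows of N (top row 1..N, bottom row 1'..N'), composed by
stacking diagrams and discarding closed loops. The mapping, due to Kauffman
and Magarshak, is:

1. flatten the structure to a line of dots with one arc per base pair,
2. discard unpaired nucleotides,
3. collapse stacked arcs, so each helix becomes one arc (the *shape*),
4. fold the line of 2N dots in half like closing a book,
5. read off a tangle in B_N.

The shape abstraction makes the result invariant to synonymous changes —
extending a helix or editing loops does not change the tangle. A structure
without pseudoknots always maps to a crossing-free (Temperley–Lieb) tangle;
every pseudoknot forces at least one crossing.

Every tangle factors into the prime generators T_i (a crossing of strands
i, i+1) and U_i (an adjacent upper and lower hook at i, i+1); the
*factorization problem* asks for a word of minimal length. `RNAtangles`
computes such factorizations with four class-specific algorithms:

* **T-tangles** (all transversals ≅ permutations): bubble-sorting the
  bottom row emits one T_i per inversion — optimal.
* **TL-tangles** (crossing-free): a region-based reader — odd-depth regions
  of the column decomposition each emit a U_i, ordered by their adjacency
  DAG — minimal.
* **U-tangles** (a lower hook of size 1): peel a U_i off the right by
  merging the hook with the unique crossing-preserving partner edge
  intersecting both flanking verticals.
* **H-tangles** (only big lower hooks): shrink the smallest lower hook to
  size 1 with T-primes, choosing the shrink location that inflates the
  other edges least.

A native term-rewriting engine then minimizes the word with the thirteen
prime-tangle identities (ten delete rules, three move rules), searching the
move-closure breadth-first for reachable deletions, and a Cayley-graph BFS
oracle certifies minimality exhaustively at small N (tested over all of B_4
and B_5).

## Worked example

```r
library(RNAtangles)
rep <- runPipeline("((((((((...))))...((((...[[[[))))...))))..]]]]")
show(rep)
#> RNA tangle factorization report
#>   input (dotbracket): ((((((((...))))...((((...[[[[))))...))))..]]]]
#>   tangle:  1:2',2:3,4:3',1':4'
#>   class:   H-tangle   crossings: 2
#>   raw word:       U2*T3*T1
#>   minimized word: U2*T3*T1  [certified minimal]
```

The structure has four helices, one of which (`[[[[`/`]]]]`) is a
pseudoknot crossing two others. The shape therefore folds to a tangle in
B_4 with two crossings, and the minimal word `U2*T3*T1` needs exactly two
T-primes — the crossing number. Which factors build which edge:

```r
gen <- trackGenerators(rep@minimizedWord)
#> 1:2'  <- T1
#> 2:3   <- U2
#> 4:3'  <- T3
#> 1':4' <- U2 T3 T1
```

The two edges crossed by the pseudoknot's edges share a T factor with it —
crossing edges always share at least one T generator.

Raw tangles work too:

```r
formatWord(factorizeTangle(parseInvariant("1:1',2:4,3:5',5:4',2':3'")))
#> [1] "T3*T4*U2"
```

A small CLI wraps the same functions (installed under `exec/`):

```sh
rnatangle map --text "((..))" --json
rnatangle factorize --text "1:1',2:4,3:5',5:4',2':3'"
rnatangle random --mode structure --stems 4 --pseudoknots 1 --seed 7
```

## Vignette

See `vignettes/rna-tangle-factorization.Rmd` for the model, the algorithms,
the design choices (fold orientation, tie-breaks, the rewriting strategy)
and known limitations.
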