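---
title: "From RNA secondary structure to prime tangle factorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RNA secondary structure to prime tangle factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNAtangles)
```

## The model

A tangle of the Brauer monoid $B_N$ is a perfect matching on $2N$ dots in
two rows of $N$ (top $1..N$, bottom $1'..N'$). Edges joining the rows are
*transversals* (positive, negative, or zero by index comparison); edges
within a row are *upper* or *lower hooks*; the size of an edge $a{:}b$ is
$|a-b|$. Composition stacks one diagram on another, identifies the middle
row, traces the resulting paths, and discards closed loops. The monoid is
generated by the primes $T_i$ (strands $i$, $i+1$ cross) and $U_i$
(adjacent upper and lower hooks at $i$, $i+1$); a *factor word* is an
ordered list of primes composing to a tangle, and the factorization
problem asks for one of minimal length.

Two conventions in the package deserve mention because the algebra does
not force them:

* **Closed loops are discarded but counted.** The monoid is taken as the
  quotient with no loop parameter, because the hook identity
  $U_i \circ U_i = U_i$ only holds there; `composeTangles(x, y, loops =
  TRUE)` still reports the count for diagnostics.
* **Crossing number is combinatorial, not geometric.** Two edges cross
  iff their endpoints interleave in the cyclic boundary order
  $1,\dots,N,N',(N-1)',\dots,1'$; this is the crossing count of a
  minimally drawn diagram, computable in $O(N^2)$, and it equals the
  number of T-primes in any minimal word.

## The mapping from RNA

`runPipeline()` carries a structure through five steps: parse (extended
dot-bracket with bracket pages `()[]{}<>Aa..Zz`, or BPSEQ), flatten to an
arc diagram over the paired positions only, collapse stacked arcs to one
arc per helix (the *shape*), fold the $2N$ remaining dots in half, and
read off a tangle.

Because stacking is tested in the paired-only index space, bulges and
interior loops never interrupt a helix: a run of pairs with any amount of
unpaired material between its strands still collapses to a single arc.
This is what makes the tangle invariant under synonymous edits (tested by
property: inserting unpaired positions or extending a helix leaves shape,
tangle and factorization unchanged).

**Fold orientation.** "Rotate the second half above the first" fixes the
picture but not the indexing. The package folds like closing a book: shape
dot $N+m$ becomes bottom dot $(N-m+1)'$. Under this map a linear position
$p$ keeps the cyclic boundary coordinate $p$, so arcs cross in the flat
diagram exactly when their edges cross in the tangle — pseudoknot
crossings survive the fold by construction. The convention is validated by
the worked tRNA example, which must (and does) reproduce the factorization
`T3*T4*U2`; the mirrored convention would instead reindex the bottom row
left-to-right and fails that check.

## Classification and the four algorithms

Tangles are labelled with precedence T → TL → U → H (`classifyTangle()`):
all-transversal; else crossing-free; else some size-1 lower hook; else
only big lower hooks. The precedence matters because the classes overlap
(every TL-tangle also has a size-1 lower hook); the dispatcher needs one
label, and the more specific algorithm is always at least as good.

**T-tangles** are permutations; bubble-sorting the bottom row emits one
$T_j$ per executed swap, giving a word whose length is the inversion
count, i.e. the crossing number — optimal.

**TL-tangles** use a region construction. Vertical lines through every
dot pair cut the diagram into $N-1$ columns; within column $i$ the edges
crossing the column are linearly ordered top to bottom, and a region with
an odd number of edges above it emits one $U_i$. Regions are ordered by
the DAG of diagonal adjacencies (at each interior vertical line, the
region above a crossing edge on one side precedes the region below it on
the other side; within a column, shallower first) and read off in a
topological order, ties resolved shallowest-then-leftmost. Everything is
computed from cyclic boundary coordinates — no plane geometry: a chord
crosses a column's midline iff exactly one midline endpoint lies inside
its coordinate interval, and "above" means separating the other chord
from the top end. A parity argument (the midline splits the dots into two
even halves) guarantees each column is crossed by an evenly many edges,
so odd-depth regions are well defined. The reader is certified minimal
against the breadth-first oracle exhaustively for all crossing-free
tangles up to $N = 5$.

**U-tangles**: to write $X = X' \circ U_i$, the leftmost size-1 lower
hook $h = i'{:}(i{+}1)'$ is merged with a partner edge $e = e_1{:}e_2$:
both are removed and replaced by $a, b$ with $a = e_1{:}i'$, $b =
(i{+}1)'{:}e_2$ when $e$ is a hook or a negative transversal, and $a =
e_1{:}(i{+}1)'$, $b = e_2{:}i'$ when positive. Three choices here were
open and are fixed as follows:

* *Endpoint roles*: hooks ascending, transversals (top, bottom); fixed by
  requiring the two worked merges (with the upper hook `2:4` and with the
  positive transversal `4:1'`) to reproduce the expected merged tangles
  frozen in the test suite.
* *Zero transversals* follow the negative-transversal branch; the rule
  only distinguishes positive from the rest, and the choice is exercised
  by the exhaustive small-$N$ oracle tests.
* *Partner selection*: candidates are edges intersecting both imaginary
  verticals $i{:}i'$ and $(i{+}1){:}(i{+}1)'$, where sharing a dot with a
  vertical counts as one intersection with it (not more); among merges
  that preserve the crossing number, the candidate with the fewest
  crossings in $X$ wins, remaining ties going to the smallest canonical
  edge. If no candidate preserves the crossing number the step raises a
  typed error (`rnatangles_heuristic_failure`) rather than degrade
  silently — no such failure occurs anywhere in $B_3$–$B_5$ or in the
  random suites, but the possibility is not excluded in general.

**H-tangles**: the smallest (leftmost on ties) lower hook
$h = i'{:}(i{+}k)'$, $k > 1$, is shrunk to size 1 at a location $j \in
1..k$ by composing with $L = T_i \cdots T_{i+j-2}$ (ascending) and $R =
T_{i+k-1} \cdots T_{i+j}$ (descending); these bounds are pinned down by
the worked five-row score table in the test suite, which they reproduce
cell by cell (deltas, sums and factor words). Each location
is scored by the summed size change over the edges attached strictly
inside the hook; the lowest-index location among minimal sums is taken
deterministically (a randomized choice would be sound too — all minimal
locations are admissible — but determinism makes runs reproducible). The
step records the reversed word, since $X = X' \circ (L \circ R)^{-1}$.

`trackGenerators()` replays a word layer by layer and attributes each
final edge to the factors whose non-identity strands lie on its path —
the per-edge "generated by" sets used to relate helices and pseudoknots
to factors. Crossing edges always share at least one T factor (tested on
random minimized words), and the edge $1{:}1'$ is present exactly when
every factor index is $\ge 2$ (tested exhaustively).

## Rewriting minimization

The heuristics can overshoot, so words are minimized with the thirteen
identities among primes: ten delete rules (e.g. $T_iT_i = I$, $U_iU_i =
U_i$, $U_iU_jU_i = U_i$ for $|i-j|=1$) and three move rules (the two
braid-like moves and far commutation $P_iP_j = P_jP_i$ for $|i-j|>1$).
`minimizeWord()` alternates (a) greedy exhaustive deletion, scanning left
to right with first match first, and (b) a breadth-first search over
words reachable by move rules alone, stopping at the first state where a
delete applies; the moves on that path plus the delete are committed and
the cycle restarts. Deletes strictly shorten, so the outer loop
terminates; moves preserve length, so the closure is finite per length
and its exhaustion certifies that no delete is reachable
(`certified = TRUE`). The search deduplicates by exact word — far
commutation is explored as ordinary transitions, which keeps the braid
moves available from every arrangement of a commutation class — and a
state budget (`maxStates`, default $10^5$) bounds the closure; exhausting
the budget only downgrades the certificate, never the soundness of the
word. Words already minimal come back unchanged. The termination
criterion "no move rule eventually leads to a delete"
has unbounded lookahead in principle; within the sizes the oracle can
check ($N \le 5$, exhaustively) the default budget always suffices.

`commutationCanonical()` (a deterministic representative of the
far-commutation class, by bubble passes under a (kind, index) order) is
exported as supporting plumbing for downstream deduplication.

## The oracle

`bfsMinimalWord()` runs breadth-first search over the Cayley graph of
$B_N$ from the identity under right multiplication by the $2(N-1)$
primes, yielding provably shortest words. It is the package's independent
standard: the test suite checks `factorizeTangle()` + `minimizeWord()`
against it for every tangle of $B_4$ (105) and $B_5$ (945), alongside
exhaustive verification of all thirteen rewrite identities by composition
at $N = 6$. The $(2N-1)!!$ growth restricts the oracle to $N \le 5$ by
default.

## Synthetic data

`randomStructure()` emulates what the mapping is sensitive to: a random
noncrossing arrangement of helices (nesting yields hairpins, bulges and
multiloops once unpaired runs of 0–3 nt are interspersed), each helix
1–4 pairs long, plus a requested number of pseudoknot arcs, each placed
with one endpoint strictly inside a randomly chosen host arc and the
other strictly outside — forcing a crossing that survives both shape
reduction and folding. Defaults were chosen once as a plausible
desk-scale regime (a handful of helices, short stems, sparse
pseudoknots) matching the worked examples' sizes; tests draw structures
with 2–6 helices and 0–2 pseudoknots. `randomTangle()` composes a seeded
uniform random prime word. Both restore the global RNG state.

What the generator does *not* emulate: nucleotide content and
thermodynamics (pairs are positional, not sequence-driven), kissing-
hairpin-specific geometries beyond generic crossings, and base triples
(excluded by the one-pair-per-position model). Passing tests therefore
certify the combinatorial pipeline on the class of structures
expressible as crossing/nested arc sets, not any folding energetics.

## Problem sizes and numerical choices

The default suite works at desk scale by design: exhaustive checks at
$N \le 5$ where the oracle is available (1 065 tangles across $B_4$ and
$B_5$), 500 seeded structures for the pseudoknot/crossing equivalence,
and random words at $N = 6..9$ for soundness properties. All randomness
is seeded with fixed constants; there are no tolerance parameters — every
comparison in the package is exact integer or string equality.

Degenerate inputs: a structure with no pairs maps to the empty tangle
($n = 0$) with the empty word; identity tangles classify as T and
factorize to the empty word; `parseInvariant` rejects duplicate, missing
and malformed dots naming the offending token.

## Known limitations

* The U-step's crossing-preserving partner is not proven to exist for
  every U-tangle; failures raise a typed error with the tangle attached.
* Minimality is *certified* only where the move-closure is exhausted
  (always, at tested sizes); for long words the budget may leave
  `certified = FALSE` with a sound but possibly non-minimal word.
* The oracle and exhaustive certification stop at $N = 5$; beyond that,
  minimality rests on the rewriting system.
* The alternative mapping in which a pseudoknot becomes a crossing
  *between* its two stems' edges is out of scope, as is any biological
  interpretation of equivalent factorizations and any structure
  prediction.
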