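---
title: "Staged exact alignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged exact alignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagealign)
```

This vignette is the package's own account of its science: the scoring
model and recurrences, the staged multi-worker procedure and its
correctness argument, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## Scoring model

Alignments are scored column-wise: `match` (+1 by default) for identical
residues, `-mismatch` (−1) for differing ones, and gap runs charged by one
of two models. The *linear* model charges `gap` (−2 by default, matching
the classic worked examples) per gap column. The *affine* model charges a
maximal run of `x` gap columns

\[
\gamma(x) = G_{open} + (x-1)\,G_{extend},
\]

which favours clustered gaps, the biologically typical pattern. Penalties
are stored as non-negative magnitudes and applied with minus signs.
Residues outside `{A,C,G,T}` (e.g. `N` and other IUPAC codes) are kept but
score as mismatches against everything, including themselves — the
conservative choice that can never inflate a score. A substitution hook
(`scoring_scheme(substitution_hook = ...)`) can replace the match/mismatch
rule, e.g. for an ad hoc matrix; matrix-file parsing is deliberately out of
scope.

The whole library works in score-maximization form. The affine global
recurrence is implemented in its standard three-matrix form — `E` and `F`
track runs of horizontal and vertical gaps,
`H = max(H_diag + p, E, F)` — with a zero branch added **only** in local
mode. Some published statements of the affine recurrence print a minus sign
on the substitution term and include the zero branch unconditionally while
simultaneously describing a global optimum at the last cell; those two
readings are mutually inconsistent, and this package resolves the conflict
in favour of the form that makes the affine kernel reduce exactly to the
linear kernels when \(G_{open} = G_{extend}\) (a property the test suite
asserts on randomized pairs).

## One engine, exact integer arithmetic

Every fill in the package — reference kernels, linear-space vectors, band
fills, strip recomputation — runs through a single column-sweep engine.
Within a column, `E` follows directly from the previous column; the
vertical-gap matrix `F` couples rows, but because
\(G_{open} \ge G_{extend}\) it satisfies a running-maximum identity

\[
F(i,j) = \max_{t<i}\bigl(H^{-}(t,j) - G_{open} - (i-1-t)G_{extend}\bigr),
\]

(where \(H^-\) is `H` before the `F` contribution), i.e. a `cummax` scan.
The observable contract is only the anti-diagonal dependency order
(`antidiagonal_schedule()` documents it; cells of one diagonal are mutually
independent), and the column sweep respects it while being a handful of
vectorized operations per column.

Scores are exact integers held in doubles (exact up to \(2^{53}\), far
beyond any reachable score), with `-Inf` as the unreachable-state sentinel.
All equality comparisons in tracebacks are therefore exact — there are no
numerical tolerances anywhere in the method, and "bit-exact" claims in the
tests are meant literally.

## Canonical traceback and tie-breaks

Wherever a single alignment must be chosen among co-optimal ones, the
package uses one canonical rule set, stated once and used everywhere:

- arrow preference diagonal > up > left (in affine state terms:
  diagonal > `F` > `E`, and inside a gap state closing the gap is
  preferred to extending it);
- local-mode end cell: highest score, ties by smallest \(i+j\), then
  smallest \(i\);
- local-mode traceback stops at the first zero-valued cell;
- midpoint matching ties take the smallest \(j^\*\).

Determinism (identical inputs give byte-identical alignments) follows, and
is asserted in the suite.

## Linear space

`linear_align()` implements divide and conquer on the middle row
\(i^\* = \lfloor m/2 \rfloor\): forward vectors `CC`/`DD` (best score, best
score ending in a vertical gap), reverse vectors `RR`/`SS` over the
reversed suffixes, and midpoint matching

\[
\max_j \; \max\bigl(CC(j) + RR(n-j),\; DD(j) + SS(n-j) + (G_{open} - G_{extend})\bigr).
\]

The correction term is forced by the run algebra: `DD` and `SS` each charge
a full opening, and
\(\gamma(x_1) + \gamma(x_2) = \gamma(x_1+x_2) + G_{open} - G_{extend}\), so
merging a run that spans the middle row must refund exactly
\(G_{open} - G_{extend}\). (A frequently quoted form refunds \(G_{open}\);
that is correct only under the alternative convention
\(\gamma(x) = G_{open} + x\,G_{extend}\).) With the refund as implemented,
the achieved maximum equals the optimal global score — the suite checks
this against the quadratic kernel on hundreds of randomized pairs, which
would fail for any other constant.

Junction plumbing: when a subproblem is entered inside a vertical run, its
first-column boundary charges extensions only (`open_top`); when the run
continues below the subproblem, the path is constrained to end in the `F`
state (`end_in_vgap`). The same two flags are reused by the pipeline's
Stage 4, so gap runs spanning any junction are charged their opening
exactly once. Local mode first locates the optimal end cell with a
linear-memory local fill, then the start cell with a *global* reverse fill
over the bounded prefix pair (a local reverse fill would be wrong: a
co-optimal path with a different end could mislocate the start), then
aligns the bounded problem globally.

`base_case_area` (default 4096 cells) is the size at which recursion hands
over to direct quadratic DP: small enough that base-case matrices are a few
tens of kilobytes, large enough that recursion overhead stays negligible.

## The staged pipeline

Stage 1 partitions the columns (`partition_columns`: contiguous,
near-equal, remainder leftmost) and chains band fills, each worker passing
its right border column (H *and* E, so affine runs crossing a border stay
exact) to the next and checkpointing special rows — H and the vertical-gap
F values — every `k` rows. Stage 2 finds the crosspoints where the optimal
path crosses partition borders by walking the canonical traceback through
strips rebuilt between consecutive special rows; since every boundary value
used is bit-exact, the walk reproduces exactly the canonical path of the
monolithic matrix, regardless of partitioning. PT resolves partitions
serially right-to-left; IST starts every partition speculatively from its
border column's maximum (`speculate_crosspoint`) and, when the true entry
arrives, keeps the speculative walk on a hit or discards it wholesale on a
miss — the simplest policy that provably never changes the output. Stage 3
records the crossing of every special row (so consecutive crosspoints are
at most `k` rows apart), Stage 4 aligns the inter-crosspoint subproblems
with the linear-space recursion, and Stage 5 concatenates, re-scores from
the columns, and refuses to return anything that does not reproduce the
Stage-1 optimum.

Worker-count invariance is a design property, not an accident: Stage-4
subproblems are delimited **only** by special-row crosspoints (which depend
on `m` and `k`, never on the partitioning); border crosspoints serve the
Stage-2 dataflow and the speculation records. Since the row crosspoints are
crossings of one canonical path, the final alignment is byte-identical for
every worker count — asserted across 1–4 workers in the suite.

Workers are deterministic logical workers exchanging immutable messages.
The package makes no claims about scheduling or concurrency; the
asynchronous overlap of real multi-device pipelines is a performance
detail with no effect on outputs, and this artifact's contract is the
dataflow.

Speculation bookkeeping: only borders the optimal path actually crosses
can be classified as hit or miss, so only those are recorded; with no
records the hit ratio is reported as 1.0 (vacuous success). Speculative
cell updates are counted separately in the run report so that energy-style
trade-off arithmetic (`speculation_breakeven`, `expected_time_saving`) has
inputs.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `match` / `mismatch` | +1 / 1 | score | the worked-example DNA scoring |
| `gap` (linear) | 2 | score | ditto |
| `gap_open` / `gap_extend` | 5 / 1 | score | a conventional affine DNA setting; the package treats them as pure inputs |
| `workers` | 1 | — | any value gives identical output; >1 exercises the staged dataflow |
| `special_row_interval` k | `ceiling(m/100)` | rows | checkpoint storage is `O(m·n/k)` values while strip recomputation is `O(k·width)`; m/100 keeps both around 1% of the matrix |
| `max_area` / `base_case_area` | 4096 | cells | recursion-to-DP handover (see above) |

## What the generator emulates — and what it does not

`generate_homolog_pair()` draws a uniform-random ancestor and derives a
homolog by independent substitutions (probability `sub_rate`, always to a
different base) and geometric-length indels (probability `indel_rate` per
position, mean `mean_indel_len`, insertions and deletions equiprobable).
Defaults (`sub_rate = 0.05`, `indel_rate = 0.001`, `mean_indel_len = 5`)
produce the high-similarity regime of closely related homologous
chromosomes — roughly 90–95% matching columns with sparse clustered gaps —
which is the regime where border-maximum speculation is expected to hit.
What it does **not** model: repeat families, GC skew, segmental
duplications, or rearrangements. Passing tests therefore demonstrate
algorithmic exactness and the expected speculation behaviour on
homology-like inputs, not robustness of the *heuristic speculation rate*
on real repeat-rich chromosomes; exactness of the final alignment is
unconditional either way. `plant_decoy_repeat()` exists precisely to build
the adversarial case: a perfect off-diagonal repeat that dominates a border
column without lying on the optimal path, forcing a speculation miss that
the pipeline must absorb without changing its output.

## Degenerate inputs and conventions

Empty sequences are legal: global alignment against an empty sequence is a
single boundary gap run scored \(-\gamma(|s|)\) (linear: \(-G|s|\)); the
local optimum of any pair with no positive-scoring match is the empty
alignment with score 0 and empty coordinate ranges. `sw_best()` on an
all-zero matrix reports score 0 with no cells. Coordinates are 1-based
inclusive throughout, with `(start, start-1)` denoting an empty range.

Coverage is not a universally standardized quantity; this package defines
it as the mean of the two aligned-span fractions,
\(\tfrac12(\mathrm{span}_0/m + \mathrm{span}_1/n)\times 100\), which
separates whole-sequence homology (≈100%) from short high-identity islands
(a few percent). It is a documented, swappable reporting policy and feeds
nothing in the method itself. Alignment `Length` counts every column,
including gap columns, which is why it can exceed both sequence lengths.

## Problem sizes used in the tests

The suite runs at desk scale, chosen so the whole battery completes in
about a minute while still exercising every code path: exhaustive
enumeration oracles at lengths ≤ 6, textbook loop-DP oracles at lengths
≤ 120, randomized pipeline-vs-oracle equivalence on 200 pairs with lengths
20–600 (both gap models, 1–4 workers, k ∈ {5, 17, m}), band equivalence on
100 partitioned fills, and synthetic homolog runs up to 5000 bp. The
acceptance script's pipeline run draws its worker count from the given
seed, and its remaining quantities are closed-form accounting.

## Known limitations

- The engine is vectorized R: exact and fast enough for hundreds of
  kilobases, but not a competitor to compiled SIMD aligners on real
  chromosomes.
- `enumerate_optimal_local()` is guarded to toy sizes (co-optimal counts
  grow combinatorially).
- Banded/pruned DP variants and alignment visualization are out of scope,
  as are PAM/BLOSUM file formats (the substitution hook is the extension
  point).
- Linear-space output is a single optimal alignment; co-optimal
  enumeration in linear memory is not attempted.
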