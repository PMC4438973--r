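---
title: "SHAPE-directed RNA sequence alignment and consensus structure modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SHAPE-directed RNA sequence alignment and consensus structure modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapealign)
```

## Rationale

RNA structure is conserved where primary sequence is not, so a model-free,
per-nucleotide readout of structure — SHAPE reactivity — carries alignment
signal that is orthogonal to base identity. Across curated rRNA alignments,
absolute reactivity differences between related nucleotides follow an
exponential decay, while randomly re-paired nucleotides differ much more.
`shapealign` turns that observation into an alignment score and a complete
small toolchain around it: alignment, benchmarking, parameter search,
difference-distribution analysis, and SHAPE-directed consensus structure
modeling through ViennaRNA.

## The scoring model

Two reactivities with absolute difference $d$ score

$$ s(d) = \max(m\,d + b,\; m + b), $$

a line of negative slope $m$ through intercept $b$, clipped at its value at
$d = 1$. With the defaults $m = -2$, $b = 2$ the score runs from $+2$
(identical reactivities) down to a floor of $0$ at differences of one SHAPE
unit or more. The clip level deserves a note: the function is specified by
its slope/intercept pair and the requirement that it flattens where the
linear branch reaches its one-unit value. Writing the floor as $m + b$ with
signed $m$ (equivalently $-|m| + b$) is the only reading under which the
floor sits *below* the intercept; a floor above the line's maximum would
make the function constant and useless, so the package adopts the
$\max(m\,d + b, m + b)$ form throughout. Because alignment quality depends
only on score *differences*, the floor at zero (rather than some other
constant) matters mainly through its interaction with the gap penalties.

In combined mode a base-identity term is added per column: `MATCH` ($+2$)
for identical bases, `MISMATCH` ($-2$) otherwise. `N` never matches
anything, including another `N` — ambiguity should not be rewarded.
Missing reactivities (unprobed positions, `-999` in the two-column file
dialect) contribute a neutral 0, so alignment through unprobed regions is
driven by the gap model and, in combined mode, base identity alone.
Negative reactivities — legitimate products of SHAPE-MaP background
subtraction — are used as-is; only $|d|$ enters the score.

### Parameters

| parameter | SHAPE-only | combined | units / meaning |
|---|---|---|---|
| `m` | −2 | −2 | score per SHAPE unit of difference |
| `b` | +2 | +2 | score at zero difference |
| `GOP` | −5 | −6 | charge for opening a gap run |
| `GEP` | −0.25 | −1 | charge per gapped column |
| `MATCH` | — | +2 | identical-base bonus |
| `MISMATCH` | — | −2 | differing-base penalty |

These defaults are the optima of an exhaustive grid search over diverged
rRNA training alignments; `param_grid()`/`grid_search()` re-run such a
search over any training set, with ranges that bracket these values. In
combined mode the convention is to keep $m, b$ at the SHAPE-only optimum and
re-search only the gap and identity terms, which `param_grid(mode =
"combined")` supports by freezing single-value candidate lists.

## The dynamic program

`gotoh_align()` is the standard three-matrix affine-gap global aligner:
$D_{ij}$ holds the best score for the prefixes, $P_{ij}$/$Q_{ij}$ the best
scores ending in a gap run in one or the other sequence; a gap of length
$L$ costs $GOP + L \cdot GEP$. Borders are initialized to $GOP + k\,GEP$
(terminal gaps are penalized exactly like internal ones; a `free_endgaps`
semi-global option exists but is off by default, since the border
initialization above *defines* the default behavior). The gap-matrix
borders hold a finite sentinel chosen four times larger than any achievable
score magnitude, keeping all arithmetic finite.

Numerical choices worth stating:

* **Traceback never compares floats.** Pointers are recorded at fill time,
  which avoids the classic affine-gap traceback hazard where re-deriving
  the path by score comparison mis-attributes a gap run in degenerate ties.
* **Tie order is fixed**: diagonal ≻ gap-in-y ≻ gap-in-x when filling $D$,
  and extension ≻ re-opening inside $P$/$Q$. Results are therefore
  bit-reproducible across runs and platforms.
* The fill is implemented in C++ (Rcpp); a 1.5 kb × 1.5 kb problem takes
  well under a second, a 3 kb × 3 kb problem a few seconds.

Correctness is established against `exhaustive_align()`, an independent
oracle that enumerates *every* global alignment of small instances (≤ 16 nt
combined) and scores them by direct summation. The test suite checks, over
hundreds of randomized instances covering both modes, missing data, `N`
bases and random valid parameters, that the DP score equals the oracle
optimum and the DP alignment is a member of the oracle's co-optimal set.
`score_alignment()` re-sums any alignment independently of the matrices and
must agree with the DP score to $10^{-9}$.

## Benchmarking alignments

`alignment_sensitivity()` is deliberately strict: the percentage of
reference aligned pairs recovered *exactly* (no positional allowance).
Reference pairs are extracted from aligned FASTA or Clustal with the rule
that a column contributes a pair only when **both** rows hold a nucleotide —
columns with one gap carry no information about relatedness.

`reactivity_difference_distribution()` and `randomized_control()` implement
the distributional argument for the method. The randomization permutes the
y-side reactivities across the matched positions — the minimal null that
destroys the pairing while conserving each profile's reactivity multiset —
in 8 trials by default, and the related-versus-pooled-randomized samples
are compared with a Welch (unequal-variance) two-sample t-test. Welch is
the safer variant when one sample is 8× the size of the other; with
degenerate zero-variance inputs (possible in constructed cases) the p-value
is defined as 1 for equal means and 0 otherwise rather than erroring.
Histogram bin width defaults to 0.1 SHAPE units and is configurable.

## The synthetic generator

`sim_config()` fixes the study conditions for data-free testing; its
defaults are chosen once to be rRNA-realistic and are not tuning knobs:

* length 1500 nt (small-subunit rRNA scale), 25% substitution rate and 2%
  indel-opening rate with geometric lengths of mean 3 nt — comparable to
  the divergence of culturable-organism rRNA pairs with ~73% identity;
* a two-component reactivity model: paired positions exponential with mean
  0.1, unpaired with mean 1.0, with 55% of positions paired — the simplest
  model consistent with how SHAPE reactivity separates paired from
  unpaired nucleotides;
* homologous positions perturbed by a sign-symmetric exponential magnitude
  with rate $\lambda = 4$ (mean related difference 0.25 SHAPE units),
  reproducing the exponential |Δ| decay by construction. A perturbation
  that would cross zero is reflected upward instead of clipped, so the
  |Δ| magnitudes remain *exactly* exponential (a hard clip at zero would
  bias the retained magnitudes downward and break the distributional
  invariant the generator exists to provide) and reactivities stay
  non-negative;
* 5% missing data, injected independently in ancestor and descendant.

What the generator does **not** emulate: covariation (substitutions are
independent, not pair-compensating), locally correlated reactivity noise,
reactivity changes caused by the substitutions themselves, and multi-taxon
phylogeny. Passing tests on synthetic pairs therefore demonstrate that the
aligner recovers truth *when the exponential-similarity assumption holds*,
not that real rRNA meets that assumption — the latter is an empirical claim
about real probing data that this package can test but not generate.

Under the frozen defaults the SHAPE-only aligner recovers >90% of true
pairs and combined mode recovers strictly more — the qualitative ordering
(combined > SHAPE-only) that motivates carrying both signals.

## Consensus structure modeling

The two-step pipeline (`consensus_structure_pipeline()`) wraps ViennaRNA
rather than reimplementing any folding:

1. **Alignment folding.** `RNAalifold -p -r --maxBPspan 600` with one
   SHAPE file per sequence (Deigan-style pseudo-free energies with engine
   defaults). The partition-function pair probabilities are parsed from
   the engine's text output; pairs with probability **strictly greater**
   than 0.95 become consensus pairs.
2. **Constrained refolding.** Each consensus pair is mapped through the
   row's gaps to sequence coordinates; pairs landing on a gap or on bases
   that cannot form a Watson-Crick/G-U pair are dropped for that sequence
   (the single-sequence engine would reject them as constraints). The
   survivors are forced (`F i j 1` commands) in a SHAPE-directed
   `RNAfold --maxBPspan 600` run, and the returned MFE structure is
   verified to contain every constraint.

The consensus probabilities are taken from the alignment-level partition
function (not averaged per sequence); the threshold and span are options.
Engine version and full command lines are captured in the results for
provenance. Because the absolute numbers any such pipeline produces depend
on the folding engine release, the package's tests pin down the *contracts*
(strict threshold, constraint containment, determinism) on a designed
4-sequence hairpin whose stem is unambiguous, rather than asserting
engine-version-dependent benchmark values.

## Structure accuracy metric

`structure_compare()` scores a prediction against a reference as
sensitivity (reference pairs found) and PPV (predicted pairs correct),
after removing pseudoknotted and non-canonical pairs from **both**
structures (applying the same filter to both sides keeps the metric
symmetric: sens(A,B) = ppv(B,A)). A reference pair $(x, y)$ is matched by a
predicted $(x', y')$ when one end coincides and the other lies within the
refolding allowance (default 5 nt) — tolerating the small register shifts
that are common between covariation models and probing-supported
structures. Allowance 0 reduces to exact matching; increasing the
allowance is monotone non-decreasing in both metrics.

## Problem sizes and determinism

The shipped tests run on synthetic instances up to 2000 nt (seconds per
alignment) and on the 18-nt hairpin for the engine pipeline; the exhaustive
oracle is used at ≤ 7 nt per side where enumeration is cheap. Every
stochastic component takes an explicit seed — the simulator through
`sim_config(seed = )`, the randomized control through its `seed` argument —
and identical seeds give bit-identical results.

## Known limitations

* Pairwise only: multiple alignments are supported by exporting pairwise
  alignments in aligned FASTA for consistency-based MSA tools, not built
  internally.
* The aligner is global; there is no local or seeded mode for scanning
  long transcripts.
* Quadratic memory in the DP (three double matrices plus pointer
  matrices): a 10 kb × 10 kb alignment needs ~2.7 GB and is near the
  practical ceiling.
* Reference-structure comparison ignores pseudoknots entirely, by design
  of the metric.
* The Table-style rRNA benchmark requires the original probing dataset,
  which is not redistributed with the package; the benchmark harness
  (published parameters, reference-alignment readers, sensitivity tables)
  is fully functional and is exercised on synthetic data instead.
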