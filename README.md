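# shapealign

Structure-informed global alignment of RNA sequences from SHAPE chemical
probing data.

## The problem

Homologous RNAs conserve structure more strongly than primary sequence, but
alignment tools traditionally see only base identity. SHAPE probing (selective
2′-hydroxyl acylation analyzed by primer extension, read out at nucleotide
resolution by mutational profiling) measures local backbone flexibility for
every nucleotide of an RNA, and related nucleotides in accepted rRNA
alignments have strikingly similar reactivities: the distribution of absolute
reactivity differences |Δ| between truly related positions decays
exponentially, while randomly re-paired positions do not. `shapealign`
exploits that signal: it aligns RNAs *model-free* — from reactivities alone,
with no structure prediction step — or from reactivities combined with base
identity, and feeds the resulting alignments into SHAPE-directed consensus
secondary-structure modeling.

It is aimed at RNA structural biologists and bioinformaticians who have
per-nucleotide probing profiles (e.g. SHAPE-MaP) for homologous RNAs and want
alignments, alignment benchmarks, and consensus structure models from them.

## The method

Two reactivity profiles *x*, *y* are aligned by the Gotoh affine-gap global
dynamic program over matrices *D*, *P*, *Q*:

    P[i,j] = max( P[i-1,j] + GEP,  D[i-1,j] + GOP + GEP )
    Q[i,j] = max( Q[i,j-1] + GEP,  D[i,j-1] + GOP + GEP )
    D[i,j] = max( s(x_i, y_j) (+ b(x'_i, y'_j)) + D[i-1,j-1],  P[i,j],  Q[i,j] )

with `D[0,0] = 0`, `D[i,0] = GOP + i·GEP`, `D[0,j] = GOP + j·GEP`. The SHAPE
comparison score is a clipped line in the absolute reactivity difference,

    s(x_i, y_j) = max( m·|x_i − y_j| + b,  m + b ),

so with the default parameters (m = −2, b = 2) identical reactivities score
+2 and differences ≥ 1 SHAPE unit score 0. In combined mode a base-identity
term b(x′, y′) = MATCH (+2) or MISMATCH (−2) is added. Default gap penalties
are GOP = −5, GEP = −0.25 (SHAPE-only) and GOP = −6, GEP = −1 (combined).
Alignments are benchmarked as sensitivity: the percentage of reference
(covariation-curated) aligned pairs recovered.

For structure modeling the package wraps ViennaRNA: `RNAalifold` folds an
alignment with covariation (ribosum) scoring plus per-sequence SHAPE
pseudo-free energies; consensus pairs with pairing probability > 0.95 are
mapped to each sequence and forced as hard constraints in a SHAPE-directed
`RNAfold` refold (maximum pairing span 600 nt throughout). Predicted
structures are scored against reference models as sensitivity/PPV with a
5-nt local refolding allowance (one helix end fixed, the other within 5 nt);
pseudoknotted and non-canonical (non-WC, non-GU) pairs are excluded.

## Worked example

```r
library(shapealign)

# simulate a pair of homologous profiles with a known true alignment
sim <- simulate_homolog_pair(sim_config(seed = 1))

# align from SHAPE reactivities alone, then with base identity added
a1 <- gotoh_align(sim$px, sim$py, alignment_params("shape_only"))
a2 <- gotoh_align(sim$px, sim$py, alignment_params("combined"))
alignment_sensitivity(alignment_pairs(a1), sim$true_pairs)
#> [1] 92.49147
alignment_sensitivity(alignment_pairs(a2), sim$true_pairs)
#> [1] 98.08874
```

At rRNA-like divergence (25% substitutions, 2% indel rate, 1500 nt), the
SHAPE-only aligner recovers 92.5% of the true nucleotide pairs with no
sequence information at all, and adding base identity raises recovery to
98.1% — the qualitative ordering the method is designed around.

```r
# is the related-pair reactivity similarity real? compare against a
# randomized control (8 trials, y-side reactivities permuted)
ctrl <- randomized_control(sim$true_pairs, sim$px, sim$py, seed = 2)
ctrl$related_mean; ctrl$randomized_mean; ctrl$p_value
#> [1] 0.25316
#> [1] 0.7246873
#> [1] 0
```

Related positions differ by ~0.25 SHAPE units on average versus ~0.72 after
randomization (Welch p below double precision).

A shell entry point with `align` / `evaluate` / `histogram` / `optimize` /
`fold` / `simulate` subcommands is installed at
`system.file("scripts", "shapealign", package = "shapealign")`.

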