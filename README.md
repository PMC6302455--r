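# diffcornet

Differential co-expression network analysis for sparse single-cell
expression data.

## The problem

Single-cell RNA-seq matrices are mostly zeros: transcripts present in a
cell are frequently not captured. When two groups of cells are compared —
drug-resistant versus naive tumor cells, two developmental stages — the
biology of interest is often a *rewiring* of gene–gene co-expression
rather than a shift in any single gene's mean. Two obstacles stand in the
way of estimating that rewiring: a zero is not evidence of zero
co-expression, and once correlations are restricted to the cells where
both genes are detected, every gene pair carries a different sample size
and raw correlations stop being comparable.

`diffcornet` addresses both. It is aimed at computational biologists who
have a normalized genes × cells matrix and a two-state cell annotation
and want the gene pairs whose co-expression changes between the states,
with exact p-values and network/hub summaries ready for Cytoscape.

## The method

Within state *n* ∈ {0, 1}, each pair's Pearson correlation is computed
over its **support** — the state's cells where both genes are non-zero:

    Cⁿ(i,j) = ρ( E(i, x_ij), E(j, x_ij) ),   x_ij = {s : E(i,s) ≠ 0} ∩ {t : E(j,t) ≠ 0}
    Sⁿ(i,j) = ‖x_ij‖

The Fisher z-transformation puts all supports on one scale (standard
normal under the null):

    Iⁿ(i,j) = √(Sⁿ(i,j) − 3) · atanh Cⁿ(i,j)

The change in interaction strength, ΔI = |I¹| − |I⁰|, is tested against
the exact closed-form null CDF of the difference of absolute standard
normals,

    F(d) = ½ + erf(d/2) − ½·sgn(d)·erf(d/2)²,

so no permutation testing is needed. Pairs surviving Bonferroni
correction over the tested pairs form the differential network; genes are
ranked as hubs by their number of incident differential pairs.

## Worked example

```r
library(diffcornet)

fx <- make_fixture(genes = 20, cells0 = 50, cells1 = 50, sparsity = 0.25,
                   pairs = list(list(i = 3, j = 7, rho0 = 0, rho1 = 0.95)),
                   seed = 23)
fit <- diff_network(fx$E, fx$states)
fit
#> Differential co-expression network
#>   states: state0 (0) vs state1 (1)
#>   genes x cells after filtering: 20 x 100 (dropout 25.7%)
#>   gene pairs tested: 190; edges at adjusted p < 0.05: 1
#>   nodes: 2, mean degree: 1.00
#>   state-specific edges: 1 in state 1, 0 in state 0

fit$edges[, c("gene_i", "gene_j", "I0", "I1", "S0", "S1", "delta", "p_adj")]
#>   gene_i gene_j        I0       I1 S0 S1    delta       p_adj
#> 1   g003   g007 -1.527479 8.913757 28 28 7.386278 5.89579e-12
```

The fixture plants one pair (g003–g007) correlated only in state 1, with
a quarter of all entries zeroed. The fit recovers exactly that pair: its
interaction score rises from −1.53 (28 supporting cells, consistent with
noise) in state 0 to 8.91 in state 1, a change of 7.39 interaction units
with a Bonferroni-adjusted p of 6 × 10⁻¹² — the pair is specifically
correlated in state 1. The other 189 testable pairs are left out of the
network.

The simulation engine reports the operating characteristics of the
intra-state test under chosen covariance (`theta`), relative noise power
(`epsilon`), cell number (`K`) and eliminated fraction (`tau`):

```r
run_scenario(sim_config(theta = 0.7, epsilon = 0.1, K = 50, tau = 0.25,
                        seed = 1))
#> Simulation scenario: theta=0.7, epsilon=0.1, K=50, tau=0.25 (paired elimination)
#>   10000 pairs (20% correlated), rule: Bonferroni alpha=0.05, seed 1, 1 rep(s)
#>   accuracy: 0.891  sensitivity: 0.456  specificity: 1.000
#>   elapsed: 1.03 s; rounding: round-half-away-from-zero
```

Here 10,000 pairs (20% truly correlated at covariance 0.7, attenuated by
10% noise, 37 of 50 observations surviving elimination) are each tested
against zero; the strict Bonferroni rule calls essentially no null pair
(specificity 1.000) and finds 46% of the correlated ones.
`threshold_sweep()` and `calibrate_threshold()` trace and pin looser
per-test operating points; see the vignette in `vignettes/`.

## Command line

A thin CLI wraps the same functions:

```sh
diffcornet=$(Rscript -e 'cat(system.file("scripts", "diffcornet", package = "diffcornet"))')
Rscript $diffcornet fixture  --genes 20 --cells0 50 --cells1 50 --sparsity 0.25 --seed 3 --out fx/
Rscript $diffcornet run      --matrix fx/matrix.tsv --labels fx/labels.tsv --out results/
Rscript $diffcornet simulate --theta 0,0.3,0.7,1.0 --epsilon 0.05 --cells 50 --tau 0.25 --out sweep.tsv
```

`run` accepts dense TSV/CSV (gene rows, cell-id header) or MatrixMarket
`--format mtx` with `genes.txt`/`cells.txt`, plus a two-column
`cell<TAB>label` file, and writes `edges.tsv`, `network.sif`,
`network.graphml`, `hubs.tsv`, `nodes.txt` and `run_log.json`.

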