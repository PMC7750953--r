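# pumar

Genome-wide miRNA–target gene regulatory network inference by message
passing, with downstream tissue-specificity, enrichment and community
analyses.

## What it does

MicroRNAs (miRNAs) repress their target mRNAs, but sequence-based target
prediction resources (TargetScan- or miRanda-style edge lists) disagree with
each other and with reality, and miRNA expression alone is a poor proxy for
regulatory activity.  `pumar` implements **PUMA** (PANDA Using MicroRNA
Associations), a message-passing algorithm that refines a bipartite
target-prediction prior against target-gene co-expression:

- three z-score-normalised networks — the regulator×gene prior `W`, the
  regulator×regulator cooperativity `P`, the gene×gene co-expression `C` —
  exchange messages through the continuous Tanimoto kernel
  `T(x, y) = x·y / sqrt(‖x‖² + ‖y‖² − |x·y|)`;
- each iteration mixes the **responsibility** `R_ij = T(P_i·, W_·j)` and
  **availability** `A_ij = T(W_i·, C_·j)` into `W` with learning rate `α`,
  until the mean absolute update `h` falls below `tol`;
- the PUMA modification: rows and columns of `P` belonging to miRNAs are
  reset to their initial values at every iteration — miRNA cooperativity is
  input, never learnt.  With no miRNAs flagged the engine is bit-identical
  to PANDA.

Because co-expression is consulted at every step, the refined network can
rank an interaction highly even when the prior missed it ("learning new
edges") and down-weight prior edges without expression support.

Downstream of the core algorithm the package provides, for collections of
per-tissue networks: tissue-specificity scores
`s_ij(t) = (w_ij(t) − med w_ij) / IQR w_ij` and edge multiplicities
(`s > 2`); pre-ranked GSEA on per-miRNA targeting profiles with a seeded
permutation null and signed `−log10(FDR)·sign(ES)` scores; binarisation at
strict FDR/ES thresholds followed by fast-greedy community detection on the
bipartite miRNA/tissue×gene-set graph; and a synthetic-data generator with
planted co-expression modules so every step is testable against ground
truth.

## Worked example

```r
library(pumar)

cfg <- simulate_config(seed = 1)            # 20 miRNAs, 60 genes, 4 tissues
sim <- simulate_regulatory_data(cfg)

fits <- lapply(names(sim$expression), function(t)
  suppressWarnings(run_puma(sim$prior_a, sim$expression[[t]], mirna = sim$mirna)))
names(fits) <- names(sim$expression)

fits[[1]]
#> <puma_fit> puma mode: 20 regulators x 60 genes
#>   200 iteration(s), NOT converged (final h = 0.00826, tol = 0.001)

scores <- edge_specificity(collect_networks(fits))
evaluate_recovery(fits, sim$truth)
#> # A tibble: 1 × 8
#>   auroc_all auroc_prior_absent median_planted median_prior_absent_planted
#>       <dbl>              <dbl>          <dbl>                       <dbl>
#> 1     0.948              0.862           4.79                       0.822
#> # ℹ 4 more variables: median_background <dbl>, ts_recovery <dbl>, ...
```

The AUROC of 0.95 says planted regulator–module edges rank far above
background in the refined networks; 0.86 restricted to planted edges that
were *removed* from the prior shows the algorithm learning edges from
co-expression alone (their median weight, 0.82, sits well above the
background median of −0.23 on the z-score-like weight scale).  The
"NOT converged" flag is expected: in all-miRNA mode the default 200-iteration
cap is an early stop — see the methods vignette
(`vignettes/mirna-regulatory-networks.Rmd`) for why full convergence takes
~900 iterations and what the cap trades off.

Smaller building blocks are exported individually: `normalize_network()`,
`tanimoto()`, `compute_coexpression()`, `message_passing_step()`,
`edge_specificity()`, `multiplicity()`, `expression_specificity()`,
`classify_edges()`, `compare_collections()`, `preranked_gsea()`,
`target_enrichment()`, `binarize()`, `detect_communities()`,
`compare_partitions()`, plus `tidy()`/`glance()`/`autoplot()` methods for
fitted objects.

## Command line

A thin CLI over the same functions is installed at `exec/puma`
(subcommands `run`, `specificity`, `gsea`, `communities`, `compare`,
`compare-communities`, `simulate`):

```sh
puma run --prior inst/extdata/example_prior.tsv \
         --expression inst/extdata/example_expression.tsv \
         --mirna inst/extdata/example_mirna.txt --out net.tsv
puma simulate --config inst/extdata/example_config.yaml --out simdir/
```

Every command writes a `.meta.json` sidecar with its parameters and run
statistics.  All shipped example data under `inst/extdata/` are synthetic.

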