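# proxiscore

Relative spatial proximity of non-cancer cell-type pairs to cancer cells in
single-cell spatial tables from multiplexed tissue imaging (imaging mass
cytometry, multiplexed IF), and its association with survival and treatment
response.

## The problem

Highly multiplexed imaging yields per-image tables of cell centroids with
phenotype labels. Absolute infiltration levels of single immune cell types
are noisy prognostic markers; the *relative* proximity of two immune cell
types to the cancer cells is often more informative. For a pair of
non-cancer types (X, Y), **proxiscore** computes the relative-distance
score

```
RD(X -> Y) = dbar_X / (dbar_X + dbar_Y)
```

where `dbar_T` is the mean, over all cancer cells in an image, of the
distance from each cancer cell to its nearest cell of type `T`, capped at
500 µm per cell (a type absent from the image contributes exactly 500 µm).
RD < 0.5 means X sits closer to the cancer cells than Y. By construction
`RD(X->Y) + RD(Y->X) = 1`, so only canonical pairs (lexicographically
smaller label first) are kept: k types give k(k-1)/2 pairs.

Because raw RD also responds to cell density, the **normalized RD (NRD)**
z-scores each RD against a permutation null in which non-cancer labels are
shuffled over the fixed non-cancer positions (1000 permutations by
default):

```
NRD = (RD - mean(RD*)) / sd(RD*)
```

Downstream, the package joins per-patient scores to clinical tables: Cox
models (per-SD hazard ratios), median-split Kaplan–Meier with log-rank
tests, Benjamini–Hochberg FDR, rank-based AUC for responder classification
with the rescaling `AUC' = 0.5 + |AUC - 0.5|`, and a directed network of
FDR-significant pairs oriented favorable → unfavorable. A synthetic cohort
generator with known spatial interactions and outcome effects
(LUAD-like survival and TNBC-like two-arm response presets) makes every
stage testable end to end.

## Worked example

Simulate a 120-patient survival cohort in which the hazard increases with
the RD score of the B → IntMo pair (per-SD log-hazard 0.8), then run the
full survival workflow:

```r
library(proxiscore)

cfg <- luad_sim_config(n_patients = 120, field_size = 500, beta = 0.8,
                       seed = 42)
cohort <- simulate_cohort(cfg)

run <- run_config(cells = cohort$images, clinical = cohort$clinical,
                  n_perm = 200, seed = 1)
res <- run_survival_workflow(run)

head(res$assoc[order(res$assoc$fdr),
               c("family", "feature", "hr", "p_value", "fdr")])
#>        family            feature    hr  p_value      fdr
#> 19         rd           B->IntMo 2.101 3.14e-08 3.30e-06
#> 61         rd Endothelial->IntMo 1.658 1.03e-05 5.40e-04
#> 232 abundance     fraction:IntMo 1.617 2.71e-05 4.06e-03
#> 6          rd      AltMac->IntMo 1.624 1.47e-04 5.15e-03
#> 247 abundance    mean_dist:IntMo 0.549 7.87e-05 5.90e-03
#> 217 abundance      density:IntMo 1.536 2.51e-04 1.25e-02
```

The ground-truth pair tops the table (HR 2.10 per SD, FDR 3.3e-06), ahead
of every conventional abundance feature. The significant pairs form a
directed network; the simulated pro-tumor type collects all the in-degree:

```r
res$network
#> Pair network: 12 significant pair(s) at FDR < 0.05, 15 cell type(s)

head(res$network$edges[order(res$network$edges$fdr), ], 4)
#>           from    to    hr      fdr
#> 2            B IntMo 2.101 3.30e-06
#> 7  Endothelial IntMo 1.658 5.40e-04
#> 1       AltMac IntMo 1.624 5.15e-03
#> 10          Tc IntMo 0.675 1.47e-02
```

For response cohorts, `run_response_workflow()` filters an arm and
timepoint, scores the TME pair universe against the aggregate cancer
compartment and each requested cancer-subtype reference, and writes one
AUC/AUC' row per (pair, reference).

A command-line dispatcher over the same functions ships at
`system.file("cli", "proxiscore", package = "proxiscore")` with
subcommands `rd`, `nrd`, `features`, `assoc-survival`, `assoc-response`,
`simulate` and `run` (exit codes: 0 ok, 2 schema/config error, 3
statistical degeneracy).

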