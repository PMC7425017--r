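# sifcall

Significant-interacting-fragment calling for Hi-C paired-end ligation data,
at restriction-fragment resolution.

Hi-C libraries mix three kinds of ligation products: self-ligations
(re-circularised fragments), re-ligations (re-joined cut sites) and valid
ligations. Valid ligations are themselves dominated by random collisions
whose frequency decays with genomic distance as a power law, with genuine
spatial contacts (*proximate* ligations) hidden among them. `sifcall`
separates the two at the level of individual restriction-fragment pairs,
for analysts who want loop calls attached to single genes and regulatory
elements rather than fixed multi-kilobase bins.

## The model

For every fragment pair, the score `D` is the number of deduplicated valid
read pairs joining it. Scores are modelled as a two-component Poisson
mixture

```
L(D; θ) = Π_l Σ_k ω_k g(D_l; λ_k),     k = 1 (random), 2 (proximate)
```

fitted by EM (optionally bootstrap-robustified with inner-fence trimming of
per-round estimates). A power-law fit of ligation probability against
distance, combined with a digestion-efficiency term `(1 − E)^|k−j|`
multiplied over the `K` fragments flanking one anchor, scores how easily the
*background* model explains each record; near-diagonal artifact records
score high and are removed. Significance uses a per-score local FDR,

```
FDR_d = FP_d / (FP_d + TP_d)
```

with `TP_d` the proximate-component Poisson pmf and `FP_d` an empirical
null resampled from the observed score multiset. Records with
`score > FTR` and monotonised `FDR(score)` below the cut-off are calls;
adjacent equal-score calls merge, and the merged anchor lengths define the
per-anchor resolution. Downstream helpers classify promoter-distal loops
(P1D1/P1D2 around annotated TSSs), compare conditions, and evaluate loop
sets by aggregate peak analysis (APA) and ROC/AUC against a reference.

See `vignettes/sif-calling-model.Rmd` for the full account of the model,
parameter defaults and design decisions.

## Worked example

Everything below runs on synthetic data with known ground truth — the
generator plants 50 true loops (mean score 8) among ~2500 background
fragment pairs on a 1000-fragment chromosome:

```r
library(sifcall)

sc  <- simulate_hic_scenario(seed = 7)
run <- run_pipeline(sc$pairs, sc$map, run_config(seed = 7))
run
#> SIF pipeline run: 3289 pairs -> 2414 valid -> 1287 records -> 44 candidates -> 44 SIFs
#>   mixture: omega = (0.972, 0.028), lambda = (1.650, 9.557)
#>   background: alpha = -0.732, 11 records removed

tidy(run$fit)
#> # A tibble: 2 × 3
#>   component weight lambda
#>   <chr>      <dbl>  <dbl>
#> 1 random    0.972    1.65
#> 2 proximate 0.0280   9.56

head(run$sifs[, c("start1", "end1", "start2", "end2", "score", "fdr")], 3)
#> # A tibble: 3 × 6
#>   start1   end1  start2    end2 score    fdr
#>    <int>  <int>   <int>   <int> <int>  <dbl>
#> 1   6227  11139 2173354 2177661    14 0.0132
#> 2 164748 169911  467199  468535    14 0.0132
#> 3 248014 248148 3388681 3396251     7 0.0663

score_against_truth(run, sc$truth)
#> # A tibble: 1 × 6
#>   n_true n_called n_recovered n_false sensitivity    fdp
#> 1     50       44          42       2        0.84 0.0455
```

Reading the output: of 3289 read pairs, 2414 are valid ligations collapsing
to 1287 scored fragment pairs. The mixture puts 97% of records in the
random component (fitted mean 1.65 — the zero-truncated mean of the planted
Poisson(1) background, as expected) and finds the proximate component near
the planted mean of 8. At the default operating point (FTR = 1,
FDR < 0.1), 44 fragment pairs are called: 42 of the 50 planted loops, with
2 false calls (observed false discovery proportion 0.045 at nominal 0.1).
The eight loops missed are those that drew fewer than ~6 reads — below any
threshold separating them from the background.

A shell front end wrapping the same functions ships at
`inst/scripts/sifcall` (subcommands `digest`, `qc`, `fit`, `background`,
`call`, `annotate`, `compare`, `apa`, `roc`, `simulate`, `run`).

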