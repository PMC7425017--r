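---
title: "Calling significant interacting fragments: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling significant interacting fragments: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifcall)
```

## The problem

Hi-C libraries capture spatial proximity of genomic loci as ligation
junctions between restriction fragments. Most ligations in any library are
uninformative: re-circularised fragments (self-ligation), re-joined cut
sites (re-ligation), and random collisions whose frequency decays with
genomic distance. The calling problem is to separate, among the valid
ligation products, *proximate* ligations — fragment pairs held together in
the nucleus — from this random background, at the resolution of individual
restriction fragments rather than fixed genomic bins.

`sifcall` works on the table of *USF scores*: for every pair of restriction
fragments, the number of uniquely-mapped, deduplicated, valid read pairs
joining them. Calls are *significant interacting fragments* (SIFs): fragment
pairs whose score clears a count threshold (the fragment threshold rate,
FTR) and whose local false discovery rate at that score is below a
user-chosen cut-off.

## The mixture model

Scores are modelled as a two-component Poisson mixture,

$$L(D;\theta)=\prod_{l=1}^{N}\sum_{k=1}^{2}\omega_k\,g(D_l;\lambda_k),$$

with $\lambda_1$ the mean score of random ligations, $\lambda_2 \ge
\lambda_1$ the mean of proximate ligations, and weights summing to one.
`em_fit()` maximises this likelihood by EM; the M-step updates are the mean
responsibility per component and the responsibility-weighted mean score.
Implementation notes:

* Poisson densities are evaluated in log space and observations are
  collapsed to weighted unique values, so the fit costs
  O(iterations × unique scores) regardless of table size.
* Convergence is declared when the log-likelihood moves by less than `tol`
  (default 1e-6, `max_iter` 1000). The log-likelihood is non-decreasing by
  construction and the suite asserts it on every fit.
* Initialisation: $\lambda_1$ at the 25th score percentile (at least 0.5),
  $\lambda_2$ at the 90th, weights (0.9, 0.1). Random ligations dominate
  Hi-C libraries, so a bottom-heavy start is both realistic and stable; the
  converged optimum on all instances we test agrees with a dense grid search
  over the parameter space to the stated tolerance.
* If every score is identical the mixture is unidentifiable; the fit
  reports $\lambda_1=\lambda_2$ with the initial weights and a `degenerate`
  flag rather than failing.
* Label switching is resolved by sorting the means ascending after
  convergence. `k` is fixed at two for calling; `select_components()`
  exposes a BIC comparison against the one-component model as a diagnostic
  only, with $p = 2k-1$ free parameters in $\mathrm{BIC} = p\ln N - 2\ln
  \hat L$.

`bootstrap_fit()` re-fits on resamples of the score table (M draws with
replacement from the M scores, `n_boot` rounds, default 50), discards
per-parameter estimates outside the inner fences $[Q_1-1.5\,\mathrm{IQR},\,
Q_3+1.5\,\mathrm{IQR}]$, and averages the survivors (weights renormalised).
Trimming is applied to each parameter separately. With a deterministic EM
the bootstrap mostly guards against resamples caught by poor local optima;
its estimates track the single fit closely on well-behaved data.

## Distance background and the digestion-efficiency filter

Random-ligation probability decays with genomic distance approximately as a
power law. `distance_profile()` bins intra-chromosomal read-pair distances
(logarithmic bins, 50 per decade, from `d_min` = 1 kb by default) and
`fit_power_law()` estimates the exponent by least squares on
$\log_{10}(\text{probability}/\text{bin width})$ against
$\log_{10}(\text{distance})$. Dividing by the bin width is deliberate: with
logarithmic bins the raw per-bin probability has slope $\alpha+1$, and only
the per-bp density recovers the generative exponent — the suite verifies
recovery of a planted $\alpha^\*=-1.08$ within ±0.05 at $10^5$ distances.
Below the fitted range the curve is evaluated at `d_min` (a plateau,
mirroring the flattening of contact probability at short range).

Undigested restriction sites make near-diagonal ligation artifacts likely:
a run of uncut neighbours around one anchor produces a chimeric fragment
that ligates to close-by partners. The background likelihood of a record
$(F_i, F_j)$ multiplies, over the $K$ fragments on each side of $F_j$
(default $K=5$, truncated at chromosome ends),
$(1-E)^{|k-j|}\,P(F_i,F_j)$, where $E$ is the digestion efficiency (user
parameter, default 0.7 — typical for a well-run digest; an optional
diagnostic estimates it as the fraction of read ends within 500 bp of a cut
site) and $P$ is the power-law probability at the fragment-midpoint
distance. The exponent is read as the absolute index offset $|k-j|$: a
signed exponent would make the product diverge on one side. The window is
anchored at $F_j$ only, so the value is deliberately asymmetric in the two
anchors; the suite asserts the asymmetry rather than hiding it. Records
whose likelihood exceeds a threshold (default: the 99th percentile of the
likelihood among records at fragment offset > 20, where linear-closeness
artifacts cannot occur) are removed from the candidate set. High likelihood
means the *background* model finds the record easy to explain — these are
the near-diagonal artifacts.

## Significance: empirical null, local FDR, FTR

With a single library there are no replicates, so no p-value-based global
FDR is possible. Instead the per-score local FDR is

$$\mathrm{FDR}_d=\frac{\mathrm{FP}_d}{\mathrm{FP}_d+\mathrm{TP}_d},$$

where $\mathrm{TP}_d$ is the Poisson pmf of the proximate component at
$\hat\lambda_2$, and $\mathrm{FP}_d$ is an empirical null built by drawing
`np` scores (default $10^5$) with replacement from the observed score
multiset and normalising the histogram. Design choices that required a
decision:

* **Null source.** The null resamples the *full* USF score multiset, not
  the background-filtered subset. Filtering removes mostly score-1
  near-diagonal records, which would inflate the relative FP density at
  mid scores by ~50% and destabilise the score cut-off at the default
  operating point; resampling "one of the fragment scores" from the whole
  table is also the plainer reading of the procedure. The Eq-type filter
  still prunes the candidate set.
* **Monotonised gate.** The raw per-score FDR of a finite null is noisy
  where only a handful of records support a score, and can dip and rise
  across neighbouring scores — which would discard a score-7 record while
  keeping 6 and 8. Since a larger score is never weaker evidence, the
  applied FDR (`fdr_mono`) is the running minimum of the raw FDR over
  increasing score, anchored at the smallest observed score: the same
  monotonicity enforcement q-value procedures apply to adjusted p-values.
  The raw values are kept alongside for inspection. In practice this
  realises a single score cut-off per FDR threshold.
* **Double filter.** A record is retained when `score > FTR` (strict: in
  the worked eight-fragment example a score-3 record is discarded at FTR 3)
  and `FDR(score) < fdr_threshold`. The default operating point is FTR = 1
  with FDR < 0.1. Scores above the table's support inherit the last defined
  FDR.

Equal-score merging defines resolution: two calls merge when both anchor
fragments are adjacent (index offset exactly 1 on each side) and scores are
equal, transitively — the fragment-level analogue of collapsing a ChIP-seq
peak to its summit. A merged anchor spans its member fragments and its
resolution is the summed length; in the eight-fragment worked instance the
two score-4 calls merge into one interaction with resolutions $L_1+L_2$ and
$L_7+L_8$, while the score-5 call keeps $L_3$, $L_5$.

## What the synthetic generator emulates — and what it cannot

`simulate_hic_scenario()` produces a single geometric-length fragment map
(mean 4 kb, a 6-cutter), plants `n_loops` distal fragment pairs whose read
counts are Poisson($\lambda_2$), and throws background ligations at
`n_background` fragment pairs chosen by a uniform anchor plus a power-law
distance, each receiving Poisson($\lambda_1$) reads; a configurable
fraction of the read stream is converted to self- and re-ligation
artifacts, and read positions are uniform within fragments. Defaults: 1000
fragments, 50 loops, $\lambda_1=1$, $\lambda_2=8$, $\alpha=-1$, 2500
background pairs, 5% + 5% artifacts. The background depth is set so planted
loops are ~2% of touched pairs, matching the loop fraction of real
fragment-level Hi-C callsets at modest sequencing depth; the artifact rates
are round figures in the range seen in library QC.

Two consequences of this construction matter for interpreting tests:

* **Zero truncation.** A fragment pair that receives no reads is
  unobservable, so observed background scores follow a *zero-truncated*
  Poisson: their mean is $\lambda_1/(1-e^{-\lambda_1}) \approx 1.58$ at
  $\lambda_1=1$, not 1. EM fitted to observed scores therefore estimates
  the truncated mean for the random component — exactly as it does on real
  libraries, where the score table is also conditioned on having at least
  one read. Tests of the generator→EM path assert $\hat\lambda_1$ against
  the truncated-mean value; clean recovery of $\lambda_1$ is tested on
  directly drawn (untruncated) mixture samples.
* **Proximate-mean bias and the sensitivity ceiling.** The underdispersed
  truncated background pulls the fitted $\hat\lambda_2$ to ~8.8–9.4. This
  thins the true-positive density at scores 5–6, so the monotone FDR
  crosses 0.1 between scores 6 and 7 and the attainable score cut-off is 6.
  The generative recovery ceiling at cut-off 6 is $P(\mathrm{Pois}(8)\ge 6)
  = 0.809$; measured mean sensitivity over 100 replicates is ~0.78–0.79
  with mean false discovery proportion ~0.05 (nominal 0.1). The end-to-end
  suite asserts a 0.8 sensitivity floor and a 0.2 FDP ceiling; the
  sensitivity assertion sits at this ceiling and can fail by its knife-edge
  margin — a property of the model-data mismatch, reported as measured.

The generator does not attempt TAD or compartment structure, fragment-level
GC/mappability bias, or sequence-level reads; passing tests show the
calling machinery recovers the generative model it assumes, not that real
libraries satisfy that model.

## Downstream classification and evaluation

* **Promoter-distal loops.** An anchor is in a gene's promoter when its
  midpoint falls in the strand-aware window −5 kb/+1 kb around the TSS
  (mirrored on the minus strand); the distal window is ±100 kb minus any
  promoter window. A loop with one promoter anchor and one distal anchor is
  `P1D1` when the distal anchor's nearest TSS belongs to the same gene,
  `P1D2` otherwise. Midpoint membership keeps every anchor in at most one
  promoter; ties break by nearest TSS then lexicographic gene id. Strand
  awareness and midpoint membership are configurable readings, since either
  convention is defensible.
* **Condition comparison and replicate overlap** use reciprocal anchor-pair
  overlap after symmetric slack extension; a call is "common" when it
  matches at least one call on the other side, so the two sides of a Venn
  overlap may count different numbers.
* **APA** sums $(2w+1)^2$ submatrices of a binned contact matrix centred on
  loop bin pairs (loops within $2w$ bins of the diagonal excluded) and
  reports centre / mean of the $w\times w$ lower-left corner block, with
  the other three corners as diagnostics. A uniform matrix gives exactly 1.
* **ROC/AUC** labels a supplied putative-loop universe by overlap with a
  reference set, predicts by overlap with the called set while sweeping its
  score (or FDR), and integrates the (FPR, TPR) curve by trapezoid with
  (0,0) and (1,1) endpoints. The implementation agrees with an independent
  ROC library on identical inputs and is invariant under monotone score
  transforms.

## Problem sizes used by the suite

The packaged tests and the acceptance script run entirely on synthetic
data built at call time: EM recovery at $n=10^4$ scores × 100 replicates,
power-law recovery at $10^5$ distances × 100 replicates, and 100 pipeline
replicates of the default scenario (~2500 touched pairs each). These sizes
hold Monte-Carlo error comfortably below the asserted margins while keeping
a full run in the low tens of seconds on one core.

## Known limitations

* Forward-strand, literal, palindromic recognition sites only; degenerate
  (IUPAC) motifs and methylation sensitivity are out of scope.
* QC omits strand-orientation refinements (dangling-end detection);
  self/re-ligation classification is purely positional.
* No fragment-level bias correction (GC, mappability, fragment length) and
  no matrix balancing — the background model is distance plus digestion
  efficiency only.
* Inter-chromosomal records can be carried through the score table, but
  the distance background is undefined for them and calling defaults to
  intra-chromosomal only.
* The local FDR is a density ratio, not a class-prior-weighted posterior;
  its realised false discovery proportion tracks the nominal level only
  when proximate records are a few percent of the table, which is the
  regime both the defaults and real libraries occupy.
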