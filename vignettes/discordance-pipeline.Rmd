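---
title: "Consensus perturbation signatures and discordance-based response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus perturbation signatures and discordance-based response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdiscord)
```

# The analysis problem

Connectivity-map style drug repositioning asks whether a compound's
transcriptional effect *opposes* the expression program of a disease
subtype. If a drug pushes down the genes a tumor subgroup over-expresses
(and vice versa), the drug is a candidate therapy for that subgroup. The
motivating application is pediatric medulloblastoma (MB), whose four
molecular subgroups — WNT, SHH, Group 3 (G3) and Group 4 (G4) — differ
sharply in outcome: MYC-amplified G3 tumors carry the worst prognosis and
the greatest need for new agents.

`sigdiscord` implements the full desk pipeline for this question:

1. **Consensus response signature** from multi-cell-line differential
   z-score profiles (LINCS L1000 level-5 style data).
2. **Subgroup-differentiating disease signatures** from a labeled tumor
   expression cohort.
3. **Discordance scoring** of drug vs. subgroup by Spearman rank
   correlation, with a negative correlation predicting response.
4. **Patient stratification**: hierarchical clustering on signature genes,
   and quartile stratification of aggregated gene-set expression with a
   Q4-vs-Q1 log-rank survival comparison.
5. **Dependency ranking** of signature genes against RNAi/CRISPR screen
   scores.
6. **HSA synergy scoring** of two-agent dose-response surfaces, and the
   sigmoidal EC50 / one-phase-decay fits used around such experiments.

Every stage runs on synthetic data with planted, recoverable ground truth,
so the whole pipeline is testable without any external downloads.

# Models and procedures

## Consensus response signature

Input is a genes x samples matrix of differential expression z-scores, one
column per (cell line, timepoint), approximately standard-normal under the
null. After restricting to one timepoint (default `"24 h"`) and averaging
replicates within cell line (`collapse_cell_lines()`), `build_consensus()`
retains gene $g$ iff

$$\frac{\#\{l : z_{gl} \ge z_{\min}\}}{n_{\text{lines}}} \ge \tau
\quad\text{XOR}\quad
\frac{\#\{l : z_{gl} \le -z_{\min}\}}{n_{\text{lines}}} \ge \tau$$

with defaults $\tau = 0.30$ (the gene must change in the same direction in
at least 30% of cell lines) and $z_{\min} = 2$ (roughly two-sided 0.05 on a
standard-normal score; the retention threshold for "changed" is not
canonical, so it is an exposed parameter). The consensus value is the mean
z over **all** cell lines, responders and non-responders alike — this makes
the signature an honest average effect rather than a responder-only
estimate. Missing values are handled available-case in both the fractions
and the mean.

Two deliberate consequences of the XOR rule are worth noting:

* A gene meeting $\tau$ in *both* directions is direction-conflicted and
  excluded: a consensus signature must assign each gene one direction.
* Retention is therefore monotone in $\tau$ only up to conflicted genes: a
  gene excluded at a loose $\tau$ because both directions qualified can
  reappear at a stricter $\tau$ where only one direction survives. The
  property tests assert exactly this qualified monotonicity.

`top_genes()` ranks by $|\bar z|$ (the natural effect-size ordering; ties
broken lexicographically for determinism), and `split_directions()`
partitions the signature into its up- and downregulated arms, the latter
feeding the dependency ranking.

## Disease signatures

For each gene and subgroup, the signature value is the log2 fold change of
the subgroup's central expression against the whole cohort. Two variants
exist because both are in common use: `subgroup_log2fc()` uses the median
(robust; the "disease signature") and `subgroup_markers()` the mean (the
"subgroup markers"). On log2-scale data the value is a difference of
centers; on linear-scale data it is
$\log_2\!\big((c_{\text{sub}} + \varepsilon)/(c_{\text{all}} + \varepsilon)\big)$
with pseudocount $\varepsilon = 1$ by default (standard for nonnegative
intensities, configurable). The median of an even-sized group is the
conventional midpoint of the two central order statistics. Either variant
can feed the scorer; the median form is the default throughout because it
is robust to the heavy-tailed outliers typical of expression data.

## Discordance scoring

`discordance_score()` aligns the genes shared between drug and disease
signatures (exact id match, minimum 3 — Spearman is degenerate below that)
and computes Spearman's $\rho$ with average ranks for ties. The response
prediction is the bare sign rule $\rho < 0$: the stated decision criterion
is the negative correlation itself, not a significance threshold. A
two-sided permutation p-value (gene-label shuffles, default 10,000, seeded,
computed by a vectorized rank-matrix product) is reported alongside for
context but does not gate the call.

## Quartile survival analysis

`geneset_score()` averages the expression of a gene list per patient;
`quartile_stratify()` sorts patients ascending by score (ties broken by
patient id, so the split is deterministic) and cuts four contiguous rank
blocks whose sizes differ by at most one; when $n \bmod 4 > 0$ the extra
patients go to the outer quartiles first (Q1, then Q4, then Q2), so
$n = 10$ gives sizes 3, 2, 2, 3. `q4_vs_q1_survival()` compares overall
survival between the top and bottom quartiles with the two-group
Mantel–Cox log-rank statistic

$$\chi^2 = \frac{(O_A - E_A)^2}{V},$$

expected events and hypergeometric variance summed over distinct event
times, tied deaths counted together; Q2/Q3 patients are excluded, as the
comparison is defined between the extreme quartiles. The statistic is
computed via `survival::survdiff`; the test suite checks it against an
independent explicit event-table implementation on hundreds of random
datasets. With a single-gene list the same operation is the per-gene
outcome-predictor analysis (e.g. MYC expression in G3).

## Patient clustering

`cluster_patients()` restricts to the signature genes, standardizes each
gene to mean 0 / sd 1 across patients (so distance is not dominated by
high-variance genes; constant genes are dropped with a warning), and
agglomerates with Euclidean distance and complete linkage by default —
the defaults of the common heatmap-clustering stacks; both knobs are
exposed since no single choice is canonical.

## Dependency ranking

`rank_dependencies()` averages each gene's dependency score over the
selected cell-line columns and sorts ascending: more negative means the
screen found the gene more essential. Genes absent from the table are
reported last and flagged rather than imputed.

## HSA synergy

On the inhibition scale (0 = no effect, 100 = full kill; viability input is
converted by `to_inhibition()`), the highest-single-agent reference for a
dose pair $(a, b)$, $a, b > 0$, is
$\max\{R(a, 0),\, R(0, b)\}$ — the better of the two single agents at those
doses. The synergy score is the unweighted mean of the observed excess over
this reference across all combination cells, in percentage points.
Classification uses the conventional thresholds: above $+10$ synergistic,
below $-10$ antagonistic, otherwise additive; the boundary values
themselves classify as additive.

## Curve fits

`fit_4pl()` fits the four-parameter logistic
$y = \text{bottom} + (\text{top} - \text{bottom}) / (1 + (\text{EC}_{50}/x)^{h})$
by Levenberg–Marquardt least squares (multi-start over EC50 at the
nonzero-dose quantiles crossed with Hill slopes 0.5/1/2; lowest residual
sum of squares wins; tight `ftol`/`ptol` so noiseless data are recovered to
machine precision). Zero-dose (vehicle) wells are evaluated at the model's
exact $x \to 0$ limit — which is `bottom` for $h > 0$ — rather than at a
surrogate small dose; the limit form anchors the lower asymptote without
introducing any approximation error into the fit. For responses normalized
to vehicle and full kill, `fix_bottom = 0` / `fix_top = 100` gives the
standard normalized-response model; anchoring the asymptotes roughly halves
the EC50 sampling error on noisy single-plate data and is what normalized
viability assays conventionally use. Fit failures (degenerate or
non-converging data) are returned as values with `converged = FALSE`, never
exceptions, so batch processing of many curves does not abort.

`fit_one_phase_decay()` fits
$y(t) = (y_0 - \text{plateau})\,e^{-kt} + \text{plateau}$ with $k > 0$ and
reports the half-life $\ln 2 / k$; the plateau can be fixed (e.g. at 0 for
a fully degradable protein normalized to a loading control). Fits pinned at
the lower $k$ bound or with $y_0 \le$ plateau describe growth, not decay,
and are flagged `converged = FALSE` so a negative or meaningless half-life
is never reported.

# The synthetic-data generators

All generators are pure functions of their specification (same spec + seed,
identical output; the caller's RNG stream is left untouched). They emulate
the *structure* the pipeline consumes, with planted effects the downstream
stages must recover.

* `simulate_perturbation_set()`: 18 cell lines by default (the scale of the
  multi-line perturbation sets this emulates), background z-scores
  $\mathcal N(0, 1)$ (level-5 scores are approximately standard normal
  under the null), planted genes shifted by $\pm 4$ z-units in a random
  half of the cell lines — a strong but not universal responder pattern.
* `simulate_cohort()`: log2-scale expression, baseline
  $\mathcal N(6, 1)$ (microarray-like), default subgroup mix
  WNT 10% / SHH 30% / G3 25% / G4 35% (the approximate frequencies in
  published MB cohorts), 20 planted markers per subgroup at +2 log2 units.
  When a discordant subgroup is requested its markers are the drug
  signature's genes shifted *opposite* to the consensus direction — the
  exact structure the scorer is supposed to flag. Survival is exponential
  with baseline median 1500 days (a plausible pediatric high-risk figure);
  membership in the realized top quartile of mean planted-gene-set
  expression multiplies the hazard by the specified Q4-vs-Q1 ratio, with
  middle quartiles at the geometric interpolation — the simplest generative
  model whose planted effect the quartile/log-rank stage can recover.
  Censoring marks each patient censored with the given probability at a
  uniform fraction of the event time.
* `simulate_dose_response()`: single agents follow 4PL inhibition curves;
  each combination cell is the HSA expectation plus the planted excess plus
  noise, clipped to $[0, 110]$ (the plausibility window of the reader). The
  default 2-fold grid and $EC_{50} = 10$ keep the single-agent margins
  within about 23–75% inhibition, so any noiseless planted excess in
  $[-23, +35]$ survives the clipping untouched and is recovered *exactly*
  by `hsa_score()` — a designed property, used by the tests.
* `simulate_dependency_table()`: planted essential genes score
  $\mathcal N(-1.5, 0.3)$, background $\mathcal N(0, 0.3)$ — strong
  essentials on the usual "more negative = more required" scale.

What the generators do **not** emulate: probe effects, batch structure,
normalization artifacts, copy-number contamination of expression,
subgroup-correlated survival confounding, or non-proportional hazards.
Passing tests therefore demonstrate that the *algorithms* recover planted
structure under clean Gaussian noise at realistic sizes — not that the
pipeline is robust to every artifact of real microarray or viability data.

# Numerical and design choices

* **Quartile ties and split**: deterministic id-order tie-breaking and the
  outer-first remainder rule are documented choices; no convention is
  canonical and determinism matters for reproducible stratification.
* **Gene identifiers** are opaque strings matched case-sensitively after
  whitespace trimming; symbol mapping would silently merge ids and is out
  of scope.
* **Expression scale** is declared, not sniffed: cohort readers take a
  `scale` flag (default `"log2"`), because guessing the scale from value
  ranges is fragile.
* **Permutation p-values** use the $(\#\{|r^\ast| \ge |r|\} + 1)/(B + 1)$
  estimator, so they are never exactly zero.
* **Stage seeding**: `run_full()` derives a per-stage seed from the master
  seed and the stage name, so stochastic stages are independent of
  execution order and reruns are bit-identical.
* **Fit failures are values**: both curve fitters return
  `converged = FALSE` results instead of throwing, so a batch over many
  curves completes and reports which fits to distrust.

# Problem sizes used by the tests

The test suite and the acceptance script exercise the pipeline at desk
scale: 1000-gene / 18-line perturbation sets over 20 seeds for signature
recovery; 100 seeded 200-gene / 100-patient cohorts for discordance sign
recovery; 20 cohorts of 200 patients for survival power at hazard ratio 3
and 1000 for the null size; 500 random instances per brute-force oracle
comparison; 50 seeds for noisy EC50 recovery under the quadruplicate
normalized-response design. These sizes give stable Monte-Carlo estimates
while keeping a full run in well under a minute.

# Known limitations

* The discordance prediction is a sign rule on one correlation; it reports
  no effect size calibration against actual drug response, which requires
  wet-lab validation by construction.
* The log-rank stage compares extreme quartiles only; it neither models
  covariates (no Cox regression) nor handles more than two groups.
* The HSA model is the only synergy reference implemented; Bliss, Loewe and
  ZIP disagree with it in well-known ways.
* The 4PL fitter assumes a monotone response in dose; biphasic curves will
  fit poorly and should be caught by inspecting `rss`.

# A short worked example

```{r example}
set.seed(1)
pert <- simulate_perturbation_set(perturbation_sim_spec(seed = 7))
sig <- build_consensus(collapse_cell_lines(pert$profiles, "24 h"))
sig

cohort <- simulate_cohort(
  cohort_sim_spec(discordant_subgroup = "G3",
                  survival_geneset = signature_genes(sig),
                  survival_hazard_ratio = 3, n_patients = 200, seed = 3),
  drug_signature = sig)
discordance_score(sig, subgroup_log2fc(cohort$cohort), n_perm = 1000)

q4_vs_q1_survival(cohort$cohort, signature_genes(sig))
```
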