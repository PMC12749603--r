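---
title: "Deriving and scoring a tumor-necrosis expression signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and scoring a tumor-necrosis expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necrosig)
```

## The problem

Tumor necrosis — non-regulated cell death in the tumor mass, scored
histologically as present (N+) or absent (N−) — marks aggressive disease in
breast cancer. A transcriptional surrogate for this morphologic feature lets
the phenotype travel to cohorts that have expression data but no slide
review, and gives a continuous rather than binary readout. `necrosig`
implements that workflow end to end: derive a directional gene signature
from an N+/N− comparison, sum it into a per-sample score, and carry the
score through association, survival, signature-panel and somatic-mutation
analyses. A synthetic-cohort generator with planted ground truth makes every
stage testable at desk scale.

## The differential-expression model

For gene $i$ with group means $\bar x_{i1}$ (N+) and $\bar x_{i2}$ (N−) on
the log2 scale, the modified t-statistic is

$$d_i = \frac{\bar x_{i1} - \bar x_{i2}}{s_i + s_0},$$

where $s_i$ is the pooled two-sample standard error of the mean difference
and $s_0$ is a small positive "fudge factor" that keeps low-variance genes
from dominating the ranking. With $s_0 = 0$, $d_i$ is exactly the classical
pooled-variance t-statistic (the test suite asserts this against an
independent oracle at `1e-10`). Three $s_0$ rules are available: the median
of the $s_i$ (default — simple and widely used), a fixed value, and a
Tusher-style search over the 0–95th percentiles of $s$ that minimizes the
coefficient of variation of the spread of $d$ across windows of $s$.

The false-discovery rate attached to each gene is permutation-based: group
labels are permuted $B$ times (group sizes preserved, all draws derived from
a mandatory seed), and for the threshold $|d_i|$,

$$\widehat{FDR}(|d_i|) = 100 \times
\frac{\mathrm{median}_b \#\{|d^{*}_b| \ge |d_i|\}}{\#\{|d| \ge |d_i|\}}\ \%$$

with the proportion of true nulls fixed conservatively at 1. The per-gene
q-value is the minimum $\widehat{FDR}$ over thresholds at or below $|d_i|$,
which enforces monotonicity in $|d|$. With finite $B$ the smallest non-zero
q is bounded below, so a strict cut such as `q < 0.008` (in percent, i.e.
8×10⁻⁵ as a proportion) is in practice met only by genes no permutation ever
beats (q = 0). On cohorts small enough that $B$ exceeds the number of
distinct group assignments, exhaustive enumeration replaces sampling and the
result becomes seed-independent.

A gene enters the signature as UP if its signed linear fold change
($2^{\Delta}$, reported as $-1/r$ below 1) is at least `fc_min` **and** its
q-value is below `q_max_percent`; as DOWN with the mirrored fold-change cut.
Defaults are `fc_min = 2.5` and `q_max_percent = 0.008`. Group 1 is
necrosis-present, so a positive fold change always means higher expression
in necrotic tumors. The derivation reports whatever UP/DOWN counts its
thresholds produce; no count is hard-coded.

## The score and its groupings

The per-sample score is an unweighted directional sum on the log2 scale:

$$\mathrm{score}(j) = \sum_{g \in UP} x_{gj} - \sum_{g \in DOWN} x_{gj}.$$

Missing signature genes are skipped, never imputed, and the skip count is
part of the output. Three grouping schemes are supported: the zero cut
(score > 0 is "high"; exactly 0 goes to "low" so that "high" requires
strictly positive evidence), a mean split (strictly above the within-cohort
arithmetic mean), and rank-based quartiles (ties stay together in the lower
quartile, so group sizes may be unequal — they are logged; Q4 holds the
highest scores). Published proliferation/hypoxia/stemness panels are scored
with the same generic sum — the original publications' weighted formulas are
deliberately **not** approximated — and panel columns are z-normalized per
signature. The shipped panel GMT files are editable stand-ins labelled as
such; replace them with the published gene lists for real analyses.

## Statistics

Associations between categorical variables use the uncorrected Pearson
chi-square; continuous-by-group comparisons use the tie-corrected
Mann–Whitney U normal approximation (exact enumeration available for small
samples) and Kruskal–Wallis H; correlations use Spearman rank with a
t-approximate p. All tests are two-sided at the 5% level, and the
association battery reports raw p-values with no multiplicity adjustment —
a deliberate, logged choice mirroring how such clinico-pathological tables
are conventionally reported.

Survival uses the disease-specific endpoint: death from disease is the
event; deaths from other causes are censored at the death date, survivors at
last follow-up; time is months since diagnosis. Kaplan–Meier tables, the
unweighted log-rank test, and Cox proportional-hazards fits are backed by
the `survival` package behind thin, contract-enforcing wrappers
(complete-case covariates only; Wald 95% CIs; per-unit and per-SD hazard
ratios both reported because the per-unit HR of a sum-score depends on the
expression scale). Ties default to Efron — better with month-resolution
ties — with Breslow available to mimic software that defaults to it.

Mutation contrasts take a MAF, keep all variant classes by default (a
non-synonymous preset is available), collapse multiple hits per gene per
sample to one, and compare per-gene and per-pathway mutated fractions with
the two-sided Fisher exact test plus Benjamini–Hochberg q-values. Pathway
memberships ship as editable GMT stand-ins (named `*_synthetic`); nothing
is hard-coded.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` draws per-gene baseline means from Normal(7, 1) on the
log2 scale (microarray-like intensities), then applies the planted group
contrast **symmetrically**: UP genes get $+\delta/2$ in N+ and $-\delta/2$
in N−, DOWN genes the mirror. The group difference is therefore exactly
$\delta$ (so the noiseless fold change is exactly $2^{\delta}$), and the
directional sum-score straddles zero between the groups — as in real
cohorts, where DOWN genes such as *ESR1* are genuinely high in non-necrotic
tumors, not merely un-shifted in necrotic ones. This is what makes the zero
cut a meaningful grouping in the simulated world.

Survival times are exponential with hazard
$\lambda_0 \exp(\beta z)$, $z$ the standardized true score; censoring is an
independent exponential whose rate is calibrated numerically so the expected
censored fraction hits the target (exponential rather than Weibull so every
sanity check has a closed form; a Weibull shape could be added but the
default world does not need it). About a third of censored cases are
recorded as other-cause deaths to exercise the disease-specific endpoint.
Mutations are independent Bernoulli draws per (sample, gene) at per-group
rates defaulting to the reported necrosis contrast for *TP53* (0.67/0.26),
*PIK3CA* (0.24/0.39), *CDH1* (0.01/0.11), *GATA3* (0.10/0.12) and *MAP3K1*
(0.05/0.14, direction reported, magnitudes chosen once as plausible).
Receptor and PAM50 labels are drawn with necrosis-dependent frequencies
taken from the published cohort table (e.g. Basal-like at 45% given N+ vs
7% given N−).

Not emulated: gene–gene correlation, batch structure, subtype-specific
expression programs beyond label mixing, copy number. A green recovery test
therefore establishes that the pipeline's machinery is correct under its own
model assumptions — not that the thresholds would reproduce any particular
cohort's gene list.

## Numerical choices and edge cases

* Zero-variance genes with $s_0 = 0$ are an error instructing $s_0 > 0$,
  never a silent infinity.
* Probe collapse keeps the probe with the highest mean across all samples;
  ties break by input order, deterministically.
* Probe means are never mixed across probes within one gene row.
* Quartile boundaries are `ceiling(4 * rank / n)` with minimum ranks, so a
  tie group never straddles a cut.
* The censoring-rate calibration solves
  $\mathbb{E}[\text{censored}] = \text{target}$ by `uniroot` on
  $c \mapsto \overline{c/(c+\lambda_i)}$.
* Expression input is assumed log2 unless the pipeline is told otherwise
  (`log2_input = FALSE`, pseudocount default 0); matrices must be complete —
  how missing expression values were handled upstream is out of scope and
  the readers reject them loudly with cell coordinates.

## Known limitations

The permutation FDR is a cohort-level estimate; with very small $B$ its
granularity is coarse, and under a complete null the q-values concentrate
near 100 (they are not uniform like p-values — a property the test suite
exploits rather than fights). The logistic basal-like predictor reports
coefficients for whatever covariates are supplied; published coefficient
values from other cohorts are not reproduced. Weighted signature formulas,
GSEA-style enrichment, PAM50 classification and driver discovery are out of
scope by design.

## A minimal run

```{r, eval = FALSE}
co <- simulate_cohort(sim_config(seed = 1))
cfg <- de_config(n_permutations = 200, seed = 1)
de <- sam_de(co$expression, co$truth$groups, cfg)
sig <- derive_signature(de, cfg, name = "NECROSIS_SIG")
truth_report(sig, co$truth)

scores <- score_signature(co$expression, sig)
grp <- dichotomize_zero(scores)
rec <- dss_prepare(co$clinical)
log_rank(rec, grp)
cox_fit(rec, data.frame(score_per_sd = as.numeric(scale(scores))))
```

The same workflow runs from the command line via the `simulate` and `run`
subcommands of the wrapper installed at
`system.file("cli", "necrosig", package = "necrosig")`.
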