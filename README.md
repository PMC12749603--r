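# necrosig

Tumor necrosis — non-regulated cell death inside the tumor mass, scored on
H&E slides as present (N+) or absent (N−) — marks aggressive breast cancer.
`necrosig` builds a *transcriptional surrogate* for that morphologic
feature: it derives a directional gene-expression signature from an N+/N−
comparison, sums it into a per-sample score, and carries the score through
the downstream analyses a molecular-pathology study needs — association
tests, disease-specific survival, signature-panel scoring, and somatic
mutation contrasts. It is aimed at computational biologists working with
gene × sample log2 expression matrices plus clinical annotation (and
optionally MAF mutation calls).

## The model in brief

Differential expression uses a SAM-style modified t-statistic per gene,

    d_i = (mean_i(N+) − mean_i(N−)) / (s_i + s0),

with `s_i` the pooled standard error and `s0` a stabilizing fudge factor
(median of the `s_i` by default). False-discovery rates come from seeded
label permutations: the FDR at threshold `|d_i|` is the median permutation
count of `|d*| ≥ |d_i|` over the observed count, made monotone in `|d|`.
Genes pass into the signature with signed linear fold change `≥ 2.5` in
absolute value and permutation FDR `< 0.008%` (both configurable). The
per-sample score is then

    score = Σ expression(UP genes) − Σ expression(DOWN genes)

on the log2 scale, dichotomized at zero ("high" = strictly positive) or
split by mean or quartiles. Survival analysis uses the disease-specific
endpoint (other-cause deaths censored) with Kaplan–Meier/log-rank and Cox
proportional hazards; mutation contrasts use per-gene and per-pathway
Fisher exact tests with Benjamini–Hochberg adjustment. A synthetic-cohort
generator plants UP/DOWN genes, score-linked exponential survival and
group-dependent mutation rates, so every stage is verifiable against known
truth.

## Worked example

```r
library(necrosig)

co  <- simulate_cohort(sim_config(seed = 1))           # 50 N+ / 50 N-, 2000 genes
cfg <- de_config(n_permutations = 200, seed = 1)
de  <- sam_de(co$expression, co$truth$groups, cfg)
sig <- derive_signature(de, cfg, name = "NECROSIS_SIG")
#> derived signature 'NECROSIS_SIG': 20 UP, 20 DOWN genes

unlist(truth_report(sig, co$truth))
#>        sensitivity          precision direction_accuracy
#>                  1                  1                  1

scores <- score_signature(co$expression, sig)
grp <- dichotomize_zero(scores)
table(grp, necrosis = co$clinical$necrosis)
#>       necrosis
#> grp    absent present
#>   low      50       0
#>   high      0      50

rec <- dss_prepare(co$clinical)
log_rank(rec, grp)
#>       test statistic df      p_value n_used n_missing_excluded
#> 1 log-rank  32.95733  1 9.420382e-09    100                  0

cox_fit(rec, data.frame(score_per_sd = as.numeric(scale(scores))))
#> <cox fit> n = 100, events = 77, ties = efron
#>           term  beta    hr ci_low ci_high     se   p_value
#> 1 score_per_sd 0.684 1.982  1.542   2.548 0.1282 9.479e-08
```

Reading: all 40 planted genes are recovered with no false positives
(sensitivity = precision = 1); the zero-cut score groups coincide exactly
with the true necrosis labels; the score-high group has markedly worse
disease-specific survival (log-rank p ≈ 9×10⁻⁹), and one standard deviation
of score roughly doubles the hazard (HR 1.98, 95% CI 1.54–2.55) — close to
the planted per-SD log-hazard of 0.7.

The same pipeline runs from the shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "necrosig", package = "necrosig"))')
Rscript "$cli" simulate --out cohort --seed 1
Rscript "$cli" run --expression cohort/expression.tsv --clinical cohort/clinical.csv \
        --maf cohort/mutations.maf --out run1 --seed 1 --permutations 200
```

`run1/manifest.json` then records input hashes, the seed, per-stage timings
and output hashes; re-running with the same config reproduces identical
hashes.

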