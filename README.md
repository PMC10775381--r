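# tmahet

Expression-heterogeneity analysis for tissue-microarray (TMA) cohorts of
metastatic castration-resistant prostate cancer (CRPC).

Rapid-autopsy programs sample many metastatic sites per patient, and cell
surface targets under clinical development (TROP2, PSMA, DLL3, CEACAM5) vary
in expression both between a patient's metastases and within a single tumor.
For drugs whose efficacy depends on target expression, the questions that
matter are: which molecular subtype expresses which target, how often two
targets are co-expressed in the same lesion, and how heterogeneous expression
is within and between tumors of one patient. `tmahet` implements that
analysis as a tested pipeline over per-core immunohistochemistry (IHC)
scores.

## What it computes

* **H-scores** — semiquantitative expression on a 0–200 scale,
  `H = 0·p0 + 1·p1 + 2·p2`, where `p_i` is the percent of cells at staining
  intensity *i* (two levels above background). Positivity cut-off: H ≥ 20,
  boundary inclusive.
* **AR/NE molecular subtypes** — each tumor block is placed in one of four
  quadrants by its androgen-receptor-axis markers (AR, NKX3.1) and
  neuroendocrine markers (SYP, INSM1): AR+/NE− (adenocarcinoma), AR−/NE+
  (neuroendocrine, NEPC), AR+/NE+ (amphicrine), AR−/NE− (double negative).
  An axis is positive when the maximum of its two marker H-scores reaches
  the cut-off.
* **Co-expression tables** — 2×2 contingency of binarized statuses for a
  marker pair within a subtype stratum, with half-up rounded percentages.
* **Patient expressor classes** — non-expressor (all sites H < 20),
  heterogeneous (sites on both sides of the cut-off), uniform-high (all
  sites H ≥ 20), with explicit evaluable-patient denominators.
* **Heterogeneity indices** — the probability that a randomly drawn pair of
  samples is discordant (one H ≥ 20, one H < 20). Pairs come from the same
  tumor block (intra-tumoral) or from different blocks of the same patient
  (inter-tumoral). For a group of `n` samples with `k` positive, the exact
  concordant fraction is the without-replacement form
  `(C(k,2) + C(n−k,2)) / C(n,2)`; `heterogeneity_exact()` enumerates every
  eligible pair, and `heterogeneity_bootstrap()` is its Monte-Carlo
  counterpart (1000 pairs × 1000 replicates by default) with
  bias-corrected accelerated (BCa) 95% confidence limits.
* **Association models** — anatomic-site contrasts of mean H-score from a
  linear mixed model with patient random intercepts (REML, Wald inference),
  and marker-positivity vs genomic-alteration odds ratios from (random-
  intercept) logistic regression, with complete-separation flagging.
* **Synthetic cohorts** — `generate_cohort()` emulates a 52-patient /
  ~372-site / ~753-sample rapid-autopsy cohort with subtype-conditional
  marker distributions, patient-level clustering, site shifts and genomic
  effects, and returns the full ground truth for every estimator.

## Worked example

```r
library(tmahet)

g <- generate_cohort(generator_config(), seed = 1)
cohort <- g$cohort
cohort
#> <cohort_table> 819 samples / 389 sites / 52 patients
#>   markers measured: TROP2, PSMA, DLL3, CEACAM5, AR, NKX3.1, SYP, INSM1
#>   genomic flags: 52 patients x 7 genes

tabulate_coexpression(cohort, "TROP2", "PSMA", stratum = "AR+/NE-")
#> <coexpression_table> TROP2 x PSMA (AR+/NE-, unit = core, n = 345)
#>   TROP2+ PSMA+        243/345 (70%)
#>   TROP2+ only          60/345 (17%)
#>   PSMA+ only           42/345 (12%)
#>   neither               0/345 (0%)

pool <- enumerate_pairs(cohort, "TROP2", "inter_tumoral")
pool
#> <pair_pool> TROP2 / inter_tumoral: 6397 pairs in 52 groups (819 samples), 902 discordant

heterogeneity_bootstrap(pool, seed = 17)
#> <het_estimate> inter_tumoral heterogeneity of TROP2
#>   14.1% (95% CI 12 to 16.4)
#>   pool: 6397 pairs; 1000 pairs/replicate x 1000 replicates; seed 17

heterogeneity_exact(pool)
#> [1] 0.1410036
```

The bootstrap point estimate (14.1%) sits on the exact enumerated index
(14.10%): about one in seven pairs of metastases from the same patient
disagree in TROP2 status in this simulated cohort. The mixed model reads
similarly:

```r
fit <- site_mixed_model(cohort, "TROP2")
fit[fit$site %in% c("vertebral bone", "liver", "lung"), ]
#>             site   n mean_difference ci_low ci_high p_value wide_ci
#> 1 vertebral bone 157            0.00    0.0    0.00      NA   FALSE
#> 5          liver 124           -4.73  -17.9    8.43   0.481   FALSE
#> 6           lung  79           -7.09  -22.0    7.78   0.350   FALSE
```

i.e. liver metastases average 4.7 H-score units below vertebral-bone
metastases in this run, with a confidence interval spanning zero.
`run_pipeline(cohort_tsv, out_dir, seed = ...)` executes all stages
(scoring → subtyping → co-expression → patient classes → heterogeneity →
associations) and writes tidy TSVs plus a JSON run manifest; reruns with the
same seed are byte-identical.

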