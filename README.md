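# ifnsig

Scoring and evaluation of interferon-stimulated neutrophil gene
signatures as immunotherapy-response biomarkers.

Blood neutrophils carrying an interferon-stimulated (ISG-high) expression
program mark patients likely to respond to immune checkpoint therapy.
Working with that biomarker computationally requires a chain of methods
that this package implements end to end, for analysts who want to apply
or stress-test the approach on their own cohorts:

* **Single-sample enrichment scoring** — a binned-control module score
  per cell (mean expression of signature genes minus expression-matched
  controls) and a rank-ECDF random-walk enrichment score per sample
  (GSVA-style ES in [-1, 1], exactly invariant under per-gene monotone
  transforms).
* **Cross-species signature derivation** — union of three hallmark-style
  response programs, enriched-cluster detection, rank-test markers
  (FDR < 0.001, log2 FC > 1.5), and reduction to a compact
  "near-exclusive" signature (top 15 by p then fold-change with
  expressing-fraction filters).
* **Bulk deconvolution** — non-negative least-squares fractions against a
  10-type reference matrix, plus group-mode imputation of per-group
  neutrophil profiles with per-gene means and CVs.
* **NB model-based bootstrap** — the core identity is the
  method-of-moments negative binomial dispersion

  &nbsp;&nbsp;&nbsp;&nbsp;α_g = CV_g² − 1/μ_g&nbsp;&nbsp;(clamped at 0),
  so that Var = μ + αμ² and CV² = 1/μ + α;

  replicate samples are drawn NB(μ, α) per group, scored, normalized
  per dataset (median/MAD), and compared NR vs R by one-sided
  Mann-Whitney with significance stars at p < 0.01 / 0.001 / 0.0001.
* **Biomarker evaluation** — midrank Mann-Whitney U (exact by enumeration
  for n₁+n₂ ≤ 12 without ties), AUC = U/(n₁n₂), and stratified-bootstrap
  percentile confidence intervals (1000 replicates).
* **Synthetic data with planted truth** — NB single-cell matrices with a
  planted IFN-high neutrophil state, Dirichlet bulk mixtures over a
  packaged synthetic LM10-shaped reference, Beta-distributed flow
  frequencies; every generator returns a ground-truth record.

Two packaged signatures ship in `inst/extdata/`: the 15-gene
IFN-stimulated neutrophil signature (Neut_IFN-15: IFIT1, MX1, HERC5,
IFI6, ISG15, IFIT3, RSAD2, GBP1, IFIT2, XAF1, PARP9, UBE2L6, IRF7,
PARP14, APOL6) and the 6-gene IFN-gamma comparator (IDO1, CXCL10, CXCL9,
HLA-DRA, STAT1, IFNG); they share no genes.

## Worked example

Simulate a flow-cytometry cohort with a moderate responder effect and
evaluate the ISG-high neutrophil frequency as a biomarker:

```r
library(ifnsig)

ft <- simulate_flow_table(mean_freqs = c(NR = 0.10, R = 0.22), seed = 42)
evaluate_biomarkers(ft, "ly6e_hi_freq", n_boot = 1000, seed = 42)
#>      biomarker   auc ci_low ci_high  p_value n_pos n_neg status
#> 1 ly6e_hi_freq 0.952  0.898   0.992 2.23e-08    25    25     ok
```

The frequency separates responders from non-responders with AUC 0.95
(95% stratified-bootstrap CI 0.90–0.99) and a one-sided Mann-Whitney
p of 2.2e-08 — the R group sits above the NR group.

The dispersion identity on a worked vector:

```r
estimate_dispersion(group_profile_from_values(c(10, 20, 30, 40)))$alpha
#> [1] 0.2266667   # CV^2 - 1/mu = (500/3)/625 - 1/25
```

The full single-cell pipeline on synthetic data recovers the planted
15-gene signature exactly:

```r
res <- run_sc_pipeline(default_config(seed = 7))
res$enriched$cluster
#> [1] "neutrophil_ifnhi"
sort(res$signature$genes)
#>  [1] "APOL6"  "GBP1"   "HERC5"  "IFI6"   "IFIT1"  "IFIT2"  "IFIT3"
#>  [8] "IRF7"   "ISG15"  "MX1"    "PARP14" "PARP9"  "RSAD2"  "UBE2L6"
#> [15] "XAF1"
```

A command-line interface covers the same stages
(`simulate`, `score`, `deconvolve`, `bootstrap`, `evaluate`,
`pipeline sc|bulk`); see `inst/cli/ifnsig`.

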