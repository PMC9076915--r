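# neostrat

Analysis pipeline for chemotherapy response in HER2-negative breast
cancer, for researchers who want to relate pre-treatment gene expression
to a quantitative measure of neoadjuvant response, stratify patients by
process-level metagenes, and contrast paired pre/post-treatment genomes.

Neoadjuvant chemotherapy rarely produces all-or-nothing responses; most
tumors respond partially. The pipeline therefore works with the
Neoadjuvant Response Index (NRI), a semi-continuous response measure on
[0, 1], alongside pathological complete response (pCR), and covers three
linked analyses:

1. **Response association.** Each gene's log2 expression is regressed on
   NRI; the slope r and its standard error s are moderated into
   d = r / (s + s0), with the fudge factor s0 chosen to stabilize the
   variance of d across the range of s. Significance is assessed against
   a permutation null of the response vector, and a per-gene q-value is
   the (conservative, pi0 = 1) median number of null exceedances of |d|
   over the observed number, monotonized in |d|. Genes at q < 0.05 form
   a "core set", clustered (average linkage, correlation distance) into
   three process metagenes: proliferation, immune response, and
   extracellular matrix (ECM) organization.

2. **Metagene stratification and survival.** A sample's metagene score
   is the median log2 expression of the process's genes. Scores are
   dichotomized at the within-cohort median (H strictly above, else L),
   yielding the profile HHL (proliferation high, immune high, ECM low),
   its mirror LLH, or "other". Profiles are compared on response
   (Wilcoxon rank-sum on NRI, Fisher exact on pCR) and on
   recurrence-free survival (Kaplan-Meier curves, log-rank test, and a
   two-group Cox fit reporting HR with a 95% Wald CI).

3. **Paired pre/post genomics.** Probe-level copy-number log ratios are
   corrected for tumor purity p by inverting the two-component mixture
   logR_adj = log2((2^logR_obs − (1 − p)) / p), VAFs by the linear
   rescaling min(VAF / p, 1). The purity-adjusted pre-minus-post delta
   track is segmented by recursive binary splitting with a t-statistic
   stop rule, somatic variants are retained when coding with VAF > 10%
   in either sample, classified as shared / pre-only / post-only with a
   depth-guarded absence rule, and recurrent aberration frequencies are
   tested against reference-cohort frequencies (exact binomial or
   one-sided Fisher).

A synthetic cohort generator (`sim_config()`, `simulate_cohort()`,
`simulate_survival()`, `simulate_paired_genomics()`) plants exactly the
latent structure these stages assume — three latent processes coupled to
NRI with subtype-specific coefficients, a planted hazard ratio between
profiles, purity-mixed copy-number blocks with a pre-only loss, and
binomially read-sampled variants — so every stage is testable without
access to controlled patient data. Packaged fixtures
(`inst/extdata/table1_cohort.tsv`, `table2_patients.tsv`,
`table2_annotation.tsv`) encode the printed clinical tables of the
motivating cohort: 317 pre-treatment samples (200 ER+, 117 TN) and the
22-patient paired cohort.

## Worked example

The numbered drivers under `analysis/` run the whole pipeline on a
simulated 200-sample cohort and one paired genome:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_response_association.R
Rscript analysis/03_stratify_survival.R
Rscript analysis/04_paired_genomics.R
Rscript analysis/05_cohort_tables.R
```

which prints, among other things:

```
core set at FDR<5%: 295 genes (191 positive, 104 negative)
process assignment agrees with simulator truth for 100.0% of core genes
TN response: Wilcoxon NRI p = 2.4e-07, Fisher pCR p = 0.000344 (HHL n=18, LLH n=18)
TN survival HHL vs LLH: HR 0.36 (95% CI 0.13-0.97), log-rank p = 0.0356 (planted HR 0.29)
segments with |mean delta| > 0.5: 1 (planted loss at chr1:190000-349000)
variants: 30 called, 26 retained (>10% AF, coding)
planted loss gene aberrated pre/post: 1/0
```

Reading: the association stage recovers a core set dominated by the
three planted processes; TN patients with the HHL profile have higher
NRI and pCR rates than LLH patients and an estimated hazard ratio of
0.36 against a planted 0.29; the paired analysis finds exactly one
large delta segment — the planted pre-only loss — and classifies the
planted variant sharing correctly. Outputs land under `results/`.

The same orchestration is available programmatically via
`run_pipeline(config, out_dir)`, which writes every stage product plus
a deterministic `report.json`.

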