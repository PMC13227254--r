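# pvgrad — periventricular gradient analysis of normal-appearing white matter

White-matter damage in aging and neurological disease is not spatially
uniform: microstructural metrics from diffusion MRI (NODDI's neurite density
index NDI and orientation dispersion index ODI) degrade more near the
ventricles and recover with distance, consistent with CSF-associated
inflammatory processes. `pvgrad` is an R package for quantifying that
pattern as a single statistic — the **periventricular gradient** — and for
the analyses built on it. It is aimed at neuroimaging researchers who have
aligned tissue masks and metric maps (NIfTI) plus a subject table, and at
methodologists who want the estimators exercised against synthetic ground
truth.

The analysis chain:

1. **Ring parcellation** — exact Euclidean distance (mm, anisotropic voxel
   spacing honoured) from the ventricular mask; concentric half-open rings
   `[3k, 3k+3)` mm, ten rings spanning 3–33 mm by default (1.5 mm × 15 and
   1 mm × 20 variants included); ring means of each metric over NAWM
   (white matter minus WMH lesions).
2. **Normalization** — per ring z-scores against the younger-HC stratum
   (age ≤ 45): `z = (m − μ_ref) / σ_ref`.
3. **Gradient estimation** — linear mixed model `z ~ ring + (1 | subject)`;
   the fixed ring slope (z-units per ring) *is* the periventricular
   gradient. Pairwise group contrasts come from the pooled
   `z ~ group × ring + (1 | subject)` model with BH-FDR across the family.
   Subject-level gradients are OLS slopes over rings.
4. **Mediation** — product-of-coefficients with percentile bootstrap CIs:
   choroid plexus volume (inflammation proxy) → gradient → WMH volume /
   NAWM metric / WMV / GMV, and gradient → parallel mediators → cognitive
   scores; percentage mediated `PM = 100 · indirect / total`.
5. **Transcriptomics** — ring-wise expression vs the gradient profile via
   PLS1; permutation test of the variance explained; bootstrap gene Z-scores
   (`Z = weight / bootstrap SE`), PLS1−/PLS1+ lists at `|Z| > 5`,
   `q < 0.001`; hypergeometric cell-type enrichment.
6. **Phantoms** — synthetic anatomy, metric maps, cohorts (linear structural
   causal model with known paths) and expression matrices, so every stage is
   testable with no data downloads.

## Worked example

The end-to-end synthetic experiment simulates seven groups (three HC age
strata, AD, PD, CSVD, MS; 100 subjects each) with group gradients mirroring
the magnitudes reported in this literature, then runs the full chain:

```r
library(pvgrad)
cfg <- default_config(seed = 1, out_dir = "pvgrad_demo")
run_pipeline(cfg)
read_tsv("pvgrad_demo/group_gradients.tsv")
```

```
      group     slope     se ci_lower ci_upper       p n_subjects
         ad  5.82e-02 0.0064  0.04560  0.07080 1.5e-19        100
       csvd  7.09e-02 0.0064  0.05840  0.08330 7.1e-29        100
  middle_hc -7.97e-03 0.0065 -0.02070  0.00475 2.2e-01        100
         ms  5.78e-02 0.0062  0.04550  0.07000 2.0e-20        100
   older_hc  4.85e-02 0.0061  0.03670  0.06040 1.3e-15        100
         pd  1.53e-02 0.0065  0.00254  0.02800 1.9e-02        100
 younger_hc  3.35e-18 0.0062 -0.01220  0.01220 1.0e+00        100
```

Reading this: slopes are on the z-normalized scale (z-units per ring), so
they are the generating raw slopes divided by the reference SD (≈ 0.36
here) — e.g. CSVD's generating 0.032 appears as ≈ 0.07. The younger-HC
slope is exactly zero because that stratum is its own normalization
reference. The middle-aged HC gradient (generating value 0.0064, the
smallest in the design) is not detectable at n = 100/group — a power
statement, not an estimator defect; the null is correctly retained. The
strongest contrasts (e.g. CSVD vs middle-aged HC, q ≈ 3e-17 in
`contrasts.tsv`) separate the steep-gradient disease groups from the HC
strata.

The same run writes `mediation.tsv` (indirect/direct/total effects and PM
per outcome), `pls_genes.tsv` + `gene_lists.tsv` (bootstrap Z per gene and
the PLS1−/PLS1+ lists), `enrichment.tsv` (cell-type hypergeometric tests)
and a `report.json` echoing every parameter and seed.

Lower-level entry points mirror the stages: `distance_map()`,
`build_rings()`, `nawm_mask()`, `extract_ring_means()`,
`reference_stats()` / `normalize_profiles()`, `fit_group_gradient()` /
`fit_subject_gradient()` / `compare_gradients()`, `adjusted_regression()` /
`mediate_single()` / `mediate_parallel()`, `fit_pls1()` /
`permute_varexp()` / `bootstrap_gene_z()` / `select_genes()` /
`celltype_enrichment()`, and the generators `make_anatomy()`,
`make_metric_map()`, `make_cohort()`, `make_expression()`. See the methods
vignette (`vignettes/periventricular-gradient.Rmd`) for the model, the
conventions and their rationale.

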