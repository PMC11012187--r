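# lipidMAE

Optimization and analysis tooling for Microwave-Assisted Extraction (MAE)
of lipids from dairy matrices such as mozzarella, paired with the
chemometric machinery used in untargeted lipidomics: factorial design of
the extraction, per-subclass response modelling, multivariate screening
diagnostics, Pareto-front multi-objective optimization, and lipid
shorthand annotation. It is aimed at analytical chemists and lipidomics
data analysts who want the full computational side of an MAE method
development — from design matrix to compromise extraction settings to
inventory reports — as reproducible, tested R code.

## What it computes

**Extraction design.** A 2³ full factorial design on the three MAE
factors — solvent-to-solid ratio X₁ (16–32 mL g⁻¹), time X₂ (6–30 min),
temperature X₃ (50–80 °C) — plus center replicates (coded (0,0,0) =
24 mL g⁻¹, 18 min, 65 °C; 11 runs with 3 center points).

**Response models.** Each lipid-subclass abundance sum Y (range-scaled to
[0, 1]) is fitted by ordinary least squares to the 8-term interaction
model on coded factors:

    Y = b0 + b1·X1 + b2·X2 + b3·X3 + b12·X1X2 + b13·X1X3 + b23·X2X3 + b123·X1X2X3

with two-sided t tests per coefficient (df = n − 8), an overall F test
per model, and a significance table that blanks non-significant entries
and sets aside subclasses with no significant dependence.

**Screening diagnostics.** For the solvent comparison
(methanol/ethyl-acetate ME, ethanol/ethyl-acetate EE,
isopropanol/ethyl-acetate IE): PCA, UPGMA hierarchical clustering on
squared Euclidean distances of [0, 1]-scaled subclass sums, and PLS-DA
(NIPALS PLS2 on one-hot classes) validated by double cross-validation
and by stratified bootstrap, reporting per class RMSECV,
Q² = 1 − PRESS/TSS, discriminant DQ² (residuals of
correct-side-overshooting predictions zeroed, so DQ² ≥ Q²), accuracy,
sensitivity and specificity.

**Multi-objective optimization.** PC1/PC2 scores of the modelled
subclasses are themselves modelled as 8-term surfaces of the factors,
evaluated on a dense grid (40 levels per factor → 64,000 points), and
the non-dominated (Pareto) front is extracted; the compromise setting is
the front point nearest the utopia point in min-max-normalized objective
space.

**Annotation.** A parser for shorthand names like `TG(4:0/18:1/18:2+OO)`
(sn-resolved `/` vs unresolved `_`, `+O`/`+OO` oxidation promoting
TG→TG_1OX/TG_2OX and DG→DG_OX, sphingoid `d` prefix), fatty-acyl
classification (SFA/MUFA/PUFA; short 4–10 C, medium 11–15 C, long ≥16 C
chains; odd-chain flag), inventory summaries per subclass and
sn-position, method comparison (e.g. MAE vs Folch), and a QC gate on the
RSD% of deuterated-standard replicate areas (pass iff RSD < 20%).

A deterministic synthetic-data module generates every input the pipeline
consumes, so all of the above is exercised without any external data.

## Worked example

```r
library(lipidMAE)

design <- build_full_factorial(mae_factors(), n_center = 3)
responses <- gen_ffd_responses(design, generator_config(seed = 1, noise_sd = 0))

fit <- fit_ffd(design, responses$LPI, "LPI")
fit
#> <ffd_fit> LPI: R2adj = 1.000, model p = 0 (df_resid = 3)
#>  term  value std_error t_stat p_value tier
#>    b0  0.364 9.221e-17    Inf       0  p01
#>    b1  0.345 1.081e-16    Inf       0  p01
#>    b2  0.021 1.081e-16    Inf       0  p01
#>    ...

opt <- run_optimization(design, responses, grid_levels = 40,
                        directions = c("max", "min"),
                        scale_responses = FALSE)
opt
#> <optimization_report> 10 modelled subclasses; 64000 grid points; 91 front points
#> <pareto_compromise> nearest-to-utopia (min-max normalized) (distance 0.6448)
#>  solvent_to_solid time_min temperature_C       PC1        PC2
#>          27.89744       30            50 0.4570961 -0.4429161
```

The LPI fit says lysophosphatidylinositol recovery rises with the
solvent-to-solid ratio (b1 = 0.345 on the scaled response) — fitted from
noiselessly generated responses, the coefficients come back exactly. In
the optimization report, PC1 separates the lyso-lipids (positive
loadings) from the phospholipids and ceramides (negative), so the two
objectives pull the solvent-to-solid ratio in opposite directions and
the compromise lands strictly inside the experimental range.

The screening and annotation workflows run the same way:

```r
scr <- gen_solvent_screening(generator_config(seed = 1))
run_screening(scr, bootstrap_B = 500, seed = 1)

run_annotation(simulate_inputs(tempdir())$identifications)
#> <subclass_summary> 449 species in 18 subclasses
```

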