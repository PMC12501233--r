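# mitodyn

Kinetic modelling of mitochondrial fusion–fission dynamics and ATP
energetics in high-grade serous ovarian carcinoma (HGSC) phenotypes under
serum starvation, for computational biologists studying the metabolic
switch of stem-like cancer cells — plus the quantitative desk procedures
that surround such a study: label-free proteomics enrichment filtering,
qPCR relative mtDNA content, and xenograft tumor scoring. Seeded
synthetic-data generators with planted ground truth make every stage
testable offline.

## The model

Four mitochondrial classes — healthy/deviant crossed with unfused/fused —
and the ATP concentration evolve as

```
dN_HU/dt = (B − M_H − F·[ATP]·e^s)·N_HU + K·[ATP]·e^−s·N_HF
dN_DU/dt = (B − M_D − F·[ATP]·e^s)·N_DU + K·[ATP]·e^−s·N_DF
dN_HF/dt = (B − K·[ATP]·e^−s)·N_HF + F·[ATP]·e^s·N_HU
dN_DF/dt = (B − K·[ATP]·e^−s)·N_DF + F·[ATP]·e^s·N_DU
d[ATP]/dt = θ·[ε·(α·N_HF + N_DF) + (α·N_HU + N_DU)] − μ
            − K·[ATP]·(N_HF+N_DF)·e^−s − F·[ATP]·(N_HU+N_DU)·e^s
```

where the stress level `s` (0 when serum-fed, positive when starved)
promotes fusion and suppresses fission, `F = F_0·[OPA1]` and
`K = K_0·[DRP1]` scale with the measured fusion/fission promoter proteins,
biogenesis `B` balances mitophagy exactly (conserving the total count),
and the ATP production factor

```
θ = (c_n + e^{m_p}) / (c_w + c_jw)
```

is driven by cristae count per unit length, membrane potential, cristae
width and crista junction width. A packaged preset table carries these
measured parameters for five HGSC cell lines (OVCAR3, CAOV3, OVCA420, A4,
OVMZ6 — the epithelial-to-mesenchymal gradient) under both serum
conditions. The closed-form assay scores are `2·2^ΔCt` for relative mtDNA
content, `0.5·length·width²` for tumor volume, and the tumor inhibitory
score `Control[(%PKHhi+%PKHlo)/V] − Test[(%PKHhi+%PKHlo)/V]`.

See the methods vignette (`vignettes/mitochondrial-dynamics.Rmd`) for the
assumptions, the free-constant calibration, and the numerical policies.

## Worked example

```r
library(mitodyn)
presets <- load_presets(fill_missing = TRUE)
#> load_presets: filled 1 missing cell(s) from the matching +S row (OVCAR3 SS m_p=0.99)
panel <- run_panel(presets)             # 10 scenarios over t in [0, 10]
ps <- panel_summary(panel)
ps$metrics[, c("cell_line", "condition", "hf_count", "unfused_fraction", "atp")]
#>    cell_line condition hf_count unfused_fraction    atp
#> 1     OVCAR3        +S    0.237         0.939071  59.67
#> 2      CAOV3        +S    0.881         0.765365  44.83
#> 3    OVCA420        +S    0.450         0.883136  30.99
#> 4         A4        +S    1.152         0.691950   7.46
#> 5      OVMZ6        +S    2.218         0.197080  25.42
#> 6     OVCAR3        SS    2.040         0.008192 737.62
#> 7      CAOV3        SS    2.056         0.003174 203.40
#> 8    OVCA420        SS    2.065         0.007982 294.82
#> 9         A4        SS    2.019         0.003723 160.45
#> 10     OVMZ6        SS    2.012         0.000396 357.82
```

Under serum starvation every phenotype ends with its unfused classes
almost gone (unfused fraction below 0.01 at `t = 10`) and far more ATP
than its serum-fed counterpart, while under serum the fused-mitochondria
count ranks the phenotypes from mesenchymal down to epithelial:

```r
rank_phenotypes(ps, "hf_count", "+S")
#> [1] "OVMZ6"   "A4"      "CAOV3"   "OVCA420" "OVCAR3"
atp_contrast(panel[["OVCAR3 SS"]], panel[["OVCAR3 +S"]], t = 10)
#> $difference
#> [1] 677.9519
#> $ratio
#> [1] 12.36339
```

The proteomics filter recovers planted truth from the seeded generator,
and the assay formulas evaluate in closed form:

```r
synth <- make_lfq_table(generator_spec(seed = 1))
length(enriched_set(synth$lfq))   # the 20 exclusive-SS + 30 up-SS planted ids
#> [1] 50
relative_mtdna_content(20, 15)    # delta-Ct 5
#> [1] 64
tumor_inhibitory_score(xenograft_record("vehicle", 5, 20, tumor_volume = 500),
                       xenograft_record("doxy",   10, 25, tumor_volume = 100))
#> [1] -0.3
```

A thin command-line wrapper exposes the same stages
(`simulate | panel | sweep | enrich | scores | synth`):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "mitodyn", package = "mitodyn"))')" \
  panel --out panel_out
```

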