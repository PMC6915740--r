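# coldevb

Enthalpy–entropy partitioning of enzyme activation barriers from EVB
free-energy profiles, with a desk-scale surrogate for the molecular
dynamics layer.

## The problem

Psychrophilic (cold-adapted) enzymes are fast in the cold not because their
activation free energy ΔG‡ is much lower than their mesophilic orthologs'
— it usually differs by ~1 kcal/mol — but because it is *partitioned*
differently: a much lower activation enthalpy ΔH‡, compensated by a more
negative activation entropy ΔS‡. Since rates decay with temperature as
exp(−ΔH‡/RT) while exp(ΔS‡/R) is temperature-independent, the low-enthalpy
enzyme keeps its speed near 0 °C. For salmon (SPE) versus porcine (PPE)
pancreatic elastase the computed wildtype partitioning at 22 °C is
(ΔH‡, TΔS‡) = (4.6, −13.4) versus (17.2, −2.0) kcal/mol, and the shift
tracks the mobility of a handful of surface loops.

Extracting (ΔH‡, ΔS‡) computationally takes empirical valence bond (EVB)
free-energy profiles of the rate-limiting step at several temperatures —
two diabatic states mixed by a mapping potential over 51 FEP windows,
umbrella-corrected onto the energy-gap coordinate X = ε₁ − ε₂′, with the
adiabatic ground surface

    Eg = ½(ε1 + ε2′) − ½·sqrt((ε1 − ε2′)² + 4·H12²)

— followed by an Arrhenius decomposition: ΔG‡/T regressed on 1/T has slope
ΔH‡ and intercept −ΔS‡. Rates follow from transition-state theory,
k = (k_B·T/h)·exp(−ΔG‡/RT).

`coldevb` is for computational enzymologists and methods developers who
want this analysis layer as tested, reusable code. It implements the EVB
energetics, the Zwanzig/umbrella estimators, the Arrhenius and TST layer
with the replicate-batch convergence rule (add 10 replicates until
R² > 0.8), bootstrap uncertainties, and the backbone-mobility module
(Kabsch superposition, iterative averaging, RMSF, loop reports). The
cluster-scale all-atom MD is replaced by a **surrogate reactive system**
— harmonic diabats under the published coupling (Δα = 195.0,
H12 = 113.0 kcal/mol), a shared "scaffold strain" term as the enthalpic
dial, and bath modes that stiffen at the transition state as the entropic
dial — whose (ΔH‡, TΔS‡) are known in closed form, so every estimator is
validated against an exact oracle. Sixteen presets are calibrated at build
time to the published activation parameters of the two wildtypes and all
fourteen surface-loop mutants.

## Worked example

```r
library(coldevb)

# published wildtype activation parameters at 22 degC as inputs
wt_spe <- activation_parameters("WT SPE", dh = 4.6, tds = -13.4)
wt_ppe <- activation_parameters("WT PPE", dh = 17.2, tds = -2.0)
rate_table(list(wt_spe, wt_ppe))
#>   variant temperature_c temperature_k   dg     k_s k_x100
#> 1  WT SPE             4           277 17.2 0.16298 16.298
#> 2  WT SPE            22           295 18.0 0.28885 28.885
#> 3  WT SPE            39           312 18.8 0.46826 46.826
#> 4  WT PPE             4           277 19.1 0.00522  0.522
#> 5  WT PPE            22           295 19.2 0.03734  3.734
#> 6  WT PPE            39           312 19.3 0.19501 19.501
compare_variants(wt_spe, wt_ppe)$ddg
#> [1] 1.2
```

The 22 °C wildtype SPE rate, 28.9 in the table's ×100 s⁻¹ convention,
reproduces the published value exactly; the 1.2 kcal/mol is the intrinsic
wildtype barrier difference. (Rates at 4 and 39 °C extrapolate from the
*rounded* one-decimal activation parameters, so they differ slightly from
the published entries, which used unrounded fit output.)

Sampling a surrogate variant end to end — four replicates of the 51-window
ladder at the five protocol temperatures, barrier per replicate, Arrhenius
fit — takes a few seconds:

```r
sys <- build_variant("SPE_like")          # calibrated psychrophilic preset
analytic_activation(sys)[c("dg", "dh", "tds")]
#> $dg  18.00   $dh  4.60   $tds  -13.40       (closed-form oracle)

res <- run_temperature_series(sys, n_replicates = 4, master_seed = 1,
                              reduce = function(r) umbrella_profile(r)$dg_act)
barr <- lapply(res, unlist)
arrhenius_fit(as.numeric(names(barr)), sapply(barr, mean), label = "SPE_like")
#> SPE_like: dG_act(295.15 K) = 18.03, dH_act = 4.32, TdS_act = -13.71 kcal/mol (R^2 = 0.955)
```

The sampled decomposition lands within a few tenths of the declared
(4.6, −13.4); `bootstrap_ci()` quantifies the replicate uncertainty, and
`run_pipeline()` wraps the whole protocol (convergence batching, report
tables, Arrhenius plot, provenance log) behind one YAML config
(`validate_config()` documents the defaults, which are the full study
protocol). `flex_profile()` / `generate_backbone_ensemble()` / `rmsf()` /
`loop_report()` provide the matching backbone-mobility analysis.

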