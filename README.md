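# fdgrepeat

Quantification and test–retest repeatability analysis of dynamic brain
[18F]FDG PET studies, aimed at preclinical (non-human primate) imaging
groups choosing between absolute and simplified outcome parameters.

Dynamic FDG PET with arterial sampling yields the cerebral metabolic rate
of glucose via the Patlak plot:

    Ct(T)/Cp(T) = Ki * (∫₀ᵀ Cp dt) / Cp(T) + V,        Ki = K1·k3/(k2+k3)
    CMRglu = Ki · Gly / LC × 100     [µmol·min⁻¹·(100 g)⁻¹]

with Cp the arterial input function, Gly the glycemia and LC the lumped
constant (0.34 by default, linearization from t\* = 30 min). The simplified
indices are the plateau SUV (30–60 min), SUV×Gly, and reference-region
ratios SUVR\_pons and SUVR\_cerebellum. For a test–retest cohort the package
computes, per region and parameter: absolute variability
(100·|test−retest|/mean), the intra-/inter-subject variance decomposition
(within-subject variance from paired differences; remainder clipped at
zero), 95% confidence intervals (t-quantile on 2N values, lower bound
clipped at 0), precision-based sample sizes n = ⌈(t·s/(0.2·mean))²⌉, exact
small-sample Spearman and Wilcoxon signed-rank tests, and a robustness
check counting how much of an independent group falls inside the
test–retest CIs.

A synthetic study generator produces complete test–retest cohorts —
arterial input functions (gamma-variate bolus + two-exponential tail,
peak ≈ 0.73 min, plasma exposure ≈ 94 SUV·min), irreversible
two-compartment regional kinetics on the standard 60-min/21-frame
schedule, metadata, and ground-truth kinetics with separable
subject/session/scan variance components — so the entire pipeline is
testable without any proprietary data.

## Worked example

```r
library(fdgrepeat)

study  <- simulate_study(study_design(), seed = 42)   # 6 subjects x 2 sessions
quant  <- quantify_study(study)                       # 5 parameters per region
decomp <- decompose_variability(quant)
subset(decomp, parameter == "cmrglu" & region == "thalamus")
#>  parameter   region mean   sd ci95_low ci95_high absvar_mean absvar_sd
#>     cmrglu thalamus 20.2 6.06     6.88      33.6        27.1      15.8
#>  cv_intra cv_inter ev_intra ev_inter n_subjects
#>      22.8     19.5     57.9     42.1          6
```

Thalamic CMRglu in this simulated cohort averages 20.2 µmol/min/100 g over
the 12 scans; a future single measurement is expected in [6.9, 33.6] with
95% confidence; the mean test–retest absolute variability is 27%, and the
within-subject component explains 58% of the total variance.

```r
naive <- simulate_study(study_design(n_subjects = 4, n_sessions = 1),
                        seed = 43, subject_prefix = "N")
robustness_check(decomp, quantify_study(naive))
#>        parameter within total fraction
#>           cmrglu     39    40    0.975
#>              suv     40    40    1.000
#>          suv_gly     40    40    1.000
#>  suvr_cerebellum     31    36    0.861
#>        suvr_pons     34    36    0.944
#>  plasma_exposure      4     4    1.000
```

Nearly all regional values of the independent 4-animal group fall inside
the test–retest confidence intervals — the parameters are robust in the
CI-membership sense.

`run_pipeline(config, out_dir, seed)` executes
simulate → quantify → repeatability → robustness in one call and writes
every table (CSV) plus a provenance log; `inst/cli/fdgrepeat.R` exposes the
same stages as shell subcommands (`simulate`, `quantify`, `repeatability`,
`robustness`, `run`).

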