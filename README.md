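# bchescreen

Quantitative analysis pipeline for characterising butyrylcholinesterase
(BChE) inhibitors discovered by hybrid virtual screening. BChE degrades
acetylcholine and is a drug target in Alzheimer's disease; candidate
inhibitors typically flow from a fingerprint-based QSAR classifier through
an ADMET filter cascade into wet-lab mechanism studies. This package
implements every quantitative step of that workflow for R users:

* **Classifier evaluation** — IC50-based activity labelling, ECFP4
  featurisation (via RDKit), pluggable classifier backends (xgboost /
  random forest / SVM / k-NN), confusion-matrix metrics
  (accuracy, precision, recall, specificity, F1, MCC), rank-statistic
  ROC/AUC, stratified cross-validation.
* **Screening cascade** — sequential filters on predicted-activity
  probability (> 0.5), docking score (<= −7.000 kcal·mol⁻¹), CNS/BBB
  penetration (CNS > 0, QPlogBB > −3, BBB score > 3), absorption
  (Caco-2 > 500 nm·s⁻¹, HOA > 70 %), and Lipinski/Jorgensen drug-likeness,
  with per-stage survivor counts and first-failure attribution.
* **Enzyme kinetics** — percent inhibition, four-parameter logistic IC50,
  reversibility calls, Lineweaver–Burk primary/secondary plots under the
  general mixed-inhibition law
  *v* = *V*max·[S] / (*K*m(1 + [I]/*K*i) + [S](1 + [I]/(α·*K*i))),
  yielding *K*m, *V*max, *K*i, α·*K*i, α and an inhibition-mode call from
  the line-intersection geometry, plus a global nonlinear cross-check.
* **Binding biophysics** — Stern–Volmer quenching
  (F₀/F = 1 + *K*sv[Q], *K*q = *K*sv/τ₀), static/dynamic mechanism
  classification against the 2×10¹⁰ L·mol⁻¹·s⁻¹ diffusion ceiling,
  double-log binding constants (log((F₀−F)/F) = log *K*a + n·log[Q]),
  Van't Hoff thermodynamics (ln *K*a = −ΔH/RT + ΔS/R), Gibbs energies
  (ΔG = ΔH − TΔS), binding-force assignment and fluorescence-lifetime fits.
* **Synthetic data** — seeded generators for every input above, each with
  a recorded ground truth, so the whole pipeline is verifiable offline.

Functions are data-frame-first and return tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(bchescreen)

# Evaluation metrics from a confusion matrix
classification_metrics(confusion_counts(tp = 289, tn = 386, fp = 11, fn = 25))
#> # A tibble: 1 × 10
#>      tp    tn    fp    fn accuracy precision recall specificity    f1   mcc
#>   <int> <int> <int> <int>    <dbl>     <dbl>  <dbl>       <dbl> <dbl> <dbl>
#> 1   289   386    11    25    0.949     0.963  0.920       0.972 0.941 0.898

# Inhibition typing from synthetic mixed-inhibition rates
rates <- sim_mixed_inhibition(km = 0.2, vmax = 1, ki = 10.73, alpha = 3.01)
kinetics_report(rates)
#> Inhibition type: mixed (second quadrant) (median intersection x = -1.661, y = 0.6678)
#> Km = 0.2 mM, Vmax = 1
#> Ki = 10.73 uM, alpha*Ki = 32.3 uM, alpha = 3.01

# Quenching and thermodynamics from a three-temperature titration
titr <- sim_titration(f0 = 1000, dh = -35770, ds = -25.49, n = 1)
binding_report(titr)
#> Quenching mechanism: static (max Kq = 8.68e+12 L/mol/s, Ksv non-increasing)
#> Van't Hoff: dH = -35.77 kJ/mol, dS = -25.49 J/mol/K (r2 = 1.0000)
#>   dG(298 K) = -28.17 kJ/mol
#> Forces: hydrogen bonding / van der Waals, enthalpy-driven, spontaneous
```

The kinetics report reads: the double-reciprocal lines intersect left of
the y-axis and above the x-axis (second quadrant), the signature of mixed
inhibition, and the secondary plots return exactly the constants the
generator was given. The binding report finds a quenching rate constant
far above the diffusion-collision ceiling with Ksv falling as temperature
rises — static quenching via complex formation — and an exothermic,
enthalpy-driven, spontaneous binding consistent with hydrogen bonding or
van der Waals contacts.

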