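# bindspectra

Tidy analysis of drug–protein binding from bench-top spectroscopy.

Small molecules — metallodrugs in particular — bind serum albumins on
their way through plasma, and the standard way to characterise that
binding without specialised calorimetry is a chain of classical
spectroscopic analyses: a UV–Vis titration for the association constant
and its thermodynamics, fluorescence quenching for the binding mechanism
and site count, a thermal melt for the stability shift, and absorbance
kinetics for the reaction order. `bindspectra` implements that whole
chain as composable, tested R functions, for anyone who has
concentration/signal tables from a spectrophotometer or fluorimeter and
wants defensible numbers out.

## The models

* **Binding isotherm (double-reciprocal).** For a 1:1 association the
  measured signal obeys
  `1/(A − A₀) = 1/(A∞ − A₀) + 1/(K_b (A∞ − A₀)) · 1/[L]`,
  so an ordinary least-squares line on the reciprocal axes gives
  `K_b = intercept/slope` and the bound-state signal `A∞`. A direct
  nonlinear fit of the underlying hyperbola is run alongside as a
  cross-check, and free ligand is related to total ligand by an exact
  mass balance `[L]ₜ = [L]_f + ν[P]ₜ` solved by bracketed root finding.
* **van't Hoff thermodynamics.** `ΔG° = −RT ln K_b`; from constants at
  two temperatures, `ΔH° = R ln(K₂/K₁)/(1/T₁ − 1/T₂)` and
  `ΔS° = (ΔH° − ΔG°)/T`, with the classical sign rules classifying the
  dominant force (van der Waals/H-bond, hydrophobic, electrostatic).
* **Cooperativity.** Binding capacity `θ = n_H ν(g − ν)/(gRT)` and its
  linearisation `RTθ/ν = n_H − (n_H/g)ν` (a straight line diagnoses a
  single set of sites); the Hill plot
  `ln(ν/(g − ν)) = ln K_H + n_H ln[L]_f`; an algorithmic Scatchard-shape
  classification; and the per-site Gibbs energy whose slope against
  `ln[L]_f` is analytically `RT(1 − n_H)`.
* **Thermal stability.** Two-state logistic melt fit
  `A(T) = A_pre + (A_post − A_pre)/(1 + exp((T_m − T)/w))`, with a
  model-free midpoint cross-check and the stabilisation shift
  `ΔT_m = T_m(bound) − T_m(free)`.
* **Kinetic order.** Integrated first-order
  (`ln(A∞ − A)` linear in `t`) versus second-order (`1/(A∞ − A)` linear
  in `t`) rate laws, selected by linearisation quality (R²).
* **Fluorescence quenching.** Stern–Volmer `F₀/F = 1 + K_sv[Q]` with an
  automatic low-concentration linear window; the bimolecular constant
  `k_q = K_sv/τ₀` against the 2×10¹⁰ M⁻¹s⁻¹ diffusion limit
  (static vs dynamic); and the double-log binding fit
  `log((F₀ − F)/F) = log K_b + n log[Q]`.

Every stage has a seeded synthetic-data generator with recorded ground
truth (`gen_uv_titration()`, `gen_quench_titration()`, `gen_melt()`,
`gen_kinetic()`), so the whole chain is validated by parameter recovery.

## Worked example

The package ships small synthetic example files (generated by its own
simulators, with known truth: K_b = 6778 M⁻¹ at 300 K and 3038 M⁻¹ at
310 K, melting midpoints 37 °C free / 47 °C bound):

```r
library(bindspectra)
ext <- function(f) system.file("extdata", f, package = "bindspectra")

report <- run_study(list(
  isotherm = list(
    list(path = ext("synthetic_titration_300K.csv"),
         protein_total = 0.15e-6, temperature = 300),
    list(path = ext("synthetic_titration_310K.csv"),
         protein_total = 0.15e-6, temperature = 310)
  ),
  cooperativity = list(series = 1, g = 1),
  melt = list(free = ext("synthetic_melt_free.csv"),
              bound = ext("synthetic_melt_bound.csv"))
))
report
#> <study_report>
#>   stages: isotherm, thermo, cooperativity, melt
#>   delta_H = -60.5 kJ/mol; driving force: vdW_or_Hbond
#>   delta_T_m = +10.0 K (stabilizing)

report$thermo
#> # A tibble: 2 × 6
#>   temperature_K   K_b delta_G_kJ_mol delta_H_kJ_mol delta_S_J_mol_K driving_force
#> 1           300 6533.          -21.9          -60.5           -129. vdW_or_Hbond
#> 2           310 2987.          -20.6          -60.5           -129. vdW_or_Hbond
```

Reading: the fitted association constants (6533 and 2987 M⁻¹, within a
few percent of the generating 6778/3038 under 0.1 % signal noise) fall
with temperature, so binding is exothermic; the van't Hoff enthalpy
(−60.5 kJ·mol⁻¹) and entropy (−129 J·mol⁻¹·K⁻¹) are both negative,
which by the classical sign rules points to van der Waals contacts and
hydrogen bonding; and the +10 K melting-point shift says the bound
protein is thermally stabilised. Individual stages are ordinary
functions returning tibbles or tidy-able fits:

```r
s <- read_titration(ext("synthetic_titration_300K.csv"),
                    protein_total = 0.15e-6, temperature = 300)
fit <- double_reciprocal_fit(s)
fit
#> <isotherm_fit> K_b = 6533 M^-1 (double-reciprocal; direct fit 6713)
#>   A0 = 0.6594, A_inf = 0.3458 AU; L_1/2 = 0.0001548 M; R^2 = 0.99979; T = 300.0 K
glance(fit)    # one-row tibble
autoplot(fit, s)  # the double-reciprocal plot
```

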