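# rheodsd

Quality-by-design (QbD) optimisation of semisolid (ointment) preparation
processes from rheological responses, for formulation scientists and
process engineers working in R.

A high-drug-loading ointment is characterised by four rheological quality
attributes — yield stress, low- and high-shear viscosity, and storage
modulus at body temperature — each with an acceptance window. `rheodsd`
implements the full optimisation chain that links six process factors
(drug ratio, mixing time, mixing speed, petroleum and liquid-paraffin
dosage, and the drug-addition method) to those attributes:

1. **Design** — definitive screening designs (DSDs) built from conference
   matrices (`C'C = (m−1)I`): three-level screening in `2m+4` runs with
   main effects orthogonal to all second-order effects, fold-over mirror
   pairs and centre runs, plus one two-level categorical factor.
2. **Rheology** — extraction of the four responses from rheometer curves:
   yield stress as the G′ departure from the linear-viscoelastic plateau,
   Ostwald–de Waele power-law fits (η = K·γ̇ⁿ⁻¹; n < 1 = shear thinning),
   log–log viscosity interpolation, G′(37 °C) readout.
3. **Models** — coded second-order response-surface models
   (y = β₀ + Σβⱼxⱼ + Σβⱼₖxⱼxₖ + Σβⱼⱼxⱼ² + match terms) fitted by
   bidirectional stepwise selection with effect heredity, with t-ratio
   inference and joint desirability optimisation.
4. **Simulation** — Monte Carlo defect rates against the specification
   windows (a batch is defective when any response leaves its window),
   with radial-stratified space-filling sampling.
5. **Design space** — a prior-weighted CART (Gini splits, λ-blended node
   priors) carves the axis-aligned factor box with the highest pass
   probability; ROC/AUC diagnostics.
6. **Refinement** — a Gaussian-process (kriging) surrogate with Gaussian
   correlation `r_ij = exp(−Σθ_k(x_ik−x_jk)²)` over the log10 defect rate,
   maximum-likelihood θ, and bounded surrogate minimisation inside the box.

A synthetic-data generator produces rheometer curves and DoE response
tables with known ground truth, so the whole chain is testable without
instrument data. See the methods vignette (`vignettes/methods.Rmd`) for
the models, assumptions and design choices.

## Worked example

Build the 14-run screening design for the ointment factor space, load the
case-study response models, and predict at the optimised operating point:

```r
library(rheodsd)

d <- dsd_design(ointment_factors())
d
#> Definitive screening design: 14 runs, 5 continuous factors + 1 categorical
#>   6 mirror pairs, 2 centre run(s)
#>    run_id drug_ratio mixing_time mixing_speed petroleum liquid_paraffin method
#> 1    run1         35          45         1800      85.0            10.0      B
#> 2    run2         35           5          300      70.0             5.0      A
#> ...

models <- ointment_models()
models$yield_stress
#> Response model: yield_stress (Pa)
#>   intercept 42 + 8 terms
#>   +2.23 * mixing_time
#>   -3.39 * mixing_speed
#>   +8.83 * petroleum
#>   -6.96 * liquid_paraffin
#>   +2.33 * method
#>   +10.86 * mixing_speed^2
#>   -5.04 * mixing_time:liquid_paraffin
#>   -7.37 * petroleum:liquid_paraffin
#>   R-squared 0.9139, p = 0.026

round(vapply(models, predict, numeric(1), newdata = optimal_settings()), 2)
#> high_shear_visc  low_shear_visc storage_modulus    yield_stress
#>            5.31        14608.01          530.70           44.97
```

The predictions at the optimum (drug ratio 24.5%, mixing 7.77 min at
1175 rpm, 78.9 g petroleum, 6.73 g liquid paraffin, method B) land inside
all four specification windows: ~45 Pa yield stress (window 40–55), high
shear ~5.3 Pa·s (0–7), low shear ~14 600 Pa·s (11 000–18 000), storage
modulus ~531 Pa (200–1000).

Simulate the defect rate at that operating point under the default
perturbation model (factor SDs 5% of half-range, response residual SDs 5%
of each model's intercept scale):

```r
defect_rate(models, optimal_settings(), spec_limits(),
            default_noise_model(models), n = 100000, seed = 1)
#> Defect report (n = 100000, seed = 1)
#>   yield_stress     0.0112
#>   high_shear_visc  0.0000
#>   low_shear_visc   0.0004
#>   storage_modulus  0.0000
#>   overall          0.0116  (log10 -1.937)
```

About 1.2% of simulated batches miss at least one window, almost entirely
on yield stress — the response whose window is tightest relative to its
noise. `run_case_study()` executes the whole chain (design → synthetic
responses → fits → desirability optimum → defect simulation → tree box →
GP surface → constrained optimum) from one seeded configuration and
returns a reproducible report.

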