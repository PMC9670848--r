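# semifate

Environmental chemodynamics of 4-isobutylacetophenone (IBAP), the toxic
phototransformation product of ibuprofen (IBP): determination of its
gas-phase OH rate constant from smog-chamber decay data, and a
closed-form two-media (surface water + atmosphere) fate model.

## Who this is for

Atmospheric and aquatic photochemists working with relative-rate chamber
data for semivolatile organics, and environmental modelers who need the
fate of a photoproduct that is formed in water but destroyed in both
water and air.

## What it computes

**Relative-rate kinetics.** Target and reference compounds share the
same OH history in the chamber, so after subtracting independently
measured wall loss,

```
ln([T]0/[T]t) − k_WL,T·(t−t0) = (k_T/k_ref) · [ln([R]0/[R]t) − k_WL,R·(t−t0)]
```

holds for any OH time profile. The OLS slope is the ratio `k_T/k_ref`;
multiplying by the recommended `k_ref` (with its 10% uncertainty folded
in quadrature) gives `k_T`, and determinations against several references
are pooled by inverse-variance weighting. Pseudo-first-order loss rates
(`k2·[OH]`), atmospheric lifetimes (`1/(k2·[OH])`) and the steady-state
OH level of a TME-ozonolysis source complete the gas-phase picture.

**Two-media fate.** The network
`IBP_w → IBAP_w → {aqueous photodegradation, volatilization → gas-phase OH}`
is linear first-order, so the time trends are Bateman closed forms with
eigenvalues `(k_d, k_vol + k_d′, k_g)`. Summary fractions follow from the
rate constants alone: the formation yield `f = k_f/k_d`, the volatilized
share `v = k_vol/(k_vol + k_d′)`, and per-pathway degradation fractions
`F_j = k_j/(k_OH_w + k_3CDOM + k_dp + k_vol)`. A stiff-safe ODE
integrator (`simulate_ode`) serves as the numerical oracle for the
analytic forms.

## Worked example

```r
library(semifate)

# pool three independent determinations of k(IBAP + OH), NOx conditions
pooled <- weighted_average(list(
  rate_constant(4.40e-12, 0.53e-12),
  rate_constant(5.17e-12, 0.70e-12),
  rate_constant(4.63e-12, 0.71e-12)))
pooled
#> <rate constant> 4.667e-12 +/- 3.63e-13 cm3 molecule-1 s-1 (1 sigma)

atmospheric_lifetime(pooled)       # days against the 24 h average OH
#> [1] 2.194512

convert_rate(pseudo_first_order(4.7e-12), "day-1")$value
#> [1] 0.4588704

# two-media fate under the bracketing scenarios
fractions(load_scenario("fast"))$v   # volatilized share, fast kinetics
#> [1] 0.1150442
fractions(load_scenario("slow"))$v   # slow kinetics: most IBAP escapes
#> [1] 0.6341463
```

Read: pooling the three chamber determinations gives
(4.67 ± 0.36)×10⁻¹² cm³ molecule⁻¹ s⁻¹, i.e. a ~2.2-day atmospheric
lifetime — IBAP is a local pollutant. In shallow, photochemically active
water only ~12% of aqueous IBAP volatilizes before being destroyed; in
deep, high-DOC water ~63% escapes to the gas phase, where fast OH
chemistry keeps its airborne levels very low regardless.

The numbered drivers under `analysis/` run the full workflow and write
tables to `results/`:

```sh
Rscript analysis/01_chamber_kinetics.R       # synthetic chamber pipeline + pooling
Rscript analysis/02_atmospheric_descriptors.R
Rscript analysis/03_fate_scenarios.R         # trends, f, v, ODE cross-check
```

## Package layout

* `R/` — chamber kinetics fitters, gas-phase descriptors, fate model,
  scenario registry, synthetic-data generators, CSV/JSON I/O.
* `analysis/` — numbered narrative drivers over the package functions.
* `vignettes/semifate-methods.Rmd` — the model, its assumptions, and
  every numerical choice, with rationale.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
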