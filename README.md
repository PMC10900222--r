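# allokin

Dissecting how a catalyzed torsional-isomerization rate is set by its two
controlling factors — the free-energy barrier along the reaction coordinate
and the effective diffusion coefficient of the reaction dynamics — and how
both are modulated allosterically.

The motivating system is peptidyl-prolyl *cis–trans* isomerization: the
prolyl amide-bond torsion ω has wells at ω ≈ 180° (*trans*) and ω ≈ 0°
(*cis*) separated by a ≈ 90° transition state, with a dihedral potential

    V(φ; α) = α · Σₙ (Vₙ/2) [1 + cos(nφ − γₙ)] + V_bg(φ)

whose barrier amplitude is scaled by α ∈ (0, 1] so that barrier crossing
becomes tractable, plus an unscaled background representing the
environment. The pipeline combines:

- **Brownian-dynamics generation** of restrained (umbrella) and
  unrestrained ω(t) trajectories on that potential (overdamped
  Euler–Maruyama, compiled kernel, bit-reproducible seeds);
- **WHAM** free-energy profiles A(ω) from 49 umbrella windows
  (−30…210°, 5° spacing, 0.01 kcal mol⁻¹ deg⁻² restraints; 80 bins on
  [−31.5°, 208.5°], tolerance 10⁻⁶) with Monte Carlo bootstrap errors at
  the estimated decorrelation time;
- **barrier-scaled extrapolation**: profiles measured at several α < 1
  superposed at their α-insensitive anchors (ω = 0°, 180°) and regressed
  per bin against 1 − α (first-order cumulant scheme), the intercept being
  the unmodified-potential profile A₀(ω);
- **survival kinetics**: first-passage detection at the free-energy peak,
  Kaplan–Meier estimation with exponential-Greenwood 95% intervals, and
  CI-weighted single/multi-exponential fitting with a weighted-average
  effective rate k = Σ Aᵢkᵢ / Σ Aᵢ;
- **Kramers-theory regression**: with k = (ω₀ω_b β D / 2π) e^(−βΔG‡) in
  the overdamped limit, a fixed-slope (−1/k_BT) fit of ln(k/ω₀ω_b) against
  ΔG‡ across reduced barriers, whose intercept yields D_eff and whose
  extrapolation predicts the rate at the full barrier; first-order error
  propagation s_f = √(Σ (∂f/∂xᵢ)² s²ᵢ) throughout;
- **functional-mode detection**: multiensemble PCA with functional-PC
  selection by correlation with ω, and multiensemble PLS functional mode
  analysis (PLS-FMA) with 10-fold cross-validated component count;
- **comparative reporting** of per-system barrier/rate/diffusion tables,
  deltas with propagated errors and fold changes.

A synthetic-data module generates every input with known ground truth
(diffusive dynamics on the potential, harmonically restrained windows,
escape replicas, pseudo-structure ensembles with a planted collective
mode), so each stage can be validated against independent oracles
(quadrature Boltzmann inversion, mean-first-passage-time quadrature,
closed forms).

## Worked example

Free-energy profile and kinetics of a reduced-barrier double well, checked
against quadrature oracles:

```r
library(allokin)

pot <- torsion_potential(c(2, 8.4, 180))          # V2 = 8.4 kcal/mol
cfg <- brownian_config(D = 1e7, dt = 1.25e-8, n_steps = 2e5,
                       save_stride = 20, seed = 11)
win <- generate_umbrella_set(pot, cfg = cfg, n_equil = 5000)  # 49 windows
pr  <- wham_solve(win)
bs  <- barrier_stats(pr)
bs$dG_tc
#> 8.601 +- NA        # trans->cis barrier (kcal/mol), errors need bootstrap

ok <- pr$counts >= 100
sqrt(mean(((pr$A - mean(pr$A[ok])) -
           (boltzmann_profile(pot)$A - mean(boltzmann_profile(pot)$A[ok])))[ok]^2))
#> 0.05388189         # RMS deviation from the Boltzmann oracle (kcal/mol)

pot4 <- torsion_potential(c(2, 4, 180))
mfpt <- mfpt_quadrature(pot4, D = 1e7, start = 180, lower = 90, upper = 270)
reps <- generate_escape_replicas(pot4, 100,
          brownian_config(1e7, 3.2e-8, round(8 * mfpt / 3.2e-8),
                          save_stride = 50, seed = 7))
km  <- km_survival(event_records(reps, omega_ts = 90), grid = mfpt / 20)
fit <- fit_survival(km, n_components = 1)
fit$k$value * mfpt   # fitted rate x oracle MFPT: 1 means perfect agreement
#> 1.008239
```

The comparative report reproduces published-style statements from a
bundled per-system reference table (barrier deltas with propagated errors,
rate and diffusion fold changes):

```r
rep <- comparison_report(reference_summaries())
subset(rep, quantity == "dG_tc" & system_a == "FFpSPR")[, c("system_b", "value", "sd")]
#>        system_b value  sd
#> 2         FFSPR   1.0 0.7   # phosphorylation raises the barrier
#> 3 FFpSPR-PPIase   7.9 0.6   # the catalytic domain lowers it
```

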