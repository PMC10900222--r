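---
title: "Free-energy barriers, reaction-coordinate diffusion, and functional modes: the allokin methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{allokin methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

allokin dissects a catalyzed torsional-isomerization rate into its two
controlling factors — the activation free energy along the reaction
coordinate and the effective diffusion coefficient of the reaction
dynamics — and provides the statistical machinery to measure both, to
extrapolate from reduced-barrier simulations to the physical barrier, and
to detect the collective motions that correlate with the reaction's
progress. This vignette is the package's own account of the models,
estimators, parameter choices, and known limitations.

## The reaction coordinate and its potential

The coordinate is a torsion angle ω with wells near 0° (*cis*) and 180°
(*trans*) and the studied transition state near 90°. The working interval
is [−90°, 270°): both wells and the 90° barrier are interior, and the
periodic image of the second barrier sits at the interval edge. The
potential is the standard cosine series

$$V(\phi;\alpha) = \alpha \sum_n \tfrac{V_n}{2}\bigl[1 + \cos(n\phi - \gamma_n)\bigr] + V_{bg}(\phi),$$

with a single term $(n = 2, V_2, \gamma = 180^\circ)$ giving a symmetric
double well of barrier height $V_2$. The dimensionless factor
$\alpha \in (0,1]$ scales the dihedral term only; reduced-barrier
potentials ($\alpha < 1$) make spontaneous crossing observable at
simulation scale. The unscaled background series represents the smooth
periodic contribution of the environment; it defaults to zero, and a
term such as $(n = 1, V = 2, \gamma = -90^\circ)$ raises the 270°
pathway and de-symmetrizes the wells, emulating a torsion embedded in an
anisotropic protein environment.

Constants are fixed at $k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹ and
$T = 300$ K, so $k_BT = 0.59616$ kcal/mol.

## Synthetic dynamics with known ground truth

Because the package's estimators are the object of study, all inputs are
generated by overdamped Brownian dynamics with known parameters
(Euler–Maruyama):

$$\omega \leftarrow \omega - \beta D \frac{dV}{d\omega}\,dt + \sqrt{2 D\,dt}\,\eta,$$

with $D$ in deg²/s and $\eta$ standard normal. A construction-time guard
requires the per-step RMS displacement $\sqrt{2D\,dt} < 1^\circ$; the
fixtures use $0.5^\circ$ ($0.8^\circ$ for long escape runs), a compromise
between discretization error and steps per barrier crossing. The
compiled integrator carries its own counter-based RNG seeded from the
configuration, so trajectories are bit-identical for identical seeds and
independent of R's RNG state.

Harmonic restraints are $E = \tfrac{k}{2}(\omega - \omega_{ref})^2$
(minimal periodic image), so a restrained free angle has stationary
variance $k_BT/k$ — the convention every downstream bias calculation
shares.

Study conditions used by the test suite and the acceptance script, chosen
once as desk-scale analogues of a production umbrella-sampling campaign:
$D = 10^7$ deg²/s; 49 windows at −30…210° in 5° steps with
$k = 0.01$ kcal mol⁻¹ deg⁻²; 2 × 10⁵ production steps per window
(10⁶ for the extrapolation experiment, where leverage amplifies per-bin
noise — see below) after 5 × 10³ discarded equilibration steps; window
$i{+}1$ starts from the final state of window $i$ (sequential chaining).
Escape experiments use 100 replicas started in the *trans* well, each
stopped at its first detected crossing or censored at 8 oracle mean
first-passage times.

## Free-energy profiles: WHAM with bootstrap errors

Window histograms (80 half-open bins on [−31.5°, 208.5°]) are combined by
the standard self-consistent WHAM iteration over window free-energy
shifts, iterated until the largest shift change falls below 10⁻⁶
kcal/mol; a connectivity check rejects window sets whose histograms do
not overlap. The unbiased probability gives $A = -k_BT \ln P$, anchored
at min = 0; unsampled bins stay `NA` and are never interpolated —
`barrier_stats()` aborts if an interior bin is empty, because silent
interpolation hides sampling failure.

Errors come from a Monte Carlo bootstrap (default 10 trials, seed 1234):
each trial resamples, per window, the decorrelated points — every
⌈decorrelation/dt⌉-th sample at a random phase, resampled with
replacement — and re-solves WHAM; the per-bin error is the SD across
trials. The decorrelation time is estimated as twice the first lag at
which the normalized autocorrelation of ω falls below 1/e. Note that
anchored profiles have errors *relative to the anchor bin*, whose own
bootstrap SD is zero by construction.

States are located as free-energy minima in boxes 0 ± 45° and 180 ± 45°
and the maximum strictly between them; curvatures are twice the quadratic
coefficient of a parabola fit over ± 10° (≥ 4 bins) around each
stationary point. Convergence of a data set is assessed by re-solving
WHAM on cumulative time blocks and comparing the last-block change of the
state free-energy differences against twice the combined bootstrap error.

## Extrapolating reduced-barrier profiles to the physical barrier

To first cumulant order, the profile measured at scaling α obeys
$A(\omega;\alpha) = A_0(\omega) - (1-\alpha)B(\omega)$ with $B(\omega)$
the mean unmodified dihedral energy at fixed ω. Profiles measured at
several α are first superposed by the constant minimizing their squared
difference at the bins nearest 0° and 180° (where α has negligible
influence), then regressed per bin against $1-\alpha$ with
inverse-variance weights from the bootstrap errors; the intercept is
$A_0(\omega)$, the slope $-B(\omega)$. Higher-order cumulants are
dropped, with no option to include them. Weighted-fit intercept errors
are the variance-known (generalized least squares) errors
$\sqrt{[(X^TWX)^{-1}]_{11}}$ — with three points and two parameters, a
residual-based error estimate would be uselessly noisy — so adding a
consistent profile at a new α always tightens them. When a bin has no
usable errors (noiseless fixtures) the fit falls back to ordinary least
squares with a logged notice. Whether to weight per bin or per profile
was an open choice; per-bin inverse variance was selected as the finer
of the two.

The leverage of this design deserves emphasis: extrapolating from
$1-\alpha \in [0.65, 0.75]$ to 0 multiplies per-bin noise by roughly
the anchor distance over the α-spread (≈ 17 here), which is why the
extrapolation experiment samples 10⁶ steps per window and why the
acceptance check is formulated in combined-error units (agreement within
2 × the combined uncertainty of the extrapolated and directly sampled
barriers) rather than absolute ones. In this one-dimensional reduction
the cumulant relation is exact up to binning effects, so the check probes
estimator calibration, not model error.

## Survival kinetics of barrier crossing

Escape replicas are scanned for the first sample past the
transition-state angle (sample resolution, no interpolation; replicas
starting on the product side are rejected). Each replica contributes at
most one event or a right-censored record. The survival curve is the
Kaplan–Meier product-limit estimate with the exponential Greenwood
(log-minus-log) 95% interval, computed by `survival::survfit` and
evaluated on a uniform grid; an independent product-limit implementation
serves as the oracle in the tests.

Rates come from exponential fits weighted by the inverse squared
confidence-interval half-width, *measured in the space the fit runs in*:
the single-exponential fit is a linear regression of ln S on t through
the origin, so its weights use the CI half-width on the log scale. This
choice matters: S-space half-widths shrink to zero as S → 0, and using
them for a semilog fit overweights the noisiest tail of the curve,
biasing the rate low by ~10% on 100-replica fixtures (established
against the mean-first-passage-time oracle). Multi-component fits
$S(t) = \sum_i A_i e^{-k_i t}$ run in S space with S-space weights,
under $A_i > 0$ and $\sum A_i = 1$ (required by $S(0)=1$; whether the
original formulation imposed the constraint is unstated), via
multi-start BFGS on log-rate/softmax-transformed parameters,
deterministic for a given seed. The effective rate is the
coefficient-weighted average $k = \sum A_i k_i / \sum A_i$ with its error
from the fit covariance by first-order propagation.

`model_select()` compares 1…n components by small-sample AICc on the
weighted residuals, after discarding inadmissible candidates — any
component with coefficient below 0.05 or with $k_{err} \ge k$
(component collapse). Without that guard, AICc applied to correlated
Kaplan–Meier residuals with strongly heterogeneous weights favors
spurious tiny fast components.

## Kramers regression for the effective diffusion coefficient

In the overdamped limit the rate over a one-dimensional barrier is

$$k = \frac{\omega_0\,\omega_b\,\beta D_{eff}}{2\pi}\,e^{-\beta \Delta G^\ddagger},$$

where $\omega_0$ and $\omega_b$ are defined here as the square roots of
the absolute free-energy curvatures of the reactant well and the barrier
(units (kcal/mol)^½ deg⁻¹) — the only reading that makes the prefactor an
inverse time with $D$ in deg²/s. Taking logarithms,
$\ln(k/\omega_0\omega_b) = c - \beta\,\Delta G^\ddagger$ with
$c = \ln(\beta D_{eff}/2\pi)$: across barriers at several α, a linear
fit with the slope *fixed* at $-1/k_BT$ reduces to a variance-weighted
mean of $\ln(k_i/\omega_{0,i}\omega_{b,i}) + \beta\Delta G^\ddagger_i$,
whose exponential gives $D_{eff} = 2\pi k_BT\,e^{c}$, assumed independent
of the barrier scaling. The fitted line extrapolated to the physical
barrier's $\Delta G^\ddagger$ (known from umbrella sampling, directly or
via the cumulant scheme) predicts the unsimulated rate. All errors
propagate by $s_f = \sqrt{\sum_i (\partial f/\partial x_i)^2 s_i^2}$.

One subtlety, quantified against the MFPT quadrature oracle: detecting
events at the barrier *top* measures the first-passage rate to the
transition state, which exceeds the committed well-to-well rate by the
inverse splitting probability — a factor approaching 2 in the overdamped
limit (numerically 1.87–1.99 for barriers of 3–7 kcal/mol). The
kinetics validation therefore pairs top-detection with a
top-absorbing oracle, while the diffusion-recovery experiment detects
*committed* transitions (absorbing point past the barrier, at 30°) and
pairs them with the matching oracle; the background term suppresses the
second pathway so single-barrier theory applies. A production analysis
comparing systems is unaffected by the convention as long as it is used
consistently, since the factor is absorbed into $D_{eff}$.

At the desk-scale study conditions the recovered $D_{eff}$ lies within a
factor 2 of the generator's ground truth and the extrapolated
full-barrier rate within a factor 3 of the oracle; residual deviations
stem from the harmonic-saddle approximation at moderate barriers
(3–7 k_BT·2) and from curvature-fit bias, both of which shrink as the
barrier grows. Experiments use dihedral amplitudes {4, 4.5, 5} kcal/mol
over the 2 kcal/mol background, extrapolated to amplitude 8: escape
simulation cost grows as $e^{\beta\Delta G}$ at the stability-bounded
step size, and these barriers keep the full pipeline within minutes on
one CPU while leaving the extrapolation genuinely out of sample.

## Collective modes correlated with the reaction coordinate

Conformational ensembles pooled over umbrella windows, labelled by the
window's reference ω, are superposed by least-squares (Kabsch) fitting
over the analysis atoms — by default onto the mean structure (fit to the
stored reference, then re-fit to the resulting mean). Multiensemble PCA
diagonalizes the pooled Cartesian covariance; the *functional PC* is the
component (among the first 10 by default; the scree inspection that
motivates a cutoff rarely supports more than ~5) whose projection
correlates most with ω — which is not always PC1, the package's
synthetic fixtures reproduce that dissociation by planting a
high-variance noise mode uncorrelated with the labels. Multiensemble
PLS-FMA regresses ω on the centered coordinates by PLS1 (NIPALS,
authored in-package and validated against the n = rank ⇒ OLS identity);
the functional mode is the unit-normalized coefficient vector, and the
component count is chosen by seeded 10-fold cross-validation maximizing
the test-fold correlation, with the final model refit on all frames.
Leave-window-out folds are available because random frame folds can leak
window structure.

The synthetic ensembles plant one unit mode whose amplitude varies
linearly with the window label, plus orthogonal random-amplitude noise
modes and isotropic jitter; planted and noise modes are projected onto
the internal-motion subspace (orthogonal to the six rigid-body vectors of
the reference) so superposition leaves them intact. Two regimes matter
for interpreting the cross-validation: under isotropic noise the CV curve
peaks at the generative dimension (extra components only overfit),
whereas under high-variance structured orthogonal noise PLS provably
benefits from a second component that de-contaminates the covariance
direction — the CV check of the generative dimension therefore runs on
the isotropic fixture. What these fixtures do *not* emulate: anharmonic
and multi-scale protein motions, coupling between the planted mode and
the noise, window-dependent noise levels, and alignment uncertainty on
flexible regions; mode recovery on real ensembles is correspondingly
harder than the synthetic results suggest.

Modes export as per-atom displacement fields with arrows shorter than
1 Å dropped (the conventional porcupine-plot clarity filter).

## Comparative reporting

Per-system summaries (per-α rows plus one real-potential row carrying
$D_{eff}$, with a provenance column distinguishing direct sampling from
extrapolation) feed a comparison engine producing deltas with
quadrature-propagated errors and fold changes. Display rounding is
half-away-from-zero — deltas to one decimal, folds to the nearest
integer — applied only at the reporting boundary, with raw values always
retained and all inputs echoed so every reported number is reproducible
by a one-line recomputation. A bundled reference table of six
protein/peptide systems exercises this layer end to end.

## Numerical choices and degenerate inputs

* WHAM tolerance 10⁻⁶ kcal/mol on the shifts; iteration cap 10⁵ with an
  explicit non-convergence error.
* Bin assignment is half-open [left, right); samples outside the binned
  range are dropped.
* Curvature fits require ≥ 4 bins; the barrier curvature must be
  negative (warned otherwise).
* Constant series are rejected by the decorrelation estimator;
  trajectories shorter than 100 samples likewise.
* A flat survival curve (S ≡ 1) is a fit error, not a zero rate;
  all-censored-at-zero record sets are rejected.
* Multi-start fits and cross-validation consume seeds through a
  state-preserving wrapper, so library calls never perturb the caller's
  RNG stream.
* The acceptance script derives every seed from its `--seed` argument and
  touches nothing outside the repository.

## Known limitations

The one-dimensional overdamped model has no memory friction, no
position-dependent diffusion, and no recrossing correction beyond the
splitting-probability bookkeeping above; the cumulant extrapolation is
exact here but only first-order on real systems; bootstrap errors are
relative to the profile anchor; and the multi-exponential selection
guard trades sensitivity to genuinely tiny components (coefficient
< 0.05) for robustness against overfitting.
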