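---
title: "One-shot fine-tuning of charge models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-shot fine-tuning of charge models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargetune)
```

## The problem

Graph-neural-network force-field parameterizers emit, for every atom, a
continuous embedding vector together with electrostatic parameters —
an electronegativity $e_i$ and a hardness $s_i$ — from which partial
charges follow by charge equilibration (QEq). Such "foundation" charge
models are trained on quantum-chemical data and systematically misfit
condensed-phase observables like hydration free energies, largely
because condensed-phase polarization is absent from the training
signal. chargetune implements a cheap, interpretable correction: a
low-rank linear perturbation of $(e, s)$, fitted directly to
experimental free energies, with **no new molecular dynamics** — all
free-energy changes are obtained by exponential (Zwanzig) reweighting
of per-frame electrostatic potentials that were saved during the
original simulations.

## The model

**Projection.** All atom embeddings $h_i \in \mathbb{R}^m$ in the
dataset are pooled into a matrix and a truncated principal-component
basis $Q_{m\times r}$ is extracted from the centered scatter
$(H-\mu_h)(H-\mu_h)^\top$. Each embedding is projected,
$\hat h_i = Q^\top (h_i - \mu_h)$. The rank $r$ controls model capacity
($2r$ parameters in total).

**Perturbation.** A $2 \times r$ parameter matrix
$\Theta = (\theta_e; \theta_s)$ shifts the electrostatic parameters
linearly: $e_i^* = e_i + \theta_e^\top \hat h_i$,
$s_i^* = s_i + \theta_s^\top \hat h_i$. Atoms whose projected
embeddings lie in the null space of $\Theta$ are untouched, and
$\Theta = 0$ reproduces the foundation model exactly.

**Charge equilibration.** Charges are regenerated under the total-charge
constraint:
$$q_i^* = -\frac{e_i^*}{s_i^*} + \frac{1}{s_i^*}
  \frac{Q + \sum_j e_j^*/s_j^*}{\sum_j 1/s_j^*}.$$
The constraint $\sum_i q_i^* = Q$ holds to machine precision, and the
map is smooth in $(e^*, s^*)$, which the analytic loss gradient
exploits. A useful identity: adding a constant to all
electronegativities leaves the charges unchanged.

**Reweighting.** Because the molecule–environment electrostatic energy
is linear in the molecular charges,
$U(x) = \sum_i q_i^* \phi_i(x)$, only the per-atom environment
potentials $\phi_i$ need to be stored per frame. The free-energy
change of replacing $q$ by $q^*$ is the one-sided exponential average
over frames drawn at the unperturbed potential:
$$\Delta G_{\text{pert}}(\Theta) = -\beta^{-1}
  \ln \left\langle e^{-\beta \Delta U_t} \right\rangle_t, \qquad
  \Delta U_t = \sum_i (q_i^* - q_i)\, \phi_{ti},$$
with $\beta = 1/k_B T$. All weight arithmetic is done in log space
with a max-shift. Note that one encounters the definition
$\beta = k_B T$ in parts of the reweighting literature as a
typographical slip; this package always uses the inverse thermal
energy, the only convention under which the estimator is a free
energy.

**Effective sample size.** Reweighting reduces the information content
of the fixed frame set: the effective sample size
$\mathrm{ESS} = (\sum_t w_t)^2 / \sum_t w_t^2 \in [1, N]$ of the
importance weights $w_t = e^{-\beta \Delta U_t}$ is the monitored
proxy for estimator reliability. When phase-space overlap between the
unperturbed and perturbed charge states degrades, the ESS collapses
and both the variance and the finite-sample bias of the exponential
average grow rapidly.

## The objective

$$\mathcal{L}(\Theta) = \sum_{j \in \text{all molecules}}
  \mathrm{Reg}_{\mathrm{ESS}}(\mathrm{ESS}_j(\Theta))
  + \frac{1}{N_{\text{train}}} \sum_{i \in \text{train}}
  L_\delta\!\left(\delta \Delta G_i(\Theta)\right)$$

* The data term is the mean pseudo-Huber loss
  $L_\delta(x) = \delta^2(\sqrt{1+(x/\delta)^2}-1)$ of the residuals
  $\delta\Delta G_i = \Delta G^{\text{expt}}_i - (\Delta
  G^{\text{calc}}_i + \Delta G_{\text{pert},i}(\Theta))$, over
  training molecules only. It is quadratic near zero and linear in the
  tails, so outlier molecules do not dominate. By default residuals
  are expressed in units of $k_BT$ and $\delta = 1$ (one thermal
  energy); a `loss_units = "kcal"` flag keeps kcal/mol.
* The regularization term penalizes every molecule — train, validate
  and test — whose ESS falls below an onset $a$:
  $\mathrm{Reg}(\mathrm{ESS}) = k\,(a - \mathrm{ESS})^2$ for
  $\mathrm{ESS} < a$ and $0$ otherwise. Defaults $k = 100$,
  $a = 750$ samples act as a near-hard constraint in raw sample
  counts. Penalizing all splits protects prospective (test-set)
  predictions from silent sample-size collapse. The hinge-quadratic is
  $C^1$, which is sufficient for quasi-Newton optimization; a
  $C^\infty$ squared-softplus variant is available behind
  `smooth_penalty` for users who want a smooth tail.

The orientation of this penalty — active *below* the onset — is the
only one consistent with its purpose of keeping reweighting reliable;
one occasionally sees the piecewise cases printed in the opposite
order, which would penalize reliable estimates instead.

**Optimization.** BFGS (inverse-Hessian update, strong-Wolfe line
search) from $\Theta = 0$, with an analytic gradient chained through
the QEq Jacobian, the per-frame energies, and the Zwanzig/ESS weight
functions (verified against central finite differences at relative
tolerance $10^{-5}$). The loop is implemented in the package rather
than delegated to `optim()` because the method requires per-accepted-
iterate control: after every iterate, if any molecule's ESS falls
below `ess_stop` (default 500 samples) the run halts and returns the
last iterate whose minimum ESS satisfied the threshold, so the
returned parameters always lie inside the reweighting trust region.
`optim(method = "BFGS")` is retained as an independent cross-check in
the test suite. Perturbations that drive any hardness below a small
floor (`s_floor = 1e-6`) are treated as infeasible points with a large
sentinel loss, which the line search backtracks away from.

## ESS-threshold calibration

`calibrate_threshold()` reproduces the procedure that motivates the
500-sample early-stopping default: fit without regularization, keep
molecules whose full-sample ESS survives an inclusion floor, bootstrap
the free-energy perturbation at a log-spaced grid of resample sizes,
and report $|\text{bias}| + \text{sd}$ averaged over molecules with an
upper 95% envelope (97.5th percentile across molecules — the envelope
construction is this package's choice). The detected threshold is the
smallest grid size from which the envelope stays below a caller-
supplied reference error, e.g. the mean uncertainty of the baseline
free-energy estimates. Bootstrap size is equated with ESS on the
grid, a good approximation for the near-uniform-weight molecules the
inclusion floor selects. On synthetic data the *procedure* is
validated (error monotone in sample size, threshold on the boundary);
the numerical threshold depends on the ensemble and is not a constant
of the method.

## Evaluation

`evaluate_run()` reports, per split, RMSE and MUE with nonparametric
bootstrap 95% intervals, a paired-bootstrap interval on the RMSE
change, and the shift between pre- and post-fit *absolute*-residual
distributions measured by the Cramér–von Mises criterion. Two CvM
quantities are exposed: the one-directional ECDF integral
$\omega^2 = \int (F_{\text{post}} - F_{\text{pre}})^2\,
dF_{\text{pre}}$, and the symmetric two-sample rank statistic with
midrank ties whose asymptotic null distribution (evaluated through the
Bessel-$K_{1/4}$ series with Anderson's finite-sample moment
rescaling) supplies the p-value. Both are reported because the
integral is the natural effect-size reading while the rank statistic
carries the standard test theory.

## The synthetic generator

Real inputs for this method are embeddings from a pretrained GNN and
potentials saved from explicit-solvent simulations; both are out of
scope to regenerate, so the package ships a generator that emulates
their statistical structure with a crucial advantage: exact oracles.

* **Embeddings** are drawn around `n_clusters` archetype vectors
  (chemical-environment classes) with Gaussian jitter, so the PCA step
  has genuine low-dimensional structure to find.
* **Electrostatic parameters** use per-cluster electronegativities
  (spread ~40 kcal mol$^{-1}$e$^{-1}$; only differences matter for
  QEq) and hardnesses in the 150–300 kcal mol$^{-1}$e$^{-2}$ range
  typical of charge-equilibration parameterizations. Charges are
  exactly `qeq_charges(e, s, 0)` — neutral molecules — so the
  zero-perturbation identity is exact by construction.
* **Potentials** follow a Gaussian linear-response ensemble
  $\phi \sim \mathcal N(\mu_0 - A q,\ \Sigma_\phi)$: the mean responds
  linearly to the molecular charges (dielectric-like response,
  $A \approx 30$ kcal mol$^{-1}$e$^{-2}$), per-atom fluctuations of
  4–8 kcal mol$^{-1}$e$^{-1}$ with short-range inter-atom correlation,
  scaled by `overlap_scale` to control how fragile reweighting is.
  Frames are i.i.d. — the package treats stored frames as
  decorrelated snapshots throughout, an assumption the caller must
  ensure for real trajectory data.
* **Labels**: experimental values are
  $\Delta G^{\text{calc}} + \Delta G_{\text{exact}}(\Theta_{\text{true}})
  + \mathcal N(0, \sigma_{\text{expt}}^2)$ with a hidden
  $\Theta_{\text{true}}$ expressed in the generator's own PCA basis
  (making recovery well-posed) and $\sigma_{\text{expt}} = 0.2$
  kcal/mol by default, a typical experimental uncertainty for
  hydration free energies.

Under this ensemble the exponential average integrates in closed form,
$\Delta G = \Delta q^\top \mu - \tfrac{\beta}{2} \Delta q^\top
\Sigma_\phi \Delta q$, which serves as ground truth for the
reweighting estimator, and the exponentially tilted (perturbed)
ensemble is again Gaussian, providing an exact stand-in for
"re-simulation at the perturbed charges". What passing tests on this
generator do **not** show: robustness to correlated frames, to
non-Gaussian solvent response (dielectric saturation, hydrogen-bond
rearrangement), or to embedding distributions without cluster
structure.

## Numerical choices and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| $T$ | 298.15 | K | standard condition for hydration free energies; $\beta = 1/k_BT$ |
| $\delta$ | 1 | $k_BT$ | one thermal energy separates "noise" from "signal" residuals |
| $k$ (`k_reg`) | 100 | — | stiff enough that the penalty acts as a near-hard constraint |
| $a$ (`a_onset`) | 750 | samples | penalty onset safely above the stopping threshold |
| `ess_stop` | 500 | samples | early-stopping trust-region boundary |
| `s_floor` | $10^{-6}$ | kcal mol$^{-1}$e$^{-2}$ | QEq divides by $s^*$; below this the point is infeasible |
| Coulomb constant | 332.0637 | kcal Å mol$^{-1}$e$^{-2}$ | dataset units |
| cutoff $r_{\text{cut}}$ | 12 | Å | toy potential cutoff; contributions beyond are omitted |
| grad tol | $10^{-6}$ | — | max-norm BFGS stopping |

Other deliberate choices:

* **PCA centering.** Fitting always centers the scatter; projection
  centers by default, with `center = FALSE` available because the
  uncentered projection is also a legitimate reading of the model (the
  two differ only by a constant shift of every $\hat h_i$, which the
  fitted $\Theta$ can absorb through the training data). Eigenvalues
  follow the unnormalized scatter convention; eigenvector signs are
  fixed by making each column's largest-magnitude component positive,
  so repeated fits are bit-identical.
* **PCA pool.** The basis is fitted on all molecules, not the training
  split only: the projection is unsupervised and uses no labels.
* **Splits.** `floor(train_fraction * N)` to train; remaining
  molecules split 25/75 into validate/test (floor for validate,
  remainder to test). Deterministic given a seed; sizes depend only on
  `N` and the fraction.
* **Early-stop return value.** The last iterate whose minimum ESS met
  the threshold — returning the violating iterate would hand the
  caller parameters whose free energies are exactly the unreliable
  ones the procedure exists to avoid.
* **Toy potential switch.** The reference potential calculator uses
  $f(r) = \cos^8\!\big(\tfrac{\pi}{2}(r/r_{\text{cut}})^3\big)$, which
  is 1 at contact and decays smoothly to zero at the cutoff, with a
  bare-Coulomb `switch = "none"` fallback. An Ewald-style direct-space
  screening factor is deliberately omitted: its splitting coefficient
  is an engine convention, and the fine-tuning mathematics only needs
  *some* consistent potential definition for fixtures — real
  potentials arrive precomputed in the dataset.
* **Container.** Datasets are stored as a directory of parquet tables
  plus a JSON manifest; parquet stores IEEE doubles losslessly, so
  write–read round trips are exact on every numeric field.

## Problem sizes

The package's own validation uses desk-scale ensembles chosen to make
every statistical check sharp: 200 molecules of 5–30 atoms with
2000 frames for parameter recovery, 40 molecules with 5000 frames for
the reweighted-versus-exact comparison, 20 replicate seeds of a
20-molecule overlap-fragile ensemble for the regularization contrast,
and $10^5$-sample Gaussian draws for the estimator oracle. Embedding
dimension defaults to 64 (configurable up to the 512 used by current
GNN parameterizers); basis ranks of 2–5 are used throughout since the
generator plants its signal in a rank-5 subspace.

## Known limitations

* Only the charge model is corrected; steric (Lennard-Jones) and
  intramolecular terms are out of scope, as is any re-simulation
  machinery (the package consumes stored potentials).
* The ESS is a proxy, not an error bar: high ESS can mask missing
  coverage of configuration space, and the i.i.d.-frame assumption
  makes the ESS optimistic for correlated trajectories.
* One-sided exponential averaging is biased at finite sample size;
  the calibration module quantifies exactly this, but the estimator
  itself is not replaced by bridge-type estimators.
* The fitted perturbation is linear in the projected embeddings;
  strongly nonlinear corrections would require refitting the upstream
  model, which this package deliberately avoids.
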