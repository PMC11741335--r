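# chargetune

One-shot fine-tuning of molecular-mechanics charge models against
experimental free energies, **without re-running molecular dynamics**.

## The problem

Pretrained graph-neural-network force-field parameterizers emit, per
atom, a continuous embedding vector $h_i \in \mathbb{R}^m$ plus
electrostatic parameters — electronegativity $e_i$ and hardness $s_i$ —
from which partial charges follow by charge equilibration (QEq). Trained
mostly on gas-phase quantum chemistry, such models misfit condensed-phase
observables like hydration free energies, largely through missing
polarization in the charges. Re-simulating every molecule after each
parameter update is the bottleneck that usually makes empirical refitting
impractical.

chargetune is for computational chemists who already have (i) baseline
alchemical free-energy calculations, (ii) per-frame *per-atom environment
electrostatic potentials* $\phi_{ti}$ saved from those simulations, and
(iii) experimental values for a subset of molecules. It fits a low-rank
correction to the charge model using only that stored data.

## The method

1. **Project**: pool all atom embeddings, extract a rank-$r$ PCA basis
   $Q_{m\times r}$, and project each embedding,
   $\hat h_i = Q^\top(h_i - \mu_h)$.
2. **Perturb**: with a $2\times r$ parameter matrix
   $\Theta = (\theta_e; \theta_s)$, shift
   $e_i^* = e_i + \theta_e^\top \hat h_i$,
   $s_i^* = s_i + \theta_s^\top \hat h_i$.
3. **Re-equilibrate**: regenerate charges
   $q_i^* = -e_i^*/s_i^* + s_i^{*-1}\,(Q + \sum_j e_j^*/s_j^*)/\sum_j s_j^{*-1}$,
   conserving the total molecular charge exactly.
4. **Reweight**: because the molecule–environment electrostatic energy is
   linear in the charges, the perturbed free energy per molecule is the
   Zwanzig exponential average over stored frames,
   $\Delta G_{\text{pert}}(\Theta) = -\beta^{-1}\ln\langle
   e^{-\beta\sum_i(q_i^*-q_i)\phi_{ti}}\rangle_t$.
5. **Optimize**: minimize a pseudo-Huber loss of the residuals
   $\Delta G^{\text{expt}} - (\Delta G^{\text{calc}} +
   \Delta G_{\text{pert}})$ over training molecules, **regularized by the
   effective sample size** $\mathrm{ESS} = (\sum w)^2/\sum w^2$ of every
   molecule's importance weights — a flat-to-quadratic penalty below 750
   samples plus early stopping below 500 — so the optimizer never leaves
   the region where reweighting is trustworthy. BFGS with an analytic
   gradient does the minimization.

A synthetic-data module generates datasets with the same statistical
structure (clustered embeddings, Gaussian linear-response potential
ensembles) for which the perturbed free energy has a closed form, so the
whole pipeline is testable end to end with exact oracles.

## Worked example

```r
library(chargetune)

# synthetic study: 200 molecules, 2000 stored frames each, hidden
# rank-5 perturbation, 0.2 kcal/mol experimental noise
ds    <- generate_dataset(generator_config(seed = 101)) |>
           assign_splits(train_fraction = 0.75, seed = 101)
basis <- fit_basis(ds, r = 5)
fit   <- finetune(ds, basis, loss_config(),
                  finetune_control(max_iter = 150))
glance(fit)
#> # A tibble: 1 × 8
#>    rank iterations  loss data_loss    reg_loss min_ess theta_norm stop_reason
#>   <int>      <int> <dbl>     <dbl>       <dbl>   <dbl>      <dbl> <chr>
#> 1     5        150 0.170     0.170 0.000000867    750.       1.18 max_iter

evaluate_run(ds, basis, fit$theta, seed = 1)$stats |>
  dplyr::filter(split == "test")
#> # A tibble: 2 × 9
#>   split phase  rmse   mue rmse_lo rmse_hi mue_lo mue_hi     n
#>   <chr> <chr> <dbl> <dbl>   <dbl>   <dbl>  <dbl>  <dbl> <int>
#> 1 test  pre   1.04  0.794   0.809   1.29   0.608  1.04     38
#> 2 test  post  0.366 0.298   0.302   0.433  0.237  0.370    38
```

Reading: the fit stops while every molecule still has at least ~750 of
its 2000 frames effectively alive (`min_ess`), and on molecules it never
trained on, the free-energy RMSE drops from 1.04 to 0.37 kcal/mol —
close to the 0.2 kcal/mol noise floor built into the synthetic
experiment. `autoplot(fit)` shows the loss/ESS trace;
`consistency_check(ds, basis, fit$theta)` compares every reweighted
prediction against the generator's closed-form answer.

A command-line wrapper around the same functions lives at
`inst/scripts/chargetune-cli.R` (subcommands `generate`, `finetune`,
`reweight`, `calibrate`, `evaluate`, `pipeline`), and `run_pipeline()`
drives the whole workflow from a YAML config.

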