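---
title: "Modelling the photosynthetic rate of young canopy leaves with PSO-initialised backpropagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the photosynthetic rate of young canopy leaves with PSO-initialised backpropagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psobp)
```

## The problem

The youngest leaves at the top of a greenhouse crop canopy (cucumber here)
have an immature photosynthetic apparatus: their net photosynthetic rate
(Pn, umol CO2 m-2 s-1) is low, and under strong light they are prone to
photoinhibition because their capacity to dissipate excess energy as heat is
limited. Supplemental-lighting control therefore needs a model that predicts
Pn for these young leaves from the environmental drivers — air temperature
(Tem, degC), CO2 mole fraction (CO2, umol mol-1) and light intensity
(PAR, umol m-2 s-1) — and, ideally, a cross-check against chlorophyll
fluorescence parameters, which report the internal state of photosystem II
(PSII) directly.

`psobp` implements that modelling chain end to end:

1. a **synthetic factorial experiment generator** that emulates a
   multi-environment gas-exchange + fluorescence protocol, so that every
   downstream stage is testable without access to instrument data;
2. **Pearson correlation screening** of candidate drivers against Pn, with
   bilateral significance at the 0.01 level;
3. a **from-scratch single-hidden-layer backpropagation (BP) network**
   with a particle-swarm-optimised (PSO) choice of initial weights and a
   damped least-squares (Levenberg–Marquardt, LM) fine-tuner;
4. an **evaluation battery**: plain BP vs PSO-BP under matched evaluation
   budgets, and auxiliary models predicting the electron transport rate
   (ETR) and non-photochemical quenching (NPQ) from the same inputs.

## The synthetic experiment

The default design is a full factorial grid: 6 temperatures
(18–36 degC) x 4 CO2 levels (300–1200 umol mol-1) x 13 light intensities
(20–1500 umol m-2 s-1), relative humidity fixed at 50%, with 3 replicate
plants per combination — 312 environmental combinations, 936 records.

### The Pn surface

No mechanistic biochemistry model is attempted (see *Non-goals* below).
The ground truth is the minimal smooth surface that reproduces the three
light-response regimes observed on young leaves — a fast rise at
0–300 umol m-2 s-1, saturation with incipient photoinhibition at
300–1000, and flattening/decline at 1000–1500:

$$Pn(I, T, C) = \frac{\alpha I (1-\beta I)}{1+\gamma I}\;
e^{-\left(\frac{T-T_{opt}}{\sigma_T}\right)^2}\;
\frac{C}{C+K_C} - R_d$$

a modified rectangular hyperbola in light $I$ with a linear $(1-\beta I)$
photoinhibition factor, times separable Gaussian temperature and
Michaelis–Menten CO2 modifiers, minus dark respiration $R_d$.

Defaults (all tunable through `pn_surface_params()`):

| parameter | default | units | role |
|---|---|---|---|
| `alpha`   | 0.10    | umol CO2 / umol photons | initial light-response slope |
| `beta`    | 2.54e-4 | per umol m-2 s-1 | photoinhibition strength |
| `gamma`   | 2e-3    | per umol m-2 s-1 | light saturation curvature |
| `t_opt`   | 30      | degC | temperature optimum |
| `t_sigma` | 15      | degC | temperature breadth |
| `k_c`     | 200     | umol mol-1 | CO2 half-saturation |
| `r_d`     | 0.8     | umol m-2 s-1 | dark respiration |

`beta` and `gamma` were calibrated once, by a grid search over the light
axis, so that the light-saturation point (the PAR maximising Pn at 18 degC
and 600 umol mol-1) sits at 989 umol m-2 s-1 — the ~990 value typical of
young cucumber leaves. The closed form of the maximiser of
$I(1-\beta I)/(1+\gamma I)$ is
$I^* = (\sqrt{1+\gamma/\beta}-1)/\gamma$, so the two parameters pin $I^*$
independently of temperature and CO2 (which enter multiplicatively).
`t_opt`, `t_sigma` and `k_c` were chosen in the same calibration pass so
that, across the factorial grid, light is the dominant environmental
correlate of Pn, with temperature and CO2 clearly positive but weaker —
the rank structure seen in field screens of this kind. The calibration was
frozen before any model-fitting experiments.

### The fluorescence surfaces

All six PSII parameters are driven by light with a mild (±10%)
temperature/CO2 modulation $m(T, C)$:

* `phips2` (actual PSII quantum yield): $\Phi_0\, e^{-I/I_\Phi}\, m(T,C)$ —
  declines from ~0.75 as light increases;
* `etr`: the conventional construction
  $ETR = \Phi_{PSII} \times I \times a \times f_{PSII}$ with leaf
  absorptance $a = 0.84$ and PSII fraction $f = 0.5$, so
  $ETR = 0.42\,\Phi_{PSII} I$ exactly — rising steeply, then flattening near
  the top of the light range;
* `fvpfmp` (Fv'/Fm'): a compressed power of `phips2`
  ($F_0 (\Phi/\Phi_0)^q$, $q = 0.6$), guaranteeing
  $\Phi_{PSII} \le F_v'/F_m' \le 1$;
* `qp`: the ratio `phips2 / fvpfmp`, clipped to (0, 1];
* `npq`: a Hill function of light (half-saturation 350, exponent 1.4,
  maximum 2.5) multiplied by a photodamage factor that declines linearly
  beyond 1000 umol m-2 s-1 — so NPQ rises, slows, and turns downward under
  damaging light;
* `qn`: a *deliberately weakly coupled* channel,
  $q_N = 0.55 + 0.01\,(1-e^{-NPQ}) + \varepsilon$. Field screens of this
  design repeatedly find qN essentially uncorrelated with Pn even though
  NPQ correlates strongly; the generator reproduces that by compressing the
  systematic component far below the additive jitter
  ($\varepsilon$, sd 0.05 at the default noise level). With the default
  design this yields $|r(Pn, q_N)| \approx 0\text{–}0.09$, non-significant
  at the 0.01 level in the large majority of seeds, while every other
  factor is strongly significant.

### Replicate noise

Each observed quantity is the surface value times $(1+\epsilon)$ with
$\epsilon \sim N(0, cv)$, $cv = 3\%$ by default. The observation noise of
this class of gas-exchange measurements is not publicly characterised; 3%
is a stand-in chosen once as a realistic instrument-plus-biology
coefficient of variation, and it produces correlation strengths of the
magnitude reported for real screens. The additive qN jitter scales with
`noise_cv / 0.03`, so a zero-noise configuration produces exactly
identical replicates. After noise, values are clipped to their physical
ranges (`0 <= qp <= 1`, `phips2 <= fvpfmp <= 1`, `etr, npq >= 0`).

At PAR = 0 (supported, though the default grid starts at 20) the
fluorescence parameters are undefined: records carry `NA` values and
`valid_fluor = FALSE`, and are excluded from fluorescence correlations and
fluorescence-target models.

### What the generator does *not* emulate

No FvCB biochemistry, no stomatal or humidity response (RH is constant),
no diurnal course or "midday break", no leaf-position gradient, no
instrument drift, and no correlated replicate effects (plants are
exchangeable). Tests passing on these data show that the pipeline recovers
structure *of this kind*; they do not certify accuracy on any particular
instrument's data.

## Preprocessing

Features are mapped to $[-1, 1]$ by $y = 2(x - x_{min})/(x_{max} -
x_{min}) - 1$, with the min/max always taken **from the training split
only**; validation values outside the training range deliberately map
outside $[-1, 1]$ (no clipping), and a dedicated test asserts this
leakage guard. Constant features (RH in the default design) are rejected
by a degenerate-feature error, which is also why RH can never be selected
as a model input here.

The Pearson coefficient is computed in its population (divide-by-n) form,
$r = S_{xy}/(S_x S_y)$ — algebraically identical to the sample form, since
the $1/n$ factors cancel. Significance uses the standard two-sided t test,
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom; the reported
flag is "significant at the 0.01 level (bilateral)". The implementation is
cross-checked against `stats::cor` / `stats::cor.test` to 1e-12.

The 80/20 train/validation split is a seeded uniform permutation with
`round(0.8 n)` training rows (936 → 749/187). Whether such splits should
be stratified by environmental combination is a design choice; uniform
random is the default because the factorial grid is balanced, so uniform
sampling already covers the design space well.

## The network and its trainers

A single hidden layer of $L = (m+n)/2 + c$ nodes (floor for odd $m+n$;
$c = 3$, so a 3-input, 1-output network gets 5 hidden nodes — 26
parameters). The hidden activation defaults to `tansig` (tanh), the
natural companion of $[-1,1]$-normalized data; the logistic `logsig`
$1/(1+e^{-x})$ is selectable, as both conventions circulate under the
"S-type" label. The output is linear and unbounded. The error function is
the half sum of squares $E = \tfrac12\sum_j (\hat y_j - y_j)^2$, and the
analytic back-propagated gradient is verified against central finite
differences ($h = 10^{-6}$) on 100 random architectures.

Two trainers:

* **`gd`** — the literal full-batch steepest descent
  $w \leftarrow w - \eta\, \nabla E$, step factor $\eta = 0.05$ by default;
* **`lm`** (default) — damped least squares on the residual vector: solve
  $(J^\top J + \lambda I)\,\delta = -J^\top r$ with the exact closed-form
  Jacobian; $\lambda$ is multiplied by 10 on a rejected step and divided
  by 10 on an accepted one, starting from $10^{-3}$. The MSE trace is
  non-increasing by construction, and training terminates early if no
  improvement is possible at $\lambda = 10^{12}$ (stall).

Training stops when the normalized training MSE reaches `goal`
(default 1e-3) or the epoch budget (default 500) is exhausted. Full-batch
updates are used throughout for determinism.

## The swarm

The PSO state is a population (default 110) of flattened weight vectors.
Velocities update per particle and per dimension with fresh uniform draws,

$$V \leftarrow \omega V + c_1 r_1 (P - X) + c_2 r_2 (P_g - X), \qquad
X \leftarrow X + V,$$

with the standard constriction-equivalent coefficients
$\omega = 0.729$, $c_1 = c_2 = 1.49445$ as defaults (the inertia and
acceleration constants are otherwise unconstrained choices). Velocities
are clamped to ±0.5 per dimension; positions are unclamped; initial
positions are uniform on $[-0.5, 0.5]$, the scale of useful initial
network weights. Fitness is the per-sample, per-output-neuron mean squared
error on the **training split only** — never the validation split — and is
exactly $2E/(p\,n_{out})$ for the half-sum-of-squares $E$. The run stops
after 100 iterations or 20 consecutive iterations with global-best
improvement below 1e-8. Per-dimension random draws (rather than one scalar
per particle) are the standard reading of the update rule and are what is
implemented.

The swarm's bookkeeping guarantees a monotone non-increasing global-best
history; on the 5-dimensional sphere function the default configuration
reaches fitness < 1e-3 well within 200 iterations, and on sphere and
Rosenbrock benchmarks it beats pure random search at equal evaluation
budgets in at least 8 of 10 seeds.

## The pipeline and the comparisons

`run_psobp()` chains: split → fit normalization on the training rows →
PSO over the 26-dimensional weight vector (for `method = "psobp"`) → LM
fine-tune → denormalized predictions → metrics. Reported metrics are MSE,
RMSE, MAE, mean relative error (entries with $|y| < 10^{-9}$ excluded and
counted) and $R^2 = 1 - SS_{res}/SS_{tot}$, in **raw units**, plus the
normalized-scale MSE/RMSE under separate labels — raw-unit and
normalized-unit RMSE differ by the half-range factor (~10 for Pn), which
is worth keeping explicit because headline RMSE values in this literature
are reported on both scales without always saying which.

`compare_methods()` runs plain BP (seeded random initial weights) against
PSO-BP per seed with **matched total evaluation budgets**: each PSO fitness
evaluation is one full-batch forward pass, so the plain-BP arm's epoch
budget is inflated by `iterations x population` equivalent epochs. Both
arms train to their error floor, and *epochs-to-goal* is read off the
training trace at a reference error level of 3e-3 normalized MSE — the
order of the expected-error level at which hybrid-vs-plain convergence is
conventionally compared. (Measuring epochs-to-goal at the trainer's own
1e-3 default would be vacuous at the 3% noise level, where the reachable
floor is ≈1.7e-3.) With the default data, the median PSO-BP run crosses
the reference level in about half the epochs of the median plain-BP run,
and ends at a slightly lower training MSE; the validation accuracies of
the two arms are nearly identical, because the LM fine-tuner is powerful
enough to rescue most random initializations — the swarm's benefit here is
convergence speed and reliability, not final accuracy.

`fit_fluorescence_models()` fits three PSO-BP models with identical inputs
(Tem, CO2, Par): Model1 → Pn, Model2 → ETR, Model3 → NPQ. On the default
synthetic data the ETR and NPQ models consistently validate at or above
the Pn model's $R^2$ — the fluorescence surfaces are smoother functions of
the drivers than the peaked Pn surface, mirroring the observation that
fluorescence parameters are the easier prediction targets.

## Numerical choices and degenerate inputs

* Ties in factor selection break stably by input order.
* `pearson_cor` clamps $|r|$ to 1 against rounding and reports $p = 0$ at
  exact ±1; constant series raise a degenerate-correlation error, except in
  `correlation_screen()`, where constant factors (RH) are carried through
  with `NA` and a note.
* `nn_train` raises a divergence error naming the epoch if the loss goes
  non-finite; the swarm does the same for non-finite fitness.
* `hidden_node_count` floors $(m+n)/2$ for odd sums and rejects
  $c \notin [1, 10]$.
* Datasets round-trip through an annotated CSV (a `#`-prefixed metadata
  block carrying seed, schema version and the full generator config as
  JSON) at full double precision.

## Problem sizes used by the test battery

The acceptance-style property tests run at the default study conditions:
the 936-record design, 5 generator or run seeds per majority vote, PSO
population 110 with a 100-iteration budget, LM budget 500 epochs (plain-BP
arms receive the matched inflated budget). The complete battery executes
in about two minutes; unit tests use a reduced 72-record design and a
30-particle swarm.

## Known limitations

* **The 5-node architecture has an approximation floor on the default
  surface.** Multi-start LM from 120 random initializations and an
  independent optimizer both bottom out at a normalized training MSE of
  ≈4.7e-4 on noise-free data — validation $R^2 \approx 0.998$, not 1. The
  peaked, multiplicatively-structured Pn surface is genuinely hard for five
  tanh units; a sixth node would lift the ceiling, but the 5-node layout is
  kept because it is the reference architecture for this problem. Typical
  single-run pipeline results on noise-free data are $R^2$ 0.993–0.997.
* The BP-vs-PSO-BP final-accuracy gap is small by construction (LM erases
  most of the initialization advantage); the robust, repeatable difference
  is in epochs-to-goal.
* The generator's correlation structure is a calibrated emulation, not a
  fitted model of any published dataset; magnitudes (as opposed to signs
  and ranks) of the correlations should not be over-interpreted.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  results are exactly reproducible per seed bundle; nothing touches the
  global RNG state.
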