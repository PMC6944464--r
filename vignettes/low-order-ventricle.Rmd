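---
title: "Low-order left-ventricular mechanics by congruency training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-order left-ventricular mechanics by congruency training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvreduce)
```

## The model

`lvreduce` simulates left-ventricular (LV) contraction with a deliberately
small model: one biophysical myofilament unit, two linear transformations
that couple it to organ-level pressure and volume, and lumped hemodynamic
boundary conditions. The premise is the well-established similarity between
the contraction of an isolated muscle strip and of the whole chamber: over a
wide range of loading conditions, cavity volume is nearly an affine function
of myofiber stretch, so a single representative cell unit, suitably scaled,
can reproduce global pressure–volume behavior.

The pieces are:

**Passive law.** About the unloaded volume $V_0$, with $x = V/V_0 - 1$,

$$
P_\mathrm{pass}(V) =
\begin{cases}
\alpha\,[1 - e^{-\beta\gamma x}] & V \le V_0 \\
a x^3 + b x^2 + c x & V > V_0,
\end{cases}
$$

continuous (value 0) at $V_0$. The cubic branch describes passive filling;
the exponential branch the stiffer response under compression, which the
ventricle only reaches at peak systole. $\gamma$ exists so that the
compression shape can be adjusted from *active* beats after
$\{\alpha,\beta\}$ have been fixed from a quasi-static inflation that never
compresses the cavity.

**Cell unit.** A calcium transient drives a myofilament ODE whose states
determine active tension. The default unit (used throughout; any model with
the same state/tension interface can replace it) is

- a biexponential calcium transient with rise/decay times
  $\tau_1 = 30$ ms, $\tau_2 = 150$ ms, normalized so the peak is
  $Ca_d + Ca_{amp}$;
- an activation gate $dA/dt = k_{on} H(Ca)(1-A) - k_{off}A$ with Hill
  activation $H(Ca) = Ca^{n_A}/(Ca^{n_A} + Ca_{50}^{n_A})$
  ($n_A = 5$, $Ca_{50} = 0.5\ \mu M$);
- crossbridge recruitment $dF/dt = f_{XB} A (1-F) - g_{XB} F$
  ($f_{XB} = 25$/s, $g_{XB} = 15$/s);
- tension $T_a = S_a F \cdot L(\lambda)$ with the linear length factor
  $L(\lambda) = \max(0, (\lambda - n_0)/(1 - n_0))$, $n_0 = 0.6$ the minimum
  stretch for force generation.

The maximum shortening velocity is represented implicitly: scaling $f_{XB}$
and $g_{XB}$ together (`scale_vmax()`) speeds or slows contraction while
leaving isometric steady tension unchanged, since the steady bound fraction
depends only on their ratio. The tension scale $S_a = 95$ kPa was sized once
so that an isometric twitch at $\lambda = 1.1$ peaks near 60 kPa, a
physiological myocardial tension; all cell parameters are plain arguments of
`cell_params()` and are recorded in run metadata.

**Trained transforms.** Stretch and pressure couple to the organ through

$$\lambda = \mu_1 (V/V_0 - 1) + 1, \qquad P = \mu_2 T_a + P_\mathrm{pass}(V).$$

$\mu_1$, $\mu_2$, and the eight passive/active coefficients are the
"trained" parameters: they carry the anatomy- and tissue-specific
information that a 3-D model would encode in its geometry and constitutive
law.

**Circulation.** A constant-pressure (or discharging-capacitor) atrium fills
the ventricle through a mitral resistance; ejection passes an aortic valve
resistance $R_1$ into a 3-element Windkessel ($R_2$, $C$, $R_3$). Valves are
ideal diodes realized by flow clamping, $Q = \max(0, \Delta P / R)$, which
makes regurgitation impossible by construction and keeps the right-hand side
continuous. Valve state flags (and beat phases) are derived afterwards from
the flow signs with a small deadband.

## Numerics

The coupled states (cell gates, cavity volume, Windkessel and atrial
pressures) are integrated with fixed-step RK4 at $dt = 0.1$ ms; pressure is
eliminated algebraically at every stage, so no DAE machinery is needed. A
fixed step was chosen over an adaptive stiff solver because the clamped
diodes only introduce mild kinks (the fastest coupled time constant,
$R_1 \cdot dV/dP$, is tens of ms), the traces must be bitwise deterministic
for the training optimizer, and the refinement test (halving $dt$ moves
ejection fraction by far less than 0.1 percentage points) confirms the step
is converged. Beats are paced at a fixed 1000 ms cycle (60 bpm), calcium
onset at the cycle start, up to 20 beats; the run stops early when both the
end-diastolic volume and the Windkessel pressure are cycle-to-cycle stable
to a relative $10^{-3}$. (The Windkessel pressure is included in the
stopping rule because its relaxation time $R_3 C \approx 1.6$ s outlives the
end-diastolic volume, which is pinned by the atrium within a beat or two.)
The returned trace is the final beat sampled at 1 ms, with phases
(filling, isovolumic contraction, ejection, isovolumic relaxation) attached.

Initial conditions are rest: $V = V_0$, cell gates at zero, Windkessel and
atrial pressures at the atrial set point. In capacitor-atrium mode the
atrium is recharged to its set point at each cycle start — a minimal,
explicitly arbitrary choice of refilling, which is why diastolic filling
metrics are excluded from all objectives.

## Multi-element configurations

To study how well a single trained unit summarizes heterogeneous tissue, the
package builds multi-element references with 256 subunits on a midpoint
$\xi \in [0,1]$ grid:

- **parallel** — subunits share the cavity volume but carry their own
  $\mu_1(\xi)$, linear over $[0.01, 0.179]$: heterogeneous stretch, one
  summed pressure, $P = P_\mathrm{pass} + \mu_2 \int_0^1 T_a(\xi) d\xi$
  (midpoint quadrature; 128 vs 256 subunits moves EF by under 0.05 points);
- **series** — subunits share the pressure and contribute volume
  subportions averaging to $V$, with $\{\alpha, a, b, c, \mu_2\}$ scaled by
  a weight $w(\xi)$ linear over $[0.6, 1.0]$. $\beta$ is deliberately not
  weighted (a `weight_beta` switch exists). The algebraic constraint — a
  common $P$ with $P_{\mathrm{pass},i}(V_i) + \mu_{2,i} T_{a,i} = P$ and
  $\mathrm{mean}_i V_i = V$ — is solved at every integrator stage by a
  warm-started joint Newton iteration to residuals below $10^{-11}$ kPa and
  $10^{-12}$ ml.

These multi-element models double as the package's *pseudo-high-fidelity
reference generator* (`make_reference_bundle()`): they stand in for 3-D
finite-element simulations as training targets. They reproduce the features
that matter for congruency training — smooth periodic PV loops under the
training conditions, subunit heterogeneity, a near-linear volume–stretch
relation (the generator reports its $R^2$, typically $\ge 0.99$) — but they
are *not* finite elements: they have no spatial wall mechanics, no fiber
architecture, no activation sequence. Passing tests against them shows the
training machinery is correct, not that a particular 3-D model is well
approximated.

A noteworthy property of the default cell unit: because its length factor
$L(\lambda)$ is linear above $n_0$ and its state kinetics are
length-independent, the parallel configuration is *exactly* reducible to a
single element with $\mu_1 = \overline{\mu_1(\xi)}$ whenever all subunits
stay above $n_0$. The trained single element therefore tracks the parallel
reference to numerical precision, and the residual study errors come almost
entirely from the series configuration, where the weighted passive laws make
the reduction genuinely approximate. A cell unit with length-dependent
kinetics would break the exactness — which is precisely why the study keeps
the parallel case as a sanity bound and the series case as the stress test.

## Congruency training

Training is two-stage:

1. **Passive fit** (`fit_passive()`): bounded Levenberg–Marquardt least
   squares of $\sum_p [(V_\mathrm{ref}(p) - V_\mathrm{LO}(p))/V_\mathrm{ref}(p)]^2$
   over $\{\alpha, \beta, a, b, c\}$ with $\gamma = 1$, where
   $V_\mathrm{LO}(p)$ inverts the passive law (closed form under
   compression, safeguarded root finding on the cubic). The default
   inflation protocol spans $-0.5$ to $4$ kPa: the small negative-pressure
   extension is a package decision — a purely tensile inflation leaves
   $\{\alpha,\beta\}$ unconstrained, in which case they are returned at
   their initial values with an explicit warning flag. Because $\gamma$ is
   pinned at 1 here, the fitted $\hat\beta$ absorbs the product
   $\beta\gamma$ of whatever generated the data; the active stage then
   refits $\gamma$, so only the product is ever identified — consistent
   with the law, where they never appear separately.
2. **Active fit** (`fit_active()`): minimizes the congruency error
   $$C^2 = \frac{1}{n}\sum_{i=1}^{n}\left[
   \frac{\int (V_\mathrm{ref}-V_\mathrm{LO})^2 dt}{\int V_\mathrm{ref}^2 dt} +
   \frac{\int (P_\mathrm{ref}-P_\mathrm{LO})^2 dt}{\int P_\mathrm{ref}^2 dt}
   \right]_i$$
   over $\{\mu_1, \mu_2, \gamma\}$ (bounds $[0.01,1]$, $[0.01,1]$,
   $[0.5,20]$), with the $1/n$ averaging applied to the sum of both the
   volume and pressure terms of the $n$ training protocols — the symmetric
   reading of an ambiguous convention; the per-protocol decomposition is
   returned so either convention can be reconstructed. Traces are compared
   on their shared 1 ms clock (both models are paced identically), and
   `congruency_error()` refuses mismatched grids rather than silently
   resampling.

The optimizer is a practical OrthoMADS-style direct search
(`mads_minimize()`): a seeded Latin-hypercube search step (15% of the
budget) to locate the basin, then orthogonal polling with Householder
directions, dynamic ordering toward the last successful direction, and mesh
halving on failed polls. The incumbent is monotone and the whole evaluation
sequence reproducible under the seed. Because the trained coefficients live
in a narrow curved valley ($\mu_1$ and $\gamma$ partially compensate),
`fit_active()` follows the direct search with a deterministic Nelder–Mead
refinement of the incumbent; on self-generated references this recovers
$\mu_1, \mu_2$ to well under 1% and drives $C$ below $10^{-6}$. A kriging
surrogate search step was considered and omitted: at ~25 ms per objective
evaluation the surrogate bookkeeping would dominate, and the contract only
requires a derivative-free, seed-deterministic search.

## Geometry emulation

For cohorts of anatomies the per-case training cost is amortized by a
regression from geometry to the 8 trained coefficients. Anatomies are
6-parameter truncated prolate spheroids (outer basal radius $R_b$, basal
thickness $L$, long axis $Z$, apical thickness $H$, conicity
$e \in [0.5, 1]$, truncation angle $\Psi_0 < 0$), sampled by Latin
hypercube over ranges bracketing the two reference geometries by ±30% (the
exact cohort ranges are not published; these are the package's defaults).
The cavity volume uses a documented superellipse solid of revolution —
exponent $2e$, ellipsoidal at $e = 1$, conical at $e = 0.5$ — verified
against the closed-form spheroid in the $e = 1$ limit; it approximates the
imaging parameterization and $V_0$ can always be overridden.

Cases that do not compress to 85% of $V_0$ under the low-afterload training
circulation are excluded (boundary inclusive), because only compressing
beats identify $\gamma$; the sampled/admissible/excluded counts are always
reported. Each coefficient gets an independent Gaussian process
(anisotropic squared-exponential kernel, fitted nugget, standardized
features, marginal-likelihood hyperparameters with seeded restarts —
implemented in-package because no installed library offers
automatic-relevance-determination GP regression with likelihood-fitted
noise), scored by seeded 5-fold cross-validation. `train_cohort()` runs the
whole loop at desk scale (default $n = 30$, with a documented polynomial
geometry-to-coefficient map standing in for per-case 3-D references).

## Inverse estimation from clinical indices

`fit_clinical()` adapts $\{\tau_2, S_a, R_2, R_3, C, C_{at}\}$ — calcium
decay, contraction efficiency, and the Windkessel/atrial lumped parameters,
with the aortic valve resistance held at its training value — to match four
image-derivable indices: ejection fraction, ejection time, isovolumic
relaxation time, and aortic pulse pressure. The objective is the mean of
squared relative target errors plus a hinge penalty (weight 10) on the
beat's aortic pressure extremes outside 85–110 mmHg; the equal weights and
penalty form are package choices, exposed as arguments. The atrium runs in
capacitor mode here (constant-pressure during congruency training),
mirroring the two roles the boundary plays. Diastolic filling metrics are
excluded by construction — the cyclic atrial reset makes filling dynamics
the least trustworthy part of the model. Bounds ($\tau_2 \in [75, 400]$ ms,
$S_a$ 0.2–2× baseline, $R_2 \in [0, 0.05]$, $R_3 \in [0.02, 0.4]$
kPa·ml⁻¹·s, $C \in [2, 20]$, $C_{at} \in [5, 100]$ ml/kPa) bracket the
training hemodynamics and physiological ranges. On synthetic targets
generated by an in-band parameter set, the optimizer reaches average
relative mismatches far below 1%; the four indices do not uniquely pin all
six parameters (notably $C_{at}$ is weakly informed), so recovered
*parameters* should be read as one consistent explanation, not a unique
one.

## A worked run

```{r example, eval = FALSE}
lp <- lo_params_normal()        # trained coefficients, normal geometry
cell <- cell_params()
trace <- simulate_beats(lp, cell, circ_preset("A1"))
beat_metrics(trace)
autoplot(trace)

# single- vs multi-element error study (series, calcium-decay sweep)
study <- multi_element_error_study("series", "tau2", seed = 1)
tidy(study)
glance(study)
```

The study sizes used throughout (256 subunits, 10-point sweeps, training
budget 400 + 200 refinement evaluations, up to 20 beats per run) are the
configurations the package's own acceptance checks run at; a single-element
beat costs a few milliseconds, a 256-subunit series beat well under a
second.

## Known limitations

- The default cell unit is a minimal two-state model: no force–velocity
  relation beyond the implicit rate scaling, no length-dependent kinetics,
  no electrophysiology. Its linear length factor makes the parallel
  reduction exact (see above), which flatters the parallel study numbers.
- Diastolic filling is not credible: the atrium is a set-point device with
  cyclic recharge, so only systolic and isovolumic metrics are fit or
  reported with confidence.
- The synthetic reference generator shares its numerical core with the
  model being trained; it validates the training machinery, not the fidelity
  of any 3-D model reduction.
- Trained coefficients are phenomenological. They carry indirect anatomical
  meaning (the emulator's trends are physically sensible) but no direct
  constitutive interpretation.
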