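---
title: "A reduced-order model of ctenophore metachronal swimming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of ctenophore metachronal swimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctenoswim)
```

## The model

Ctenophores (comb jellies) swim with eight rows of millimetre-scale paddles
(ctenes) beating in antiplectic metachronal waves at Reynolds numbers of
order 1–1000, where viscous and inertial forces both matter. `ctenoswim`
models the animal as a neutrally buoyant rigid prolate spheroid propelled by
oscillating flat plates and integrates the coupled rigid-body equations

$$\vec F_{net} + \vec F_D + \vec F_{AR} = m \ddot{\vec X}, \qquad
  \vec T'_{net} + \vec T'_{op} = [I]\dot{\vec\omega}' +
  \vec\omega' \times [I]\vec\omega',$$

with quasi-steady blade-element hydrodynamics:

* **Propulsion.** Each ctene is a flat plate of width $w = l/2$ and
  time-varying length $y_A(t)$ whose tip follows a closed elliptical path.
  The force on the body is the negative of the plate's quasi-steady drag,
  $-\tfrac{\rho w}{2}\, y_A C_A \lvert\dot{\vec X} + \vec u\rvert^2 \hat u$,
  where $\vec u$ is the plate velocity (tangent to the body surface, set by
  the meridian tangent angle $\lambda$ and the row azimuth $\varepsilon$)
  and $C_A$ is evaluated at the instantaneous plate Reynolds number.
* **Body drag.** Component-wise quadratic drag in the body frame with
  flow-normal areas $\pi a^2$ (axial) and $\pi a b$ (lateral) and
  speed-dependent coefficients $C_{B\parallel}, C_{B\perp}$.
* **Added mass.** $-\rho V\,\mathrm{diag}(C_{m\parallel}, C_{m\perp},
  C_{m\perp})$ acting on the body-frame acceleration; it is moved to the
  left-hand side as an effective mass matrix, which keeps the system
  explicit.
* **Rotational resistance.** Per-axis quadratic opposing torque
  $-\tfrac{\rho}{2}(d_e/2)^5\,\mathrm{sgn}(\omega_i) C_{R} \omega_i^2$.

## Paddle kinematics

The tip path is the ellipse centred at $(0,\, l(1 - Sa/2))$ with horizontal
semi-axis $l\sin(\Phi/2)$ and vertical semi-axis $l\,Sa/2$: the plate reaches
full extension $l$ at mid power stroke, the sweep amplitude matches $\Phi$,
and the enclosed area equals $Sa$ times the practical maximum (the largest
ellipse of the same width inscribed in the half-circle of radius $l$). The
upper arc (power stroke) is traversed at a constant parameter rate in time
$t_p = (1-Ta)/2f$ and the lower arc in $t_r = (1+Ta)/2f$, realising the
temporal asymmetry definition $Ta = (t_r - t_p)/(t_r + t_p)$ with the
simplest pacing. Ctene $k$ of a row (1 = most aboral) is delayed by
$(k-1)\,P_L/f$, so the wave of beating travels aborally→orally while the
power stroke sweeps orally→aborally (antiplectic). Reversing the power
stroke time-mirrors the traversal, which reverses both the thrust and the
wave — the mechanism of backward swimming.

This parametrization is a reconstruction from the printed constraints
(full extension, amplitude, exact area ratio, $t_p/t_r$ split); the original
implementation's exact tip path is not published in the main text. The
consequences are discussed under *Limitations*.

### Defaults

| parameter | default | units | meaning |
|---|---|---|---|
| $L_B,\ d_B$ | 7.8, 6.1 | mm | body length / diameter (population means) |
| $l$, $s$ | 0.5, 0.8 | mm, — | ctene length, spacing/length ratio |
| $n_S,\ n_T$ | 10, 7 | — | ctenes per sagittal / tentacular row |
| $\varepsilon_S,\ \varepsilon_T$ | 63.9, 23 | deg | row azimuths from the tentacular plane |
| $\kappa$ | 27 | deg | polar angle of the most aboral ctene |
| $\Phi$ | 112 | deg | stroke amplitude |
| $P_L$ | 13.2 | % of period | inter-ctene phase lag |
| $Ta,\ Sa$ | 0.3, 0.3 | — | temporal / spatial asymmetry |
| $\rho,\ \nu$ | 1025, 1.05e-6 | kg/m³, m²/s | seawater |

The tentacular row count is rounded to the integer 7 (the measured sample
mean is 7.1) and the spacing column $s$ is interpreted as the normalized
inter-ctene spacing $\delta/l$, giving $\delta = 0.4$ mm. Mass is the
displaced fluid mass (neutral buoyancy) and the inertia tensor is that of a
homogeneous solid spheroid; rotational added inertia is outside the model's
scope.

## Coefficient correlations

The exact intermediate-Reynolds correlations used by the original
implementation are not published in the main text, so the package ships a
parametric strategy set chosen once, before any comparison with published
outputs, and kept fixed:

* plate: $C_A = 1.95 + 10/\sqrt{Re_p}$ with
  $Re_p = \lvert\dot x_A\rvert y_A/\nu$;
* body: $C_B = \frac{24}{Re_b} K \left(1 + 0.15\,Re_b^{0.687}\right)$ with
  $Re_b = \lvert V\rvert L_B/\nu$ and shape factors $K_\parallel, K_\perp$
  fixed by requiring the creeping-flow limit to equal Oberbeck's exact
  spheroid drag (the correlation reduces to the classical sphere form when
  $a = b$);
* added mass: Lamb's potential-flow coefficients (exact);
* rotation: creeping-flow spheroid rotational drag (exact shape factors
  $G_\parallel, G_\perp$) with a $1 + 0.2\sqrt{Re_r}$ inertial correction.

All parameters are arguments of `default_coefficients()`, so better-sourced
correlations drop in without touching the dynamics. Reynolds-number
arguments outside $[10^{-3}, 10^5]$ are clamped (with a warning from the R
evaluators).

## Numerics

The integrator is classical fixed-step RK4 with 200 steps per beat cycle of
the fastest active row (convergence: halving the step changes a 0.5-s
mode-1 displacement by well under 0.1%; a test guards this). A fixed step
keeps every run — and the full 612-run sweep — deterministic and
bit-reproducible; the package uses no random numbers anywhere.

Attitude is integrated as the rotation matrix itself
($\dot R = -[\omega']_\times R$ with per-step re-orthonormalization) rather
than as Euler angles: turning modes rotate about oblique axes and sweep the
pitch angle through ±90°, where Euler-angle rates are singular. Yaw, pitch
and roll are extracted from $R$ only for output. Time is carried as an
integer step count, so a simulation advanced in segments (steady-state
checks, replay schedules) is bit-identical to one long run.

Simulations start from rest at the origin, oral axis along +x. The
steady-state halting rule stops a run when the trailing 2-s mean of the
normalized turning radius changes by less than 1% between consecutive beat
cycles, or once it exceeds 10 (straight swimming), with a hard cap of 10 s.
The terminal-speed rule is analogous with a 0.1% threshold on the trailing
mean speed.

Degenerate inputs are handled explicitly: inactive rows ($f = 0$) produce
static plates that contribute no force; an all-inactive program returns a
fixed point; a plate at stroke reversal has zero oscillatory speed and is
skipped (no division by $\lvert u\rvert$); zero body velocity gives exactly
zero drag.

## Maneuverability and agility metrics

Agility $\bar V$ is the path length over elapsed time in body lengths per
second. Maneuverability $\overline{R/L}$ is the mean normalized turning
radius, clamped at 10 (treated as straight swimming). Two estimators are
provided:

* `curvature_radius()` — path geometry, $R = \lvert v\rvert^3 /
  \lvert v \times a\rvert$ from central differences of positions smoothed
  over one beat period, excluding the first two beat cycles. This is the
  only option for landmark tracks and analytic fixtures, and it recovers
  lines, circles and helices to better than 1%.
* `turning_radius_state()` — the rigid-body ratio $R = \lvert v\rvert /
  \lvert\omega\rvert$ per sample. For a steady turn the two agree, but for
  a 1-s maneuver started from rest the path estimator averages over the
  spin-up spiral (the mechanical transient lasts ~0.5–0.8 s) and roughly
  doubles the reported radius, whereas $v/\omega$ is meaningful from the
  first beat because speed and turning rate grow together.

`maneuver_metrics()` uses the state-based estimator whenever angular
velocity is available (simulated trajectories) and falls back to path
geometry otherwise. This choice reproduces the published simulated
turning-mode table within ±20% across both metrics, all three modes and
both swimming directions, which we take as strong evidence that it matches
the original analysis; the path estimator remains available via
`method = "path"`.

## What the experiments produce

* `run_sweep()` — the 612-run grid (4 turning configurations ×
  $f_{out} \in \{2,\dots,34\}$ Hz × $f_{in} \in \{0,\dots,f_{out}-2\}$ Hz,
  2-Hz resolution) with steady-state halting, yielding the
  maneuverability–agility (MAP) table. Runs take ~2 minutes on one core.
* `run_subsets()` — all 255 non-empty row subsets at 30 Hz for 1 s (the
  hypothetical fully independent row control), in either or both
  power-stroke directions.
* `motor_volume()` — the reachable-space estimate: canonicalized
  trajectories rasterized as oriented spheroids on a voxel grid (default
  convergence: halving the voxel changes a smooth fixture's volume by <2%).

## Design choices where the problem was open

* **Quadrant pairing.** A "quadrant" is one sagittal plus one tentacular
  row between the two symmetry planes; mode 1 drives one quadrant pair at
  $f_{out}$ and the diagonally opposite pair at $f_{in}$ ("opposite" read
  as diagonal). Mode-2 variants split the eight rows across the sagittal or
  the tentacular plane; mode 3 slows one quadrant pair.
* **Symmetric row placement.** Rows sit exactly at $\pm\varepsilon$ and
  their 180° reflections; per-individual asymmetries are not modelled
  (only mean azimuths are available).
* **Initial conditions.** All protocol runs start from rest at a common
  canonical pose; the sweep and subset experiments inherit this.
* **Sa at the boundary.** $Sa = 1$ makes the tip ellipse touch $y = 0$;
  the plate length momentarily vanishes, which the force expression handles
  (zero area, zero force).
* **Replay.** Per-row frequency schedules are held stepwise-constant per
  beat cycle of the currently fastest active row; plate phases restart at
  each frequency change. A constant schedule reproduces `simulate_swim()`
  exactly.

## Limitations

* **No hydrodynamic interactions** between plates or between plates and
  body; no plate flexibility; no Basset history force; no rotational added
  inertia; no sporadic/irregular beating. These are inherent to the
  quasi-steady blade-element approach.
* **Terminal-speed ceiling.** With the elliptical tip path constrained to
  touch full extension and enclose exactly $Sa$ of the reachable area, the
  recovery stroke retains 70–100% of the plate length. Its drag penalty
  grows quadratically with body speed, so net thrust vanishes near
  1.4–1.7 BL/s at 30–34 Hz — low-speed behaviour (two active rows) is
  quantitatively right, while multi-row top speeds under-predict published
  simulated values by ~40%. Kinematics with a strongly folded recovery
  plate (smaller recovery $y_A$) would raise the ceiling; the printed
  constraints do not admit such an ellipse, so the package keeps the
  faithful reconstruction and documents the gap rather than retrofitting
  parameters.
* **Steady tight-turn radius** depends on the rotational-resistance
  correlation, the least-constrained coefficient family; the sharpest
  steady turns come out ~50% wider than the published minimum.
* The synthetic landmark fixtures emulate rigid, noise-free tracking of the
  apical organ and tentacular bulbs; real tracks carry digitization noise,
  missing frames and soft-body deformation, so passing the
  canonicalization and metric tests does not certify performance on noisy
  experimental data.

## A worked example

```{r example}
program <- assign_mode("mode1", f_out = 30, f_in = 0)
program
trajectory <- simulate_swim(program, duration = 1)
maneuver_metrics(trajectory)
```
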