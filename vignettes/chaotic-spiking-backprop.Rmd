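---
title: "Chaotic spiking backpropagation: model, parameters, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic spiking backpropagation: model, parameters, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(csbp)
```

## The model and its assumptions

The package trains layered feed-forward networks of discrete-time leaky
integrate-and-fire (LIF) neurons with hard reset. Writing $V_{ij}^t$ and
$O_{ij}^t \in \{0,1\}$ for the membrane potential and spike of neuron $j$
in layer $i$ at step $t$:

$$V_{ij}^{t+1} = k_\tau V_{ij}^t\,(1 - O_{ij}^t) + \sum_{k=0}^{M_{i-1}} w_{ijk}\,O_{i-1,k}^{t+1},
\qquad O_{ij}^{t+1} = \Theta(V_{ij}^{t+1} - V_{th}),$$

with $\Theta(0)=1$ (a neuron exactly at threshold fires) and $O_{i-1,0}^t
\equiv 1$ a constant bias channel, so $w_{ij0}$ is the bias. Membrane
potentials start at zero. Training is backpropagation through time with the
spike derivative replaced by a surrogate; the reset factor $(1-O^t)$ is
treated as a constant during differentiation (the "detach" convention —
stable and standard; a "through" mode exists for the finite-difference
oracle, see below).

The contribution this package is built around is a *neuron-intrinsic chaotic
loss*. Each neuron carries a hidden activity, the sigmoid of its
time-averaged drive,

$$h_{ij} = \sigma\!\Big(\tfrac1T\sum_{t}\sum_{k} w_{ijk}\,O_{i-1,k}^t\Big),$$

and contributes $-z\,[I_0 \ln h_{ij} + (1-I_0)\ln(1-h_{ij})]$ to the loss —
a cross-entropy pulling $h_{ij}$ toward the constant interior target $I_0$.
Because the cross-entropy's $1/h(1-h)$ cancels the sigmoid's $h(1-h)$, the
gradient is exactly $-z\,(I_0-h_{ij})\,s_k$ with $s_k$ the mean presynaptic
activity; the package implements only this cancelled form (the quotient
would be 0/0-fragile at saturation). The full update is therefore ordinary
gradient descent plus one extra per-neuron feedback term, and the intensity
is annealed geometrically, $z \leftarrow \beta z$, after every full-batch
update. At $z=0$ the chaos code path is skipped entirely, so the step is the
baseline BP step bit for bit — the degeneration property is structural, not
numerical.

Viewed as a map $W^{m+1} = G(W^m)$ on the flat weight vector, the update has,
for large $z$, a unique repelling fixed point at
$\bar w = \varepsilon \ln\frac{I_0}{1-I_0} + O(1/z)$ and a snap-back
repeller — the Marotto certificate of chaos. The `dynamics` module verifies
these statements numerically on reduced maps and measures the
chaos-to-gradient transition on real training runs.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `k_tau` | membrane decay per step (dimensionless, in (0,1)) | 0.25 | the simplified Euler LIF lineage this model family uses |
| `v_th` | firing threshold (membrane units) | 0.5 | same lineage; spike at equality |
| `T` | simulation steps per forward pass | 8 | smallest horizon at which XOR rate targets 0/1 are well separated while keeping 10^4-epoch runs cheap; rates quantise to 1/8 |
| `I0` | hidden-activity target, in (0,1) | 0.65 | the constant used in all of the source experiments; must differ from 0.5 for the snap-back construction |
| `z0` | initial chaos intensity | 20 | the desk-scale experiment value |
| `beta` | annealing constant, in (0,1) | 0.9995 | ditto; 10^4 epochs anneal z to 0.135 |
| `eta` | learning rate | 0.1 (`train`), 1.0 (experiment drivers) | see "calibration of eta" below |
| surrogate | rectangular window, width 1 | — | the customary boxcar of this model lineage; `sigmoid_derivative` available |
| mask | neurons receiving the chaotic term | all, bias included | the per-neuron loss is defined for every neuron; h's drive always includes the bias channel |
| init | uniform weight interval | [-1, 1] | the first of the four robustness intervals |

## Calibration of eta

The learning rate for the desk-scale experiments is the one genuinely
unstated quantity. The reduced scalar analysis fixes the admissible range:
freezing $z$ and linearising around the fixed point, the per-neuron
multiplier along the presynaptic direction is $1 - \eta z \sigma'(\bar u)
\lVert s\rVert^2$ with $\sigma'(\bar u) = I_0(1-I_0) = 0.2275$, so the
fixed point repels only when $\eta z \sigma' \lVert s\rVert^2 > 2$. At
$z_0 = 20$ this demands $\eta \lVert s\rVert^2 \gtrsim 0.44$; with
presynaptic norms of order a few, $\eta$ of order one is required for the
run to *start* in the chaotic regime, which is the regime the source
experiments display at $z_0 = 20$. The experiment drivers therefore default
to $\eta = 1$; `train()` keeps the conservative $\eta = 0.1$. Results are
sensitive to this choice: far smaller $\eta$ never enters the repelling
regime (no initial chaos, and plain BP behaves reasonably), while $\eta = 1$
is large enough that baseline BP alone oscillates without solving XOR —
the paired comparison in the acceptance suite is a comparison *at this
shared* $\eta$, not a claim about each method at its separately tuned best.

## The synthetic tasks

`xor_dataset()` is the four-row XOR truth table with one-hot targets,
constant-encoded (bit 1 spikes every step). A Poisson encoder exists behind
an explicit seed but is not the default: the constant encoder makes the
full-batch update map strictly deterministic, which the dynamical analysis
requires. `regression_dataset()` is a deliberate stand-in — $y=\sin x$ on a
uniform grid, rate-encoded — that exercises the continuous-target code path;
it does not claim to match any published regression benchmark. What a green
test on these fixtures establishes is that the *mechanism* behaves as the
theory says on exactly reproducible desk-scale problems; it says nothing
about convolutional architectures, event-stream data, minibatch noise, or
any benchmark accuracy.

## Numerical and estimator choices

- **Lyapunov exponents.** Two-trajectory Benettin: companion displaced by
  $\delta_0 = 10^{-8}$, renormalised every step, exponent = mean log stretch.
  The default displacement direction is the normalised all-ones vector, not
  a coordinate axis: under saturated spiking the hidden-weight coordinates
  can span an invariant neutral subspace (the Heaviside blocks infinitesimal
  coupling), and an axis-aligned perturbation trapped there reads a spurious
  $\lambda \le 0$. Steps with exactly zero separation (flat pieces of the
  rectangular surrogate) carry no stretch information and are dropped and
  counted rather than clamped.
- **Windowed exponents on training runs.** The training map is
  nonautonomous ($z$ shrinks every step). Exponents are reported per window
  with $z$ frozen at the window's opening value (window length 200, no
  within-window discard), run from the recorded weight state at the window
  start. This is a stated approximation, reasonable because $\beta$ is close
  to 1 ($z$ moves by 10% across a window).
- **Fixed points.** Damped Newton on $G(x)-x$ with central-difference
  Jacobians and step halving; the identity-map degeneracy at $z=0$ (every
  point fixed) is detected and flagged instead of "solved". The scale
  constant $\varepsilon$ in the closed-form prediction is realised as $1/s$
  on single-input reductions, where it is provable from
  $\sigma(\bar w s) = I_0$; it is asserted only there.
- **Snap-back search.** Numerical and one-sided: verify the repeller
  prerequisite from the Jacobian spectrum, seed at
  $\varepsilon\ln\frac{2I_0-1}{2-2I_0}$ ($I_0 > 0.5$), Newton-solve
  $G^k(w)=\bar w$ for $k = 1,2,\dots$, and require the solution to differ
  from $\bar w$ and to lie in the expanding region. Failure is reported as
  "not found", never as disproof. $I_0 = 0.5$ is rejected (the candidate
  formula degenerates).
- **Gradient oracle.** The finite-difference check of BPTT runs on the
  *smoothed* network (spikes replaced by $\sigma((V-V_{th})/\text{width})$)
  with the sigmoid surrogate and gradients *through* the reset — in that
  configuration the backward pass is the exact chain rule of a smooth
  function and central differences are a true oracle. On the spiking
  forward pass no such oracle exists (the loss is piecewise constant), which
  is precisely why surrogates are used.
- **Clamps.** $h$ is clamped to $[10^{-12}, 1-10^{-12}]$ inside the chaotic
  loss's logarithms only (the sigmoid saturates to exact 0/1 in double
  precision beyond $|u| \approx 37$); the gradient path needs no clamp.
- **Ties.** Predicted class is the argmax of output rates; exact ties break
  toward the lowest index.
- **Compiled hot loop.** The 10^4-epoch experiment loops run in C++
  (identical arithmetic to the reference R engine; the suite asserts
  agreement, over short horizons when $z>0$ since chaos amplifies roundoff
  exponentially, and over long horizons at $z=0$).

## The bifurcation structure, honestly

On the scalar reduced map ($\eta=1$, $I_0=0.65$) the route to chaos is the
classic period-doubling cascade: a single fixed point below
$z = 2/0.2275 \approx 8.79$, cycles of period 2, 4, 8 up to $z \approx 15$,
a chaotic band around $z \approx 15$–$18$, then a *period-3 window* over
roughly $z \approx 20$–$40$ (with a 6-cycle near 50) before chaos resumes.
A period-3 orbit itself implies Li–Yorke chaos, and the snap-back
certificate holds throughout the large-$z$ range — but the *metric*
attractor at a given large $z$ may be periodic. The full network map is
higher-dimensional and does show positive measured exponents at $z_0=20$;
the point of recording the scalar structure is that "sufficiently large $z$
is chaotic" must be read as a statement about topological chaos, not about
every $z$ having a strange attractor.

## Known limitations

- Fully connected layers only; no refractory period, adaptive threshold,
  convolution or event-stream input.
- The windowed-Lyapunov numbers are estimator-dependent (frozen-$z$
  approximation, window length, displacement direction); signs are robust
  in practice, magnitudes should not be over-interpreted.
- The regression fixture is a stand-in, and the XOR spike encoder is a
  stated choice (constant encoding) rather than a certified reproduction of
  the source raster.
- Annealing below $z \approx 0.13$ requires more than 10^4 epochs at
  $\beta = 0.9995$; the final-window dynamics therefore still contain a
  faint chaotic pull (visible as final-window MSE of order $10^{-2}$ rather
  than 0 on solved runs).
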