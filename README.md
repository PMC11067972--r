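# csbp — chaotic spiking backpropagation

Surrogate-gradient training of spiking neural networks (SNNs) gets stuck in
local minima: the gradient of the Heaviside spike is replaced by a surrogate,
the landscape is riddled with flat and dead regions, and plain
backpropagation-through-time (BPTT) descends into whatever basin it starts
in. This package implements a brain-inspired remedy: add to the task loss a
small *neuron-intrinsic chaotic loss*, whose annealed negative feedback makes
the weight-update map chaotic at first (global, ergodic search) and lets it
relax into ordinary gradient descent as the chaos intensity is annealed away.
It is aimed at researchers studying SNN training dynamics and chaotic
optimisation at desk scale, and ships a full dynamical-systems toolbox to
*verify* the claimed regime rather than take it on faith.

## The model

Leaky integrate-and-fire neurons with hard reset, simulated for `T` discrete
steps:

    V_ij^{t+1} = k_tau * V_ij^t * (1 - O_ij^t) + sum_k w_ijk O_{i-1,k}^{t+1}
    O_ij^{t+1} = Theta(V_ij^{t+1} - V_th)

with a constant-1 bias channel at presynaptic index `k = 0`. Each neuron
`(i,j)` also carries a *hidden activity* — the sigmoid of its time-averaged
drive —

    h_ij = sigmoid( (1/T) sum_t sum_k w_ijk O_{i-1,k}^t ),

and the chaotic loss is the cross-entropy of `h_ij` against a constant
target `I0` (0.65 throughout), scaled by an intensity `z`:

    loss_chaos = - sum_ij z [ I0 ln h_ij + (1 - I0) ln(1 - h_ij) ].

Its gradient collapses analytically to `-z (I0 - h_ij) s_k` (with `s_k` the
mean presynaptic activity), so the full update is

    w_ijk <- w_ijk - eta d(loss_bp)/dw_ijk + eta z (I0 - h_ij) s_k,
    z     <- beta z                       (chaotic simulated annealing),

i.e. plain surrogate-gradient BP plus one extra term that can be bolted onto
any existing trainer ("plug-in unit"). For large `z` the update map has a
unique repelling fixed point `w_bar = eps * ln(I0/(1-I0)) + O(1/z)` and a
snap-back repeller (Marotto chaos); as `z -> 0` it degenerates — exactly,
bit for bit — to the baseline BP step. The `dynamics` tools (Benettin
maximum-Lyapunov estimator, bifurcation scans, damped-Newton fixed-point
location, numerical snap-back search) check each of these statements.

## Worked example

The desk-scale experiment from the small-model validation: XOR on a [2,5,2]
SNN, `z0 = 20`, `beta = 0.9995`, 10,000 full-batch epochs, paired
chaotic-vs-baseline runs over ten seeds:

```r
library(csbp)
summ <- run_fig2_experiment(run_config(eta = 1), seeds = 0:9)
summ
#> <experiment_summary>
#>   median final-window MSE: chaotic 0.07107 vs baseline 0.5
#>   XOR solved (4/4): chaotic 9/10 seeds, baseline 0/10
#>   lambda_max: first window +0.1677 (z = 20), last window -0.0110 (z = 0.149)
```

Reading: over the last 500 epochs the chaotic runs reach a median rate-MSE
of 0.071 versus 0.5 for plain BP (which at this learning rate never solves
XOR); the chaotic runs classify all four XOR rows correctly in 9 of 10
seeds. The windowed maximum Lyapunov exponent of the training map (z frozen
per window) is positive at the start — the search really is chaotic — and
negative at the end — the run has collapsed onto gradient descent.

The closed-form checks on the scalar reduced map:

```r
fp <- find_fixed_point(chaos_map_scalar(z = 20), x_init = 0, I0 = 0.65)
fp
#> <fixed_point_report> w_bar = 0.61903921, residual = 0.00e+00, |eig(J)| = 3.55, repeller = TRUE
snapback_check(chaos_map_scalar(z = 50), fp$w_bar, I0 = 0.65)
#> <snapback_report> snap-back point found: 2-step image within 1.78e-10 of the fixed point
```

`w_bar` is `ln(13/7) = ln(I0/(1-I0))`, the Jacobian magnitude is
`|1 - z I0 (1 - I0)| = 3.55 > 1` (repeller), and a point near the
theoretical candidate `ln((2 I0 - 1)/(2 - 2 I0))` maps back onto the fixed
point in finitely many steps — the Marotto chaos certificate.

## Command line

```sh
CSBP_CLI=$(Rscript -e 'cat(system.file("cli/csbp.R", package = "csbp"))')
Rscript "$CSBP_CLI" train --task xor --arch 2,5,2 --z0 20 --beta 0.9995 \
        --eta 1 --epochs 10000 --seed 0 --track 2:2:0 --out runs/xor_csbp
Rscript "$CSBP_CLI" train --z0 0 --out runs/xor_bp    # baseline
Rscript "$CSBP_CLI" lyapunov --run runs/xor_csbp --window 200
Rscript "$CSBP_CLI" bifurcation --z-max 50 --z-min 0.01 --points 400 --out bif.csv
Rscript "$CSBP_CLI" fixed-point --I0 0.65 --eta 1.0 --z 20
```

Runs persist `trajectory.csv`, `weights.json` and `config.json`; a persisted
config re-runs bit-identically.

## Scope

Desk-scale only: fully connected LIF layers, rate decoding, XOR and a sine
regression fixture. No convolutions, event-camera loaders, refractory
periods, adaptive thresholds, or multi-GPU training. The methods vignette
(`vignettes/chaotic-spiking-backprop.Rmd`) documents the model, every
tunable parameter, the estimator designs and their limitations.
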