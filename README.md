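# pibop — predictive information bottleneck for optimal prediction

Biological encoders — a retina tracking a moving object, an immune
repertoire tracking a mutating pathogen — cannot store their input exactly.
`pibop` computes the best they could possibly do: the representation
$\tilde X$ of the current state $X_t$ that maximizes information about the
future state $X_{t+\Delta t}$ at every level of coding cost, by minimizing
the information-bottleneck objective

$$\mathcal L = I(X_t;\tilde X) - \beta\, I(\tilde X; X_{t+\Delta t}).$$

Sweeping the tradeoff $\beta$ traces the Pareto frontier
$I_{\text{future}}(I_{\text{past}})$ against which any encoder — biological,
engineered, or a Kalman filter — can be judged.

The package is written for quantitative biologists and physicists and
covers three classes of input dynamics end to end:

* **Stochastically driven damped harmonic oscillator** (2-D Gaussian
  state, damping $\zeta$, lag $\Delta t$): exact spectral solution of the
  Gaussian bottleneck (`ib_spectrum()`, `optimal_encoder()`,
  `info_curve()`), closed forms for the encoding angle, curve slope and
  total predictive information, parameter sweeps at fixed capacity,
  encoder transferability maps with the integrated `Q` metric, and a
  steady-state Kalman-filter baseline that provably never beats the curve.
* **Generalized Langevin dynamics with power-law memory** (friction kernel
  $\gamma|t-t'|^{-\alpha}$, fluctuation–dissipation noise): extended-history
  bottlenecks over past/future windows built from simulated
  autocovariances, and the saturation of predictive information with
  history length.
* **Wright–Fisher allele-frequency dynamics** ($N$, $N\mu$, $Ns$,
  generations): exact generation-kernel and Crank–Nicolson diffusion
  propagators on the frequency grid, closed-form steady states, and a
  Blahut–Arimoto solver for the discrete bottleneck with annealing,
  restart policy, effective-cardinality/bifurcation detection, decoder
  tilings and cross-model transfer.

Seeded simulators (`simulate_sddho()`, `simulate_gle()`, `simulate_wf()`)
generate the exact processes the theory assumes and back every analytic
object with a Monte-Carlo oracle. All results are tidy: tibbles in and out,
`tidy()`/`glance()` on fitted encoders, `autoplot()` on curves, transfer
maps and decoders.

## Worked example

Optimal prediction of an underdamped oscillator ($\zeta = 1/2$,
$\Delta t = 1$):

```r
library(pibop)

p <- sddho_params(zeta = 0.5, dt_pred = 1)
j <- sddho_joint(p)
j
#> <pib_joint_gaussian> past dim 2 | future dim 2 | I(past;future) = 1.5605 bits

ib_spectrum(j)
#> <pib_ib_spectrum>
#> # A tibble: 2 x 3
#>   lambda beta_c     r
#>    <dbl>  <dbl> <dbl>
#> 1  0.136   1.16     1
#> 2  0.843   6.38     1
```

The environment holds 1.56 bits about its own future. Below $\beta = 1.16$
the optimal code stores nothing; between the two critical tradeoffs it is a
one-dimensional projection of (position, velocity); above $\beta = 6.38$ it
becomes two-dimensional. At a 3-bit coding budget:

```r
enc <- encoder_at_ipast(j, 3)
evaluate_encoder(enc, j)
#> # A tibble: 1 x 2
#>   i_past_bits i_future_bits
#>         <dbl>         <dbl>
#> 1           3          1.38

leading_angle(p)    # encoding direction, radians from the position axis
#> 0.468
slope_at_origin(p)  # bits of future per bit of past at high compression
#> 0.8637
```

Storing 3 bits about the present buys 1.38 of the 1.56 available future
bits; the first encoded direction leans 0.47 rad off pure position, and at
high compression each stored bit is worth 0.86 predictive bits.

The discrete side — a binary summary of allele frequencies under weak
mutation ($N = 100$, $N\mu = 0.2$, $Ns = 0.001$, one-generation lag):

```r
wj <- wf_joint(wf_params(N = 100, n_mu = 0.2, n_s = 0.001, dt_pred = 1))
ba_best(wj, m = 2, beta = 4, n_restarts = 4, seed = 1)
#> <pib_discrete_encoder> m = 2, beta = 4 | i_past = 0.9816,
#>   i_future = 0.9267 bits | converged in 230 iter
```

One bit — "is the mutant allele common or rare?" — captures 0.93 bits about
the next generation, because under weak mutation alleles dwell near
fixation or extinction and flip basins rarely. `autoplot(enc, wj)` draws
the two decoder distributions tiling frequency space.

Figure-style bundles (curves, encoders, manifest, log) are produced by
`run_analysis(list(analysis = "fig9", out_dir = "out", seed = 1))`; presets
`fig3`–`fig11` and `s1fig` cover the standard analyses, and identical
configurations reproduce byte-identical CSVs.

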