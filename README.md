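# isitools

Analysis of spontaneous spike trains from hair-cell afferent neurons via
their interspike intervals (ISIs): distribution-shape metrics,
renewal-process model fitting, serial-dependence statistics, and the
generative simulators needed to test which synaptic-release mechanisms
can produce the observed patterns.

## The scientific problem

Hair cells release neurotransmitter spontaneously, so the afferent
neurons that innervate them fire spontaneously too. In the auditory
system (one afferent, one synapse) vesicle-pool depletion makes
consecutive ISIs *negatively* correlated. Lateral-line afferents contact
many synapses on several hair cells, and their spontaneous ISI patterns
look different: distributions that are either exponential-shaped or
"L-shaped" (sharp decay, heavy tail), and *positive* serial correlation
— long ISIs follow long ones, short follow short — as if spike
generation switched between a fast and a slow mode. This package
implements the complete analysis chain for such data and two generative
models to probe the mechanisms:

* **Renewal ISI models.** Each ISI = absolute refractory period
  `t_abs` + exponential relative refractory (mean `tau_rel`) +
  excitation wait with density `f_E`; the ISI density is the
  convolution `f_ISI(t) = ∫ f_R(t_R) f_E(t − t_R) dt_R`. Three
  excitation laws: exponential (case i), gamma–exponential mixture
  (case ii, a caricature of depletion), two-exponential mixture
  (case iii, fast + slow release sources).
* **Shape metrics.** Quartile decomposition `E_1..E_4` of the
  integrated squared difference between the empirical CDF and the
  best-fit exponential (`λ̂ = 1/mean ISI`), and the L-shape index
  `ℓ = E_3/E_1`: `ℓ < 1` exponential-shaped, `ℓ > 1` L-shaped.
* **Fitting and comparison.** Least-squares CDF fitting of all three
  renewal cases with multi-start bounded optimisation, per-quartile
  residuals, AIC/BIC.
* **Serial statistics.** `SRC(n)` (lagged correlation with global
  moments) with Pearson significance, shuffle controls, the 4×4
  recurrence quartile matrix (uniform 1/16 under independence),
  short/long ISI sequence detection, and sliding-window Fano factors.
* **Two-state switching simulator.** Exact continuous-time simulation
  of slow/fast release-mode switching (rates `k_sf`, `k_fs`); slow
  switching reproduces the positive serial correlation seen in the
  data.
* **Depletion–replenishment simulator.** Fixed-step (Δt = 0.001 ms,
  compiled kernel) Monte Carlo of vesicle pools `n(t) ≤ n_max`
  releasing at rate `p_depl·n(t)` and refilling on timescale
  `tau_repl`, with any number of heterogeneous sources; strong
  depletion gives negative SRC(1) and `ℓ ≪ 1`, many or strongly
  heterogeneous sources remove or invert that signature.
* **Synthetic cohorts.** `make_cohort()` generates study-scale cohorts
  (26 recordings × 2000 spikes, 85–257 s) with ground-truth manifests
  for end-to-end validation.

All times are milliseconds, rates 1/ms.

## Worked example

```r
library(isitools)

# one synthetic recording: slow switching between a fast (40 ms) and
# slow (200 ms) release mode, 2 + 2 ms refractory
sp <- switching_params(k_sf = 1e-4, p_fast = 0.5,
                       tau_fast = 40, tau_slow = 200)
isis <- simulate_switching(sp, n_isis = 1999, seed = 42)$isis

shape_metrics(isis, dataset_id = "demo")
#>   dataset_id    M mean_ms   cv kurtosis lambda_hat     E1    E2    E3    E4
#> 1       demo 1999    86.6 1.57     26.6     0.0115 0.0143 0.222 0.709 0.733
#>   E_total  ell shape_label
#> 1    1.68 49.5    L-shaped

s1 <- serial_correlation(isis, 1)
sh <- serial_correlation(shuffle_isis(isis, seed = 1), 1)
c(src1 = s1$src, p = s1$p_value, shuffled = sh$src)
#> SRC(1) = 0.285 (p = 1.4e-38); shuffled: 0.002

fit <- fit_renewal(isis, "iii", n_starts = 8, seed = 1)
data.frame(fit$params)
#>   case t_abs tau_rel     p lambda_E1 lambda_E2
#> 1  iii  1.31    3.54 0.759    0.0263   0.00453
```

Reading the output: the 5:1 timescale contrast makes the ISI
distribution L-shaped (`ell = 49.5 > 1`, CV well above the exponential
value 1), and the slow switching leaves strong positive serial
correlation (SRC(1) = 0.285) that vanishes when the ISI order is
shuffled. The case (iii) fit recovers the generating rates
(`lambda_E1 ≈ 1/40`, `lambda_E2 ≈ 1/200`); the fitted weight `p = 0.76`
exceeds the fast-state time share 0.5 because the fast state emits more
spikes per unit time, so the marginal ISI distribution is the
spike-weighted mixture (see the methods vignette).

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study-style
analysis on a synthetic cohort, writing tables under `results/`:

1. `01_simulate_cohort.R` — 26-recording cohort + ground-truth manifest;
2. `02_shape_metrics.R` — moments, exponential fits, `ℓ`, shape labels;
3. `03_renewal_fits.R` — cases i/ii/iii per recording, AIC/BIC ranking;
4. `04_serial_stats.R` — SRC(n), shuffle controls, recurrence matrices,
   sequence fractions, Fano curves;
5. `05_switching_sweeps.R` — SRC(1) vs switching rate, timescale ratio,
   and `p_fast`; SRC(n) decay; Fano steepening;
6. `06_depletion_experiments.R` — strong-depletion reference run,
   single-source parameter scan, source-count and two-source
   heterogeneity experiments.

Each script prints what it found; e.g. `02` reports the 13/13
exponential/L-shaped split with 100% classifier agreement against the
manifest; `03` reports case (iii) winning the AIC comparison on 24/26
recordings with fitted rate ratios near 2.6 on exponential-shaped and
7.8 on L-shaped data; and `04` reports 24/26 recordings with
significantly positive SRC(1) and ~34%/~9% of ISIs inside short/long
sequences.

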