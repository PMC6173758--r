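---
title: "Models and methods for spontaneous ISI analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for spontaneous ISI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isitools)
```

# The scientific setting

Hair cells release neurotransmitter spontaneously, driving spontaneous
action potentials in the afferent neurons that innervate them. The
temporal structure of those spikes — summarized by the distribution of
interspike intervals (ISIs) and by the dependence between successive
ISIs — carries information about the release machinery. In the auditory
system, where one afferent contacts one hair cell, depletion of the
readily releasable vesicle pool produces *negative* serial correlation
(a short ISI drains the pool, lengthening the next ISI). Lateral-line
afferents instead contact many synapses on several hair cells; their
spontaneous ISI patterns show *positive* serial correlation and ISI
distributions that are either exponential-shaped or "L-shaped" (sharper
initial decay with a heavier tail). This package implements the full
analysis chain for such data — distribution-shape quantification,
renewal-model fitting, serial statistics — together with two generative
models (two-state switching; depletion–replenishment) that probe which
release mechanisms can or cannot produce the observed patterns.

All times in the package are milliseconds; rates are 1/ms.

# Renewal ISI models

Each ISI is modeled as refractory period plus excitation wait,

$$t_{ISI} = t_{abs} + t_{rel} + t_E,$$

with a constant absolute refractory period $t_{abs}$, an exponential
relative refractory period with mean $\tau_{rel}$ (rate
$\lambda_R = 1/\tau_{rel}$), and an excitation (synaptic release) wait
$t_E$ with density $f_E$. The ISI density is the convolution

$$f_{ISI}(t) = \int_{t_{abs}}^{t} f_R(t_R)\, f_E(t - t_R)\, dt_R .$$

Three excitation laws are implemented:

* **case (i)** `exp_excitation(lambda_E)` — release at a constant rate
  (Poisson-like release);
* **case (ii)** `gamma_mix_excitation(p, lambda_E, n)` — with
  probability $1-p$ the wait is gamma with shape $n \ge 1$ (several
  sub-events needed per release: a caricature of pool depletion); the
  shape is treated as continuous and the model collapses to case (i) at
  $n = 1$;
* **case (iii)** `two_exp_mix_excitation(p, lambda_E1, lambda_E2)` —
  a mixture of a fast and a slow exponential release source,
  $\lambda_{E1} \ge \lambda_{E2}$ by convention.

**Numerics.** For cases (i) and (iii) the convolution is a sum of
shifted hypoexponential terms and is evaluated in closed form; the
removable singularity at $\lambda_R = \lambda_E$ is switched to the
Erlang limit when the rates agree within a relative $10^{-10}$. For
case (ii) the scalar `isi_pdf()`/`isi_cdf()` use adaptive quadrature
(relative tolerance $10^{-9}$, integration truncated where $f_R$ falls
below $10^{-14}$ of its peak). Vectorized CDF evaluation — the inner
loop of fitting — uses the substitution $u = 1 - e^{-\lambda_R r}$,
which maps the conditioning integral onto a bounded smooth integrand
handled by 48-node Gauss–Legendre quadrature; for long inputs the CDF
is computed exactly on a ~600-point grid and interpolated with a
monotone Hyman spline (observed error ~$10^{-9}$, about ten times
cheaper in `pgamma` calls). `tau_rel = 0` (a point-mass refractory) is
handled analytically, never as a numerical limit.

# Shape metrics: quartile errors and the L-shape index

The empirical CDF $F_{data}$ is the right-continuous step function of
the sorted ISIs. Against any model CDF $F$ the package computes the
integrated squared difference split at the quartile boundaries
$T_0 = 0 \le T_1 \le T_2 \le T_3 \le T_4 = \max ISI$:

$$E_k = \int_{T_{k-1}}^{T_k} \left(F(t) - F_{data}(t)\right)^2 dt,
\qquad E_{total} = \sum_k E_k,$$

and the L-shape index $\ell = E_3 / E_1$ against the maximum-likelihood
exponential fit ($\hat\lambda = 1/\overline{ISI}$). Exponential-shaped
distributions misfit mostly in the first quartile (refractoriness
suppresses short ISIs), giving $\ell < 1$; L-shaped distributions also
misfit in the upper quartiles, giving $\ell > 1$.

Choices the definition leaves open, fixed here once:

* quartile boundaries use the type-1 (inverted-CDF) empirical quantile;
  an ISI equal to a boundary belongs to the lower quartile;
* $T_0 = 0$ (the first integral starts below the smallest ISI) and
  $T_4 = \max ISI$;
* integration is exact piecewise — $F_{data}$ is constant between
  order statistics and the model CDF is integrated per piece by
  16-node Gauss–Legendre — so no grid resolution parameter exists;
* $\ell = 1$ exactly classifies as "L-shaped" (a measure-zero
  tie-break), and $E_1 = 0$ makes $\ell$ undefined (reported `NA`, not
  infinity).

# Least-squares fitting and model comparison

`fit_renewal()` minimizes $\int_0^{T_4}(F_{model} - F_{data})^2 dt$ —
the same functional as the shape metric, so fitted error decompositions
are directly comparable — over the model parameters, from 10 (default)
Latin-hypercube starts on a unit-cube parameterisation with rates and
$\tau_{rel}$ on log scale. Bounds: $t_{abs} \in [0, \min ISI]$,
$\tau_{rel} \in (0, 50]$ ms, rates $\in [10^{-5}, 10]$ 1/ms,
$p \in [0,1]$, $n \in [1, 20]$. Case (iii) enforces
$\lambda_{E1} \ge \lambda_{E2}$ by fitting the slow rate as
$\lambda_{E1} \cdot r$, $r \in (0,1]$.

Two structural facts matter for interpretation:

* **Label symmetry in case (i).** $\mathrm{Exp}(\lambda_R) +
  \mathrm{Exp}(\lambda_E)$ is symmetric in the two rates, so data alone
  cannot tell the relative-refractory rate from the excitation rate.
  Fits are canonicalized to $\lambda_E \le \lambda_R$: the excitation
  wait is the slow, ISI-dominating timescale and the relative
  refractory the short one.
* **Warm starts for the mixtures.** Cases (ii) and (iii) contain case
  (i) as a degenerate submodel; each mixture fit adds a start derived
  from a case (i) fit. Without it, case (ii) — whose $(p, n,
  \lambda_E, \tau_{rel})$ surface is long-valleyed and weakly
  identifiable — frequently converges to CDF-equivalent but
  biologically different optima. Case (iii) recovery at 5000 ISIs is
  within 15% for all five parameters; case (ii) recovery is reliable
  for the CDF but not for the individual parameters, which is the
  expected behaviour of gamma mixtures with free shape and is why the
  per-parameter recovery checks target cases (i) and (iii).

AIC and BIC are evaluated at the least-squares optimum (the
log-likelihood is *not* re-maximized): a deliberate two-stage choice
that mirrors fitting CDFs first and scoring second; the absolute
criterion values are therefore slightly conservative but the
between-model deltas, which is all the comparison uses, are meaningful.
An ISI at or below the fitted $t_{abs}$ yields an explicit $-\infty$
log-likelihood rather than a silent omission.

# Serial statistics

`serial_correlation()` implements

$$SRC(n) = \frac{\langle (ISI_{k+n} - \overline{ISI})(ISI_k -
\overline{ISI})\rangle}{\mathrm{Var}(ISI)}$$

with the *global population* mean and variance of the whole sequence
and the average taken over the $M - n$ lagged pairs — exactly the
printed estimator, which differs at order $1/M$ from the textbook
autocorrelation that uses per-lag subsample moments. Significance is
the Pearson p-value on the lagged pair set. The null band used in
tests is $|SRC| \le 2/\sqrt{M-n}$.

The recurrence quartile matrix $q_{ij}$ tallies consecutive-pair
quartile transitions over $M-1$ pairs (uniformly $1/16$ under
independence). Sequence detection classifies each ISI as short (below
the global mean) or long, computes the class means $\mu_{short}$,
$\mu_{long}$, and accepts maximal same-class runs of length $\ge 2$
whose run mean is at or below $\mu_{short}$ (short) or at or above
$\mu_{long}$ (long) — a greedy left-to-right scan with no overlap; the
inclusive comparison keeps the degenerate case where one run contains
the entire class. The Fano factor uses sliding windows fully inside
the recording with stride $dt/10$ (the stride is configurable; a
200-s recording estimates $F(1000\,\mathrm{ms})$ with a standard
deviation near 0.09, which is why benchmark checks average several
independent trains).

# The two-state switching generator

Release alternates between a slow state (mean wait $\tau_{slow}$) and
a fast state ($\tau_{fast} < \tau_{slow}$) with Markov rates $k_{sf}$,
$k_{fs}$; the stationary fast-state occupancy is
$p_{fast} = k_{sf}/(k_{sf} + k_{fs})$. Simulation is exact in
continuous time by competing exponential clocks — during an excitation
wait the release clock races the switch clock, and memorylessness lets
the release clock be redrawn at each switch without discretisation
error. The hidden state keeps evolving through the refractory period
(it is a presynaptic property), and the initial state is drawn from the
stationary law to avoid burn-in bias. Defaults mirror the reference
regime: $\tau_{fast} = 40$, $\tau_{slow} = 200$, $t_{abs} = \tau_{rel}
= 2$ ms.

Slow switching (state persisting over many ISIs) produces positive
SRC(1) that is maximal near $p_{fast} = 0.5$, vanishes at the
occupancy extremes, shrinks as switching accelerates or as the
timescales approach each other, and decays gradually with lag — the
signature observed in lateral-line data.

**The mixture mapping.** Ignoring serial order, the model corresponds
to the case (iii) renewal model with $\lambda_{E1} = 1/\tau_{fast}$,
$\lambda_{E2} = 1/\tau_{slow}$, $p = p_{fast}$. One subtlety: the
continuous-time process emits more spikes per unit time in the fast
state, so its marginal ISI distribution is the *spike-weighted*
(length-biased) mixture — at $p_{fast} = 0.5$ with $\tau$ 40/200 ms,
83% of spikes originate in the fast state. The mapping with weight
exactly $p_{fast}$ holds for the per-interval-resampling variant
(`resample_per_interval = TRUE`), in which the state is redrawn
independently each interval; that variant is also the natural
serially-independent control, and it is what the distributional
equivalence tests use. For the continuous-time process the
$p_{fast}$-weighted mixture mean is an upper bound on the mean ISI
(the fast state is over-represented), which is checked as an
invariant.

# The depletion–replenishment generator

Each release source $k$ (a hair-cell synapse) carries a continuous
pool $n^k(t) \in [0, n^k_{max}]$. Per time step $\Delta t$ (default
0.001 ms) and per source, a release occurs with probability
$p^k_{depl} \cdot n^k(t) \cdot \Delta t$ (at most one per source per
step; the step guard rejects $p_{depl} n_{max} \Delta t > 0.1$); a
release decrements the pool by 1 (floored at 0) and resets that
source's release clock. A release triggers a spike only outside the
refractory period $t_D + \mathrm{Exp}(t_R)$; releases falling inside
refractoriness still deplete the pool by default (the pool is
presynaptic; configurable), but do not spike. The compiled kernel in
`src/` keeps the 10⁷–10⁸-step runs inside interactive budgets.

**Replenishment scheme.** Between releases the pool refills toward
$n_{max}$ on the timescale $\tau_{repl}$. The default scheme advances
the pool by the exact per-step solution of
$dn/dt = (n_{max} - n)/\tau_{repl}$, so the pool deficit decays
exponentially with time constant $\tau_{repl}$ independent of
$\Delta t$. An alternative recursive update, in which the per-step
increment factor uses the absolute time since the source's last
release, is retained as `scheme = "printed"` for sensitivity analysis:
applied at every step it compounds, making the deficit decay on a
$\sqrt{\tau_{repl}\, \Delta t}$ timescale (~0.07 ms at the reference
parameters) — effectively instantaneous replenishment that erases the
depletion memory the model exists to study (its SRC(1) is ~0 where the
relaxation scheme reproduces the published negative value). The
relaxation scheme is therefore the default.

**Refractory parameters.** The depletion model descends from the
auditory-nerve literature; the package default is $t_D = t_R =
0.6$ ms, the standard auditory-nerve refractory scale. This matters:
with the lateral-line refractory (2 + 2 ms) the pool recovers during
refractoriness ($\tau_{repl} = 2.5$ ms at the reference parameters)
and SRC(1) collapses to zero. With the defaults, the strong-depletion
reference configuration ($\tau_{repl} = 2.5$ ms, $p_{depl} =
0.08$/ms, $n_{max} = 4$, 10,000 ISIs) gives SRC(1) $\approx -0.020
\pm 0.009$ and $\ell \approx 0.030 \pm 0.003$ across seeds: strong
depletion suppresses short ISIs ($\ell \ll 1$, the opposite of
L-shaped) and induces negative serial correlation.

**Parameter scans.** The published scan ranges are not stated; the
package samples log-uniformly over $p_{depl} \in [0.01, 1]$/ms and
$\tau_{repl} \in [0.1, 50]$ ms (single-source scan) and over
source-parameter ratios in $[10^{-3}, 10^3]$ (two-source scan, wide
enough to contain the reference heterogeneous pair whose $p_{depl}$
ratio is ~1/255), at around a hundred trials instead of thousands —
the structure of the maps (negative SRC(1) only in the
high-$p_{depl}$, high-$\tau_{repl}$ corner; no L-shapes anywhere;
positive SRC(1) only for widely differing sources) is stable at this
size. With several identical sources the per-source depletion memory
dilutes; under this package's parameterization the shrinkage of
|SRC(1)| is non-monotone at 2–4 sources (extra sources also shorten
ISIs, deepening per-pool depletion) and unambiguous by 8, so trend
checks compare 1 against 8 sources.

# The synthetic cohort generator

`make_cohort()` emulates the study's data scale: 26 recordings of 2000
spikes (85–257 s). Half the datasets (configurable) are
exponential-shaped — fast/slow rate ratio drawn from $[1.6, 2.2]$,
target mean ISI 45–60 ms — and half L-shaped — ratio $[7, 11]$, mean
75–105 ms — on the reference refractory ($2 + 2$ ms). The default
`switching` mode generates each recording from the slow two-state
switching simulator, so datasets carry positive SRC(1); because the
process is length-biased, $\tau_{fast}$ is calibrated per dataset by
root-finding on the occupancy-weighted spike rate so that the realized
mean ISI hits its target (the `renewal` mode, which resamples the
state per interval, uses the direct mixture mean instead).
Exponential-shaped datasets switch slightly faster ($k_{sf} =
5\times10^{-4}$/ms vs $2\times10^{-4}$/ms): their smaller fast/slow
contrast needs better state mixing for a stable marginal, while both
rates remain slow enough for clear positive correlation. All
per-dataset parameters and seeds go into a manifest from which the
cohort regenerates bit-identically.

What the generator does *not* emulate: recording noise, spike-sorting
errors, slow non-stationary drift in overall excitability, and the
idiosyncratic per-recording parameter spread of real neurons. Tests
passing on these cohorts therefore validate the analysis chain
(generator → metrics → fits → serial statistics round-trips), not the
biological fidelity of any particular recording.

# Problem sizes used in checks

The test-suite and benchmark scripts use: $10^5$ draws for moment
benchmarks; 20,000 iid ISIs for the recurrence matrix; 200-s Poisson
trains for Fano benchmarks (averaged over replicate trains); 10,000
ISIs per depletion reference run, averaged over a handful of seeds;
5000-ISI, 10-start fits for parameter recovery; and 10–25 trials of
2000–5000 ISIs per point for simulator trend checks. These sizes give
Monte Carlo error comfortably below each tolerance being checked
while keeping the whole suite interactive.

# Known limitations

* Case (ii) parameters are reported as fitted but are weakly
  identifiable; compare models via CDF error and information-criterion
  deltas, not via case (ii) point estimates.
* AIC/BIC use the two-stage (least-squares-then-score) likelihood; do
  not compare their absolute values across packages.
* The switching model has exactly two states; multi-state or
  hidden-Markov inference from data is out of scope.
* The depletion simulator's fixed-step Bernoulli scheme is the
  reference; no event-driven acceleration is provided.
* Sequence detection follows one specific burst-style rule (greedy
  maximal runs, inclusive thresholds); other published burst criteria
  will partition differently.
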