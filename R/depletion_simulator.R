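# Monte Carlo depletion-replenishment model of spike generation.
#
# Each release "source" (hair-cell synapse) holds a readily releasable
# vesicle pool n(t) in [0, n_max] that releases units at probability rate
# p_depl * n(t) and refills toward n_max on a timescale tau_repl. A release
# outside the neuron's refractory period triggers a spike. Strong depletion
# (large p_depl and tau_repl) suppresses short ISIs and induces negative
# serial correlation; several independent sources wash the correlation out,
# and strongly heterogeneous sources can make it positive.

#' Depletion-source parameters
#'
#' @param n_max Maximum pool size (>= 1).
#' @param p_depl Per-unit release probability rate, 1/ms.
#' @param tau_repl Replenishment timescale, ms.
#' @export
depletion_source_params <- function(n_max = 4, p_depl = 0.08,
                                    tau_repl = 2.5) {
  stopifnot(n_max >= 1, p_depl > 0, tau_repl > 0)
  structure(list(n_max = n_max, p_depl = p_depl, tau_repl = tau_repl),
            class = "depletion_source_params")
}

#' Refractory parameters of the depletion model
#'
#' Constant absolute refractory `t_D` followed by an exponentially
#' distributed relative part with mean `t_R`. Defaults are the standard
#' auditory-nerve values (0.6 ms each) the depletion model was developed
#' with; they are much shorter than the lateral-line afferent refractory
#' used elsewhere in this package.
#'
#' @param t_D Absolute refractory period, ms.
#' @param t_R Mean relative refractory period, ms.
#' @export
depletion_refractory <- function(t_D = 0.6, t_R = 0.6) {
  stopifnot(t_D >= 0, t_R >= 0)
  structure(list(t_D = t_D, t_R = t_R), class = "depletion_refractory")
}

#' Simulate the depletion-replenishment model
#'
#' Fixed-step Monte Carlo (default step 0.001 ms): at each step and for
#' each source, a release occurs when a uniform draw falls below
#' `p_depl * n(t) * dt`; a release decrements the pool by 1 (floored at 0)
#' and resets that source's release clock, otherwise the pool replenishes
#' toward `n_max`. A release triggers a spike only outside the refractory
#' period; each spike starts a new `t_D + Exp(t_R)` refractory interval.
#'
#' Two replenishment schemes are provided. `"relaxation"` (the default)
#' advances the pool by the exact per-step solution of
#' `dn/dt = (n_max - n) / tau_repl`, so the pool deficit decays
#' exponentially with time constant `tau_repl` independent of `dt`.
#' `"printed"` applies the recursive update whose exponent uses the time
#' since the source's last release; its effective replenishment speed
#' scales with `sqrt(tau_repl * dt)` and is kept only for sensitivity
#' comparison (see the methods vignette).
#'
#' @param sources A [depletion_source_params()] object or a list of them
#'   (one per source).
#' @param refractory A [depletion_refractory()] object.
#' @param n_isis Number of ISIs to generate.
#' @param dt Step size, ms; the per-step release probability
#'   `p_depl * n_max * dt` must not exceed 0.1.
#' @param seed Optional integer seed.
#' @param scheme Replenishment scheme, `"relaxation"` or `"printed"`.
#' @param deplete_during_refractory Should releases occurring during the
#'   refractory period still deplete the pool (default TRUE; the pool is
#'   presynaptic)?
#' @param record_releases Keep per-source release times (including those
#'   falling inside refractoriness)?
#' @param max_steps Safety cap on simulation steps.
#' @return A list of class `depletion_result`: `spikes` (a `spike_train`),
#'   `isis` (an `isi_seq`), `releases` (per-source release times, ms),
#'   `final_pools`.
#' @export
simulate_depletion <- function(sources, refractory = depletion_refractory(),
                               n_isis, dt = 0.001, seed = NULL,
                               scheme = c("relaxation", "printed"),
                               deplete_during_refractory = TRUE,
                               record_releases = FALSE, max_steps = 5e9) {
  scheme <- match.arg(scheme)
  if (inherits(sources, "depletion_source_params")) sources <- list(sources)
  stopifnot(length(sources) >= 1, n_isis >= 1, dt > 0,
            inherits(refractory, "depletion_refractory"))
  if (!is.null(seed)) set.seed(seed)
  n_max <- vapply(sources, `[[`, numeric(1), "n_max")
  p_depl <- vapply(sources, `[[`, numeric(1), "p_depl")
  tau_repl <- vapply(sources, `[[`, numeric(1), "tau_repl")

  res <- simulate_depletion_cpp(n_max, p_depl, tau_repl,
                                refractory$t_D, refractory$t_R,
                                as.integer(n_isis), dt,
                                deplete_during_refractory,
                                if (scheme == "relaxation") 0L else 1L,
                                record_releases, max_steps)
  spikes <- spike_train(res$spikes)
  structure(list(spikes = spikes, isis = isis_from_spikes(spikes),
                 releases = res$releases, final_pools = res$final_pools,
                 scheme = scheme),
            class = "depletion_result")
}

#' Random scan of single-source depletion parameters
#'
#' Samples `n_points` (p_depl, tau_repl) pairs log-uniformly over the given
#' ranges, simulates `n_isis` ISIs at each, and records SRC(1) and the
#' L-shape index against the best-fit exponential.
#'
#' @param p_depl_range,tau_repl_range Length-2 positive ranges (1/ms, ms).
#' @param n_points Number of sampled pairs.
#' @param n_isis ISIs per trial.
#' @param n_max Pool size (fixed across the scan).
#' @param refractory A [depletion_refractory()].
#' @param dt Step size, ms.
#' @param seed Base seed.
#' @return A `data.frame`: `p_depl`, `tau_repl`, `src1`, `src1_p`, `ell`,
#'   `mean_isi_ms`.
#' @export
single_source_scan <- function(p_depl_range = c(0.01, 1),
                               tau_repl_range = c(0.1, 50),
                               n_points = 100, n_isis = 2000, n_max = 4,
                               refractory = depletion_refractory(),
                               dt = 0.001, seed = 1) {
  stopifnot(all(p_depl_range > 0), all(tau_repl_range > 0))
  set.seed(seed)
  lp <- stats::runif(n_points, log(p_depl_range[1]), log(p_depl_range[2]))
  lt <- stats::runif(n_points, log(tau_repl_range[1]), log(tau_repl_range[2]))
  rows <- lapply(seq_len(n_points), function(i) {
    src <- depletion_source_params(n_max, exp(lp[i]), exp(lt[i]))
    sim <- simulate_depletion(src, refractory, n_isis, dt,
                              seed = (seed + 131L * i) %% .Machine$integer.max)
    s <- serial_correlation(sim$isis, 1)
    q <- ell_index(sim$isis)
    data.frame(p_depl = exp(lp[i]), tau_repl = exp(lt[i]),
               src1 = s$src, src1_p = s$p_value, ell = q$ell,
               mean_isi_ms = mean(sim$isis))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect of the number of release sources on SRC(1)
#'
#' For each entry of `n_sources_list`, runs `n_trials` simulations with
#' that many identical sources and records SRC(1): with strongly depleting
#' sources the negative correlation of a single source shrinks toward zero
#' as independent sources are added.
#'
#' @param n_sources_list Integer vector of source counts.
#' @param source A [depletion_source_params()] shared by all sources, or a
#'   list of per-source parameter objects (heterogeneous sources; then
#'   `n_sources_list` is ignored and the list defines one configuration).
#' @param n_trials Trials per configuration.
#' @param n_isis ISIs per trial.
#' @param refractory A [depletion_refractory()].
#' @param dt Step size, ms.
#' @param seed Base seed.
#' @return A `data.frame`: `n_sources`, `trial`, `src1`, `src1_p`.
#' @export
multi_source_experiment <- function(n_sources_list = c(1, 2, 4),
                                    source = depletion_source_params(),
                                    n_trials = 100, n_isis = 2000,
                                    refractory = depletion_refractory(),
                                    dt = 0.001, seed = 1) {
  configs <- if (is.list(source) && !inherits(source, "depletion_source_params")) {
    list(source)
  } else {
    lapply(n_sources_list, function(ns) rep(list(source), ns))
  }
  rows <- list()
  for (ci in seq_along(configs)) {
    for (tr in seq_len(n_trials)) {
      sim <- simulate_depletion(configs[[ci]], refractory, n_isis, dt,
                                seed = (seed + 104729L * ci + tr) %% .Machine$integer.max)
      s <- serial_correlation(sim$isis, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        n_sources = length(configs[[ci]]), trial = tr,
        src1 = s$src, src1_p = s$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random scan over two heterogeneous sources
#'
#' Samples pairs of sources whose `p_depl` and `tau_repl` ratios vary
#' log-uniformly over the given ranges (geometric means sampled from
#' `p_depl_range` / `tau_repl_range`), and records SRC(1) per trial along
#' with the fraction of trials with strongly positive SRC(1) > 0.05.
#'
#' @param ratio_range Length-2 range for the source-1/source-2 parameter
#'   ratios (applied to both `p_depl` and `tau_repl`, sampled
#'   independently).
#' @param p_depl_range,tau_repl_range Ranges for the geometric-mean values.
#' @param n_points Number of sampled configurations.
#' @param n_isis ISIs per trial.
#' @param n_max Pool size for both sources.
#' @param refractory A [depletion_refractory()].
#' @param dt Step size, ms.
#' @param seed Base seed.
#' @return A `data.frame` with per-trial parameters and `src1`; the
#'   attribute `frac_strong_pos` holds the fraction of trials with
#'   `src1 > 0.05`.
#' @export
two_source_scan <- function(ratio_range = c(1e-3, 1e3),
                            p_depl_range = c(0.01, 0.5),
                            tau_repl_range = c(1, 50),
                            n_points = 100, n_isis = 2000, n_max = 4,
                            refractory = depletion_refractory(),
                            dt = 0.001, seed = 1) {
  stopifnot(all(ratio_range > 0))
  set.seed(seed)
  lr_p <- stats::runif(n_points, log(ratio_range[1]), log(ratio_range[2]))
  lr_t <- stats::runif(n_points, log(ratio_range[1]), log(ratio_range[2]))
  gm_p <- exp(stats::runif(n_points, log(p_depl_range[1]), log(p_depl_range[2])))
  gm_t <- exp(stats::runif(n_points, log(tau_repl_range[1]), log(tau_repl_range[2])))
  rows <- lapply(seq_len(n_points), function(i) {
    p1 <- gm_p[i] * exp(lr_p[i] / 2); p2 <- gm_p[i] * exp(-lr_p[i] / 2)
    t1 <- gm_t[i] * exp(lr_t[i] / 2); t2 <- gm_t[i] * exp(-lr_t[i] / 2)
    srcs <- list(depletion_source_params(n_max, p1, t1),
                 depletion_source_params(n_max, p2, t2))
    sim <- simulate_depletion(srcs, refractory, n_isis, dt,
                              seed = (seed + 15485863L + 37L * i) %% .Machine$integer.max)
    s <- serial_correlation(sim$isis, 1)
    data.frame(p_depl_1 = p1, p_depl_2 = p2, tau_repl_1 = t1,
               tau_repl_2 = t2, p_ratio = p1 / p2, tau_ratio = t1 / t2,
               src1 = s$src, src1_p = s$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "frac_strong_pos") <- mean(out$src1 > 0.05)
  out
}
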