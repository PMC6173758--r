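# Two-state (slow/fast) Markov switching model of spike generation.
#
# The hair-cell release machinery alternates between a slow state (mean
# exponential release wait tau_slow) and a fast state (tau_fast), with
# Markov switching rates k_sf (slow -> fast) and k_fs (fast -> slow). The
# afferent neuron adds a refractory period (t_abs + exponential relative
# part) after each spike; the hidden state keeps evolving during the
# refractory period (it is a presynaptic property). Simulation is exact in
# continuous time via competing exponential clocks: memorylessness lets the
# release clock be redrawn at each state switch without discretisation
# error.

#' Two-state switching model parameters
#'
#' @param k_sf Slow-to-fast switching rate, 1/ms.
#' @param k_fs Fast-to-slow switching rate, 1/ms.
#' @param tau_fast Mean release wait in the fast state, ms.
#' @param tau_slow Mean release wait in the slow state, ms
#'   (`tau_fast <= tau_slow`).
#' @param t_abs Absolute refractory period, ms.
#' @param tau_rel Mean relative refractory period, ms.
#' @return An object of class `switching_params`; `p_fast`, the stationary
#'   fraction of time in the fast state, is `k_sf / (k_sf + k_fs)`.
#' @export
switching_params <- function(k_sf = 1e-4, k_fs = NULL, tau_fast = 40,
                             tau_slow = 200, t_abs = 2, tau_rel = 2,
                             p_fast = NULL) {
  if (is.null(k_fs)) {
    if (is.null(p_fast)) stop("supply either k_fs or p_fast")
    # k_fs chosen so the stationary fast-state fraction equals p_fast
    k_fs <- if (p_fast <= 0) Inf else k_sf * (1 - p_fast) / p_fast
    if (p_fast >= 1) { k_fs <- 0 }
    if (p_fast <= 0) { k_fs <- k_sf; k_sf <- 0 }
  }
  stopifnot(k_sf >= 0, k_fs >= 0, tau_fast > 0, tau_slow > 0,
            t_abs >= 0, tau_rel >= 0)
  if (tau_fast > tau_slow) stop("convention requires tau_fast <= tau_slow")
  pf <- if (k_sf + k_fs > 0) k_sf / (k_sf + k_fs) else NA_real_
  structure(list(k_sf = k_sf, k_fs = k_fs, tau_fast = tau_fast,
                 tau_slow = tau_slow, t_abs = t_abs, tau_rel = tau_rel,
                 p_fast = pf),
            class = "switching_params")
}

.rexp_or_inf <- function(rate) {
  if (rate <= 0) Inf else stats::rexp(1, rate)
}

#' Simulate the two-state switching model
#'
#' @param params A [switching_params()] object.
#' @param n_isis Number of ISIs to generate.
#' @param seed Optional integer seed.
#' @param init_state Initial hidden state, `"slow"` or `"fast"`; defaults
#'   to a draw from the stationary distribution (avoids burn-in bias).
#'   Required when both switching rates are zero.
#' @param resample_per_interval If TRUE, the hidden state is redrawn
#'   independently for each interval with probability `p_fast` of being
#'   fast and frozen until the next spike. This variant has no serial
#'   dependence and its marginal ISI distribution is *exactly* the mapped
#'   two-exponential-mixture renewal model (see [equivalent_mixture()]);
#'   the continuous-time process instead weights the mixture by spike
#'   counts, over-representing the fast state.
#' @return A list of class `switching_trace`: `isis` (an `isi_seq`),
#'   `state_at_spike` (generating state per ISI), `switch_times` (absolute
#'   times of state switches, ms), and `params`.
#' @export
simulate_switching <- function(params, n_isis, seed = NULL,
                               init_state = NULL,
                               resample_per_interval = FALSE) {
  stopifnot(inherits(params, "switching_params"), n_isis >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  if (resample_per_interval) {
    if (is.na(p$p_fast)) stop("p_fast undefined (both switching rates zero)")
    fast <- stats::runif(n_isis) < p$p_fast
    rel <- if (p$tau_rel > 0) stats::rexp(n_isis, 1 / p$tau_rel) else 0
    wait <- stats::rexp(n_isis, 1 / ifelse(fast, p$tau_fast, p$tau_slow))
    return(structure(
      list(isis = isi_seq(p$t_abs + rel + wait),
           state_at_spike = ifelse(fast, "fast", "slow"),
           switch_times = numeric(0), params = p),
      class = "switching_trace"))
  }
  if (is.null(init_state)) {
    if (is.na(p$p_fast)) {
      stop("both switching rates are zero: an explicit init_state is required")
    }
    fast <- stats::runif(1) < p$p_fast
  } else {
    fast <- match.arg(init_state, c("slow", "fast")) == "fast"
  }

  out_rate <- c(p$k_sf, p$k_fs)        # index 1 = slow, 2 = fast
  rel_rate <- c(1 / p$tau_slow, 1 / p$tau_fast)

  isis <- numeric(n_isis)
  state_at_spike <- character(n_isis)
  switch_times <- numeric(0)
  t_now <- 0

  for (i in seq_len(n_isis)) {
    t_start <- t_now
    # refractory period; the hidden state keeps evolving underneath
    d <- p$t_abs + if (p$tau_rel > 0) stats::rexp(1, 1 / p$tau_rel) else 0
    remaining <- d
    repeat {
      h <- .rexp_or_inf(out_rate[fast + 1L])
      if (h >= remaining) break
      remaining <- remaining - h
      t_now <- t_now + h
      fast <- !fast
      switch_times <- c(switch_times, t_now)
    }
    t_now <- t_start + d
    # excitation wait: release clock vs switch clock
    repeat {
      t_release <- stats::rexp(1, rel_rate[fast + 1L])
      t_switch <- .rexp_or_inf(out_rate[fast + 1L])
      if (t_release <= t_switch) {
        t_now <- t_now + t_release
        break
      }
      t_now <- t_now + t_switch
      fast <- !fast
      switch_times <- c(switch_times, t_now)
    }
    isis[i] <- t_now - t_start
    state_at_spike[i] <- if (fast) "fast" else "slow"
  }

  structure(list(isis = isi_seq(isis), state_at_spike = state_at_spike,
                 switch_times = switch_times, params = p),
            class = "switching_trace")
}

#' Marginal ISI model equivalent to the switching model
#'
#' Ignoring serial dependence, the switching model's marginal ISI
#' distribution is the two-exponential-mixture renewal model with
#' `lambda_E1 = 1/tau_fast`, `lambda_E2 = 1/tau_slow`, `p = p_fast`
#' (exact in the fast-switching limit where the state is resampled every
#' interval).
#'
#' @param params A [switching_params()] object.
#' @return The corresponding [two_exp_mix_excitation()] object.
#' @export
equivalent_mixture <- function(params) {
  if (is.na(params$p_fast)) stop("p_fast undefined (both switching rates zero)")
  two_exp_mix_excitation(params$p_fast, 1 / params$tau_fast,
                         1 / params$tau_slow)
}

#' @rdname equivalent_mixture
#' @export
equivalent_renewal_model <- function(params) {
  renewal_model(refractory_params(params$t_abs, params$tau_rel),
                equivalent_mixture(params))
}

#' Serial-correlation sweep over switching-model parameters
#'
#' Runs `n_trials` independent simulations at every row of `param_grid`
#' and records SRC at each requested lag, for box-plot style summaries of
#' how serial correlation depends on switching rate, timescale ratio, and
#' state occupancy.
#'
#' @param param_grid A `data.frame`; columns with names matching
#'   [switching_params()] arguments override the defaults row-wise
#'   (`p_fast` may be given instead of `k_fs`).
#' @param n_trials Trials per grid point.
#' @param n_isis ISIs per trial.
#' @param lags SRC lags to record.
#' @param seed Base seed; trial seeds are derived deterministically.
#' @return Long-format `data.frame`: grid columns, `trial`, `lag`, `src`,
#'   `p_value`.
#' @export
src_sweep <- function(param_grid, n_trials = 100, n_isis = 5000,
                      lags = 1, seed = 1) {
  stopifnot(nrow(param_grid) >= 1)
  rows <- list()
  for (g in seq_len(nrow(param_grid))) {
    args <- as.list(param_grid[g, , drop = FALSE])
    sp <- do.call(switching_params, args)
    for (tr in seq_len(n_trials)) {
      trace <- simulate_switching(sp, n_isis,
                                  seed = (seed + 7919L * g + tr) %% .Machine$integer.max)
      for (lg in lags) {
        s <- serial_correlation(trace$isis, lg)
        rows[[length(rows) + 1L]] <- cbind(
          param_grid[g, , drop = FALSE],
          data.frame(trial = tr, lag = lg, src = s$src, p_value = s$p_value,
                     row.names = NULL))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
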