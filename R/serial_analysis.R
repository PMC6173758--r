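# Serial-dependence statistics for ISI sequences: serial correlation
# coefficients, the recurrence quartile matrix, short/long ISI sequence
# detection, and the Fano factor of spike counts.

#' Serial correlation coefficient SRC(n)
#'
#' Correlation between ISIs separated by `n` intermediate spikes, using the
#' global (population) mean and variance of the whole sequence and
#' averaging the lagged cross-products over the `M - n` available pairs.
#' Positive SRC(1) means long ISIs tend to follow long ones and short
#' follow short. Significance is the Pearson correlation p-value on the
#' lagged pair set under the null SRC(n) = 0.
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms.
#' @param lag Number of intermediate spikes `n` (>= 1).
#' @return A list with `lag`, `src`, `p_value`, `n_pairs`.
#' @export
serial_correlation <- function(isis, lag = 1) {
  x <- as.numeric(isis)
  M <- length(x)
  if (M <= lag + 1) stop("need more than lag + 1 ISIs")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) stop("serial correlation undefined: zero ISI variance")
  lead <- x[(lag + 1):M]
  trail <- x[1:(M - lag)]
  src <- mean((lead - m) * (trail - m)) / v
  pv <- stats::cor.test(trail, lead, method = "pearson")$p.value
  list(lag = lag, src = src, p_value = pv, n_pairs = M - lag)
}

#' Shuffle an ISI sequence
#'
#' Uniform random permutation; destroys serial structure while preserving
#' the ISI multiset (so the marginal distribution, mean, CV etc. are
#' unchanged).
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms.
#' @param seed Optional integer seed.
#' @export
shuffle_isis <- function(isis, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  isi_seq(sample(as.numeric(isis)))
}

#' Recurrence quartile matrix
#'
#' 4 x 4 matrix of fractions `q[i, j]`: the previous ISI lies in quartile
#' `i` and the next in quartile `j`, tallied over the `M - 1` consecutive
#' pairs. Under serial independence every entry is near 1/16. Quartile
#' membership uses type-1 quantile boundaries; a value equal to a boundary
#' belongs to the lower quartile.
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms (length >= 20).
#' @return A 4 x 4 numeric matrix summing to 1.
#' @export
recurrence_matrix <- function(isis) {
  x <- as.numeric(isis)
  M <- length(x)
  if (M < 20) stop("recurrence matrix requires at least 20 ISIs")
  Tk <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  if (any(duplicated(Tk))) {
    stop("degenerate quartiles: tied boundaries at ",
         paste(unique(Tk[duplicated(Tk)]), collapse = ", "), " ms")
  }
  qrt <- 1L + (x > Tk[1]) + (x > Tk[2]) + (x > Tk[3])
  prev <- qrt[-M]
  nxt <- qrt[-1]
  q <- matrix(0, 4, 4)
  for (k in seq_len(M - 1)) q[prev[k], nxt[k]] <- q[prev[k], nxt[k]] + 1
  q / (M - 1)
}

#' Detect sequences of short and long ISIs
#'
#' ISIs are classed as short (below the global mean) or long (at or above
#' it); `mu_short` / `mu_long` are the means of the two classes. A maximal
#' same-class run of length >= `min_run` is accepted as a *sequence* when
#' its within-run mean is at or below `mu_short` (short runs) or at or
#' above `mu_long` (long runs); the inclusive comparison keeps the
#' degenerate case where one run holds the entire class. The scan is
#' greedy left-to-right with no overlaps.
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms (length >= 10).
#' @param min_run Minimum run length for a sequence (default 2).
#' @return A list with `runs` (data.frame: `start`, `end`, `label`),
#'   `mu_short`, `mu_long`, `frac_in_short`, `frac_in_long`.
#' @export
detect_sequences <- function(isis, min_run = 2) {
  x <- as.numeric(isis)
  M <- length(x)
  if (M < 10) stop("sequence detection requires at least 10 ISIs")
  m <- mean(x)
  short <- x < m
  if (!any(short) || all(short)) {
    stop("sequence detection undefined: short or long ISI class is empty")
  }
  mu_short <- mean(x[short])
  mu_long <- mean(x[!short])

  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run
  runs <- data.frame(start = integer(0), end = integer(0),
                     label = character(0), stringsAsFactors = FALSE)
  n_short <- 0L
  n_long <- 0L
  for (i in which(keep)) {
    seg <- x[starts[i]:ends[i]]
    if (r$values[i] && mean(seg) <= mu_short) {
      runs <- rbind(runs, data.frame(start = starts[i], end = ends[i],
                                     label = "short", stringsAsFactors = FALSE))
      n_short <- n_short + length(seg)
    } else if (!r$values[i] && mean(seg) >= mu_long) {
      runs <- rbind(runs, data.frame(start = starts[i], end = ends[i],
                                     label = "long", stringsAsFactors = FALSE))
      n_long <- n_long + length(seg)
    }
  }
  list(runs = runs, mu_short = mu_short, mu_long = mu_long,
       frac_in_short = n_short / M, frac_in_long = n_long / M)
}

#' Fano factor of spike counts
#'
#' Variance-to-mean ratio of the number of spikes in sliding windows of
#' length `dt`, for each `dt` in `dt_list`. Windows lie fully inside the
#' recording and advance by `stride_frac * dt` (overlapping windows). A
#' homogeneous Poisson train has F(dt) = 1 at every window size; switching
#' or drifting rates inflate F at long windows.
#'
#' @param train A `spike_train` or numeric vector of spike times, ms.
#' @param dt_list Counting-window lengths, ms.
#' @param stride_frac Window stride as a fraction of `dt` (default 0.1).
#' @return A `data.frame` with columns `dt`, `fano`, `n_windows`; `fano`
#'   is NA where the mean count is zero.
#' @export
fano_factor <- function(train, dt_list, stride_frac = 0.1) {
  times <- as.numeric(train)
  if (length(times) < 2) stop("need at least 2 spikes")
  t0 <- times[1]
  t1 <- times[length(times)]
  if ((t1 - t0) < 10 * max(dt_list)) {
    stop("recording must be at least 10x the largest counting window")
  }
  rows <- lapply(dt_list, function(dt) {
    starts <- seq(t0, t1 - dt, by = dt * stride_frac)
    counts <- findInterval(starts + dt, times) - findInterval(starts, times)
    mu <- mean(counts)
    data.frame(dt = dt,
               fano = if (mu == 0) NA_real_ else stats::var(counts) / mu,
               n_windows = length(starts))
  })
  do.call(rbind, rows)
}

#' Serial-statistics report for one ISI sequence
#'
#' Convenience bundle: SRC at the requested lags with p-values, the
#' recurrence quartile matrix, and sequence fractions.
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms.
#' @param lags Lags for SRC (default `c(1, 5, 10, 50)`).
#' @return A list with `src` (data.frame `lag`, `src`, `p_value`),
#'   `recurrence` (4 x 4 matrix), `sequences` (see [detect_sequences()]).
#' @export
serial_stats <- function(isis, lags = c(1, 5, 10, 50)) {
  src <- do.call(rbind, lapply(lags, function(n) {
    s <- serial_correlation(isis, n)
    data.frame(lag = n, src = s$src, p_value = s$p_value)
  }))
  list(src = src,
       recurrence = recurrence_matrix(isis),
       sequences = detect_sequences(isis))
}
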