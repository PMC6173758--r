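#' Construct a spike train
#'
#' A spike train is an ordered vector of spike timestamps in milliseconds.
#' Timestamps must be strictly increasing; at least two spikes are required
#' to produce any interspike interval (ISI).
#'
#' @param times Numeric vector of spike times, ms, strictly increasing.
#' @return An object of class `spike_train` (a numeric vector).
#' @export
spike_train <- function(times) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1L
    stop(sprintf("spike times must be strictly increasing (violation at position %d)", bad))
  }
  structure(times, class = "spike_train")
}

#' Construct an ISI sequence
#'
#' An ISI sequence holds interval durations (ms) in their original temporal
#' order; order is meaningful for serial statistics and is only discarded
#' inside CDF/quartile computations.
#'
#' @param isis Numeric vector of interval durations, ms, all > 0.
#' @return An object of class `isi_seq` (a numeric vector).
#' @export
isi_seq <- function(isis) {
  isis <- as.numeric(isis)
  if (length(isis) < 1) stop("ISI sequence must contain at least one interval")
  if (anyNA(isis) || any(isis <= 0)) stop("all ISIs must be positive and non-missing")
  structure(isis, class = "isi_seq")
}

#' Interspike intervals from a spike train
#'
#' @param train A `spike_train` or numeric vector of strictly increasing
#'   spike times, ms.
#' @return An `isi_seq` of the successive differences, in temporal order.
#' @export
isis_from_spikes <- function(train) {
  times <- as.numeric(train)
  if (length(times) < 2) stop("need at least 2 spikes to form ISIs")
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  isi_seq(diff(times))
}

#' Reconstruct spike times from an ISI sequence
#'
#' Inverse of [isis_from_spikes()] up to the (lost) time of the first spike.
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms.
#' @param t0 Time of the first spike, ms.
#' @return A `spike_train`.
#' @export
spikes_from_isis <- function(isis, t0 = 0) {
  spike_train(t0 + c(0, cumsum(as.numeric(isis))))
}

#' Empirical cumulative distribution function of ISIs
#'
#' Right-continuous step function: 0 below the smallest ISI, n/M between the
#' n-th and (n+1)-th order statistics, 1 above the largest. Repeated values
#' step by their multiplicity.
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms.
#' @return A function of class `ecdf` mapping time (ms) to the fraction of
#'   ISIs less than or equal to it.
#' @export
empirical_cdf <- function(isis) {
  x <- as.numeric(isis)
  if (length(x) < 1) stop("empirical CDF requires at least one ISI")
  stats::ecdf(x)
}

#' Summary statistics of an ISI distribution
#'
#' Mean (ms), coefficient of variation (sd/mean), and raw kurtosis: the
#' fourth standardized moment without excess subtraction or bias correction,
#' so exponentially distributed data have CV = 1 and kurtosis = 9.
#'
#' @param isis An `isi_seq` or numeric vector of ISIs, ms (length >= 4).
#' @return A list with elements `mean`, `cv`, `kurtosis`, and `n`.
#' @export
summary_stats <- function(isis) {
  x <- as.numeric(isis)
  if (length(x) < 4) stop("summary statistics require at least 4 ISIs")
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)      # population moments throughout
  cv <- sqrt(v) / m
  kurt <- if (v == 0) NA_real_ else mean(d^4) / v^2
  list(mean = m, cv = cv, kurtosis = kurt, n = length(x))
}

#' Read a spike-time or ISI file
#'
#' Accepts UTF-8 text with one timestamp (ms) per line, `#` comment lines,
#' and an optional single header line. A CSV with a `time_ms` (or `isi_ms`)
#' column is also accepted.
#'
#' @param path File path.
#' @return A `spike_train`.
#' @export
read_spike_file <- function(path) {
  vals <- .read_numeric_column(path, c("time_ms"))
  bad <- which(diff(vals$values) <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-monotone spike times at line %d of %s",
                 vals$lines[bad[1] + 1L], path))
  }
  spike_train(vals$values)
}

#' @rdname read_spike_file
#' @export
read_isi_file <- function(path) {
  vals <- .read_numeric_column(path, c("isi_ms"))
  isi_seq(vals$values)
}

.read_numeric_column <- function(path, header_names) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))
  if (length(keep) == 0) stop("no data lines in ", path)
  lines <- raw[keep]
  first <- trimws(lines[1])
  # CSV with a named column, or a bare single-token header
  if (grepl(",", first) || first %in% header_names) {
    if (grepl(",", first)) {
      df <- utils::read.csv(text = lines, header = TRUE)
      col <- intersect(header_names, names(df))
      if (length(col) == 0) stop("no '", header_names[1], "' column in ", path)
      return(list(values = as.numeric(df[[col[1]]]), lines = keep[-1]))
    }
    lines <- lines[-1]
    keep <- keep[-1]
  } else if (is.na(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]  # tolerate one non-numeric header token
    keep <- keep[-1]
  }
  vals <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(vals)) {
    stop(sprintf("unparseable value at line %d of %s", keep[which(is.na(vals))[1]], path))
  }
  list(values = vals, lines = keep)
}

#' Write a spike train (or ISI sequence) to a text file
#'
#' One value per line, ms, with a `time_ms`/`isi_ms` header so files
#' round-trip through [read_spike_file()] / [read_isi_file()].
#'
#' @param x A `spike_train` or `isi_seq`.
#' @param path Output file path.
#' @export
write_spike_file <- function(x, path) {
  header <- if (inherits(x, "isi_seq")) "isi_ms" else "time_ms"
  writeLines(c(header, format(as.numeric(x), digits = 15, trim = TRUE,
                              scientific = FALSE)), path)
  invisible(path)
}
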