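#' Construct an end-tidal CO2 trace
#'
#' Container for a sampled end-tidal CO2 (etCO2) partial-pressure trace, the
#' source of the stimulus regressor used in CVR estimation.
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param etco2_mmHg etCO2 values in mmHg, all positive.
#' @return A data frame of class `etco2_trace` with columns `time_s` and
#'   `etco2_mmHg`.
#' @export
etco2_trace <- function(time_s, etco2_mmHg) {
  stopifnot(is.numeric(time_s), is.numeric(etco2_mmHg))
  if (length(time_s) != length(etco2_mmHg))
    stop("`time_s` and `etco2_mmHg` must have equal length")
  if (any(!is.finite(time_s)) || any(!is.finite(etco2_mmHg)))
    stop("etCO2 trace must be finite")
  if (any(diff(time_s) <= 0))
    stop("`time_s` must be strictly increasing")
  if (any(etco2_mmHg <= 0))
    stop("etCO2 values must be positive (partial pressure in mmHg)")
  structure(data.frame(time_s = time_s, etco2_mmHg = etco2_mmHg),
            class = c("etco2_trace", "data.frame"))
}

.trace_values <- function(trace) {
  if (is.data.frame(trace)) trace$etco2_mmHg else as.numeric(trace)
}

.trace_times <- function(trace) {
  if (is.data.frame(trace)) trace$time_s else stop("trace has no time axis")
}

#' Hypercapnic challenge amplitude of an etCO2 trace
#'
#' The challenge amplitude (delta-etCO2) is the difference between the mean
#' of the highest 25% and the mean of the lowest 25% of the etCO2 samples.
#' With `k = max(1, floor(N / 4))` samples in each tail, this is robust to the
#' exact block timing and is the subject-level covariate entered into the
#' voxel-wise mixed models.
#'
#' @param trace An [etco2_trace()] or a numeric vector of etCO2 values (mmHg).
#' @param window Optional `c(start_s, end_s)` restricting the computation to
#'   a time window (e.g. the hypercapnic challenge only). Requires a trace
#'   with a time axis. Default: full trace.
#' @return Challenge amplitude in mmHg (non-negative scalar).
#' @export
delta_etco2 <- function(trace, window = NULL) {
  values <- .trace_values(trace)
  if (!is.null(window)) {
    times <- .trace_times(trace)
    stopifnot(length(window) == 2, window[1] < window[2])
    values <- values[times >= window[1] & times <= window[2]]
  }
  n <- length(values)
  if (n < 8)
    stop("delta_etco2 requires at least 8 samples, got ", n)
  k <- max(1L, floor(n / 4))
  s <- sort(values)
  mean(s[(n - k + 1L):n]) - mean(s[1:k])
}

#' Resample an etCO2 trace onto the BOLD acquisition grid
#'
#' Linearly interpolates the trace onto the volume mid-times
#' `(i - 0.5) * tr_s`, after applying an optional bulk delay, and centres the
#' result on its median. The median is preferred over the mean because block
#' designs spend unequal time at the baseline and hypercapnic levels.
#'
#' A positive `shift_s` delays the trace (models the hemodynamic lag of the
#' BOLD response behind the gas challenge): the regressor at volume time `t`
#' takes the trace value at `t - shift_s`.
#'
#' @param trace An [etco2_trace()].
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of BOLD volumes.
#' @param shift_s Bulk delay applied to the trace, seconds. Default 0.
#' @return An object of class `cvr_regressor`: list with `values` (mmHg,
#'   median-centred, length `n_volumes`), `tr_s`, and `shift_s`.
#' @export
to_regressor <- function(trace, tr_s, n_volumes, shift_s = 0) {
  stopifnot(tr_s > 0, n_volumes >= 1)
  times <- .trace_times(trace)
  values <- .trace_values(trace)
  t_query <- (seq_len(n_volumes) - 0.5) * tr_s - shift_s
  if (min(t_query) < min(times) || max(t_query) > max(times))
    stop("trace does not cover the acquisition window after shifting by ",
         shift_s, " s")
  v <- approx(times, values, xout = t_query, method = "linear")$y
  structure(list(values = v - median(v), tr_s = tr_s, shift_s = shift_s),
            class = "cvr_regressor")
}

.regressor_values <- function(regressor) {
  if (inherits(regressor, "cvr_regressor")) regressor$values
  else as.numeric(regressor)
}

#' Estimate the bulk delay between a BOLD signal and the etCO2 trace
#'
#' Grid search (step `tr_s / 2`) for the trace delay maximising the Pearson
#' correlation between the mean BOLD signal and the delayed, resampled trace.
#' A positive result means the BOLD signal lags the trace; feed it to
#' [to_regressor()] as `shift_s`. Off by default in the fitting pipeline:
#' real acquisitions normally align the trace upstream.
#'
#' @param bold_global_signal Numeric vector, e.g. the mean signal over a
#'   brain mask, one value per volume.
#' @param trace An [etco2_trace()] covering the acquisition (with margin for
#'   the searched shifts).
#' @param tr_s Repetition time, seconds.
#' @param search_window_s Half-width of the searched delay range, seconds.
#' @return Estimated delay in seconds. If the optimum sits on the search
#'   boundary a warning is emitted and the attribute `at_boundary` is `TRUE`.
#' @export
estimate_bulk_shift <- function(bold_global_signal, trace, tr_s,
                                search_window_s = 20) {
  y <- as.numeric(bold_global_signal)
  if (length(y) < 20 || nrow(trace) < 20)
    stop("bulk shift estimation needs at least 20 samples in both series")
  if (sd(y) == 0 || sd(.trace_values(trace)) == 0)
    stop("cannot estimate a shift from a flat series")
  shifts <- seq(-search_window_s, search_window_s, by = tr_s / 2)
  times <- .trace_times(trace)
  t_vol <- (seq_len(length(y)) - 0.5) * tr_s
  cors <- vapply(shifts, function(s) {
    tq <- t_vol - s
    if (min(tq) < min(times) || max(tq) > max(times)) return(NA_real_)
    v <- approx(times, .trace_values(trace), xout = tq)$y
    if (sd(v) == 0) return(NA_real_)
    cor(y, v)
  }, numeric(1))
  if (all(is.na(cors)))
    stop("trace does not cover the acquisition window for any searched shift")
  best <- which.max(cors)  # ties: smallest index = most negative shift
  shift <- shifts[best]
  at_boundary <- best == 1L || best == length(shifts) ||
    is.na(cors[best - 1L]) || is.na(cors[best + 1L])
  if (at_boundary)
    warning("bulk shift estimate lies on the search boundary (",
            signif(shift, 3), " s); result is unreliable")
  structure(shift, at_boundary = at_boundary,
            correlation = cors[best])
}
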