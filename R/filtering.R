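#' Band-pass and notch filtering of raw voltage traces
#'
#' Conditions raw extracellular recordings before spike detection: a
#' fourth-order Butterworth band-pass (default 20-2000 Hz) removes drift and
#' high-frequency noise, and a notch at 60 Hz removes mains hum. Both are
#' applied forward-backward ([signal::filtfilt()]) so the filtering is
#' zero-phase and spike peak times are not shifted.
#'
#' @param trace numeric vector or samples x channels matrix.
#' @param sampling_rate samples per second; must be at least twice the upper
#'   band edge.
#' @param band two-element numeric, band-pass edges in Hz.
#' @param order Butterworth order of the band-pass.
#' @param notch_freq centre of the notch in Hz (0 disables).
#' @param notch_width half-bandwidth of the notch in Hz.
#' @return filtered trace, same shape as the input; the `sampling_rate`
#'   attribute is preserved.
#' @export
bandpass_and_notch <- function(trace, sampling_rate = attr(trace, "sampling_rate"),
                               band = c(20, 2000), order = 4,
                               notch_freq = 60, notch_width = 2) {
  if (is.null(sampling_rate)) stop("`sampling_rate` is required")
  if (sampling_rate < 2 * max(band)) {
    stop("sampling_rate (", sampling_rate,
         " Hz) is below the Nyquist requirement for a ", max(band),
         " Hz band edge")
  }
  nyq <- sampling_rate / 2
  bp <- signal::butter(order, band / nyq, type = "pass")
  filters <- list(bp)
  if (notch_freq > 0) {
    nf <- signal::butter(2, c(notch_freq - notch_width, notch_freq + notch_width) / nyq,
                         type = "stop")
    filters <- c(filters, list(nf))
  }
  # odd-reflection padding suppresses the forward-backward filter's edge
  # transients (notch ringing at the trace boundaries would otherwise cross
  # the detection threshold)
  pad <- min(as.integer(sampling_rate / 2), 10000L)
  apply_one <- function(x) {
    n <- length(x)
    p <- min(pad, n - 1L)
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    for (f in filters) xp <- signal::filtfilt(f, xp)
    xp[(p + 1):(p + n)]
  }
  out <- if (is.matrix(trace)) apply(trace, 2, apply_one) else apply_one(trace)
  attr(out, "sampling_rate") <- sampling_rate
  out
}

#' Adaptive-threshold spike detection
#'
#' Detects extracellular spikes with a per-channel adaptive threshold:
#' within each non-overlapping 10-s window the background-noise SD is
#' estimated robustly (median absolute deviation / 0.6745, insensitive to
#' the spikes themselves) and the threshold is `threshold_sd` times that
#' estimate. Each excursion of |V| above threshold contributes exactly one
#' spike, timed at the sample of its absolute maximum; spikes closer than
#' `dedup` to the previous retained spike are discarded so a single
#' multiphasic waveform is never counted twice.
#'
#' @param trace numeric vector or samples x channels matrix (filtered; see
#'   [bandpass_and_notch()]).
#' @param sampling_rate samples per second.
#' @param threshold_sd threshold in units of the noise SD (default 4.5).
#' @param window_s noise-estimation window, seconds (default 10). A trailing
#'   partial window shares the last full window's threshold; a trace shorter
#'   than one window is treated as a single window.
#' @param dedup minimum inter-spike interval, seconds (default 0.002).
#' @return a [spike_raster()] with provenance `"recorded"`, one source per
#'   channel, and `duration` equal to the trace duration.
#' @export
detect_spikes <- function(trace, sampling_rate = attr(trace, "sampling_rate"),
                          threshold_sd = 4.5, window_s = 10, dedup = 0.002) {
  if (is.null(sampling_rate)) stop("`sampling_rate` is required")
  if (!is.matrix(trace)) trace <- matrix(trace, ncol = 1)
  if (anyNA(trace)) stop("trace contains NA/NaN samples")
  n_samp <- nrow(trace)
  duration <- n_samp / sampling_rate
  win <- max(1L, round(window_s * sampling_rate))
  starts <- seq.int(1L, n_samp, by = win)
  # drop a trailing fragment shorter than the window: it reuses the previous
  # threshold
  spikes <- lapply(seq_len(ncol(trace)), function(ch) {
    x <- trace[, ch]
    thr <- numeric(n_samp)
    last_t <- NA_real_
    for (s in starts) {
      e <- min(s + win - 1L, n_samp)
      t_w <- threshold_sd * stats::mad(x[s:e], constant = 1 / 0.6745)
      if ((e - s + 1L) < win && !is.na(last_t)) t_w <- last_t
      thr[s:e] <- t_w
      last_t <- t_w
    }
    over <- abs(x) > thr
    if (!any(over)) return(numeric(0))
    r <- rle(over)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    runs <- which(r$values)
    peak_idx <- vapply(runs, function(k) {
      i0 <- begins[k]; i1 <- ends[k]
      i0 + which.max(abs(x[i0:i1])) - 1L
    }, integer(1))
    times <- (peak_idx - 1L) / sampling_rate
    times[enforce_refractory_keep(times, dedup)]
  })
  names(spikes) <- if (!is.null(colnames(trace))) colnames(trace) else
    sprintf("ch%d", seq_along(spikes))
  spike_raster(spikes, duration, provenance = "recorded")
}

enforce_refractory_keep <- function(times, refractory) {
  if (length(times) < 2L) return(rep(TRUE, length(times)))
  dedup_times(as.numeric(times), as.numeric(refractory))
}
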