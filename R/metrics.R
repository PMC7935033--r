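#' Firing rate of a spike train
#'
#' @param times spike times, seconds.
#' @param duration recording duration, seconds (> 0).
#' @return rate in Hz: `length(times) / duration`.
#' @export
spike_rate <- function(times, duration) {
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  length(times) / duration
}

#' Interspike-interval statistics
#'
#' ISIs are the successive differences of the spike times; the coefficient
#' of variation is the sample SD of the ISIs divided by their mean. A long
#' Poisson train has CV near 1, a clock-regular train has CV 0, a bursty
#' train has CV above 1. Statistics that are undefined at the given spike
#' count (mean needs >= 2 spikes, CV >= 3) are returned as `NA` rather than
#' silently zero.
#'
#' @param times sorted spike times, seconds.
#' @return list with `mean_isi`, `cv_isi`, `n_isi`.
#' @export
isi_statistics <- function(times) {
  isi <- diff(times)
  mean_isi <- if (length(isi) >= 1L) mean(isi) else NA_real_
  cv_isi <- if (length(isi) >= 2L && mean(isi) > 0) {
    stats::sd(isi) / mean(isi)
  } else {
    NA_real_
  }
  list(mean_isi = mean_isi, cv_isi = cv_isi, n_isi = length(isi))
}

#' Fano factor of a spike train
#'
#' Variance-to-mean ratio of spike counts in non-overlapping bins of
#' `bin_width` seconds; 1 for a Poisson process, below 1 for regular firing,
#' above 1 for clustered/bursty firing. The recording is truncated to a
#' whole number of bins. Undefined (no spikes, or fewer than two bins)
#' yields `NA`.
#'
#' @param times spike times, seconds.
#' @param duration recording duration, seconds.
#' @param bin_width counting-window width, seconds (default 1).
#' @return Fano factor (dimensionless) or `NA`.
#' @export
fano_factor <- function(times, duration, bin_width = 1) {
  if (duration < 2 * bin_width) stop("duration must cover at least 2 bins")
  n_bins <- floor(duration / bin_width)
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  times <- times[times < n_bins * bin_width]
  counts <- tabulate(findInterval(times, edges, left.open = FALSE),
                     nbins = n_bins)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Select active sources by the 75th-percentile rule
#'
#' A source (electrode) is active when its firing rate is at or above the
#' 75th percentile of the rate distribution across sources, the percentile
#' being computed with linear interpolation ([stats::quantile()] type 7).
#' With tied rates every source can qualify; a single source always does.
#'
#' @param rates named numeric vector of firing rates (Hz).
#' @param prob percentile defining activity (default 0.75).
#' @return names (or indices, when unnamed) of the active sources.
#' @export
active_sources <- function(rates, prob = 0.75) {
  if (!length(rates)) stop("need at least one source")
  thr <- stats::quantile(rates, prob, type = 7, names = FALSE)
  idx <- which(rates >= thr)
  if (!is.null(names(rates))) names(rates)[idx] else idx
}

burst_event <- function(start, end, n, indices, kind) {
  list(start = start, end = end, n_spikes = n, indices = indices, kind = kind)
}

#' Detect burstlets on a single electrode
#'
#' Implements the per-electrode burst rule used for MEA recordings
#' (following Wagenaar-style burst detection): a core is a run of at least
#' `min_core_spikes` spikes whose successive ISIs are all at most the lesser
#' of `core_cap` (100 ms) and a quarter of the electrode's mean ISI
#' (`1 / (4 * rate)`); peripheral spikes are then appended at either end
#' while their ISI to the burst is at most the lesser of `peri_cap` (200 ms)
#' and a third of the mean ISI (`1 / (3 * rate)`). Burstlets are maximal and
#' non-overlapping; cores whose peripheral extensions meet are merged.
#'
#' @param times sorted spike times, seconds.
#' @param electrode_rate the electrode's firing rate in Hz (> 0); sets the
#'   rate-adaptive part of both thresholds.
#' @param min_core_spikes minimum spikes in a core (default 4).
#' @param core_cap absolute cap on the core ISI threshold, seconds.
#' @param peri_cap absolute cap on the peripheral ISI threshold, seconds.
#' @return list of burst events, each with `start`, `end`, `n_spikes`,
#'   `indices` (into `times`) and `kind = "burstlet"`.
#' @export
detect_burstlets <- function(times, electrode_rate,
                             min_core_spikes = 4,
                             core_cap = 0.1, peri_cap = 0.2) {
  if (electrode_rate <= 0) stop("`electrode_rate` must be > 0")
  n <- length(times)
  if (n < min_core_spikes) return(list())
  core_thr <- min(core_cap, 1 / (4 * electrode_rate))
  peri_thr <- min(peri_cap, 1 / (3 * electrode_rate))
  isi <- diff(times)
  close_core <- isi <= core_thr
  r <- rle(close_core)
  run_end <- cumsum(r$lengths)
  run_begin <- run_end - r$lengths + 1L
  cores <- which(r$values & r$lengths >= (min_core_spikes - 1L))
  if (!length(cores)) return(list())
  events <- list()
  for (k in cores) {
    i0 <- run_begin[k]          # first spike of core
    i1 <- run_end[k] + 1L       # last spike of core
    while (i0 > 1L && isi[i0 - 1L] <= peri_thr) i0 <- i0 - 1L
    while (i1 < n && isi[i1] <= peri_thr) i1 <- i1 + 1L
    m <- length(events)
    if (m > 0L && i0 <= events[[m]]$indices[length(events[[m]]$indices)]) {
      # peripheral extensions touched the previous burstlet: merge
      i0 <- events[[m]]$indices[1L]
      events[[m]] <- burst_event(times[i0], times[i1], i1 - i0 + 1L,
                                 i0:i1, "burstlet")
    } else {
      events[[m + 1L]] <- burst_event(times[i0], times[i1], i1 - i0 + 1L,
                                      i0:i1, "burstlet")
    }
  }
  events
}

#' Detect network bursts in a pooled raster
#'
#' A network burst is a population event with at least `min_spikes` spikes
#' (default 50) inside a sliding window of `window` seconds (default 50 ms)
#' over the spikes pooled across all sources. Every window position that
#' satisfies the rule is found, overlapping qualifying windows are merged,
#' and each merged event is reported with the times of its first and last
#' member spike.
#'
#' @param raster a [spike_raster()], or a sorted numeric vector of pooled
#'   spike times.
#' @param min_spikes minimum spikes per window (default 50).
#' @param window window length, seconds (default 0.05).
#' @return list of burst events (`start`, `end`, `n_spikes`, `indices` into
#'   the pooled train, `kind = "network_burst"`).
#' @export
detect_network_bursts <- function(raster, min_spikes = 50, window = 0.05) {
  pooled <- if (is_spike_raster(raster)) pool_spikes(raster) else
    sort(as.numeric(raster))
  n <- length(pooled)
  if (n < min_spikes) return(list())
  # count of spikes in [t_i, t_i + window): windows anchored at spikes are
  # sufficient, the count is maximal when the window starts on a spike
  upper <- findInterval(pooled + window, pooled, left.open = TRUE)
  in_win <- upper - seq_len(n) + 1L
  qualifies <- which(in_win >= min_spikes)
  if (!length(qualifies)) return(list())
  events <- list()
  cur_first <- qualifies[1L]
  cur_last_idx <- upper[qualifies[1L]]
  for (q in qualifies[-1L]) {
    if (q <= cur_last_idx) {
      cur_last_idx <- max(cur_last_idx, upper[q])
    } else {
      events[[length(events) + 1L]] <- burst_event(
        pooled[cur_first], pooled[cur_last_idx],
        cur_last_idx - cur_first + 1L, cur_first:cur_last_idx,
        "network_burst")
      cur_first <- q
      cur_last_idx <- upper[q]
    }
  }
  events[[length(events) + 1L]] <- burst_event(
    pooled[cur_first], pooled[cur_last_idx],
    cur_last_idx - cur_first + 1L, cur_first:cur_last_idx, "network_burst")
  events
}

#' Interburst intervals
#'
#' Time between successive burst events, measured onset to onset.
#'
#' @param bursts list of burst events as returned by
#'   [detect_network_bursts()] or [detect_burstlets()].
#' @return numeric vector of intervals, seconds (length `length(bursts) - 1`).
#' @export
interburst_intervals <- function(bursts) {
  if (length(bursts) < 2L) return(numeric(0))
  diff(vapply(bursts, `[[`, 0, "start"))
}

#' Per-source spike-train metrics table
#'
#' Computes, for every source of a raster, the spike count, firing rate,
#' mean ISI, CV of the ISI, Fano factor and burstlet rate. Undefined
#' statistics are `NA`.
#'
#' @param raster a [spike_raster()].
#' @param bin_width Fano-factor counting window, seconds (default 1).
#' @return data frame with one row per source.
#' @export
train_metrics <- function(raster, bin_width = 1) {
  stopifnot(is_spike_raster(raster))
  rows <- lapply(names(raster$spikes), function(id) {
    tt <- raster$spikes[[id]]
    rate <- spike_rate(tt, raster$duration)
    isi <- isi_statistics(tt)
    ff <- fano_factor(tt, raster$duration, bin_width)
    nb <- if (rate > 0) length(detect_burstlets(tt, rate)) else 0L
    data.frame(source_id = id, n_spikes = length(tt), spike_rate = rate,
               mean_isi = isi$mean_isi, cv_isi = isi$cv_isi,
               fano_factor = ff,
               burstlet_rate = nb / raster$duration * 60,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a per-source metrics table as delimited text
#'
#' @param metrics data frame from [train_metrics()].
#' @param path file path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
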