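#' Specification for a synthetic spike raster
#'
#' Describes a ground-truth raster: homogeneous-Poisson background activity
#' per source, optional bursts inserted as compound events, and optional
#' pairwise correlation with planted community structure. Correlation is
#' produced by a shared "mother" Poisson train per group: each group member
#' keeps each mother spike with probability `share_prob` (jittered by a
#' zero-mean Gaussian of SD `jitter`) and receives an independent Poisson
#' train at rate `base_rate * (1 - share_prob)`, so every source keeps an
#' expected total rate of `base_rate` while within-group pairs share spikes.
#'
#' @param n_sources number of sources (electrodes/neurons).
#' @param duration recording duration, seconds.
#' @param base_rate background firing rate per source, Hz.
#' @param burst_spec optional list with elements `rate` (bursts per second),
#'   `n_spikes` (spikes per burst) and `isi` (intra-burst inter-spike
#'   interval, seconds).
#' @param correlation_spec optional list with elements `groups` (integer
#'   group label per source, length `n_sources`), `share_prob` (within-group
#'   spike-sharing probability in `[0, 1]`) and `jitter` (SD of spike-time
#'   jitter, seconds).
#' @param seed integer seed; identical spec + seed reproduces the raster
#'   exactly.
#' @return a list of class `raster_spec`.
#' @seealso [generate_raster()]
#' @export
raster_spec <- function(n_sources, duration, base_rate,
                        burst_spec = NULL, correlation_spec = NULL,
                        seed = 1L) {
  if (!is.numeric(n_sources) || n_sources < 1 || n_sources != round(n_sources)) {
    stop("invalid `n_sources`: must be a positive integer")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("invalid `duration`: must be > 0")
  }
  if (!is.numeric(base_rate) || base_rate < 0) {
    stop("invalid `base_rate`: must be >= 0")
  }
  if (!is.null(burst_spec)) {
    need <- c("rate", "n_spikes", "isi")
    if (!all(need %in% names(burst_spec))) {
      stop("invalid `burst_spec`: needs fields rate, n_spikes, isi")
    }
    if (burst_spec$rate < 0) stop("invalid `burst_spec`: rate must be >= 0")
    if (burst_spec$n_spikes < 1) stop("invalid `burst_spec`: n_spikes must be >= 1")
    if (burst_spec$isi <= 0) stop("invalid `burst_spec`: isi must be > 0")
  }
  if (!is.null(correlation_spec)) {
    need <- c("groups", "share_prob", "jitter")
    if (!all(need %in% names(correlation_spec))) {
      stop("invalid `correlation_spec`: needs fields groups, share_prob, jitter")
    }
    if (length(correlation_spec$groups) != n_sources) {
      stop("invalid `correlation_spec`: groups must have length n_sources")
    }
    p <- correlation_spec$share_prob
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("invalid `correlation_spec`: share_prob must be in [0, 1]")
    }
    if (correlation_spec$jitter < 0) {
      stop("invalid `correlation_spec`: jitter must be >= 0")
    }
  }
  structure(list(n_sources = as.integer(n_sources), duration = duration,
                 base_rate = base_rate, burst_spec = burst_spec,
                 correlation_spec = correlation_spec, seed = as.integer(seed)),
            class = "raster_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

poisson_train <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * duration)
  sort(stats::runif(n, 0, duration))
}

# absolute refractory period: greedily drop spikes closer than `refractory`
# to the last retained spike
enforce_refractory <- function(times, refractory = 0.002) {
  times[enforce_refractory_keep(times, refractory)]
}

#' Generate a synthetic spike raster with known ground truth
#'
#' Draws the raster described by a [raster_spec()]: Poisson background,
#' optional compound bursts unioned with the background, and optional
#' mother-train correlation structure. A 2-ms absolute refractory period is
#' imposed on every generated train, matching the duplicate-spike rule the
#' analysis side applies.
#'
#' @param spec a [raster_spec()].
#' @return a [spike_raster()] with provenance `"synthetic"`. The planted
#'   group labels (if any) are attached as attribute `"groups"`.
#' @examples
#' r <- generate_raster(raster_spec(4, duration = 10, base_rate = 2, seed = 1))
#' n_spikes(r)
#' @export
generate_raster <- function(spec) {
  if (!inherits(spec, "raster_spec")) spec <- do.call(raster_spec, spec)
  with_seed(spec$seed, {
    n <- spec$n_sources
    cs <- spec$correlation_spec
    trains <- vector("list", n)
    if (is.null(cs) || cs$share_prob == 0) {
      for (i in seq_len(n)) trains[[i]] <- poisson_train(spec$base_rate, spec$duration)
    } else {
      mothers <- lapply(sort(unique(cs$groups)), function(g)
        poisson_train(spec$base_rate, spec$duration))
      names(mothers) <- as.character(sort(unique(cs$groups)))
      for (i in seq_len(n)) {
        m <- mothers[[as.character(cs$groups[i])]]
        keep <- m[stats::runif(length(m)) < cs$share_prob]
        if (cs$jitter > 0 && length(keep)) {
          keep <- keep + stats::rnorm(length(keep), 0, cs$jitter)
        }
        own <- poisson_train(spec$base_rate * (1 - cs$share_prob), spec$duration)
        trains[[i]] <- sort(c(keep, own))
      }
    }
    if (!is.null(spec$burst_spec) && spec$burst_spec$rate > 0) {
      bs <- spec$burst_spec
      offsets <- (seq_len(bs$n_spikes) - 1) * bs$isi
      for (i in seq_len(n)) {
        onsets <- poisson_train(bs$rate, spec$duration)
        if (length(onsets)) {
          burst_spikes <- as.vector(outer(onsets, offsets, `+`))
          trains[[i]] <- sort(c(trains[[i]], burst_spikes))
        }
      }
    }
    trains <- lapply(trains, function(x) {
      x <- x[x >= 0 & x <= spec$duration]
      enforce_refractory(sort(x), 0.002)
    })
    names(trains) <- sprintf("s%d", seq_len(n))
    out <- spike_raster(trains, spec$duration, provenance = "synthetic")
    if (!is.null(cs)) attr(out, "groups") <- cs$groups
    out
  })
}

#' Specification for a synthetic multichannel voltage trace
#'
#' Describes an extracellular-recording-like trace: Gaussian background noise
#' per channel, a stereotyped spike waveform inserted at known times, and an
#' optional 60-Hz mains-hum sinusoid. Ground-truth spike times are carried
#' along so detector recall can be scored exactly.
#'
#' @param true_spike_times list of numeric vectors (seconds), one per
#'   channel; the channel count is its length.
#' @param duration trace duration, seconds.
#' @param sampling_rate samples per second (default 20000, the usual MEA
#'   acquisition rate).
#' @param noise_sd SD of the Gaussian background noise (volts).
#' @param spike_template waveform samples (volts) added at each true spike
#'   time; its absolute maximum is aligned to the spike time. Default: a
#'   biphasic negative-leading waveform of ~1.5 ms, peak amplitude
#'   `10 * noise_sd` (see [default_spike_template()]).
#' @param mains_hum amplitude (volts) of an added 60-Hz sinusoid; 0 disables.
#' @param seed integer seed.
#' @return a list of class `trace_spec`.
#' @export
trace_spec <- function(true_spike_times, duration, sampling_rate = 20000,
                       noise_sd = 1e-6, spike_template = NULL,
                       mains_hum = 0, seed = 1L) {
  if (!is.list(true_spike_times)) true_spike_times <- list(true_spike_times)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("invalid `sampling_rate`: must be > 0")
  }
  if (duration <= 0) stop("invalid `duration`: must be > 0")
  if (noise_sd < 0) stop("invalid `noise_sd`: must be >= 0")
  if (is.null(spike_template)) {
    spike_template <- default_spike_template(sampling_rate,
                                             amplitude = 10 * noise_sd)
  }
  if (length(spike_template) > duration * sampling_rate) {
    stop("spike template is longer than the trace")
  }
  structure(list(true_spike_times = lapply(true_spike_times, sort),
                 duration = duration, sampling_rate = sampling_rate,
                 noise_sd = noise_sd, spike_template = spike_template,
                 mains_hum = mains_hum, seed = as.integer(seed)),
            class = "trace_spec")
}

#' Default extracellular spike waveform
#'
#' Biphasic, negative-leading waveform of about 1.5 ms: a sharp negative
#' deflection followed by a smaller positive rebound, the shape typical of
#' extracellular somatic spikes. The absolute maximum is stored in attribute
#' `"peak_index"` so generators can align it to the nominal spike time.
#'
#' @param sampling_rate samples per second.
#' @param amplitude absolute peak amplitude, volts.
#' @return numeric waveform with attribute `peak_index`.
#' @export
default_spike_template <- function(sampling_rate, amplitude = 1) {
  t <- seq(0, 0.0015, by = 1 / sampling_rate)
  w <- -exp(-((t - 4e-4) / 1.2e-4)^2) + 0.35 * exp(-((t - 8e-4) / 2.5e-4)^2)
  w <- w / max(abs(w)) * amplitude
  attr(w, "peak_index") <- which.max(abs(w))
  w
}

#' Generate a synthetic multichannel voltage trace
#'
#' @param spec a [trace_spec()].
#' @return numeric matrix (samples x channels) with attributes
#'   `sampling_rate` and `true_spike_times`.
#' @export
generate_trace <- function(spec) {
  if (!inherits(spec, "trace_spec")) spec <- do.call(trace_spec, spec)
  with_seed(spec$seed, {
    n_samp <- round(spec$duration * spec$sampling_rate)
    n_ch <- length(spec$true_spike_times)
    tmpl <- spec$spike_template
    peak <- attr(tmpl, "peak_index")
    if (is.null(peak)) peak <- which.max(abs(tmpl))
    out <- matrix(stats::rnorm(n_samp * n_ch, 0, spec$noise_sd),
                  nrow = n_samp, ncol = n_ch)
    if (spec$mains_hum > 0) {
      hum <- spec$mains_hum *
        sin(2 * pi * 60 * (seq_len(n_samp) - 1) / spec$sampling_rate)
      out <- out + hum
    }
    for (ch in seq_len(n_ch)) {
      for (tt in spec$true_spike_times[[ch]]) {
        i0 <- round(tt * spec$sampling_rate) + 1L - (peak - 1L)
        idx <- seq.int(i0, i0 + length(tmpl) - 1L)
        ok <- idx >= 1L & idx <= n_samp
        out[idx[ok], ch] <- out[idx[ok], ch] + tmpl[ok]
      }
    }
    colnames(out) <- sprintf("ch%d", seq_len(n_ch))
    attr(out, "sampling_rate") <- spec$sampling_rate
    attr(out, "true_spike_times") <- spec$true_spike_times
    out
  })
}

#' Read and write voltage traces
#'
#' The container is a plain-text header (magic line, channel count, sampling
#' rate, sample count) followed by the samples as little-endian IEEE-754
#' doubles in column-major order. The header is human-readable; the payload
#' is binary for size.
#'
#' @param trace samples x channels matrix as from [generate_trace()].
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   matrix with its `sampling_rate` attribute restored.
#' @export
write_trace <- function(trace, path) {
  sr <- attr(trace, "sampling_rate")
  if (is.null(sr)) stop("trace must carry a `sampling_rate` attribute")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("SPIKETRACE 1\nchannels %d\nsampling_rate %.10g\nsamples %d\n\n",
                 ncol(trace), sr, nrow(trace))
  writeBin(charToRaw(hdr), con)
  writeBin(as.vector(trace), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header: read bytes until the blank line
  hdr_raw <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (!length(b)) stop("malformed trace file: no header terminator")
    hdr_raw <- c(hdr_raw, b)
    n <- length(hdr_raw)
    if (n >= 2 && hdr_raw[n] == as.raw(10) && hdr_raw[n - 1] == as.raw(10)) break
  }
  hdr <- strsplit(rawToChar(hdr_raw), "\n", fixed = TRUE)[[1]]
  if (!grepl("^SPIKETRACE", hdr[1])) stop("not a SPIKETRACE file")
  field <- function(key) {
    m <- grep(paste0("^", key, " "), hdr, value = TRUE)[1]
    as.numeric(sub(paste0("^", key, " "), "", m))
  }
  n_ch <- as.integer(field("channels"))
  sr <- field("sampling_rate")
  n_samp <- as.integer(field("samples"))
  x <- readBin(con, "double", n_samp * n_ch, size = 8, endian = "little")
  out <- matrix(x, nrow = n_samp, ncol = n_ch)
  colnames(out) <- sprintf("ch%d", seq_len(n_ch))
  attr(out, "sampling_rate") <- sr
  out
}
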