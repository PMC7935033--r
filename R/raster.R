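#' Spike raster objects
#'
#' A `spike_raster` is the common currency of the package: spike times in
#' seconds grouped by source (an MEA electrode or a model neuron), together
#' with the recording duration and a provenance tag. All downstream
#' statistics ([train_metrics()], [detect_network_bursts()],
#' [build_functional_network()]) consume this class.
#'
#' Invariants enforced at construction: every spike time lies in
#' `[0, duration]`; times are sorted ascending within each source; sources
#' are named.
#'
#' @param spikes named list of numeric vectors, one per source, spike times
#'   in seconds. Unsorted input is sorted; names are generated (`"s1"`,
#'   `"s2"`, ...) when absent.
#' @param duration recording duration in seconds (single positive number).
#' @param provenance one of `"recorded"`, `"simulated"`, `"synthetic"`.
#'
#' @return an object of class `spike_raster`: a list with elements `spikes`,
#'   `duration` and `provenance`.
#' @examples
#' r <- spike_raster(list(e1 = c(0.1, 0.5), e2 = numeric(0)), duration = 1)
#' n_spikes(r)
#' @export
spike_raster <- function(spikes, duration,
                         provenance = c("synthetic", "recorded", "simulated")) {
  provenance <- match.arg(provenance)
  if (!is.list(spikes)) {
    stop("`spikes` must be a list of numeric vectors (one per source)")
  }
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number (seconds)")
  }
  spikes <- lapply(spikes, function(x) {
    x <- as.numeric(x)
    if (anyNA(x)) stop("spike times must not contain NA")
    sort(x)
  })
  if (is.null(names(spikes)) || anyNA(names(spikes)) || any(names(spikes) == "")) {
    names(spikes) <- paste0("s", seq_along(spikes))
  }
  lo <- suppressWarnings(min(vapply(spikes, function(x)
    if (length(x)) min(x) else Inf, 0)))
  hi <- suppressWarnings(max(vapply(spikes, function(x)
    if (length(x)) max(x) else -Inf, 0)))
  if (is.finite(lo) && lo < 0) stop("spike times must be >= 0")
  if (is.finite(hi) && hi > duration) {
    stop("spike times must be <= duration (", duration, " s); found ", hi)
  }
  structure(list(spikes = spikes, duration = duration, provenance = provenance),
            class = "spike_raster")
}

#' @rdname spike_raster
#' @param x a `spike_raster`.
#' @export
is_spike_raster <- function(x) inherits(x, "spike_raster")

#' @rdname spike_raster
#' @export
n_sources <- function(x) {
  stopifnot(is_spike_raster(x))
  length(x$spikes)
}

#' @rdname spike_raster
#' @export
n_spikes <- function(x) {
  stopifnot(is_spike_raster(x))
  sum(lengths(x$spikes))
}

#' @rdname spike_raster
#' @export
source_ids <- function(x) {
  stopifnot(is_spike_raster(x))
  names(x$spikes)
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d sources, %d spikes, %.3f s (%s)\n",
              n_sources(x), n_spikes(x), x$duration, x$provenance))
  invisible(x)
}

#' @export
as.data.frame.spike_raster <- function(x, ...) {
  data.frame(
    source_id = rep(names(x$spikes), lengths(x$spikes)),
    time_s = unlist(x$spikes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Pool all sources of a raster into one sorted spike train
#'
#' @param raster a `spike_raster`.
#' @return sorted numeric vector of all spike times.
#' @export
pool_spikes <- function(raster) {
  stopifnot(is_spike_raster(raster))
  sort(unlist(raster$spikes, use.names = FALSE))
}

#' Read and write spike rasters as delimited text
#'
#' The on-disk format is tab-separated with a header row `source_id time_s`,
#' one row per spike, preceded by comment lines carrying the duration and
#' provenance (`# duration_s: 300`). Sources that fired no spikes are listed
#' in a `# sources:` comment so the round trip preserves silent electrodes.
#'
#' @param raster a `spike_raster`.
#' @param path file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `spike_raster`.
#' @export
write_raster <- function(raster, path) {
  stopifnot(is_spike_raster(raster))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# duration_s: %.10g", raster$duration),
    sprintf("# provenance: %s", raster$provenance),
    sprintf("# sources: %s", paste(names(raster$spikes), collapse = ","))
  ), con)
  df <- as.data.frame(raster)
  writeLines("source_id\ttime_s", con)
  if (nrow(df)) {
    writeLines(sprintf("%s\t%.10g", df$source_id, df$time_s), con)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  duration <- as.numeric(get_field("duration_s"))
  provenance <- get_field("provenance")
  src_field <- get_field("sources")
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("source_id", "time_s") %in% names(df))) {
    stop("raster file must have columns source_id, time_s")
  }
  ids <- if (!is.null(src_field) && nzchar(src_field)) {
    strsplit(src_field, ",", fixed = TRUE)[[1]]
  } else {
    unique(df$source_id)
  }
  spikes <- lapply(ids, function(id) df$time_s[df$source_id == id])
  names(spikes) <- ids
  if (is.null(duration) || is.na(duration)) {
    duration <- if (nrow(df)) max(df$time_s) else 1
  }
  spike_raster(spikes, duration,
               provenance = if (is.null(provenance)) "recorded" else provenance)
}
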