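#' Signal fidelity
#'
#' Ratio of the output-population firing rate to the input-population firing
#' rate. Undefined (`NA`) when the input population is silent.
#'
#' @param output_rate,input_rate population firing rates, Hz.
#' @return dimensionless ratio.
#' @export
signal_fidelity <- function(output_rate, input_rate) {
  if (is.na(input_rate) || input_rate <= 0) return(NA_real_)
  output_rate / input_rate
}

phase_windows <- function(durations) {
  ends <- cumsum(durations)
  starts <- c(0, ends[-length(ends)])
  data.frame(phase = names(durations), start = starts, end = ends,
             stringsAsFactors = FALSE)
}

pop_rate <- function(raster, ids, t0, t1) {
  counts <- vapply(raster$spikes[ids], function(x)
    sum(x >= t0 & x < t1), 0L)
  sum(counts) / (length(ids) * (t1 - t0))
}

per_neuron_rates <- function(raster, ids, t0, t1) {
  vapply(raster$spikes[ids], function(x)
    sum(x >= t0 & x < t1), 0L) / (t1 - t0)
}

window_raster <- function(raster, t0, t1) {
  spikes <- lapply(raster$spikes, function(x) x[x >= t0 & x < t1] - t0)
  spike_raster(spikes, t1 - t0, provenance = raster$provenance)
}

#' Entrainment protocol: stabilize, control, train, test
#'
#' Runs the four-phase conditioned-stimulus experiment on one network:
#' after a stabilization period (discarded), a control phase records
#' baseline activity; from the training phase onward the external current
#' received by a small set of randomly chosen excitatory "input" neurons
#' (1% of the excitatory population by default) is doubled; the testing
#' phase measures the entrained response. Signal fidelity is the ratio of
#' the output-population rate (all non-input excitatory neurons) to the
#' input-population rate, evaluated before training (control phase) and
#' after training (testing phase). Fold changes compare each population's
#' testing-phase rate with its own control-phase rate. Pre/post functional
#' networks and graph measures are computed on the equal-length control and
#' testing windows.
#'
#' @param config a [simulation_config()].
#' @param condition perturbation condition passed to
#'   [apply_cypin_condition()] (default `"control"`).
#' @param seed overrides `config$seed` when given.
#' @param phase_durations named numeric: seconds of `stabilize`, `control`,
#'   `training`, `testing`.
#' @param input_fraction fraction of excitatory neurons stimulated
#'   (default 0.01).
#' @param stim_multiplier multiplier on the external current of input
#'   neurons from training onward (default 2; 1 is a null intervention).
#' @param fold_method `"pooled"` computes fold changes on population-pooled
#'   rates; `"per_neuron"` averages per-neuron fold changes (neurons silent
#'   in the control phase are excluded).
#' @param graph if `TRUE` (default), build pre/post functional networks and
#'   graph metrics; skip for speed when only rates are needed.
#' @param fc_bin,fc_max_lag functional-connectivity settings, seconds.
#' @param louvain_repeats restarts for the Louvain step.
#' @return list of class `protocol_result`: phase table, input/output ids,
#'   per-phase population rates, `fidelity_pre`, `fidelity_post`,
#'   `fold_input`, `fold_output`, pre/post `functional_network` and
#'   `network_metrics` (when `graph`), the recorded raster and the config.
#' @export
run_entrainment <- function(config, condition = "control", seed = NULL,
                            phase_durations = c(stabilize = 10, control = 300,
                                                training = 300, testing = 300),
                            input_fraction = 0.01, stim_multiplier = 2,
                            fold_method = c("pooled", "per_neuron"),
                            graph = TRUE,
                            fc_bin = 0.001, fc_max_lag = 0.020,
                            louvain_repeats = 100) {
  fold_method <- match.arg(fold_method)
  stopifnot(inherits(config, "simulation_config"))
  stopifnot(all(c("stabilize", "control", "training", "testing") %in%
                  names(phase_durations)))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- apply_cypin_condition(config, condition)

  n <- config$n_e + config$n_i
  n_input <- max(1L, round(input_fraction * config$n_e))
  with_seed(config$seed + 2L, {
    input_ids <- sort(sample.int(config$n_e, n_input))
  })
  output_ids <- setdiff(seq_len(config$n_e), input_ids)

  edges <- build_circuit(config)
  dur <- phase_durations[c("stabilize", "control", "training", "testing")]
  rec <- c(FALSE, TRUE, TRUE, TRUE)
  mult <- matrix(1, n, 4)
  mult[input_ids, 3:4] <- stim_multiplier
  res <- sim_phases(config, edges, dur, rec, mult, sim_seed = config$seed)
  rec_dur <- sum(dur[-1])
  raster <- raster_from_spikes(res$spike_time, res$spike_neuron, n, rec_dur)

  win <- phase_windows(dur[-1])   # recorded frame starts after stabilization
  in_lab <- sprintf("n%d", input_ids)
  out_lab <- sprintf("n%d", output_ids)
  rates <- do.call(rbind, lapply(seq_len(nrow(win)), function(k) {
    data.frame(phase = win$phase[k],
               input_rate = pop_rate(raster, in_lab, win$start[k], win$end[k]),
               output_rate = pop_rate(raster, out_lab, win$start[k], win$end[k]),
               stringsAsFactors = FALSE)
  }))

  ctrl <- rates[rates$phase == "control", ]
  test <- rates[rates$phase == "testing", ]
  if (fold_method == "pooled") {
    fold_input <- if (ctrl$input_rate > 0) test$input_rate / ctrl$input_rate
      else NA_real_
    fold_output <- if (ctrl$output_rate > 0) test$output_rate / ctrl$output_rate
      else NA_real_
  } else {
    fold_of <- function(lab) {
      r0 <- per_neuron_rates(raster, lab, win$start[1], win$end[1])
      r1 <- per_neuron_rates(raster, lab,
                             win$start[nrow(win)], win$end[nrow(win)])
      ok <- r0 > 0
      if (!any(ok)) return(NA_real_)
      mean(r1[ok] / r0[ok])
    }
    fold_input <- fold_of(in_lab)
    fold_output <- fold_of(out_lab)
  }

  out <- list(
    condition = condition,
    phases = win,
    input_ids = input_ids, output_ids = output_ids,
    rates = rates,
    fidelity_pre = signal_fidelity(ctrl$output_rate, ctrl$input_rate),
    fidelity_post = signal_fidelity(test$output_rate, test$input_rate),
    fold_input = fold_input, fold_output = fold_output,
    raster = raster, config = config,
    manifest = list(seed = config$seed, condition = condition,
                    input_ids = input_ids,
                    stim_multiplier = stim_multiplier,
                    phase_durations = dur)
  )
  if (graph) {
    pre_r <- window_raster(raster, win$start[1], win$end[1])
    post_r <- window_raster(raster, win$start[nrow(win)], win$end[nrow(win)])
    out$pre_network <- build_functional_network(pre_r, fc_bin, fc_max_lag)
    out$post_network <- build_functional_network(post_r, fc_bin, fc_max_lag)
    out$pre_metrics <- network_metrics(out$pre_network, local = FALSE,
                                       n_repeats = louvain_repeats,
                                       seed = config$seed + 3L)
    out$post_metrics <- network_metrics(out$post_network, local = FALSE,
                                        n_repeats = louvain_repeats,
                                        seed = config$seed + 4L)
  }
  class(out) <- "protocol_result"
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf(
    paste0("<protocol_result> %s | fidelity pre %.3f -> post %.3f | ",
           "fold input %.2f, output %.2f\n"),
    x$condition, x$fidelity_pre, x$fidelity_post,
    x$fold_input, x$fold_output))
  invisible(x)
}

replicate_metrics <- function(sim, bin_width = 1, graph = TRUE,
                              fc_bin = 0.001, fc_max_lag = 0.020,
                              louvain_repeats = 100, metrics_seed = 1L) {
  raster <- sim$raster
  n <- n_sources(raster)
  tm <- train_metrics(raster, bin_width = bin_width)
  bursts <- detect_network_bursts(raster)
  out <- data.frame(
    spike_rate = n_spikes(raster) / (n * raster$duration),
    mean_isi = mean(tm$mean_isi, na.rm = TRUE),
    cv_isi = mean(tm$cv_isi, na.rm = TRUE),
    fano_factor = mean(tm$fano_factor, na.rm = TRUE),
    burst_rate = length(bursts) / raster$duration
  )
  if (graph) {
    fn <- build_functional_network(raster, fc_bin, fc_max_lag)
    nm <- network_metrics(fn, local = FALSE, n_repeats = louvain_repeats,
                          seed = metrics_seed)
    out$global_efficiency <- nm$global_efficiency
    out$n_communities <- nm$n_communities
    out$Q <- nm$Q
  }
  out
}

#' Replicate simulations across perturbation conditions
#'
#' Runs `n_replicates` independent simulations per condition, analyzes each
#' raster exactly like a recording (spike rate, mean ISI, CV, Fano factor,
#' network-burst rate with the 50-spikes-in-50-ms rule, and optionally the
#' functional-network graph measures), and reports every metric normalized
#' to the control-condition mean.
#'
#' @param config a [simulation_config()]; its `duration`, `stabilization`
#'   and `n_replicates` define the per-replicate runs (override
#'   `n_replicates` with the argument).
#' @param conditions character vector of condition names; must include
#'   `"control"`.
#' @param n_replicates replicates per condition (default from config).
#' @param seed master seed; replicate sub-seeds are derived from it.
#' @param graph compute functional-connectivity graph metrics per replicate
#'   (default `TRUE`).
#' @param bin_width Fano-factor window, seconds.
#' @param fc_bin,fc_max_lag,louvain_repeats functional-network settings.
#' @return list of class `condition_summary`: `replicates` (one row per
#'   condition x replicate with raw metric values), `normalized` (per
#'   condition and metric: mean and SEM of the replicate values divided by
#'   the control mean).
#' @export
run_condition_suite <- function(config,
                                conditions = c("control", "cypin_oe_1",
                                               "cypin_oe_2"),
                                n_replicates = config$n_replicates,
                                seed = config$seed,
                                graph = TRUE, bin_width = 1,
                                fc_bin = 0.001, fc_max_lag = 0.020,
                                louvain_repeats = 100) {
  stopifnot(inherits(config, "simulation_config"))
  if (!("control" %in% conditions)) {
    stop("`conditions` must include \"control\" (the normalization baseline)")
  }
  with_seed(seed, {
    sub_seeds <- matrix(sample.int(2^30, length(conditions) * n_replicates),
                        nrow = length(conditions))
  })
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (r in seq_len(n_replicates)) {
      cfg <- apply_cypin_condition(config, cond)
      cfg$seed <- sub_seeds[ci, r]
      sim <- run_simulation(cfg)
      m <- replicate_metrics(sim, bin_width = bin_width, graph = graph,
                             fc_bin = fc_bin, fc_max_lag = fc_max_lag,
                             louvain_repeats = louvain_repeats,
                             metrics_seed = cfg$seed)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(condition = cond, replicate = r), m)
    }
  }
  reps <- do.call(rbind, rows)
  metric_cols <- setdiff(names(reps), c("condition", "replicate"))
  ctrl_means <- vapply(metric_cols, function(mc)
    mean(reps[reps$condition == "control", mc], na.rm = TRUE), 0)
  norm_rows <- list()
  for (cond in conditions) {
    for (mc in metric_cols) {
      v <- reps[reps$condition == cond, mc] / ctrl_means[mc]
      v <- v[!is.na(v)]
      norm_rows[[length(norm_rows) + 1L]] <- data.frame(
        condition = cond, metric = mc,
        mean = mean(v),
        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
    }
  }
  structure(list(replicates = reps,
                 normalized = do.call(rbind, norm_rows),
                 conditions = conditions, n_replicates = n_replicates,
                 seed = seed),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %d condition(s) x %d replicate(s)\n",
              length(x$conditions), x$n_replicates))
  print(x$normalized, row.names = FALSE)
  invisible(x)
}

#' Normalize condition values to a baseline
#'
#' Elementwise ratio `values / baseline`, excluding pairs whose baseline is
#' below `min_baseline` (guarding against aberrant normalization by
#' near-zero baselines; the convention used when normalizing local
#' efficiency, where values below 0.001 are dropped).
#'
#' @param values,baseline equal-length numeric vectors.
#' @param min_baseline exclusion threshold on the baseline (default 0.001).
#' @return numeric vector of ratios for the retained pairs (named by their
#'   original positions); `NA` (with a warning) if every pair is excluded.
#' @export
normalize_to_baseline <- function(values, baseline, min_baseline = 0.001) {
  if (length(values) != length(baseline)) {
    stop("`values` and `baseline` must have equal length")
  }
  keep <- which(baseline >= min_baseline)
  if (!length(keep)) {
    warning("all pairs excluded: every baseline is below min_baseline")
    return(NA_real_)
  }
  out <- values[keep] / baseline[keep]
  names(out) <- as.character(keep)
  out
}
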