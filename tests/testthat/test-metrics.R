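test_that("spike_rate is the exact quotient", {
  expect_equal(spike_rate(numeric(0), 300), 0)
  expect_equal(spike_rate(seq_len(600) / 2, 300), 2)
  expect_error(spike_rate(1, 0), "> 0")
})

test_that("Poisson rate estimates fall within 4 SD of the generator rate", {
  r <- generate_raster(raster_spec(1, duration = 300, base_rate = 5, seed = 21))
  est <- spike_rate(r$spikes[[1]], 300)
  expect_lt(abs(est - 5), 4 * sqrt(5 / 300))
})

test_that("ISI statistics match their defining formulas", {
  reg <- regular_train(1, 100)
  s <- isi_statistics(reg)
  expect_equal(s$cv_isi, 0)
  expect_equal(s$mean_isi, 1)

  pois <- generate_raster(raster_spec(1, 600, 5, seed = 8))$spikes[[1]]
  sp <- isi_statistics(pois)
  expect_lt(abs(sp$cv_isi - 1), 0.1)          # near-Poisson CV ~ 1
  expect_lt(abs(sp$mean_isi - 1 / 5), 0.02)   # mean ISI ~ 1/rate

  # bursty train: CV > 1, value equals the direct formula on the ISI list
  bursty <- generate_raster(raster_spec(1, 600, 0.2,
    burst_spec = list(rate = 0.5, n_spikes = 6, isi = 0.005), seed = 8))$spikes[[1]]
  sb <- isi_statistics(bursty)
  isis <- diff(bursty)
  expect_gt(sb$cv_isi, 1)
  expect_equal(sb$cv_isi, sd(isis) / mean(isis))

  # undefined cases flagged, not zero
  expect_true(is.na(isi_statistics(c(1))$mean_isi))
  expect_true(is.na(isi_statistics(c(1, 2))$cv_isi))
})

test_that("Fano factor matches hand computation and known limits", {
  # regular train, bin an exact multiple of the period -> FF = 0
  expect_equal(fano_factor(regular_train(4, 100) - 0.125, 100, bin_width = 1), 0)

  # hand-computed toy: counts 0,2,1,3,0,2,1,3,0,2 over 10 one-second bins
  counts <- c(0, 2, 1, 3, 0, 2, 1, 3, 0, 2)
  times <- unlist(lapply(seq_along(counts), function(b)
    if (counts[b] > 0) (b - 1) + seq_len(counts[b]) / (counts[b] + 1)
    else numeric(0)))
  expect_equal(fano_factor(times, 10, 1), var(counts) / mean(counts))

  # long Poisson train: FF within 4 SD of 1 (SD ~ sqrt(2/n_bins))
  pois <- generate_raster(raster_spec(1, 600, 5, seed = 13))$spikes[[1]]
  expect_lt(abs(fano_factor(pois, 600, 1) - 1), 4 * sqrt(2 / 600))

  expect_true(is.na(fano_factor(numeric(0), 100, 1)))
  expect_error(fano_factor(1, 1.5, 1), "2 bins")
})

test_that("FF and CV are invariant to uniform time translation", {
  tr <- generate_raster(raster_spec(1, 120, 4, seed = 17))$spikes[[1]]
  shifted <- tr - min(tr) + 0.25
  expect_equal(isi_statistics(tr)$cv_isi, isi_statistics(shifted)$cv_isi)
  expect_equal(fano_factor(tr, 120, 1),
               fano_factor(shifted, 120, 1), tolerance = 0.15)
})

test_that("active sources follow the 75th-percentile rule with interpolation", {
  expect_equal(active_sources(c(a = 2, b = 2, c = 2)), c("a", "b", "c"))
  expect_equal(active_sources(setNames(1:8, letters[1:8])), c("g", "h"))
  expect_equal(active_sources(c(only = 3)), "only")
})

test_that("burstlet detection applies the core and peripheral rules", {
  # below the 4-spike minimum
  expect_length(detect_burstlets(c(0.1, 0.11, 0.12), 1), 0)

  # 5 spikes at 10-ms spacing, rate 1 Hz: core threshold min(0.1, 0.25) = 0.1
  b <- detect_burstlets(seq(0, 0.04, by = 0.01), 1)
  expect_length(b, 1)
  expect_equal(b[[1]]$n_spikes, 5)

  # a spike 150 ms after the core end is peripheral (min(0.2, 1/3) = 0.2)
  b2 <- detect_burstlets(c(seq(0, 0.04, by = 0.01), 0.19), 1)
  expect_length(b2, 1)
  expect_equal(b2[[1]]$n_spikes, 6)

  # at a high electrode rate the adaptive threshold shrinks below the caps:
  # rate 20 Hz -> core 12.5 ms, so 20-ms spacing forms no burstlet
  expect_length(detect_burstlets(seq(0, 0.08, by = 0.02), 20), 0)
})

test_that("network-burst detection agrees exactly with the brute-force oracle", {
  # 49 spikes in 50 ms is below threshold
  expect_length(detect_network_bursts(seq(0, 0.049, length.out = 49)), 0)

  # 60 spikes uniform in 40 ms: one burst of 60
  b <- detect_network_bursts(seq(0, 0.04, length.out = 60))
  expect_length(b, 1)
  expect_equal(b[[1]]$n_spikes, 60)

  # two packets 1 s apart: two bursts, IBI ~ 1 s
  t2 <- c(seq(0, 0.04, length.out = 60), 1 + seq(0, 0.04, length.out = 60))
  b2 <- detect_network_bursts(t2)
  expect_length(b2, 2)
  expect_equal(interburst_intervals(b2), 1, tolerance = 1e-9)

  # randomized rasters: exact agreement with the O(n^2) oracle
  set.seed(99)
  for (rep in 1:5) {
    times <- sort(c(runif(300, 0, 10),
                    runif(1, 0, 9) + runif(80, 0, 0.04),
                    runif(1, 0, 9) + runif(60, 0, 0.03)))
    got <- detect_network_bursts(times, min_spikes = 50, window = 0.05)
    want <- oracle_network_bursts(times, min_spikes = 50, window = 0.05)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$start, unname(want[[k]]["start"]))
      expect_equal(got[[k]]$end, unname(want[[k]]["end"]))
      expect_equal(got[[k]]$n_spikes, unname(want[[k]]["n"]))
    }
  }
})

test_that("train_metrics summarizes every source and flags undefined values", {
  r <- spike_raster(list(busy = regular_train(2, 100), quiet = c(1),
                         silent = numeric(0)),
                    duration = 100)
  tm <- train_metrics(r)
  expect_equal(nrow(tm), 3)
  expect_equal(tm$spike_rate, c(2, 0.01, 0))
  expect_true(is.na(tm$cv_isi[2]) && is.na(tm$cv_isi[3]))
  expect_true(is.na(tm$fano_factor[3]))
  path <- tempfile(fileext = ".tsv")
  write_metrics(tm, path)
  expect_equal(read.delim(path)$source_id, tm$source_id)
})
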