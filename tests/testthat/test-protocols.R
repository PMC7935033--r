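test_that("normalize_to_baseline applies the exclusion rule", {
  expect_equal(unname(normalize_to_baseline(c(2, 4), c(1, 2))), c(2, 2))
  v <- c(1, 1, 1)
  b <- c(1, 0.0005, 2)
  out <- normalize_to_baseline(v, b)
  expect_equal(names(out), c("1", "3"))       # the 0.0005 baseline is dropped
  expect_equal(unname(out), c(1, 0.5))
  expect_equal(unname(normalize_to_baseline(c(5, 5), c(5, 5))), c(1, 1))
  expect_warning(res <- normalize_to_baseline(1, 1e-5), "all pairs excluded")
  expect_true(is.na(res))
  expect_error(normalize_to_baseline(1:3, 1:2), "equal length")
})

test_that("signal fidelity is a scale-free rate ratio", {
  expect_equal(signal_fidelity(2, 4), 0.5)
  expect_equal(signal_fidelity(20, 40), signal_fidelity(2, 4))
  expect_true(is.na(signal_fidelity(1, 0)))
})

test_that("entrainment bookkeeping: phases, populations, windows", {
  cfg <- tiny_config(seed = 21, sigma_pre = 900, bias_mean = 150)
  pr <- run_entrainment(cfg, condition = "control",
                        phase_durations = c(stabilize = 1, control = 10,
                                            training = 10, testing = 10),
                        graph = FALSE)
  expect_s3_class(pr, "protocol_result")
  expect_equal(pr$phases$phase, c("control", "training", "testing"))
  expect_equal(pr$phases$end - pr$phases$start, rep(10, 3))
  # input set: 1% of excitatory population (at least 1), disjoint from outputs
  expect_length(pr$input_ids, max(1, round(0.01 * 40)))
  expect_length(intersect(pr$input_ids, pr$output_ids), 0)
  expect_true(all(c(pr$input_ids, pr$output_ids) <= 40))
  # spikes only within the recorded window; stabilization never leaks
  expect_equal(pr$raster$duration, 30)
  expect_true(all(unlist(pr$raster$spikes) >= 0))
  # fidelity values recompute from the rate table
  ctrl <- pr$rates[pr$rates$phase == "control", ]
  expect_equal(pr$fidelity_pre, ctrl$output_rate / ctrl$input_rate)
})

test_that("a null intervention leaves fidelity unchanged", {
  cfg <- tiny_config(seed = 4, sigma_pre = 1000, bias_mean = 150)
  pr <- run_entrainment(cfg, condition = "control", stim_multiplier = 1,
                        phase_durations = c(stabilize = 1, control = 15,
                                            training = 15, testing = 15),
                        graph = FALSE)
  expect_gt(pr$fidelity_pre, 0)
  expect_equal(pr$fidelity_post, pr$fidelity_pre,
               tolerance = 0.35)   # finite-sample scatter only
  expect_equal(pr$fold_output, 1, tolerance = 0.35)
})

test_that("stimulation raises the input population above baseline", {
  cfg <- tiny_config(seed = 10, sigma_pre = 1000, bias_mean = 120)
  pr <- run_entrainment(cfg, condition = "control", stim_multiplier = 2,
                        phase_durations = c(stabilize = 1, control = 15,
                                            training = 15, testing = 15),
                        graph = FALSE)
  expect_gt(pr$fold_input, 1)
})

test_that("per-neuron fold method agrees in direction with pooled", {
  cfg <- tiny_config(seed = 10, sigma_pre = 1000, bias_mean = 120)
  prp <- run_entrainment(cfg, condition = "control",
                         phase_durations = c(stabilize = 1, control = 15,
                                             training = 15, testing = 15),
                         fold_method = "per_neuron", graph = FALSE)
  expect_gt(prp$fold_input, 1)
})

test_that("entrainment graph stage produces pre/post networks and metrics", {
  cfg <- tiny_config(seed = 12, sigma_pre = 1000, bias_mean = 150)
  pr <- run_entrainment(cfg, condition = "control",
                        phase_durations = c(stabilize = 1, control = 10,
                                            training = 10, testing = 10),
                        graph = TRUE, louvain_repeats = 3)
  expect_s3_class(pr$pre_network, "functional_network")
  expect_s3_class(pr$post_metrics, "network_metrics")
  expect_equal(dim(pr$pre_network$W), c(50, 50))
})

test_that("the condition suite normalizes to control and is deterministic", {
  cfg <- tiny_config(seed = 8, duration = 8, sigma_pre = 900, bias_mean = 150)
  expect_error(run_condition_suite(cfg, conditions = "cypin_oe_1"),
               "control")
  cs <- run_condition_suite(cfg, conditions = c("control", "cypin_oe_1"),
                            n_replicates = 2, graph = FALSE)
  expect_s3_class(cs, "condition_summary")
  expect_equal(nrow(cs$replicates), 4)
  # control normalizes to itself: normalized control mean is exactly 1
  ctl <- cs$normalized[cs$normalized$condition == "control", ]
  expect_equal(ctl$mean[ctl$metric == "spike_rate"], 1, tolerance = 1e-12)
  # doubled presynaptic current (part of condition 1) raises the spike rate
  norm1 <- cs$normalized[cs$normalized$condition == "cypin_oe_1", ]
  expect_gt(norm1$mean[norm1$metric == "spike_rate"], 1)
  # same seed, same result
  cs2 <- run_condition_suite(cfg, conditions = c("control", "cypin_oe_1"),
                             n_replicates = 2, graph = FALSE)
  expect_identical(cs$replicates, cs2$replicates)
})
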