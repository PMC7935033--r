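test_that("circuit sampling matches its binomial expectations", {
  cfg0 <- simulation_config(p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0)
  expect_equal(nrow(build_circuit(cfg0)), 0L)

  cfg <- simulation_config(seed = 5)
  e <- build_circuit(cfg)
  n_ee <- sum(e$is_ee)
  mu <- 400 * 399 * 0.1
  expect_lt(abs(n_ee - mu), 4 * sqrt(mu * 0.9))
  # no self-connections, valid indices
  expect_true(all(e$pre != e$post))
  expect_true(all(e$pre >= 1 & e$post <= 500))

  cfg75 <- simulation_config(cd_scale = 0.75, seed = 6)
  mu75 <- 400 * 399 * 0.075
  expect_lt(abs(sum(build_circuit(cfg75)$is_ee) - mu75),
            4 * sqrt(mu75 * 0.925))

  expect_warning(build_circuit(simulation_config(cd_scale = 6, seed = 1)),
                 "clipped")
})

test_that("perturbation conditions set the documented scalings", {
  cfg <- simulation_config()
  ctl <- apply_cypin_condition(cfg, "control")
  expect_equal(c(ctl$ampa_scale, ctl$cd_scale, ctl$ipre_scale), c(1, 1, 1))
  c1 <- apply_cypin_condition(cfg, "cypin_oe_1")
  expect_equal(c(c1$ampa_scale, c1$cd_scale, c1$ipre_scale), c(1, 0.75, 2))
  c2 <- apply_cypin_condition(cfg, "cypin_oe_2")
  expect_equal(c(c2$ampa_scale, c2$cd_scale, c2$ipre_scale), c(2, 2, 2))
  expect_error(apply_cypin_condition(cfg, "nope"), "control, cypin_oe_1")
})

test_that("a neuron at rest with no input stays exactly at rest", {
  cfg <- tiny_config(duration = 0.5, stabilization = 0,
                     bias_mean = 0, bias_sd = 0, sigma_pre = 0, v_init_sd = 0)
  s <- run_simulation(cfg, record_v = 1)
  expect_true(all(s$v_log[, 1] == -70))
  expect_equal(n_spikes(s$raster), 0L)
})

test_that("membrane charging follows the closed form within the Euler bound", {
  run_v <- function(dt) {
    cfg <- simulation_config(
      n_e = 1, n_i = 0, p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0,
      stabilization = 0, duration = 0.2, dt_ms = dt, seed = 1,
      params = model_parameters(bias_mean = 250, bias_sd = 0, sigma_pre = 0,
                                v_init_sd = 0))
    run_simulation(cfg, record_v = 1)$v_log[, 1]
  }
  v1 <- run_v(0.1)
  t1 <- (seq_along(v1) - 1) * 0.1
  closed <- -70 + 10 * (1 - exp(-t1 / 20))   # steady state V_L + I0/g_m
  err1 <- max(abs(v1 - closed))
  expect_lt(err1, 0.05)
  expect_equal(tail(v1, 1), -60, tolerance = 1e-3)

  # halving dt roughly halves the global error (first-order integrator)
  v2 <- run_v(0.05)
  t2 <- (seq_along(v2) - 1) * 0.05
  err2 <- max(abs(v2 - (-70 + 10 * (1 - exp(-t2 / 20)))))
  expect_lt(err2, err1)
  expect_gt(err1 / err2, 1.5)
})

test_that("simulations are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 33, duration = 5, sigma_pre = 900, bias_mean = 100)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$weights, s2$weights)
  s3 <- run_simulation(tiny_config(seed = 34, duration = 5, sigma_pre = 900,
                                   bias_mean = 100))
  expect_false(identical(s1$raster, s3$raster))
})

test_that("raster output respects the analysis window and ordering", {
  cfg <- tiny_config(seed = 3, duration = 5, stabilization = 1,
                     sigma_pre = 900, bias_mean = 150)
  r <- run_simulation(cfg)$raster
  expect_gt(n_spikes(r), 0)
  expect_equal(r$duration, 5)
  all_t <- unlist(r$spikes)
  expect_true(all(all_t >= 0 & all_t <= 5))
  expect_true(all(vapply(r$spikes, function(x) !is.unsorted(x), TRUE)))
  expect_equal(r$provenance, "simulated")
})

test_that("doubling the presynaptic current raises the firing rate", {
  rate_at <- function(scale, seed) {
    cfg <- tiny_config(seed = seed, duration = 5, sigma_pre = 800,
                       bias_mean = 100)
    cfg$ipre_scale <- scale
    n_spikes(run_simulation(cfg)$raster)
  }
  for (seed in c(2, 7, 19)) {
    expect_gt(rate_at(2, seed), rate_at(1, seed))
  }
})

test_that("subthreshold deterministic input produces no spikes", {
  cfg <- tiny_config(seed = 1, duration = 2, sigma_pre = 0,
                     bias_mean = 300, bias_sd = 0, v_init_sd = 0)
  # 300 pA * R_m = 12 mV < the 20 mV gap to threshold
  expect_equal(n_spikes(run_simulation(cfg)$raster), 0L)
})

test_that("runaway activity aborts with a diagnostic", {
  cfg <- tiny_config(seed = 1, duration = 5, stabilization = 0,
                     bias_mean = 2000, bias_sd = 0, sigma_pre = 0,
                     max_rate_guard = 5)
  expect_error(run_simulation(cfg), "runaway")
})

test_that("short-term plasticity reference updates behave as documented", {
  # tau_rec -> 0: resources recover fully, release is always U
  s <- stp_update(0.2, 0.1, dt_since_last = 1, U = 0.2, tau_rec = 1e-9)
  expect_equal(s$release, 0.2, tolerance = 1e-6)

  # paired pulses at short interval, depression only: second release smaller,
  # matching a two-spike hand iteration
  U <- 0.3; tau_rec <- 800
  s1 <- stp_update(U, 1, dt_since_last = 1e9, U = U, tau_rec = tau_rec)
  s2 <- stp_update(s1$u, s1$x, dt_since_last = 20, U = U, tau_rec = tau_rec)
  x_hand <- 1 - (1 - (1 - U)) * exp(-20 / tau_rec)    # x after release, recovered
  expect_equal(s1$release, U)
  expect_equal(s2$release, U * x_hand, tolerance = 1e-12)
  expect_lt(s2$release, s1$release)

  # facilitation raises utilization on the second pulse
  f1 <- stp_update(0.2, 1, 1e9, U = 0.2, tau_rec = 800, tau_facil = 500)
  f2 <- stp_update(f1$u, f1$x, 20, U = 0.2, tau_rec = 800, tau_facil = 500)
  expect_gt(f2$u, f1$u)
})

test_that("STDP window has the right signs, limits and decay", {
  expect_gt(stdp_delta(10), 0)
  expect_lt(stdp_delta(-10), 0)
  expect_equal(stdp_delta(1e6), 0, tolerance = 1e-12)
  expect_equal(stdp_delta(-1e6), 0, tolerance = 1e-12)
  expect_equal(stdp_delta(20, A_plus = 0.01, tau_plus = 20),
               0.01 * exp(-1), tolerance = 1e-12)
  # magnitude decays with separation on both sides
  expect_gt(stdp_delta(5), stdp_delta(15))
  expect_gt(abs(stdp_delta(-5)), abs(stdp_delta(-15)))
})

test_that("simulated rasters flow through the full analysis path", {
  cfg <- tiny_config(seed = 9, duration = 30, sigma_pre = 900, bias_mean = 150)
  r <- run_simulation(cfg)$raster
  tm <- train_metrics(r)
  expect_equal(nrow(tm), 50)
  fn <- build_functional_network(r)
  expect_equal(dim(fn$W), c(50, 50))
  nm <- network_metrics(fn, n_repeats = 3, seed = 1, local = FALSE)
  expect_true(nm$global_efficiency >= 0 && nm$global_efficiency <= 1)
  expect_gte(nm$n_communities, 1)
})
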