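#' Biophysical parameters of the circuit model
#'
#' One documented home for every quantitative constant of the
#' conductance-based leaky integrate-and-fire network, so each downstream
#' number is auditable. Values follow the common
#' recurrent-culture-model conventions (membrane constants of cortical E/I
#' cells, AMPA/NMDA/GABA-A kinetics, utilization-resource short-term
#' plasticity, pair-based STDP), with the presynaptic noise amplitude
#' calibrated once so the control network shows the periodic network
#' bursting characteristic of mature dissociated cultures.
#'
#' Units: mV (potentials), ms (times), nS (conductances), pF (capacitances),
#' pA (currents); the white-noise amplitude `sigma_pre` is in pA sqrt(ms)
#' (its increments are scaled by sqrt(dt), making the noise statistics
#' independent of the integration step).
#'
#' @param ... named overrides of any default listed below.
#' @return named list of parameters.
#' @section Parameters:
#' \describe{
#'   \item{C_m_e, C_m_i}{membrane capacitance, excitatory 500 pF /
#'     inhibitory 200 pF.}
#'   \item{g_m_e, g_m_i}{leak conductance (1/R_m), 25 / 20 nS, giving 20 and
#'     10 ms membrane time constants.}
#'   \item{V_L, V_thresh, V_reset}{resting, threshold and reset potentials:
#'     -70, -50, -70 mV (reset to rest).}
#'   \item{t_ref_e, t_ref_i}{absolute refractory periods, 2 / 1 ms.}
#'   \item{V_E_rev, V_I_rev, V_K}{glutamatergic, GABAergic and potassium
#'     reversal potentials: 0, -70, -100 mV.}
#'   \item{tau_ampa, tau_nmda, tau_gaba}{conductance decay constants, 2 /
#'     100 / 5 ms; NMDA carries the Jahr-Stevens magnesium unblock at
#'     `mg_mM` = 1 mM.}
#'   \item{g_ampa, g_nmda, g_gaba}{maximal synaptic conductances per
#'     connection (before short-term plasticity and STDP weighting).}
#'   \item{alpha_ca, tau_ca, g_ahp}{spike-triggered adaptation: calcium-like
#'     variable incremented by `alpha_ca` per spike, decaying with `tau_ca`,
#'     driving the after-hyperpolarization current
#'     `g_ahp * Ca * (V - V_K)` that terminates network bursts.}
#'   \item{stp_U, stp_tau_rec, stp_tau_facil}{short-term plasticity
#'     utilization and recovery/facilitation constants (all synapses);
#'     `stp_tau_facil = 0` selects pure depression with fixed utilization.}
#'   \item{stdp_A_plus, stdp_A_minus, stdp_tau_plus, stdp_tau_minus,
#'     stdp_w_max, stdp_w_init}{pair-based STDP on excitatory-excitatory
#'     synapses: exponential windows, additive updates, weights clipped to
#'     `[0, stdp_w_max]`.}
#'   \item{bias_mean, bias_sd}{per-neuron constant external current drawn
#'     once from a Gaussian at initialization, pA.}
#'   \item{sigma_pre}{amplitude of the Gaussian white-noise presynaptic
#'     current, pA sqrt(ms).}
#'   \item{v_init_sd}{SD of the Gaussian initial-membrane-potential spread
#'     around rest, mV.}
#'   \item{max_rate_guard}{abort threshold, mean spikes/neuron/s.}
#' }
#' @export
model_parameters <- function(...) {
  p <- list(
    C_m_e = 500, C_m_i = 200,
    g_m_e = 25, g_m_i = 20,
    V_L = -70, V_thresh = -50, V_reset = -70,
    t_ref_e = 2, t_ref_i = 1,
    V_E_rev = 0, V_I_rev = -70, V_K = -100,
    tau_ampa = 2, tau_nmda = 100, tau_gaba = 5,
    g_ampa = 50, g_nmda = 20, g_gaba = 25,
    mg_mM = 1,
    alpha_ca = 1, tau_ca = 400, g_ahp = 0.5,
    stp_U = 0.2, stp_tau_rec = 2500, stp_tau_facil = 0,
    stdp_A_plus = 0.006, stdp_A_minus = 0.006,
    stdp_tau_plus = 20, stdp_tau_minus = 20,
    stdp_w_max = 2, stdp_w_init = 1,
    bias_mean = 300, bias_sd = 20,
    sigma_pre = 300,
    v_init_sd = 4,
    max_rate_guard = 200,
    ampa_scale = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Simulation configuration
#'
#' Network composition, class-wise connection probabilities, integration and
#' duration settings, and the three perturbation scalings (AMPA conductance,
#' connection density, presynaptic current) that emulate cypin
#' overexpression. Defaults: 500 neurons (400 excitatory, 100 inhibitory);
#' connection probabilities E-E 0.1, E-I 0.05, I-E 0.2, I-I 0.2; Euler step
#' 0.1 ms; 10 s stabilization discarded before a 300 s analysis window;
#' 5 replicate runs.
#'
#' @param n_e,n_i numbers of excitatory and inhibitory neurons.
#' @param p_ee,p_ei,p_ie,p_ii directed connection probabilities by class
#'   (first letter = presynaptic class).
#' @param dt_ms Euler step, ms.
#' @param stabilization seconds discarded at the start of every run.
#' @param duration analysis window, seconds.
#' @param ampa_scale,cd_scale,ipre_scale perturbation scalings: AMPA maximal
#'   conductance, connection density (multiplies all four probabilities,
#'   clipped to 1), and the presynaptic white-noise current amplitude. The
#'   per-neuron constant bias is protocol-level external input and is scaled
#'   by entrainment stimulation, not by `ipre_scale`.
#' @param seed master seed.
#' @param n_replicates replicate simulations per condition.
#' @param params biophysical constants, see [model_parameters()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_e = 400, n_i = 100,
                              p_ee = 0.1, p_ei = 0.05,
                              p_ie = 0.2, p_ii = 0.2,
                              dt_ms = 0.1, stabilization = 10,
                              duration = 300,
                              ampa_scale = 1, cd_scale = 1, ipre_scale = 1,
                              seed = 1L, n_replicates = 5,
                              params = model_parameters()) {
  stopifnot(n_e >= 1, n_i >= 0, dt_ms > 0, duration > 0, stabilization >= 0)
  probs <- c(p_ee, p_ei, p_ie, p_ii)
  if (any(probs < 0 | probs > 1)) stop("connection probabilities must be in [0, 1]")
  if (any(c(ampa_scale, cd_scale, ipre_scale) < 0)) {
    stop("perturbation scalings must be >= 0")
  }
  structure(list(n_e = as.integer(n_e), n_i = as.integer(n_i),
                 p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii,
                 dt_ms = dt_ms, stabilization = stabilization,
                 duration = duration,
                 ampa_scale = ampa_scale, cd_scale = cd_scale,
                 ipre_scale = ipre_scale,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 params = params),
            class = "simulation_config")
}

#' Perturbation conditions emulating cypin overexpression
#'
#' Sets the three perturbation scalings of a [simulation_config()]:
#' `control` leaves all at 1; `cypin_oe_1` keeps AMPA conductance, reduces
#' connection density to 0.75 and doubles presynaptic current; `cypin_oe_2`
#' doubles all three. `custom` keeps whatever scalings the config already
#' carries.
#'
#' @param config a [simulation_config()].
#' @param condition one of `"control"`, `"cypin_oe_1"`, `"cypin_oe_2"`,
#'   `"custom"`.
#' @return the modified config, with the condition name attached as
#'   `config$condition`.
#' @export
apply_cypin_condition <- function(config, condition) {
  valid <- c("control", "cypin_oe_1", "cypin_oe_2", "custom")
  if (!is.character(condition) || length(condition) != 1L ||
      !(condition %in% valid)) {
    stop("unknown condition; valid conditions: ",
         paste(valid, collapse = ", "))
  }
  scalings <- switch(condition,
    control = c(1, 1, 1),
    cypin_oe_1 = c(1, 0.75, 2),
    cypin_oe_2 = c(2, 2, 2),
    custom = c(config$ampa_scale, config$cd_scale, config$ipre_scale))
  config$ampa_scale <- scalings[1]
  config$cd_scale <- scalings[2]
  config$ipre_scale <- scalings[3]
  config$condition <- condition
  config
}

sample_block <- function(pre_ids, post_ids, p) {
  if (p <= 0 || !length(pre_ids) || !length(post_ids)) {
    return(data.frame(pre = integer(0), post = integer(0)))
  }
  pre <- rep(pre_ids, times = length(post_ids))
  post <- rep(post_ids, each = length(pre_ids))
  ok <- pre != post
  pre <- pre[ok]; post <- post[ok]
  keep <- stats::runif(length(pre)) < p
  data.frame(pre = pre[keep], post = post[keep])
}

#' Sample the directed connectivity of a circuit
#'
#' Draws every possible directed connection independently with its
#' class-dependent probability multiplied by the connection-density scaling
#' (`cd_scale`, clipped to probability 1 with a warning). Self-connections
#' are excluded. Neurons `1..n_e` are excitatory, the rest inhibitory.
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `pre`, `post` (1-based neuron indices)
#'   and `is_ee` (logical, excitatory-to-excitatory).
#' @export
build_circuit <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- c(ee = config$p_ee, ei = config$p_ei,
         ie = config$p_ie, ii = config$p_ii) * config$cd_scale
  if (any(p > 1)) {
    warning("cd_scale pushes connection probabilities above 1; clipped")
    p <- pmin(p, 1)
  }
  e_ids <- seq_len(config$n_e)
  i_ids <- config$n_e + seq_len(config$n_i)
  blk <- function(pre_ids, post_ids, prob, is_ee) {
    d <- sample_block(pre_ids, post_ids, prob)
    d$is_ee <- rep(is_ee, nrow(d))
    d
  }
  with_seed(config$seed, {
    edges <- rbind(
      blk(e_ids, e_ids, p["ee"], TRUE),
      blk(e_ids, i_ids, p["ei"], FALSE),
      blk(i_ids, e_ids, p["ie"], FALSE),
      blk(i_ids, i_ids, p["ii"], FALSE)
    )
  })
  rownames(edges) <- NULL
  edges
}

# CSR over out-edges for all neurons plus CSC over in-edges restricted to
# E-E synapses (the STDP targets); all 0-based for the C++ core
edge_indices <- function(edges, n) {
  ord_out <- order(edges$pre)
  out_ptr <- c(0L, cumsum(tabulate(edges$pre, nbins = n)))
  ee <- which(edges$is_ee)
  ord_in <- ee[order(edges$post[ee])]
  in_ptr <- c(0L, cumsum(tabulate(edges$post[ee], nbins = n)))
  list(out_ptr = as.integer(out_ptr), out_idx = as.integer(ord_out - 1L),
       in_ptr = as.integer(in_ptr), in_idx = as.integer(ord_in - 1L))
}

sim_phases <- function(config, edges, phase_dur_s, phase_record, phase_mult,
                       sim_seed, record_v = integer(0)) {
  n <- config$n_e + config$n_i
  idx <- edge_indices(edges, n)
  params <- config$params
  params$ampa_scale <- config$ampa_scale
  with_seed(config$seed + 1L, {
    bias <- stats::rnorm(n, params$bias_mean, params$bias_sd)
  })
  # ipre_scale scales the presynaptic white-noise current; the per-neuron
  # constant bias is the initial external-current seeding and is scaled only
  # by protocol-level stimulation (the phase multipliers)
  sigma <- rep(params$sigma_pre * config$ipre_scale, n)
  res <- sim_core(
    config$n_e, config$n_i,
    as.integer(edges$pre - 1L), as.integer(edges$post - 1L),
    idx$out_ptr, idx$out_idx, idx$in_ptr, idx$in_idx,
    edges$is_ee,
    params, bias, sigma,
    phase_dur_s * 1000, phase_record, phase_mult,
    config$dt_ms, as.numeric(sim_seed),
    as.integer(record_v - 1L))
  res
}

#' Run one network simulation
#'
#' Builds the circuit, integrates the coupled membrane/synapse equations
#' with the Euler step of the config, discards the stabilization period and
#' returns the spike raster of the analysis window. Replicates and
#' conditions derive their own seeds via [run_condition_suite()].
#'
#' @param config a [simulation_config()]; apply a perturbation first with
#'   [apply_cypin_condition()] if wanted.
#' @param record_v optional neuron indices whose membrane potential is
#'   logged every step (use only for short diagnostic runs).
#' @return list of class `sim_result`: `raster` (a [spike_raster()],
#'   provenance `"simulated"`, times relative to the end of stabilization),
#'   `weights` (final E-E STDP weights alongside `edges`), `edges`, `v_log`
#'   (matrix, if requested), `config`, and a `manifest` (seed, scalings,
#'   durations, spike count).
#' @export
run_simulation <- function(config, record_v = integer(0)) {
  stopifnot(inherits(config, "simulation_config"))
  edges <- build_circuit(config)
  has_stab <- config$stabilization > 0
  phase_dur <- if (has_stab) c(config$stabilization, config$duration) else
    config$duration
  phase_rec <- if (has_stab) c(FALSE, TRUE) else TRUE
  n <- config$n_e + config$n_i
  phase_mult <- matrix(1, n, length(phase_dur))
  res <- sim_phases(config, edges, phase_dur, phase_rec, phase_mult,
                    sim_seed = config$seed, record_v = record_v)
  raster <- raster_from_spikes(res$spike_time, res$spike_neuron, n,
                               config$duration)
  manifest <- list(seed = config$seed, condition = config$condition,
                   ampa_scale = config$ampa_scale,
                   cd_scale = config$cd_scale,
                   ipre_scale = config$ipre_scale,
                   stabilization = config$stabilization,
                   duration = config$duration,
                   n_edges = nrow(edges), n_spikes = n_spikes(raster))
  structure(list(raster = raster, weights = res$weights, edges = edges,
                 v_log = if (length(record_v)) res$v_log else NULL,
                 config = config, manifest = manifest),
            class = "sim_result")
}

raster_from_spikes <- function(times, neurons, n, duration) {
  # clamp tiny float overshoot at the window edge
  times <- pmin(pmax(times, 0), duration)
  spikes <- split(times, factor(neurons, levels = seq_len(n)))
  names(spikes) <- sprintf("n%d", seq_len(n))
  spike_raster(spikes, duration, provenance = "simulated")
}

#' @export
print.sim_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<sim_result> %s | %d neurons, %d synapses | %d spikes in %.0f s (%.2f Hz/neuron)\n",
    if (is.null(m$condition)) "custom scalings" else m$condition,
    x$config$n_e + x$config$n_i, m$n_edges, m$n_spikes, m$duration,
    m$n_spikes / (m$duration * (x$config$n_e + x$config$n_i))))
  invisible(x)
}

#' Reference short-term-plasticity update (utilization/resource dynamics)
#'
#' Pure-R, single-synapse version of the event-driven update the simulator
#' core applies at every presynaptic spike: resources `x` recover toward 1
#' with `tau_rec`; utilization `u` relaxes toward `U` with `tau_facil` and
#' is incremented at the spike (facilitation); the released fraction is
#' `u * x`, which depletes `x`. With `tau_facil = 0` utilization stays at
#' `U` (pure depression).
#'
#' @param u,x utilization and resource state just after the previous spike.
#' @param dt_since_last time since the previous presynaptic spike, ms.
#' @param U,tau_rec,tau_facil plasticity constants (ms).
#' @return list with updated `u`, `x` and the `release` fraction of this
#'   spike.
#' @export
stp_update <- function(u, x, dt_since_last, U, tau_rec, tau_facil = 0) {
  x <- 1 - (1 - x) * exp(-dt_since_last / tau_rec)
  if (tau_facil > 0) {
    u <- U + (u - U) * exp(-dt_since_last / tau_facil)
    u <- u + U * (1 - u)
  } else {
    u <- U
  }
  release <- u * x
  list(u = u, x = x - release, release = release)
}

#' Reference STDP weight change for one spike pair
#'
#' Exponentially windowed pair rule: potentiation for pre-before-post
#' (`dt_pre_post > 0`), depression for post-before-pre, zero in the limit of
#' large separations.
#'
#' @param dt_pre_post `t_post - t_pre`, ms.
#' @param A_plus,A_minus amplitudes of potentiation and depression.
#' @param tau_plus,tau_minus window time constants, ms.
#' @return the (unclipped) weight change.
#' @export
stdp_delta <- function(dt_pre_post, A_plus = 0.01, A_minus = 0.0105,
                       tau_plus = 20, tau_minus = 20) {
  ifelse(dt_pre_post >= 0,
         A_plus * exp(-dt_pre_post / tau_plus),
         -A_minus * exp(dt_pre_post / tau_minus))
}
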