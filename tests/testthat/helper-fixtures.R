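# Shared fixtures, all built in code.

# block-diagonal weight matrix of k unit-weight cliques of size m
clique_matrix <- function(k, m) {
  W <- kronecker(diag(k), matrix(1, m, m))
  diag(W) <- 0
  W
}

# perfectly regular spike train at `rate` Hz
regular_train <- function(rate, duration) {
  seq(1 / rate, duration, by = 1 / rate)
}

# brute-force network-burst oracle: every window anchored at a spike,
# O(n^2), merged exactly like the documented rule
oracle_network_bursts <- function(times, min_spikes = 50, window = 0.05) {
  times <- sort(times)
  n <- length(times)
  qual <- integer(0)
  last <- integer(0)
  for (i in seq_len(n)) {
    cnt <- sum(times >= times[i] & times < times[i] + window)
    if (cnt >= min_spikes) {
      qual <- c(qual, i)
      last <- c(last, i + cnt - 1L)
    }
  }
  if (!length(qual)) return(list())
  events <- list()
  cf <- qual[1]; cl <- last[1]
  if (length(qual) > 1) {
    for (k in 2:length(qual)) {
      if (qual[k] <= cl) {
        cl <- max(cl, last[k])
      } else {
        events[[length(events) + 1]] <- c(start = times[cf], end = times[cl],
                                          n = cl - cf + 1)
        cf <- qual[k]; cl <- last[k]
      }
    }
  }
  events[[length(events) + 1]] <- c(start = times[cf], end = times[cl],
                                    n = cl - cf + 1)
  events
}

# brute-force weighted global efficiency via Floyd-Warshall on 1/w lengths
oracle_global_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(NA_real_)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# small, fast simulation configuration for protocol-level tests
tiny_config <- function(seed = 1L, duration = 10, stabilization = 1, ...) {
  simulation_config(
    n_e = 40, n_i = 10, p_ee = 0.2, p_ei = 0.2, p_ie = 0.3, p_ii = 0.3,
    stabilization = stabilization, duration = duration, seed = seed,
    params = model_parameters(...))
}
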