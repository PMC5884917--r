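# shared fixtures: all synthetic, built in code at test time

default_params <- function(L = 0.5) protocol_params(preferred_step_length = L)

# a small protocol for fast signal-level tests (21 targets, 2 shifts/type)
small_params <- function(L = 0.5) {
  protocol_params(preferred_step_length = L,
                  unperturbed_block_size = 21L,
                  perturbed_block_size = 68L,
                  shifts_per_type = 2L,
                  n_perturbed_blocks = 1L)
}

# deterministic test subject; noiseless unless stated
test_subject <- function(sigma = 0.03, bias = -0.01, L = 0.5,
                         marker_noise = 0, cop_noise = 0) {
  list(id = "T001", age = 12, sigma = sigma, error_bias = bias,
       preferred_step_length = L,
       kappa_gain = 0.5, kappa_knee = 1.5,
       marker_noise_sd = marker_noise, cop_noise_sd = cop_noise)
}

quiet_score <- function(...) suppressMessages(score_trial(...))

# independent oracle: population SD of raw errors as % of L
oracle_variability <- function(e, L) {
  100 / L * sqrt(mean((e - mean(e))^2))
}

# independent oracle: brute-force BH step-up
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  passes <- which(ranked <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(passes)) rejected[o[seq_len(max(passes))]] <- TRUE
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(ranked * m / seq_len(m))))
  list(adjusted = pmin(adj, 1), rejected = rejected)
}
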