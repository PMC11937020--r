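# Independent oracles used across tests (kept free of the code paths they
# check: direct evaluation, quadrature, root-finding, enumeration).

# direct pointwise evaluation of the decay law
oracle_intensity <- function(t, A, B, C) A / sinh(t / B + C)^2

# mean intensity over [0, W] by adaptive quadrature
oracle_window_mean <- function(A, B, C, W) {
  stats::integrate(function(t) oracle_intensity(t, A, B, C),
                   lower = 0, upper = W, rel.tol = 1e-10)$value / W
}

# decay time by root-finding on I(t) = I0 / m
oracle_decay_time <- function(A, B, C, m) {
  I0 <- oracle_intensity(0, A, B, C)
  stats::uniroot(function(t) oracle_intensity(t, A, B, C) - I0 / m,
                 interval = c(1e-9, 100 * B), tol = 1e-12)$root
}

# mean count of bin [t0, t0 + bw) by quadrature (counts, not rate)
oracle_bin_count <- function(t0, bw, A, B, C) {
  stats::integrate(function(t) oracle_intensity(t, A, B, C),
                   lower = t0, upper = t0 + bw, rel.tol = 1e-10)$value
}

# parameter grid used by the analytic-identity checks
gu_param_grid <- expand.grid(A = c(10, 100, 2000),
                             B = c(2, 10, 15, 60),
                             C = c(0.1, 0.5, 0.8, 2))

# a noise-free DL "trace" holding exact expected bin counts
noiseless_dl_trace <- function(A, B, C, duration = 300, bw = 1) {
  mu <- gu_bin_means(seq(0, duration - bw, by = bw), bw, A, B, C) * bw
  photon_trace(mu, bin_width = bw, run_kind = "DL", sample_id = "noiseless")
}
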