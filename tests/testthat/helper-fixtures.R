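# Shared fixtures. Traces constructed directly (not via the simulator)
# use the internal window_trace constructor.

mk_trace <- function(z, dt = 0.1, center = 0, k = 100, temperature = 310) {
  memperm:::window_trace(times = dt * seq_along(z), z = z, center = center,
                         force_constant = k, temperature = temperature)
}

mk_pmf <- function(z, dG, reference = "bulk-zeroed", side = "full",
                   bin_width = NA_real_) {
  memperm:::pmf_profile(z, dG, reference = reference, side = side,
                        bin_width = bin_width)
}

# constant-D diffusivity profile on a given grid
mk_dprof <- function(z, D) {
  structure(list(z = z, D = rep_len(D, length(z)),
                 windows = data.frame(), side = "full",
                 max_lag = NA, rule = "none"),
            class = "diffusivity_profile")
}

RT310 <- memperm::RGAS * 310

# effective standard error of the mean of an OU series with correlation
# time tau_c sampled every dt over total time T = n*dt
ou_se_mean <- function(v, tau_c, total_time) sqrt(v * 2 * tau_c / total_time)
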