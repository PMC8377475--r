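# shared fixture builders; all deterministic under explicit seeds

std_ring <- function(noise_sd = 0, seed = 1L, cambium = 150,
                     transition = 500, boundary = 1050, ...) {
  ring_truth(cambium, transition, boundary, noise_sd = noise_sd,
             seed = seed, ...)
}

std_profile <- function(truth = std_ring(), n_points = 500L)
  generate_profile(truth, n_points)

# logistic used by the season generator, for closed-form oracles
logistic <- function(t, A, t0, s) A / (1 + exp(-(t - t0) / s))

# closed-form day at which the logistic reaches fraction p of its asymptote
logistic_frac_day <- function(p, t0, s) t0 + s * log(p / (1 - p))

std_season <- function(seed = 1L, noise_frac = 0.03, ...)
  season_truth(seed = seed, noise_frac = noise_frac, ...)
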