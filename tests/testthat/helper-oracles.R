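# Shared helpers: independent oracles and small simulation configs.

# a sample of size n with exactly the requested mean and sd, so that
# stats::t.test() on it reproduces a summary-form Welch test
exact_moment_sample <- function(mu, sd, n) {
  x <- seq_len(n)
  mu + sd * (x - mean(x)) / stats::sd(x)
}

# Benjamini-Hochberg step-up applied by hand: p_(i) * m / i, enforced
# monotone from the largest rank down, capped at 1
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# a small experiment configuration: n carbons with simple preference
# structure, one coculture mean pattern, defaults overridable
small_config <- function(n_carbons = 6, cue_noise_sd = 0.02, seed = 1,
                         n_replicates = 3,
                         mean_ec = NULL, mean_pp = NULL,
                         interaction_spec = NULL,
                         log10_mean = -1, log10_sd = 0.1,
                         timepoints = seq(0, 24, by = 4)) {
  carbons <- sprintf("C%02d", seq_len(n_carbons))
  if (is.null(mean_ec)) mean_ec <- rep(0.3, n_carbons)
  if (is.null(mean_pp)) mean_pp <- rep(0.1, n_carbons)
  mono_means <- data.frame(carbon_id = carbons, mean_cue_ec = mean_ec,
                           mean_cue_pp = mean_pp, stringsAsFactors = FALSE)
  ratio_spec <- expand.grid(culture = coculture_labels(),
                            carbon_id = carbons, stringsAsFactors = FALSE)
  ratio_spec$log10_mean <- log10_mean
  ratio_spec$log10_sd <- log10_sd
  simulation_config(mono_means = mono_means, ratio_spec = ratio_spec,
                    interaction_spec = interaction_spec,
                    n_replicates = n_replicates,
                    timepoints = timepoints,
                    cue_noise_sd = cue_noise_sd, seed = seed)
}

# run plate readings through the reader/normaliser into a cue_matrix
pipeline_cue <- function(ex, time_h = 24) {
  r <- load_readings(ex$readings, ex$layout)
  extract_cue(a1_zero(r), ex$layout, time_h = time_h)
}
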