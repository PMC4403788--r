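# Shared fixtures and independent oracles for the test suite.

# Alexa-488-like donor / Alexa-594-like acceptor parameter set used by the
# simulation studies (lifetimes from the literature; yield and radii as
# measured for this pair).
default_params <- function(...) {
  args <- list(tau_D0 = 4.1, phi_D = 0.6, R0 = 5.4, tau_A0 = 3.9,
               P_excitation = 0.01)
  do.call(photophysics_params, utils::modifyList(args, list(...)))
}

# Donor-only fibril-like scene: the dense labeled assembly used for the
# photon-threshold studies.
donor_only_fibril <- function(seed = 99) {
  set.seed(seed)
  fibril_scene(fibril_model(acceptor_fraction = 0))
}

# One isolated donor-acceptor pair at distance r (frozen positions).
pair_scene_at <- function(r, n_pairs = 1) {
  fixed_pair_scene(r, pair_counts = n_pairs, spacing = 32, R0 = 5.4)
}

# Event-driven continuous-time oracle for a single donor with a fixed
# acceptor environment: waiting time ~ Exp(total rate), channel drawn by
# rate ratio. Returns per-channel emission counts on the config grid.
event_oracle_emission <- function(distances, params, config, n_draws) {
  k_em <- params$phi_D / params$tau_D0
  k_nr <- (1 - params$phi_D) / params$tau_D0
  kt <- if (length(distances) > 0) {
    fret_rate(distances, params$R0, params$tau_D0)
  } else {
    numeric(0)
  }
  rates <- c(k_em, k_nr, kt)
  K <- sum(rates)
  wait <- stats::rexp(n_draws, K)
  chan <- sample.int(length(rates), n_draws, replace = TRUE, prob = rates)
  t_emit <- wait[chan == 1 & wait < config$time_window]
  tabulate(floor(t_emit / config$dt) + 1L, nbins = config$n_channels)
}

# Greedily merge consecutive channels so every group has expected count of
# at least min_expected; returns the grouping index.
bin_groups <- function(expected, min_expected = 5) {
  g <- integer(length(expected))
  gi <- 1L
  acc <- 0
  for (i in seq_along(expected)) {
    g[i] <- gi
    acc <- acc + expected[i]
    if (acc >= min_expected && i < length(expected)) {
      gi <- gi + 1L
      acc <- 0
    }
  }
  # fold a trailing underfull group into the previous one
  if (acc < min_expected && gi > 1) g[g == gi] <- gi - 1L
  g
}

# Chi-square goodness of fit of observed channel counts against expected
# channel probabilities, with tail aggregation. Returns the p-value (or NA
# when there are too few informative cells for the test).
chisq_vs_probs <- function(counts, probs, min_expected = 5) {
  probs <- probs / sum(probs)
  expected <- probs * sum(counts)
  g <- bin_groups(expected, min_expected)
  obs <- tapply(counts, g, sum)
  p <- tapply(probs, g, sum)
  if (length(obs) < 3) return(NA_real_)
  suppressWarnings(stats::chisq.test(obs, p = p / sum(p))$p.value)
}

# Two-sample chi-square homogeneity test between two count vectors on the
# same channel grid, with tail aggregation.
chisq_two_sample <- function(a, b, min_expected = 5) {
  expected <- (a + b) / 2
  g <- bin_groups(expected, min_expected)
  tab <- cbind(tapply(a, g, sum), tapply(b, g, sum))
  keep <- rowSums(tab) > 0
  suppressWarnings(stats::chisq.test(tab[keep, ])$p.value)
}
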