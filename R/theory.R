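## Closed-form expected decay for mixtures of fixed donor environments;
## the engine's validation oracle.

#' A donor environment
#'
#' A donor environment is the multiset of acceptor distances surrounding
#' a class of donors, together with the fraction of donors that see it.
#' Mixtures of environments are the input of [expected_decay()].
#'
#' @param fraction Mixture weight (>= 0); weights across a mixture must
#'   sum to 1.
#' @param distances Acceptor distances (nm, > 0); may be empty for a
#'   donor-only environment.
#' @return An object of class `donor_environment`.
#' @export
donor_environment <- function(fraction, distances = numeric(0)) {
  if (fraction < 0) stop("'fraction' must be >= 0")
  if (length(distances) > 0 && any(distances <= 0)) {
    stop("distances must be > 0")
  }
  structure(list(fraction = fraction, distances = as.numeric(distances)),
            class = "donor_environment")
}

#' Expected photon counts per channel for an environment mixture
#'
#' Evaluates the closed-form decay
#' `N_P(t) = sum_i f_i * k_emission * exp(-K_i t)`, with `K_i` the total
#' deactivation rate of environment `i` (intrinsic `1/tau_D0` plus the
#' FRET rate of every acceptor in the environment), at the midpoint of
#' each TCSPC channel. The first channel is instead averaged over 1000
#' equal subintervals, because donors with very close acceptors decay
#' faster than the channel width resolves and the density can vary
#' strongly across the first channel; `average_all_bins = TRUE` extends
#' the subinterval averaging to every channel for extremely fast decays.
#'
#' The absolute scale (per excited donor, per ns) is arbitrary for
#' comparisons with a simulated histogram; [decay_residuals()] rescales.
#'
#' @param environments A [donor_environment], or a list of them whose
#'   fractions sum to 1.
#' @param params A [photophysics_params].
#' @param config A [sim_config] defining the channel grid.
#' @param subintervals Number of subintervals for the first channel
#'   (default 1000).
#' @param average_all_bins Average every channel over subintervals.
#' @return A `decay_curve`: expected value per channel plus the channel
#'   grid.
#' @examples
#' pp <- photophysics_params(tau_D0 = 4.1, phi_D = 0.6, R0 = 5.4)
#' expected_decay(donor_environment(1, distances = 5.4), pp, sim_config())
#' @export
expected_decay <- function(environments, params, config = sim_config(),
                           subintervals = 1000, average_all_bins = FALSE) {
  stopifnot(inherits(params, "photophysics_params"),
            inherits(config, "sim_config"))
  if (inherits(environments, "donor_environment")) {
    environments <- list(environments)
  }
  stopifnot(all(vapply(environments, inherits, TRUE, "donor_environment")))
  fr <- vapply(environments, function(e) e$fraction, 0)
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("environment fractions must sum to 1")
  }
  dt <- config$dt
  n <- config$n_channels
  k_em <- params$phi_D / params$tau_D0
  t_mid <- (seq_len(n) - 0.5) * dt
  values <- numeric(n)
  # Subinterval midpoints within one channel, as offsets in [0, dt).
  sub <- (seq_len(subintervals) - 0.5) / subintervals * dt
  for (e in environments) {
    K <- 1 / params$tau_D0 +
      if (length(e$distances) > 0) {
        sum(fret_rate(e$distances, params$R0, params$tau_D0))
      } else 0
    contrib <- k_em * exp(-K * t_mid)
    contrib[1] <- k_em * mean(exp(-K * sub))
    if (average_all_bins && n > 1) {
      left <- (seq_len(n) - 1) * dt
      contrib <- k_em * vapply(left, function(t0) mean(exp(-K * (t0 + sub))), 0)
    }
    values <- values + e$fraction * contrib
  }
  structure(
    list(values = values,
         time = (seq_len(n) - 1) * dt,
         time_mid = t_mid,
         dt = dt,
         environments = environments),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(
    "Expected decay curve: %d channels x %.5g ns, %d environment(s)\n",
    length(x$values), x$dt, length(x$environments)))
  invisible(x)
}

#' @export
plot.decay_curve <- function(x, log = "y", ...) {
  matplot(x$time_mid, x$values, type = "l", lty = 1, log = log,
          xlab = "time (ns)", ylab = "expected photons (arb.)", ...)
  invisible(x)
}

#' Donor environments of a fixed-position scene
#'
#' Maps a scene with zero linker lengths onto [expected_decay()]
#' environments: donors with identical acceptor-distance multisets (the
#' distances to their relevant acceptors, within the neighbour cutoff)
#' are grouped into one environment whose fraction is their share of the
#' donors. With nonzero linkers the per-cycle position resampling makes
#' the distance distribution continuous and the closed form does not
#' apply; such parameter sets are refused.
#'
#' @param scene A [fret_scene].
#' @param params A [photophysics_params] with zero linker lengths.
#' @param cutoff_multiplier Neighbour cutoff in units of `R0` (default 2,
#'   matching the engine).
#' @param digits Distances are rounded to this many decimals (nm) when
#'   grouping multisets (default 9).
#' @return A list of [donor_environment] objects.
#' @export
mixture_from_scene <- function(scene, params, cutoff_multiplier = 2,
                               digits = 9) {
  stopifnot(inherits(scene, "fret_scene"),
            inherits(params, "photophysics_params"))
  if (params$linker_D != 0 || params$linker_A != 0) {
    stop("mixture_from_scene() requires zero linker lengths: ",
         "with flexible linkers the distance distribution is continuous")
  }
  n <- nrow(scene$donor_sites)
  if (n == 0) stop("scene has no donors")
  d <- site_distances(scene$donor_sites, scene$acceptor_sites,
                      scene$box, scene$periodic)
  cutoff <- cutoff_multiplier * params$R0
  keys <- character(n)
  dist_list <- vector("list", n)
  for (i in seq_len(n)) {
    di <- if (ncol(d) > 0) sort(d[i, d[i, ] <= cutoff]) else numeric(0)
    dist_list[[i]] <- di
    keys[i] <- paste(round(di, digits), collapse = ",")
  }
  groups <- split(seq_len(n), keys)
  lapply(unname(groups), function(idx) {
    donor_environment(length(idx) / n, dist_list[[idx[1]]])
  })
}
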