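## The excitation-cycle Monte Carlo engine and its step-level primitives.

#' Simulation configuration
#'
#' Holds the TCSPC acquisition settings mirrored by the simulation. The
#' simulation time step equals the channel width
#' `dt = time_window / n_channels`, i.e. every detector channel is one
#' simulated step.
#'
#' @param time_window Observation window after each pulse (ns, default 50).
#' @param n_channels Number of TCSPC channels (default 1024).
#' @param photon_threshold Excitation cycles are repeated until one
#'   channel has collected this many emitted photons (default 10000, the
#'   smallest count at which early-channel statistics are free of
#'   stopping bias; see the package vignette).
#' @param seed Integer RNG seed, or `NULL` to continue from the current
#'   RNG state.
#' @param track_acceptor_decay If `TRUE`, cycles always run to the window
#'   end so acceptor deactivations are sampled over the whole window;
#'   otherwise a cycle ends as soon as no excited donor remains.
#' @param cutoff_multiplier Acceptors beyond `cutoff_multiplier * R0`
#'   (plus linker margins) are ignored (default 2).
#' @param resample_positions If `TRUE` (default) dye positions are redrawn
#'   from the linker sphere before every excitation cycle; `FALSE`
#'   freezes the positions drawn at the start of the run (with zero
#'   linkers, the labeling sites).
#' @param max_cycles Safety cap on the number of excitation cycles.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(time_window = 50, n_channels = 1024,
                       photon_threshold = 10000, seed = NULL,
                       track_acceptor_decay = FALSE,
                       cutoff_multiplier = 2,
                       resample_positions = TRUE,
                       max_cycles = 1e9) {
  if (time_window <= 0) stop("'time_window' must be > 0")
  if (n_channels < 1) stop("'n_channels' must be >= 1")
  if (photon_threshold < 1) stop("'photon_threshold' must be >= 1")
  if (cutoff_multiplier <= 0) stop("'cutoff_multiplier' must be > 0")
  if (max_cycles < 1) stop("'max_cycles' must be >= 1")
  structure(
    list(time_window = time_window, n_channels = as.integer(n_channels),
         photon_threshold = photon_threshold, seed = seed,
         track_acceptor_decay = isTRUE(track_acceptor_decay),
         cutoff_multiplier = cutoff_multiplier,
         resample_positions = isTRUE(resample_positions),
         max_cycles = max_cycles,
         dt = time_window / n_channels),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %g ns window, %d channels (dt = %.5g ns)\n",
    x$time_window, x$n_channels, x$dt))
  cat(sprintf("  photon threshold %g, cutoff %g x R0, %s positions\n",
              x$photon_threshold, x$cutoff_multiplier,
              if (x$resample_positions) "per-cycle resampled" else "frozen"))
  invisible(x)
}

#' Excite a random subset of donors
#'
#' Each donor is assigned an independent uniform(0, 1) value; donors whose
#' value falls below `P_excitation` are excited. If no donor is excited
#' the whole assignment is redrawn, so every cycle has at least one
#' excited donor. The excited donors are returned ordered by their
#' assigned value, ascending, which randomises the order in which they
#' are stepped through the cycle.
#'
#' @param n_donors Number of donors (>= 1).
#' @param P_excitation Per-donor excitation probability, in `(0, 1]`.
#' @return Integer vector of excited donor indices, in excitation order.
#' @export
excite_donors <- function(n_donors, P_excitation) {
  if (n_donors < 1) stop("'n_donors' must be >= 1")
  if (P_excitation <= 0 || P_excitation > 1) {
    stop("'P_excitation' must be in (0, 1]")
  }
  repeat {
    u <- runif(n_donors)
    excited <- which(u < P_excitation)
    if (length(excited) > 0) break
  }
  excited[order(u[excited])]
}

#' Advance the excited-acceptor pool by one time step
#'
#' Each excited acceptor independently relaxes with probability
#' `1 - exp(-dt / tau_A0)`; relaxed acceptors are available for energy
#' transfer again from the next donor evaluation onward.
#'
#' @param excited_acceptors Integer indices of currently excited
#'   acceptors.
#' @param tau_A0 Acceptor lifetime (ns, > 0).
#' @param dt Step length (ns, > 0).
#' @return List with `excited` (still-excited indices) and `deactivated`
#'   (indices that relaxed during this step).
#' @export
step_acceptors <- function(excited_acceptors, tau_A0, dt) {
  if (dt <= 0) stop("'dt' must be > 0")
  if (tau_A0 <= 0) stop("'tau_A0' must be > 0")
  n <- length(excited_acceptors)
  if (n == 0) {
    return(list(excited = integer(0), deactivated = integer(0)))
  }
  relax <- runif(n) < (1 - exp(-dt / tau_A0))
  list(excited = excited_acceptors[!relax],
       deactivated = excited_acceptors[relax])
}

#' Advance one excited donor by one time step
#'
#' With probability `1 - exp(-K dt)` (total rate `K` over the supplied
#' channels) the donor deactivates; the deactivation channel is then
#' drawn in proportion to the channel rates.
#'
#' @param rates A `rate_set` from [donor_rate_set()], built over the
#'   currently *available* acceptors only.
#' @param dt Step length (ns, > 0).
#' @return List with `deactivated` (logical), `channel` (`"emission"`,
#'   `"nonradiative"`, `"fret"` or `NA` if the donor stays excited) and
#'   `acceptor` (index of the acceptor excited by a FRET event, else `NA`).
#' @export
step_donor <- function(rates, dt) {
  stopifnot(inherits(rates, "rate_set"))
  p <- deactivation_probability(rates, dt)
  if (runif(1) >= p) {
    return(list(deactivated = FALSE, channel = NA_character_,
                acceptor = NA_integer_))
  }
  v <- runif(1) * sum(rates$rate)
  i <- findInterval(v, cumsum(rates$rate), left.open = TRUE) + 1L
  i <- min(i, nrow(rates))
  list(deactivated = TRUE, channel = rates$channel[i],
       acceptor = rates$acceptor[i])
}

#' Run the Monte Carlo TCSPC simulation
#'
#' Repeats excitation cycles -- redraw dye positions from the linker
#' spheres, excite a random donor subset, then march through the TCSPC
#' channels stepping acceptors (recovery) before donors (deactivation)
#' -- until one channel has accumulated `photon_threshold` emitted
#' photons. Within a step, donors are evaluated in excitation order; an
#' acceptor excited by FRET is blocked immediately for subsequent donors
#' and first becomes eligible for recovery in the next step. All photons
#' emitted during a cycle are counted in the channel of their step.
#'
#' The compiled inner loop implements exactly the per-step logic of
#' [excite_donors()], [step_acceptors()] and [step_donor()] and draws all
#' random numbers from R's generator, so a run is bitwise reproducible
#' given `config$seed`.
#'
#' @param scene A [fret_scene].
#' @param params A [photophysics_params]; `tau_A0` is required if the
#'   scene has acceptors.
#' @param config A [sim_config].
#' @return A `tcspc_histogram`: per-channel counts of every donor
#'   deactivation class plus acceptor deactivations, run totals, and the
#'   indices of donors with no acceptor within the relevant distance.
#' @examples
#' sc <- fret_scene(c(20, 10, 10), donor_sites = c(5, 5, 5),
#'                  acceptor_sites = c(10.4, 5, 5))
#' pp <- photophysics_params(tau_D0 = 4.1, phi_D = 0.6, R0 = 5.4,
#'                           tau_A0 = 3.9, P_excitation = 1)
#' h <- run_simulation(sc, pp, sim_config(photon_threshold = 50, seed = 1))
#' summary(h)
#' @export
run_simulation <- function(scene, params, config = sim_config()) {
  stopifnot(inherits(scene, "fret_scene"),
            inherits(params, "photophysics_params"),
            inherits(config, "sim_config"))
  n_donors <- nrow(scene$donor_sites)
  n_acceptors <- nrow(scene$acceptor_sites)
  if (n_donors == 0) stop("scene has no donors: nothing to excite")
  if (n_acceptors > 0 && is.null(params$tau_A0)) {
    stop("'tau_A0' is required when the scene contains acceptors")
  }
  if (params$phi_D == 0) {
    warning("phi_D = 0: no photons are ever emitted, ",
            "the photon threshold is unreachable (max_cycles applies)")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .run_simulation_cpp(
    scene$donor_sites, scene$acceptor_sites,
    scene$box, scene$periodic,
    params$linker_D, params$linker_A,
    params$R0, params$tau_D0, params$phi_D,
    if (is.null(params$tau_A0)) 1 else params$tau_A0,
    params$P_excitation,
    config$dt, config$n_channels, config$photon_threshold,
    config$cutoff_multiplier,
    config$track_acceptor_decay, config$resample_positions,
    config$max_cycles
  )
  if (!res$threshold_reached) {
    warning(sprintf(
      "photon threshold %g not reached within %g cycles (max bin: %g)",
      config$photon_threshold, res$cycles, res$max_bin_count))
  }
  counts <- cbind(emission = res$emission,
                  nonradiative = res$nonradiative,
                  fret = res$fret,
                  acceptor_deactivation = res$acceptor_deactivation)
  structure(
    list(time = (seq_len(config$n_channels) - 1) * config$dt,
         dt = config$dt,
         counts = counts,
         cycles = res$cycles,
         excitations = res$excitations,
         fret_total = res$fret_total,
         acceptor_excitations = res$fret_total,
         acceptor_deactivations_total = res$acceptor_deactivations_total,
         donors_without_acceptor = res$donors_without_acceptor,
         threshold_reached = res$threshold_reached,
         config = config, params = params,
         seed = config$seed),
    class = "tcspc_histogram"
  )
}

#' Total emitted donor photons in a histogram
#' @param hist A `tcspc_histogram`.
#' @return Total emission count.
#' @export
total_photons <- function(hist) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  sum(hist$counts[, "emission"])
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf(
    "TCSPC histogram: %d channels x %.4g ns, %g excitation cycles\n",
    length(x$time), x$dt, x$cycles))
  cat(sprintf("  photons (emission): %g, peak channel count: %g\n",
              sum(x$counts[, "emission"]), max(x$counts[, "emission"])))
  cat(sprintf("  donor deactivations: %g (FRET: %g), acceptor deactivations: %g\n",
              sum(x$counts[, c("emission", "nonradiative", "fret")]),
              x$fret_total, x$acceptor_deactivations_total))
  invisible(x)
}

#' @export
summary.tcspc_histogram <- function(object, ...) {
  x <- object
  deact <- sum(x$counts[, c("emission", "nonradiative", "fret")])
  out <- list(
    channels = length(x$time), dt = x$dt, cycles = x$cycles,
    excitations = x$excitations,
    photons = sum(x$counts[, "emission"]),
    peak = max(x$counts[, "emission"]),
    donor_deactivations = deact,
    fret_fraction = if (deact > 0) x$fret_total / deact else NA_real_,
    acceptor_deactivations = x$acceptor_deactivations_total,
    donors_without_acceptor = length(x$donors_without_acceptor)
  )
  class(out) <- "summary.tcspc_histogram"
  out
}

#' @export
print.summary.tcspc_histogram <- function(x, ...) {
  cat(sprintf("%d channels (dt = %.5g ns), %g cycles, %g excitations\n",
              x$channels, x$dt, x$cycles, x$excitations))
  cat(sprintf("photons %g (peak %g); FRET fraction of deactivations: %s\n",
              x$photons, x$peak,
              ifelse(is.na(x$fret_fraction), "-",
                     sprintf("%.4f", x$fret_fraction))))
  cat(sprintf("%d donor(s) without any acceptor in relevant distance\n",
              x$donors_without_acceptor))
  invisible(x)
}

#' Plot a simulated TCSPC histogram
#'
#' Emission counts per channel on a log count axis, the conventional
#' representation of fluorescence decays.
#'
#' @param x A `tcspc_histogram`.
#' @param channels Which count columns to draw (default `"emission"`).
#' @param log Axis specification passed to [graphics::matplot()].
#' @param ... Further plot arguments.
#' @export
plot.tcspc_histogram <- function(x, channels = "emission", log = "y", ...) {
  y <- x$counts[, channels, drop = FALSE]
  y[y == 0] <- NA
  matplot(x$time, y, type = "l", lty = 1, log = log,
          xlab = "time (ns)", ylab = "counts", ...)
  if (length(channels) > 1) {
    legend("topright", legend = channels, col = seq_along(channels),
           lty = 1, bty = "n")
  }
  invisible(x)
}
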