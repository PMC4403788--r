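## Closed-form FRET photophysics: rates, probabilities, Forster radius.

#' Photophysical parameter set for a donor/acceptor dye pair
#'
#' Bundles the dye constants used throughout the simulator. Distances are
#' in nm, lifetimes in ns. The donor lifetime `tau_D0` (lifetime in the
#' absence of acceptors) has no default: it must be measured or taken from
#' the literature for the dye at hand.
#'
#' The orientation factor `kappa2` defaults to 2/3, the isotropic
#' fast-rotation average; it enters only through [forster_radius()] and is
#' never orientation-sampled here. The donor's intrinsic deactivation is
#' split into exactly two channels, radiative and non-radiative,
#' partitioned by the quantum yield `phi_D`; any further non-FRET
#' deactivation pathway is absorbed into the non-radiative channel.
#'
#' @param tau_D0 Donor lifetime without acceptor (ns, > 0).
#' @param phi_D Donor fluorescence quantum yield, in `[0, 1]`.
#' @param R0 Forster radius (nm, > 0).
#' @param tau_A0 Acceptor lifetime (ns, > 0); may be `NULL` for
#'   donor-only systems.
#' @param phi_A Acceptor quantum yield, in `[0, 1]`, or `NULL`.
#' @param kappa2 Dipole orientation factor (dimensionless, >= 0).
#' @param refractive_index Refractive index of the medium (> 0).
#' @param P_excitation Per-cycle donor excitation probability, in `(0, 1]`.
#' @param linker_D,linker_A Dye linker lengths (nm, >= 0): the distance by
#'   which each dye is displaced from its labeling site in a random
#'   direction at the start of every excitation cycle.
#'
#' @return An object of class `photophysics_params`.
#' @examples
#' photophysics_params(tau_D0 = 4.1, phi_D = 0.6, R0 = 5.4, tau_A0 = 3.9)
#' @export
photophysics_params <- function(tau_D0, phi_D, R0,
                                tau_A0 = NULL, phi_A = NULL,
                                kappa2 = 2 / 3, refractive_index = 1.33,
                                P_excitation = 0.01,
                                linker_D = 0, linker_A = 0) {
  stopifnot(is.numeric(tau_D0), length(tau_D0) == 1L)
  if (!is.finite(tau_D0) || tau_D0 <= 0) stop("'tau_D0' must be > 0")
  if (!is.numeric(phi_D) || phi_D < 0 || phi_D > 1) {
    stop("'phi_D' must be in [0, 1]")
  }
  if (!is.numeric(R0) || R0 <= 0) stop("'R0' must be > 0")
  if (!is.null(tau_A0) && (!is.numeric(tau_A0) || tau_A0 <= 0)) {
    stop("'tau_A0' must be > 0")
  }
  if (!is.null(phi_A) && (phi_A < 0 || phi_A > 1)) {
    stop("'phi_A' must be in [0, 1]")
  }
  if (kappa2 < 0) stop("'kappa2' must be >= 0")
  if (refractive_index <= 0) stop("'refractive_index' must be > 0")
  if (P_excitation <= 0 || P_excitation > 1) {
    stop("'P_excitation' must be in (0, 1]")
  }
  if (linker_D < 0 || linker_A < 0) stop("linker lengths must be >= 0")
  structure(
    list(
      tau_D0 = tau_D0, phi_D = phi_D, R0 = R0,
      tau_A0 = tau_A0, phi_A = phi_A,
      kappa2 = kappa2, refractive_index = refractive_index,
      P_excitation = P_excitation,
      linker_D = linker_D, linker_A = linker_A
    ),
    class = "photophysics_params"
  )
}

#' @export
print.photophysics_params <- function(x, ...) {
  cat("Photophysics parameters\n")
  cat(sprintf("  donor:    tau_D0 = %g ns, phi_D = %g, linker = %g nm\n",
              x$tau_D0, x$phi_D, x$linker_D))
  if (!is.null(x$tau_A0)) {
    cat(sprintf("  acceptor: tau_A0 = %g ns%s, linker = %g nm\n", x$tau_A0,
                if (is.null(x$phi_A)) "" else sprintf(", phi_A = %g", x$phi_A),
                x$linker_A))
  }
  cat(sprintf("  transfer: R0 = %g nm, kappa2 = %g, n = %g\n",
              x$R0, x$kappa2, x$refractive_index))
  cat(sprintf("  excitation probability per cycle: %g\n", x$P_excitation))
  invisible(x)
}

#' Read photophysics parameters from a YAML file
#'
#' The file is a flat key/value mapping whose keys mirror the arguments of
#' [photophysics_params()] (e.g. `tau_D0: 4.1`). Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `photophysics_params` object.
#' @export
read_photophysics <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(photophysics_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown photophysics key(s): ", paste(bad, collapse = ", "))
  }
  do.call(photophysics_params, vals)
}

#' FRET transfer rate at a given donor-acceptor distance
#'
#' Computes the Forster transfer rate
#' `k_T = (1 / tau_D0) * (R0 / r)^6`. At `r = R0` the transfer rate
#' equals the donor's total intrinsic deactivation rate, so transfer and
#' intrinsic decay are equally likely (efficiency 1/2).
#'
#' @param r Donor-acceptor distance(s) (nm, > 0); vectorised.
#' @param R0 Forster radius (nm, > 0).
#' @param tau_D0 Donor lifetime without acceptor (ns, > 0).
#' @return Transfer rate(s) in 1/ns.
#' @examples
#' fret_rate(5.4, R0 = 5.4, tau_D0 = 4) # == 1/4
#' @export
fret_rate <- function(r, R0, tau_D0) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("'r' must be > 0")
  if (!is.numeric(R0) || R0 <= 0) stop("'R0' must be > 0")
  if (!is.numeric(tau_D0) || tau_D0 <= 0) stop("'tau_D0' must be > 0")
  (1 / tau_D0) * (R0 / r)^6
}

#' Deactivation probability within a time step
#'
#' Probability that an excited dye with total deactivation rate
#' `sum(rates)` deactivates within a step of length `dt`:
#' `P = 1 - exp(-sum(k_i) * dt)`.
#'
#' @param rates A [rate_set] or a numeric vector of rates (1/ns, >= 0).
#' @param dt Step length (ns, > 0).
#' @return Probability in `[0, 1)`.
#' @export
deactivation_probability <- function(rates, dt) {
  k <- if (inherits(rates, "rate_set")) rates$rate else rates
  if (any(k < 0)) stop("rates must be >= 0")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  1 - exp(-sum(k) * dt)
}

#' Forster radius from spectroscopic ingredients
#'
#' Evaluates
#' `R0 = (9 ln(10) kappa2 phi_D J / (128 pi^5 N_A n^4))^(1/6)`.
#'
#' Unit bookkeeping: the overlap integral `J` is expected in
#' M^-1 cm^-1 nm^4 (the customary tabulated unit), which equals
#' 1e-37 m^6/mol; with Avogadro's number in 1/mol the bracket is in m^6
#' and is converted to nm^6 (1 m^6 = 1e54 nm^6) before the sixth root, so
#' the result is in nm. Equivalent to the shortcut
#' `R0[angstrom] = 0.211 (kappa2 n^-4 phi_D J)^(1/6)`.
#'
#' @param kappa2 Orientation factor (>= 0; 2/3 for isotropic fast rotation).
#' @param phi_D Donor quantum yield, in `(0, 1]`.
#' @param n Refractive index (> 0).
#' @param J Overlap integral in M^-1 cm^-1 nm^4 (>= 0).
#' @return Forster radius in nm.
#' @export
forster_radius <- function(kappa2, phi_D, n, J) {
  if (kappa2 < 0) stop("'kappa2' must be >= 0")
  if (phi_D <= 0 || phi_D > 1) stop("'phi_D' must be in (0, 1]")
  if (n <= 0) stop("'n' must be > 0")
  if (J < 0) stop("'J' must be >= 0")
  r0_6 <- 9 * log(10) * kappa2 * phi_D * J /
    (128 * pi^5 * .avogadro * n^4) * 1e-37 * 1e54
  r0_6^(1 / 6)
}

#' Quantum yield from a set of deactivation rates
#'
#' `Phi = k_fluorescence / sum(k_i)`: the fraction of deactivations that
#' emit a photon.
#'
#' @param k_fluorescence Radiative rate (1/ns, >= 0).
#' @param all_rates A [rate_set] or numeric vector of all deactivation
#'   rates, including `k_fluorescence`.
#' @return Dimensionless yield in `[0, 1]`.
#' @export
quantum_yield <- function(k_fluorescence, all_rates) {
  k <- if (inherits(all_rates, "rate_set")) all_rates$rate else all_rates
  if (any(k < 0) || k_fluorescence < 0) stop("rates must be >= 0")
  total <- sum(k)
  if (total <= 0) stop("total deactivation rate must be > 0")
  k_fluorescence / total
}

#' Per-cycle donor excitation probability from instrument parameters
#'
#' Probability that a given donor is excited by one excitation pulse:
#' the number of photons in the pulse (`I * dt_pulse * A / E_P`) times the
#' absorbed fraction `1 - 10^(-A_abs)` (Beer-Lambert, with absorbance
#' `A_abs = eps_D * l * c`), divided by the number of donors. The donor
#' concentration `c` is the number density `N_D / V` converted to mol/L
#' via Avogadro's number so that `eps_D * l * c` is dimensionless.
#'
#' @param I Irradiance of the excitation pulse (W/cm^2, >= 0).
#' @param dt_pulse Duration of the light pulse (s, >= 0).
#' @param A Illuminated surface area (cm^2, >= 0).
#' @param E_P Energy of a single photon (J, > 0).
#' @param N_D Number of donors in the excited volume (>= 1).
#' @param eps_D Donor extinction coefficient (M^-1 cm^-1, >= 0).
#' @param l Length of the excited volume along the beam (cm, >= 0).
#' @param V Excited volume (cm^3, > 0).
#' @return Probability in `[0, 1]`; an error is raised if the parameter
#'   set yields a value above 1 (unphysical combination).
#' @export
excitation_probability <- function(I, dt_pulse, A, E_P, N_D, eps_D, l, V) {
  vals <- c(I, dt_pulse, A, E_P, eps_D, l)
  if (any(vals < 0)) stop("all physical quantities must be >= 0")
  if (E_P <= 0) stop("'E_P' must be > 0")
  if (N_D < 1) stop("'N_D' must be >= 1")
  if (V <= 0) stop("'V' must be > 0")
  conc_molar <- N_D / .avogadro / (V * 1e-3) # cm^3 -> L
  p <- I * dt_pulse * A / (E_P * N_D) * (1 - 10^(-eps_D * l * conc_molar))
  if (p > 1) {
    stop(sprintf(
      "excitation probability %.3g exceeds 1: unphysical parameter set", p
    ))
  }
  p
}

#' Deactivation rate set of an excited donor
#'
#' Builds the full channel table for one excited donor: the radiative
#' channel `phi_D / tau_D0`, the non-radiative channel
#' `(1 - phi_D) / tau_D0`, and one FRET channel per available acceptor via
#' [fret_rate()]. The two intrinsic channels always sum to `1 / tau_D0`.
#'
#' @param params A [photophysics_params] object.
#' @param acceptor_distances Distances (nm, > 0) to the available
#'   acceptors; may be empty.
#' @return A `rate_set`: a data frame with columns `channel`
#'   (`"emission"`, `"nonradiative"` or `"fret"`), `acceptor` (index into
#'   `acceptor_distances`, `NA` for intrinsic channels) and `rate` (1/ns).
#' @examples
#' p <- photophysics_params(tau_D0 = 4, phi_D = 0.6, R0 = 5.4)
#' donor_rate_set(p, acceptor_distances = c(5.4, 10.8))
#' @export
donor_rate_set <- function(params, acceptor_distances = numeric(0)) {
  stopifnot(inherits(params, "photophysics_params"))
  n_acc <- length(acceptor_distances)
  kt <- if (n_acc > 0) {
    fret_rate(acceptor_distances, params$R0, params$tau_D0)
  } else {
    numeric(0)
  }
  out <- data.frame(
    channel = c("emission", "nonradiative", rep("fret", n_acc)),
    acceptor = c(NA_integer_, NA_integer_, seq_len(n_acc)),
    rate = c(params$phi_D / params$tau_D0,
             (1 - params$phi_D) / params$tau_D0,
             kt),
    stringsAsFactors = FALSE
  )
  class(out) <- c("rate_set", "data.frame")
  out
}

#' Total deactivation rate of a rate set
#'
#' @param rates A [rate_set] or numeric vector of rates.
#' @return Sum of all channel rates (1/ns).
#' @export
total_rate <- function(rates) {
  k <- if (inherits(rates, "rate_set")) rates$rate else rates
  sum(k)
}
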