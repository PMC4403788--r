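## Generators for the three standard validation scenes: isolated pair
## mixtures, random dye solutions, fibril-like labeled assemblies.

#' Scene of isolated donor-acceptor pairs at fixed distances
#'
#' Builds a non-periodic scene of independent donor-acceptor pairs, one
#' pair per requested distance (times `pair_counts`), laid out along the
#' x axis with `spacing` nm between consecutive donors. With spacing of
#' at least four Forster radii plus the largest pair distance, each donor
#' sees only its own acceptor, so the scene realises an exact mixture of
#' single-distance environments.
#'
#' @param distances Donor-acceptor distances (nm, > 0). An empty vector
#'   gives a donor-only scene.
#' @param pair_counts Number of pairs per distance (recycled).
#' @param spacing Distance between consecutive donors (nm, default 25).
#' @param R0 Optional Forster radius; if given, `spacing` is checked to
#'   guarantee non-interacting pairs (`spacing >= 4 * R0 + max distance`).
#' @param n_donor_only Additional donors with no acceptor (for mixtures
#'   that include an unquenched fraction).
#' @return A [fret_scene].
#' @examples
#' fixed_pair_scene(c(4, 6), pair_counts = 2, R0 = 5.4)
#' @export
fixed_pair_scene <- function(distances, pair_counts = 1, spacing = 25,
                             R0 = NULL, n_donor_only = 0) {
  if (length(distances) > 0 && any(distances <= 0)) {
    stop("distances must be > 0")
  }
  maxd <- if (length(distances) > 0) max(distances) else 0
  if (!is.null(R0) && spacing < 4 * R0 + maxd) {
    stop(sprintf(
      "spacing %g nm too small: pairs closer than 4 R0 (need >= %g nm)",
      spacing, 4 * R0 + maxd))
  }
  if (spacing <= 2 * maxd) stop("spacing too small for the requested distances")
  d_rep <- rep(distances, times = rep(pair_counts,
                                      length.out = length(distances)))
  n_pairs <- length(d_rep)
  n_d <- n_pairs + n_donor_only
  if (n_d == 0) stop("scene would contain no donors")
  x0 <- spacing * (seq_len(n_d) - 1) + 1
  donor_sites <- cbind(x0, 0.5, 0.5)
  acceptor_sites <- if (n_pairs > 0) {
    cbind(x0[seq_len(n_pairs)] + d_rep, 0.5, 0.5)
  } else {
    NULL
  }
  box <- c(max(x0) + maxd + 1, 1, 1)
  fret_scene(box = box, periodic = c(FALSE, FALSE, FALSE),
             donor_sites = donor_sites, acceptor_sites = acceptor_sites)
}

#' Random dye solution scene
#'
#' Dyes distributed uniformly at random in a box, emulating a solution of
#' free donor and acceptor dyes of given molar concentrations. Dye
#' counts are `concentration * volume * N_A` (deterministically rounded,
#' or Poisson-drawn with `poisson = TRUE`).
#'
#' @param conc_D,conc_A Donor and acceptor concentrations (mol/L, >= 0).
#' @param box Three box extents (nm).
#' @param periodic Three periodicity flags (default fully periodic, the
#'   natural emulation of bulk solution).
#' @param poisson Draw counts from a Poisson distribution instead of
#'   rounding the expectation.
#' @return A [fret_scene].
#' @export
random_solution_scene <- function(conc_D, conc_A, box,
                                  periodic = c(TRUE, TRUE, TRUE),
                                  poisson = FALSE) {
  if (conc_D < 0 || conc_A < 0) stop("concentrations must be >= 0")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("'box' must be 3 extents > 0")
  v_litre <- prod(box) * 1e-24 # nm^3 -> L
  mean_d <- conc_D * v_litre * .avogadro
  mean_a <- conc_A * v_litre * .avogadro
  n_d <- if (poisson) rpois(1, mean_d) else round(mean_d)
  n_a <- if (poisson) rpois(1, mean_a) else round(mean_a)
  if (n_d == 0) {
    stop("zero donors: increase 'conc_D' or the box volume")
  }
  rand_sites <- function(n) {
    cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  }
  fret_scene(box = box, periodic = periodic,
             donor_sites = rand_sites(n_d),
             acceptor_sites = if (n_a > 0) rand_sites(n_a) else NULL)
}

#' Parametric fibril model
#'
#' A configurable amyloid-fibril-like lattice: monomers stacked with a
#' fixed axial rise along x, in one or more parallel protofilaments
#' whose labeling sites sit on a circle in the y-z plane. Each monomer
#' independently carries a donor label, an acceptor label, or none
#' (multinomial with at most one label per monomer). This is an explicit
#' parametric stand-in for a measured fibril structure: it provides the
#' dense multi-acceptor geometry the engine's validity studies need, not
#' any one specific published architecture.
#'
#' @param n_monomers Total monomer count (>= 1).
#' @param axial_rise Axial spacing between consecutive monomers of one
#'   protofilament (nm, default 0.94, one beta-hairpin monomer, i.e. two
#'   cross-beta strand spacings).
#' @param n_protofilaments Number of parallel protofilaments (default 2).
#' @param protofilament_spacing Distance between neighbouring
#'   protofilament axes (nm, default 2.5).
#' @param donor_fraction,acceptor_fraction Labeling probabilities per
#'   monomer (default 0.2 and 0.2); their sum must not exceed 1.
#' @param padding Box padding around the lattice (nm, default 10).
#' @param periodic_axial Make the box periodic along the fibril axis.
#' @return An object of class `fibril_model`.
#' @export
fibril_model <- function(n_monomers = 500, axial_rise = 0.94,
                         n_protofilaments = 2, protofilament_spacing = 2.5,
                         donor_fraction = 0.2, acceptor_fraction = 0.2,
                         padding = 10, periodic_axial = FALSE) {
  if (n_monomers < 1) stop("'n_monomers' must be >= 1")
  if (axial_rise <= 0) stop("'axial_rise' must be > 0")
  if (n_protofilaments < 1) stop("'n_protofilaments' must be >= 1")
  if (donor_fraction < 0 || donor_fraction > 1 ||
      acceptor_fraction < 0 || acceptor_fraction > 1 ||
      donor_fraction + acceptor_fraction > 1) {
    stop("labeling fractions must be in [0, 1] and sum to at most 1 ",
         "(one label per monomer)")
  }
  structure(
    list(n_monomers = n_monomers, axial_rise = axial_rise,
         n_protofilaments = n_protofilaments,
         protofilament_spacing = protofilament_spacing,
         donor_fraction = donor_fraction,
         acceptor_fraction = acceptor_fraction,
         padding = padding, periodic_axial = isTRUE(periodic_axial)),
    class = "fibril_model"
  )
}

#' Generate a fibril-like labeled scene
#'
#' Lays out the monomer labeling sites of a [fibril_model()] and draws
#' the per-monomer labels (donor / acceptor / unlabeled, independent
#' multinomial).
#'
#' @param model A [fibril_model].
#' @return A [fret_scene].
#' @examples
#' set.seed(1)
#' fibril_scene(fibril_model(n_monomers = 100))
#' @export
fibril_scene <- function(model) {
  stopifnot(inherits(model, "fibril_model"))
  npf <- model$n_protofilaments
  per_pf <- ceiling(model$n_monomers / npf)
  # Protofilament axes on a circle so that neighbours are
  # protofilament_spacing apart; a single protofilament sits on the axis.
  if (npf == 1) {
    offs <- matrix(0, 1, 2)
  } else {
    radius <- model$protofilament_spacing / (2 * sin(pi / npf))
    ang <- 2 * pi * (seq_len(npf) - 1) / npf
    offs <- cbind(radius * cos(ang), radius * sin(ang))
  }
  pf <- rep(seq_len(npf), each = per_pf)[seq_len(model$n_monomers)]
  rank <- unlist(lapply(seq_len(npf), function(p) seq_len(sum(pf == p))))
  length_x <- per_pf * model$axial_rise
  if (model$periodic_axial) {
    x <- (rank - 1) * model$axial_rise
    box_x <- length_x
  } else {
    x <- (rank - 1) * model$axial_rise + model$padding
    box_x <- length_x + 2 * model$padding
  }
  half_yz <- max(abs(offs)) + model$padding
  sites <- cbind(x, offs[pf, 1] + half_yz, offs[pf, 2] + half_yz)
  u <- runif(model$n_monomers)
  is_d <- u < model$donor_fraction
  is_a <- !is_d & u < model$donor_fraction + model$acceptor_fraction
  fret_scene(
    box = c(box_x, 2 * half_yz, 2 * half_yz),
    periodic = c(model$periodic_axial, FALSE, FALSE),
    donor_sites = sites[is_d, , drop = FALSE],
    acceptor_sites = sites[is_a, , drop = FALSE]
  )
}
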