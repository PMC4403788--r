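## Scene representation, scene-file I/O, minimum-image distances,
## neighbour search and per-cycle linker repositioning.

as_site_matrix <- function(x, what) {
  if (is.null(x) || length(x) == 0) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3) {
    x <- matrix(x, ncol = 3)
  }
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x)) {
    stop(sprintf("'%s' must be an n x 3 numeric matrix", what))
  }
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", what))
  dimnames(x) <- list(NULL, c("x", "y", "z"))
  x
}

#' Create a labeling-site scene
#'
#' A scene is the static geometry of a simulation: a rectangular box, a
#' periodicity flag per axis, and the Cartesian labeling-site coordinates
#' of donors and acceptors. All coordinates are in nm. Dye positions
#' (after linker displacement) are derived per excitation cycle with
#' [resample_dye_positions()]; the scene itself stores only the sites.
#'
#' @param box Three box extents (nm, > 0).
#' @param periodic Three logicals: is the box periodic along x, y, z?
#' @param donor_sites,acceptor_sites n x 3 numeric matrices of site
#'   coordinates (nm). On periodic axes the sites must lie inside the box.
#' @return An object of class `fret_scene`.
#' @examples
#' fret_scene(box = c(10, 10, 10), periodic = c(FALSE, FALSE, FALSE),
#'            donor_sites = c(0, 0, 0), acceptor_sites = c(4, 0, 0))
#' @export
fret_scene <- function(box, periodic = c(FALSE, FALSE, FALSE),
                       donor_sites = NULL, acceptor_sites = NULL) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("'box' must be three positive extents (nm)")
  }
  periodic <- as.logical(periodic)
  if (length(periodic) != 3 || any(is.na(periodic))) {
    stop("'periodic' must be three logical flags")
  }
  donor_sites <- as_site_matrix(donor_sites, "donor_sites")
  acceptor_sites <- as_site_matrix(acceptor_sites, "acceptor_sites")
  for (a in which(periodic)) {
    pts <- c(donor_sites[, a], acceptor_sites[, a])
    if (length(pts) > 0 && (min(pts) < 0 || max(pts) > box[a])) {
      stop(sprintf("site coordinates outside the box on periodic axis %d", a))
    }
  }
  structure(
    list(box = box, periodic = periodic,
         donor_sites = donor_sites, acceptor_sites = acceptor_sites),
    class = "fret_scene"
  )
}

#' @export
print.fret_scene <- function(x, ...) {
  cat(sprintf("FRET scene: box %g x %g x %g nm (periodic: %s)\n",
              x$box[1], x$box[2], x$box[3],
              paste(ifelse(x$periodic, "yes", "no"), collapse = "/")))
  cat(sprintf("  %d donor site(s), %d acceptor site(s)\n",
              nrow(x$donor_sites), nrow(x$acceptor_sites)))
  invisible(x)
}

#' Read a scene file
#'
#' Scene files are plain text, in nm. Lines starting with `#` and blank
#' lines are ignored. The payload is, in order: one line with the three
#' box extents; one line with three 0/1 periodicity flags; one line with
#' the donor count followed by that many coordinate lines (three
#' whitespace-separated numbers each); then the acceptor count and the
#' acceptor coordinate lines.
#'
#' @param path Path to a scene file.
#' @return A [fret_scene] object.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("scene file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  pos <- 0L
  fail <- function(msg, at = pos) {
    stop(sprintf("scene file %s, line %d: %s", path,
                 if (at >= 1 && at <= length(lineno)) lineno[at] else NA_integer_,
                 msg), call. = FALSE)
  }
  next_fields <- function(n, what) {
    pos <<- pos + 1L
    if (pos > length(lines)) {
      stop(sprintf("scene file %s: unexpected end of file, expected %s",
                   path, what), call. = FALSE)
    }
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[pos]),
                                              "\\s+")[[1]]))
    if (length(f) != n || any(is.na(f))) {
      fail(sprintf("expected %d numeric field(s) for %s", n, what))
    }
    f
  }
  box <- next_fields(3, "box extents")
  flags <- next_fields(3, "periodicity flags")
  if (!all(flags %in% c(0, 1))) fail("periodicity flags must be 0 or 1")
  read_block <- function(what) {
    n <- next_fields(1, paste(what, "count"))
    if (n < 0 || n != round(n)) fail(paste(what, "count must be a",
                                           "non-negative integer"))
    coords <- matrix(0, nrow = n, ncol = 3)
    for (i in seq_len(n)) {
      coords[i, ] <- next_fields(3, sprintf("%s coordinate %d", what, i))
    }
    coords
  }
  donors <- read_block("donor")
  acceptors <- read_block("acceptor")
  if (pos < length(lines)) {
    fail("trailing content after acceptor coordinates", at = pos + 1L)
  }
  fret_scene(box = box, periodic = flags == 1,
             donor_sites = donors, acceptor_sites = acceptors)
}

#' Write a scene file
#'
#' Inverse of [read_scene()]; the round trip reproduces the scene up to
#' float formatting (17 significant digits are written, so coordinates
#' survive exactly).
#'
#' @param scene A [fret_scene].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "fret_scene"))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  coord_lines <- function(m) apply(m, 1, fmt)
  out <- c(
    "# fretsim scene file (nm)",
    "# box extents; periodicity flags; donor count + sites;",
    "# acceptor count + sites",
    fmt(scene$box),
    paste(as.integer(scene$periodic), collapse = " "),
    sprintf("%d", nrow(scene$donor_sites)),
    coord_lines(scene$donor_sites),
    sprintf("%d", nrow(scene$acceptor_sites)),
    coord_lines(scene$acceptor_sites)
  )
  writeLines(out, path)
  invisible(path)
}

#' Minimum-image distance between two points
#'
#' Euclidean distance after per-axis minimum-image wrapping on the
#' periodic axes only. Non-periodic axes use the plain coordinate
#' difference, so the result is never larger than the unwrapped distance.
#'
#' @param p,q Numeric length-3 coordinates (nm).
#' @param box Three box extents (nm).
#' @param periodic Three logical flags.
#' @return Distance in nm.
#' @examples
#' minimum_image_distance(c(1, 0, 0), c(9, 0, 0), box = c(10, 10, 10),
#'                        periodic = c(TRUE, TRUE, TRUE)) # 2
#' @export
minimum_image_distance <- function(p, q, box, periodic) {
  if (any(!is.finite(p)) || any(!is.finite(q))) {
    stop("points must be finite")
  }
  d <- p - q
  w <- which(as.logical(periodic))
  d[w] <- d[w] - box[w] * round(d[w] / box[w])
  sqrt(sum(d^2))
}

# All pairwise minimum-image distances between two site matrices
# (rows of `a` x rows of `b`). Vectorised per axis.
site_distances <- function(a, b, box, periodic) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  d2 <- matrix(0, nrow(a), nrow(b))
  for (ax in 1:3) {
    d <- outer(a[, ax], b[, ax], "-")
    if (periodic[ax]) d <- d - box[ax] * round(d / box[ax])
    d2 <- d2 + d * d
  }
  sqrt(d2)
}

#' Acceptors within reach of a donor
#'
#' Indices of the acceptors whose labeling site lies within
#' `cutoff_multiplier * R0 + linker_D + linker_A` of the donor's labeling
#' site (minimum-image metric). The additive linker margin makes the
#' site-based test conservative: no acceptor that the displaced dyes could
#' bring closer than the cutoff is ever missed. The boundary is inclusive.
#'
#' @param scene A [fret_scene].
#' @param donor_index Donor index (1-based).
#' @param R0 Forster radius (nm).
#' @param linker_D,linker_A Linker lengths (nm).
#' @param cutoff_multiplier Cutoff in units of `R0` (default 2; beyond
#'   twice the Forster radius transfer rates are negligible).
#' @return Integer vector of acceptor indices (possibly empty).
#' @export
relevant_acceptors <- function(scene, donor_index, R0,
                               linker_D = 0, linker_A = 0,
                               cutoff_multiplier = 2) {
  stopifnot(inherits(scene, "fret_scene"))
  if (donor_index < 1 || donor_index > nrow(scene$donor_sites)) {
    stop("'donor_index' out of range")
  }
  cutoff <- cutoff_multiplier * R0 + linker_D + linker_A
  d <- site_distances(scene$donor_sites[donor_index, , drop = FALSE],
                      scene$acceptor_sites, scene$box, scene$periodic)
  which(d[1, ] <= cutoff)
}

# Random directions uniform on the unit sphere (n x 3).
runif_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  repeat {
    v <- matrix(rnorm(3 * n), ncol = 3)
    nrm <- sqrt(rowSums(v^2))
    if (all(nrm > 1e-12)) return(v / nrm)
  }
}

wrap_periodic <- function(m, box, periodic) {
  for (ax in which(periodic)) {
    m[, ax] <- m[, ax] %% box[ax]
  }
  m
}

#' Draw dye positions for one excitation cycle
#'
#' Every dye is placed at its labeling site displaced by exactly the
#' linker length in a direction drawn uniformly on the unit sphere;
#' positions are held fixed within an excitation cycle and redrawn
#' between cycles. Displaced dyes are wrapped back into the box on
#' periodic axes; on non-periodic axes they may leave the box (the
#' accessible volume grows by the linker length in those directions).
#'
#' @param scene A [fret_scene].
#' @param linker_D,linker_A Linker lengths (nm, >= 0).
#' @return A `dye_configuration`: list with `donor_positions`,
#'   `acceptor_positions` (n x 3 matrices, nm) and the parent `scene`.
#' @export
resample_dye_positions <- function(scene, linker_D = 0, linker_A = 0) {
  stopifnot(inherits(scene, "fret_scene"))
  if (linker_D < 0 || linker_A < 0) stop("linker lengths must be >= 0")
  displace <- function(sites, L) {
    if (L == 0 || nrow(sites) == 0) return(sites)
    wrap_periodic(sites + L * runif_sphere(nrow(sites)),
                  scene$box, scene$periodic)
  }
  structure(
    list(donor_positions = displace(scene$donor_sites, linker_D),
         acceptor_positions = displace(scene$acceptor_sites, linker_A),
         scene = scene),
    class = "dye_configuration"
  )
}
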