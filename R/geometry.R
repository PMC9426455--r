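#' Icosahedral capsid lattice class
#'
#' A capsid lattice is described by its triangulation number T, which must
#' belong to the icosahedral series T = h^2 + hk + k^2 for non-negative
#' integers h, k (1, 3, 4, 7, 9, 12, 13, ...). A T = n capsid is built from
#' 60n subunits occupying n quasi-equivalent positions per icosahedral
#' asymmetric unit (A, B, C for T = 3).
#'
#' @param t_number Positive integer triangulation number.
#' @return A `capsid_lattice` object.
#' @examples
#' subunit_count(capsid_lattice(3))  # 180
#' @export
capsid_lattice <- function(t_number) {
  t_number <- as.integer(t_number)
  if (is.na(t_number) || t_number < 1 || !is_t_number(t_number)) {
    stop("T = ", t_number, " is not an icosahedral class ",
         "(must equal h^2 + h*k + k^2 for integers h, k >= 0)")
  }
  structure(list(t_number = t_number), class = "capsid_lattice")
}

is_t_number <- function(t) {
  hmax <- ceiling(sqrt(t))
  for (h in 0:hmax) {
    for (k in 0:hmax) {
      if (h * h + h * k + k * k == t) return(TRUE)
    }
  }
  FALSE
}

#' Subunits and quasi-equivalent positions of a capsid lattice
#'
#' `subunit_count` returns the number of capsid protein protomers (60 T);
#' `asymmetric_unit_size` the number of quasi-equivalent subunit positions
#' per icosahedral asymmetric unit (T).
#'
#' @param lattice A [capsid_lattice()].
#' @return Integer.
#' @export
subunit_count <- function(lattice) {
  stopifnot(inherits(lattice, "capsid_lattice"))
  60L * lattice$t_number
}

#' @rdname subunit_count
#' @export
asymmetric_unit_size <- function(lattice) {
  stopifnot(inherits(lattice, "capsid_lattice"))
  lattice$t_number
}

#' Parametric genome spool
#'
#' Describes a solenoidal (helical) coil of double-stranded nucleic acid
#' of constant radius: `n_turns` turns of pitch `pitch` (axial separation
#' of adjacent turns, Angstrom) at radius `radius`, filled with base pairs
#' at `rise_per_bp` Angstrom of contour length each (3.4 for ideal B-form
#' DNA).
#'
#' @param radius Helix radius, Angstrom (> 0).
#' @param pitch Axial separation of adjacent turns, Angstrom (>= 0; 0 gives
#'   a closed ring).
#' @param n_turns Number of turns (positive, may be fractional).
#' @param rise_per_bp Contour length per base pair, Angstrom; must lie in
#'   the physical window (2.5, 4.5).
#' @return A `spool_spec` object.
#' @export
spool_spec <- function(radius, pitch = 28, n_turns = 3, rise_per_bp = 3.4) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (!is.finite(pitch) || pitch < 0) stop("pitch must be >= 0")
  if (!is.finite(n_turns) || n_turns <= 0) stop("n_turns must be positive")
  if (rise_per_bp <= 2.5 || rise_per_bp >= 4.5) {
    stop("rise_per_bp outside the physical window (2.5, 4.5)")
  }
  structure(list(radius = radius, pitch = pitch, n_turns = n_turns,
                 rise_per_bp = rise_per_bp),
            class = "spool_spec")
}

#' Base-pair capacity of a genome spool
#'
#' Contour length of the helix divided by the rise per base pair, floored
#' to complete base pairs: one turn has arc length
#' `sqrt((2 pi r)^2 + pitch^2)`.
#'
#' @param spec A [spool_spec()].
#' @return Integer number of base pairs.
#' @export
spool_capacity <- function(spec) {
  stopifnot(inherits(spec, "spool_spec"))
  turn_len <- sqrt((2 * pi * spec$radius)^2 + spec$pitch^2)
  as.integer(floor(spec$n_turns * turn_len / spec$rise_per_bp))
}

#' Spool radius needed for a base-pair capacity
#'
#' Closed-form inverse of [spool_capacity()]: the radius at which `n_turns`
#' turns of the given pitch hold `bp` base pairs.
#'
#' @param bp Base pairs to accommodate.
#' @param pitch,n_turns,rise_per_bp As in [spool_spec()].
#' @return Radius in Angstrom; `spool_capacity` of the resulting spec is
#'   within one base pair of `bp`.
#' @export
radius_for_capacity <- function(bp, pitch = 28, n_turns = 3, rise_per_bp = 3.4) {
  stopifnot(bp > 0)
  turn_len <- bp * rise_per_bp / n_turns
  if (turn_len <= pitch) {
    stop("infeasible: per-turn contour ", format(turn_len),
         " A does not exceed the pitch ", format(pitch), " A")
  }
  sqrt(turn_len^2 - pitch^2) / (2 * pi)
}

#' Generate base-pair centers along a spool
#'
#' Places one point per base pair on the helix defined by `spec` about an
#' arbitrary axis through `center`. Consecutive points are spaced exactly
#' `rise_per_bp` apart (the angular step is solved so the chord, not the
#' arc, equals the rise; at this sampling the two differ by well under
#' 0.001 Angstrom for capsid-scale radii).
#'
#' @param spec A [spool_spec()].
#' @param axis Direction of the spool axis (any non-zero 3-vector).
#' @param center Point on the axis at the base of the spool.
#' @return n x 3 matrix of base-pair centers, n = [spool_capacity()].
#' @export
generate_spool_trace <- function(spec, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  stopifnot(inherits(spec, "spool_spec"))
  axis <- as.numeric(axis)
  if (length(axis) != 3 || sqrt(sum(axis^2)) < 1e-12) {
    stop("axis must be a non-zero 3-vector")
  }
  u <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])

  n <- spool_capacity(spec)
  r <- spec$radius
  zslope <- spec$pitch / (2 * pi)  # axial rise per radian
  # chord(theta) = rise: chord^2 = 4 r^2 sin^2(t/2) + (zslope t)^2
  chord <- function(t) sqrt(4 * r^2 * sin(t / 2)^2 + (zslope * t)^2)
  upper <- if (2 * r >= spec$rise_per_bp) {
    2 * asin(spec$rise_per_bp / (2 * r))
  } else if (zslope > 0) {
    spec$rise_per_bp / zslope
  } else {
    stop("rise_per_bp exceeds the ring diameter; no valid sampling step")
  }
  step <- stats::uniroot(function(t) chord(t) - spec$rise_per_bp,
                         lower = 1e-12, upper = upper, tol = 1e-14)$root
  theta <- (seq_len(n) - 1) * step
  pts <- outer(r * cos(theta), v) + outer(r * sin(theta), w) +
    outer(zslope * theta, u)
  sweep(pts, 2, as.numeric(center), "+")
}

#' Measure the axial spacing between turns of a coiled trace
#'
#' Follows the trace's azimuth around the axis, finds where the unwrapped
#' angle crosses whole turns (a fixed azimuth), interpolates the axial
#' coordinate at each crossing, and returns the mean axial distance between
#' consecutive crossings. Stacked closed rings are handled by treating the
#' jump between rings as the turn boundary.
#'
#' @param points n x 3 matrix of ordered points along the coil.
#' @param axis Spool axis direction.
#' @return Mean turn spacing in Angstrom.
#' @export
measure_turn_spacing <- function(points, axis = c(0, 0, 1)) {
  points <- as.matrix(points)
  axis <- as.numeric(axis)
  u <- axis / sqrt(sum(axis^2))
  center <- colMeans(points)
  rel <- sweep(points, 2, center)
  zc <- as.numeric(rel %*% u)
  perp <- rel - outer(zc, u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  phi <- atan2(perp %*% w, perp %*% v)
  dphi <- diff(phi)
  dphi <- ((dphi + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]
  unwrapped <- cumsum(c(phi[1], dphi))
  total_turns <- (max(unwrapped) - unwrapped[1]) / (2 * pi)
  if (total_turns < 2 - 1e-6) {
    stop("need at least 2 full turns to measure spacing (got ",
         format(total_turns, digits = 3), ")")
  }
  z_at <- function(tg) {
    if (tg <= unwrapped[1]) return(zc[1])
    k <- which(unwrapped >= tg)[1]
    if (is.na(k) || k == 1) return(zc[length(zc)])
    span <- unwrapped[k] - unwrapped[k - 1]
    if (span < 1e-12) return(zc[k])
    f <- (tg - unwrapped[k - 1]) / span
    zc[k - 1] + f * (zc[k] - zc[k - 1])
  }
  # crossings of several fixed azimuths, pooled, to average out noise
  spacings <- numeric(0)
  for (frac in 0:7 / 8) {
    start <- unwrapped[1] + 2 * pi * frac
    n_cross <- floor((max(unwrapped) - start) / (2 * pi) + 1e-9)
    if (n_cross < 1) next
    zcross <- vapply(start + 2 * pi * (0:n_cross), z_at, numeric(1))
    spacings <- c(spacings, diff(zcross))
  }
  mean(abs(spacings))
}

#' Coverage of a double-stranded genome region by a spool model
#'
#' Fraction of the genome's double-stranded region accounted for by the
#' modeled spool.
#'
#' @param model_bp Base pairs in the spool model.
#' @param genome_ds_bp Base pairs in the genome's double-stranded region.
#' @return `model_bp / genome_ds_bp`.
#' @export
ds_region_coverage <- function(model_bp, genome_ds_bp) {
  if (genome_ds_bp <= 0) stop("genome_ds_bp must be positive")
  if (model_bp < 0) stop("model_bp must be non-negative")
  model_bp / genome_ds_bp
}

#' Write a spool trace as a pseudo-atom PDB
#'
#' One CA-style record per base-pair center, for visual inspection next to
#' a genome-layer density map.
#'
#' @param points n x 3 matrix from [generate_spool_trace()].
#' @param path Output file.
#' @export
write_spool_pdb <- function(points, path) {
  trace <- core_trace("spool", points,
                      tibble::tibble(chain = "G",
                                     resno = seq_len(nrow(points)),
                                     ins = "", aa = "DA"))
  write_ca_pdb(trace, path)
}
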