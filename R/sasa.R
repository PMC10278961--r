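# LCPO parameter table (P1..P4), keyed by element and number of bonded
# heavy neighbors. Values are the published LCPO parameter set used by the
# AMBER implementation; atoms with no bonded neighbors (free spheres/ions)
# use the exact-sphere entry P1 = 1. Hydrogens carry no surface.
.lcpo_table <- list(
  "free" = c(1.0, 0.0, 0.0, 0.0),
  "C1" = c(0.77887, -0.28063, -0.0012968, 0.00039328),
  "C2" = c(0.56482, -0.19608, -0.0010219, 0.0002658),
  "C3" = c(0.23348, -0.072627, -0.00020079, 0.00007967),
  "C4" = c(0.00000, 0.00000, 0.00000, 0.00000),
  "N1" = c(0.73511, -0.22116, -0.00089148, 0.0002523),
  "N2" = c(0.41102, -0.12254, -0.000075448, 0.00011804),
  "N3" = c(0.062577, -0.017874, -0.00008312, 0.000019849),
  "O1" = c(0.77914, -0.25262, -0.0016056, 0.00035071),
  "O2" = c(0.49392, -0.16038, -0.00015512, 0.00016453),
  "S1" = c(0.7722, -0.26393, 0.0010629, 0.0002179),
  "S2" = c(0.54581, -0.19477, -0.0012873, 0.00029247),
  "P3" = c(0.3865, -0.18249, -0.0036598, 0.0004264),
  "P4" = c(0.03873, -0.0089339, 0.0000083582, 0.0000030381)
)

lcpo_params <- function(system) {
  a <- system$atoms
  n <- nrow(a)
  heavy_neighbors <- integer(n)
  b <- system$bonds
  heavy <- is_heavy(a$element)
  for (r in seq_len(nrow(b))) {
    if (heavy[b$j[r]]) {
      heavy_neighbors[b$i[r]] <- heavy_neighbors[b$i[r]] + 1L
    }
    if (heavy[b$i[r]]) {
      heavy_neighbors[b$j[r]] <- heavy_neighbors[b$j[r]] + 1L
    }
  }
  out <- matrix(0, n, 4)
  warned <- FALSE
  for (i in seq_len(n)) {
    if (!heavy[i]) next
    key <- if (heavy_neighbors[i] == 0) "free" else
      paste0(toupper(a$element[i]), heavy_neighbors[i])
    p <- .lcpo_table[[key]]
    if (is.null(p)) {
      p <- .lcpo_table[[paste0("C", min(heavy_neighbors[i], 4))]]
      if (!warned) {
        warning("no LCPO parameters for atom type ", key,
                "; using generic sp3-carbon entry")
        warned <- TRUE
      }
    }
    out[i, ] <- p
  }
  out
}

sasa_radii <- function(system, radii = NULL) {
  a <- system$atoms
  if (is.null(radii)) radii <- a$lj_rmin_half
  radii[!is_heavy(a$element)] <- 0  # hydrogens excluded from LCPO
  if (any(is.na(radii[is_heavy(a$element)]))) {
    stop("missing atom radii for SASA")
  }
  radii
}

#' Solvent-accessible surface area by LCPO
#'
#' Linear combination of pairwise overlaps: per heavy atom,
#' `A_i = P1 S1 + P2 sum A_ij + P3 sum A_jk + P4 sum A_ij sum A_jk`, with
#' `S1 = 4 pi R_i^2` and `A_ij` the spherical-cap area of atom i buried by
#' overlapping neighbor j; radii are augmented by the probe radius.
#' Negative per-atom values are clamped at 0. Hydrogens carry no area.
#'
#' @param system A `molecular_system` (bond graph determines atom types).
#' @param frame n x 3 coordinate matrix.
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param atoms Atom indices forming the solute (default all).
#' @param radii Optional per-atom intrinsic radii (default `lj_rmin_half`).
#' @return List of class `sasa_result`: `total` (A^2) and `per_atom`
#'   (length-n vector, zero for atoms outside `atoms`).
#' @export
lcpo_sasa <- function(system, frame, probe = 1.4,
                      atoms = seq_len(n_atoms(system)), radii = NULL) {
  check_frame(system, frame)
  base <- sasa_radii(system, radii)
  P <- lcpo_params(system)
  keep <- intersect(atoms, which(base > 0))
  per_atom <- numeric(n_atoms(system))
  if (length(keep) > 0) {
    R <- base[keep] + probe
    x <- frame[keep, , drop = FALSE]
    n <- length(keep)
    d <- as.matrix(stats::dist(x))
    overlap <- d < outer(R, R, "+") & d > 0
    # buried area of sphere i by overlapping sphere j
    aij <- function(i, j) {
      2 * pi * R[i] * (R[i] - d[i, j] / 2 -
                         (R[i]^2 - R[j]^2) / (2 * d[i, j]))
    }
    for (i in seq_len(n)) {
      nb <- which(overlap[i, ])
      s1 <- 4 * pi * R[i]^2
      t2 <- 0; t3 <- 0; t4 <- 0
      for (j in nb) {
        a_ij <- aij(i, j)
        t2 <- t2 + a_ij
        shared <- setdiff(intersect(nb, which(overlap[j, ])), c(i, j))
        a_jk_sum <- 0
        for (k in shared) a_jk_sum <- a_jk_sum + aij(j, k)
        t3 <- t3 + a_jk_sum
        t4 <- t4 + a_ij * a_jk_sum
      }
      per_atom[keep[i]] <- max(0, P[keep[i], 1] * s1 + P[keep[i], 2] * t2 +
                                 P[keep[i], 3] * t3 + P[keep[i], 4] * t4)
    }
  }
  structure(list(total = sum(per_atom), per_atom = per_atom),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> total =", format(x$total, digits = 6), "A^2 over",
      sum(x$per_atom > 0), "surface atoms\n")
  invisible(x)
}

#' Numeric solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral test points on each augmented sphere; a
#' point is accessible if it lies outside every other augmented sphere.
#' Slow but assumption-free; serves as the numeric reference for LCPO.
#'
#' @inheritParams lcpo_sasa
#' @param n_points Test points per sphere.
#' @return List of class `sasa_result`.
#' @export
shrake_rupley_sasa <- function(system, frame, probe = 1.4,
                               atoms = seq_len(n_atoms(system)),
                               radii = NULL, n_points = 960) {
  check_frame(system, frame)
  base <- sasa_radii(system, radii)
  keep <- intersect(atoms, which(base > 0))
  per_atom <- numeric(n_atoms(system))
  if (length(keep) > 0) {
    # golden-spiral points on the unit sphere (deterministic)
    k <- seq_len(n_points)
    zu <- (2 * k - 1) / n_points - 1
    theta <- k * pi * (3 - sqrt(5))
    sph <- cbind(sqrt(1 - zu^2) * cos(theta),
                 sqrt(1 - zu^2) * sin(theta), zu)
    R <- base[keep] + probe
    x <- frame[keep, , drop = FALSE]
    for (i in seq_along(keep)) {
      pts <- sweep(sph * R[i], 2, x[i, ], "+")
      free <- rep(TRUE, n_points)
      for (j in seq_along(keep)) {
        if (j == i) next
        d2 <- (pts[, 1] - x[j, 1])^2 + (pts[, 2] - x[j, 2])^2 +
          (pts[, 3] - x[j, 3])^2
        free <- free & d2 > R[j]^2
        if (!any(free)) break
      }
      per_atom[keep[i]] <- 4 * pi * R[i]^2 * mean(free)
    }
  }
  structure(list(total = sum(per_atom), per_atom = per_atom),
            class = "sasa_result")
}

#' Nonpolar solvation energy from surface area
#'
#' `dG_SA = gamma * SASA + b` with the protocol defaults
#' `gamma = 0.0072 kcal/(mol A^2)`, `b = 0`.
#'
#' @param sasa A `sasa_result` or a numeric area (A^2).
#' @param config A [solvation_config()] supplying `gamma` and `b`.
#' @return Energy in kcal/mol.
#' @export
nonpolar_energy <- function(sasa, config = solvation_config()) {
  area <- if (inherits(sasa, "sasa_result")) sasa$total else as.numeric(sasa)
  if (area < 0) stop("SASA must be >= 0")
  config$gamma * area + config$b
}
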