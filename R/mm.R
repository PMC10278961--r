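#' Bonded molecular-mechanics energies
#'
#' AMBER functional forms: `E_bond = sum k (r - r0)^2`,
#' `E_angle = sum k (theta - theta0)^2`,
#' `E_dihedral = sum (Vn/2) (1 + cos(n phi - phase))`.
#'
#' @param system A `molecular_system` with bonded parameters.
#' @param frame n x 3 coordinate matrix (Angstrom).
#' @return Named list `e_bond`, `e_angle`, `e_dihedral` (kcal/mol).
#' @export
bonded_energy <- function(system, frame) {
  check_frame(system, frame)
  e_bond <- 0
  b <- system$bonds
  if (nrow(b)) {
    d <- frame[b$i, , drop = FALSE] - frame[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    if (any(r < 1e-9)) {
      stop("zero-length bond vector for bond ",
           which(r < 1e-9)[1])
    }
    e_bond <- sum(b$k * (r - b$r0)^2)
  }
  e_angle <- 0
  g <- system$angles
  if (nrow(g)) {
    v1 <- frame[g$i, , drop = FALSE] - frame[g$j, , drop = FALSE]
    v2 <- frame[g$k_atom, , drop = FALSE] - frame[g$j, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    theta <- acos(pmin(1, pmax(-1, cosang)))
    e_angle <- sum(g$force_k * (theta - g$theta0)^2)
  }
  e_dihedral <- 0
  d <- system$dihedrals
  if (nrow(d)) {
    phi <- dihedral_angle(frame, d$i, d$j, d$k_atom, d$l)
    e_dihedral <- sum((d$vn / 2) * (1 + cos(d$period * phi - d$phase)))
  }
  list(e_bond = e_bond, e_angle = e_angle, e_dihedral = e_dihedral)
}

dihedral_angle <- function(frame, i, j, k, l) {
  b1 <- frame[j, , drop = FALSE] - frame[i, , drop = FALSE]
  b2 <- frame[k, , drop = FALSE] - frame[j, , drop = FALSE]
  b3 <- frame[l, , drop = FALSE] - frame[k, , drop = FALSE]
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x)
}

# Nonbonded pair list between two atom groups with 1-2/1-3 exclusion and
# 1-4 scaling. For group_a == group_b, each unordered pair appears once;
# for disjoint groups, all cross pairs appear.
nonbonded_pairs <- function(system, group_a, group_b) {
  n <- n_atoms(system)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("empty atom group")
  }
  same <- identical(sort(group_a), sort(group_b))
  if (same) {
    if (length(group_a) < 2) {
      return(tibble::tibble(i = integer(), j = integer(),
                            scale_ee = double(), scale_lj = double()))
    }
    cmb <- utils::combn(sort(group_a), 2)
    i <- cmb[1, ]; j <- cmb[2, ]
  } else {
    if (length(intersect(group_a, group_b)) > 0) {
      stop("groups must be identical or disjoint")
    }
    grid <- expand.grid(a = group_a, b = group_b)
    i <- pmin(grid$a, grid$b); j <- pmax(grid$a, grid$b)
  }
  out <- tibble::tibble(i = i, j = j, scale_ee = 1, scale_lj = 1)
  ex <- system$exclusions
  if (nrow(ex)) {
    key <- out$i * (n + 1) + out$j
    exkey <- ex$i * (n + 1) + ex$j
    hit <- match(key, exkey)
    found <- !is.na(hit)
    out$scale_ee[found] <- ex$scale_ee[hit[found]]
    out$scale_lj[found] <- ex$scale_lj[hit[found]]
  }
  out
}

pair_distances <- function(frame, pairs) {
  d <- frame[pairs$i, , drop = FALSE] - frame[pairs$j, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Coulomb energy between (or within) atom groups
#'
#' `E = sum 332.0637 q_i q_j / (eps_in r_ij)` over unexcluded pairs; 1-4
#' pairs are scaled by the system's `scale_ee`. No cutoff is applied
#' (post-processing convention).
#'
#' @param system A `molecular_system` with charges.
#' @param frame n x 3 coordinate matrix.
#' @param eps_in Interior dielectric constant (any positive value; the
#'   end-point protocol uses 1, 2, or 4).
#' @param group_a,group_b Atom index vectors; identical groups give the
#'   intra-group energy, disjoint groups the interaction energy.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(system, frame, eps_in = 1,
                           group_a = seq_len(n_atoms(system)),
                           group_b = group_a) {
  check_frame(system, frame)
  if (eps_in <= 0) stop("eps_in must be positive")
  pairs <- nonbonded_pairs(system, group_a, group_b)
  if (nrow(pairs) == 0) return(0)
  r <- pair_distances(frame, pairs)
  live <- pairs$scale_ee != 0
  if (any(r[live] < 1e-9)) {
    bad <- which(live & r < 1e-9)[1]
    stop("coincident atoms in interacting pair (", pairs$i[bad], ", ",
         pairs$j[bad], ")")
  }
  q <- system$atoms$charge
  sum(bfe_constants$kcoul * pairs$scale_ee * q[pairs$i] * q[pairs$j] /
        (eps_in * r))
}

#' Lennard-Jones energy between (or within) atom groups
#'
#' Lorentz-Berthelot combination in the AMBER Rmin form:
#' `Rmin = rmin_half_i + rmin_half_j`, `eps = sqrt(eps_i eps_j)`,
#' `E = sum eps [ (Rmin/r)^12 - 2 (Rmin/r)^6 ]`; 1-4 pairs scaled by
#' `scale_lj`, no cutoff.
#'
#' @inheritParams coulomb_energy
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(system, frame,
                      group_a = seq_len(n_atoms(system)),
                      group_b = group_a) {
  check_frame(system, frame)
  pairs <- nonbonded_pairs(system, group_a, group_b)
  if (nrow(pairs) == 0) return(0)
  r <- pair_distances(frame, pairs)
  a <- system$atoms
  epsij <- sqrt(a$lj_epsilon[pairs$i] * a$lj_epsilon[pairs$j])
  live <- pairs$scale_lj != 0 & epsij > 0
  if (any(r[live] < 1e-9)) {
    bad <- which(live & r < 1e-9)[1]
    stop("coincident atoms in interacting pair (", pairs$i[bad], ", ",
         pairs$j[bad], ")")
  }
  rmin <- a$lj_rmin_half[pairs$i] + a$lj_rmin_half[pairs$j]
  s6 <- (rmin[live] / r[live])^6
  sum(pairs$scale_lj[live] * epsij[live] * (s6^2 - 2 * s6))
}

#' Ligand-receptor gas-phase interaction energy
#'
#' Electrostatic and van der Waals interaction energies between the ligand
#' and receptor masks, the gas-phase part of the single-trajectory
#' end-point protocol (intra-group terms cancel exactly because complex,
#' receptor and ligand share the same coordinates).
#'
#' @inheritParams coulomb_energy
#' @param breakdown If `TRUE`, attach a per-pair tibble as attribute
#'   `"pairs"` (columns `i`, `j`, `ele`, `vdw`).
#' @return Named list `ele`, `vdw` (kcal/mol).
#' @export
interaction_energy <- function(system, frame, eps_in = 1,
                               breakdown = FALSE) {
  if (length(system$ligand) == 0) stop("ligand mask is empty")
  if (length(system$receptor) == 0) stop("receptor mask is empty")
  out <- list(
    ele = coulomb_energy(system, frame, eps_in, system$ligand,
                         system$receptor),
    vdw = lj_energy(system, frame, system$ligand, system$receptor)
  )
  if (breakdown) {
    pairs <- nonbonded_pairs(system, system$ligand, system$receptor)
    r <- pair_distances(frame, pairs)
    a <- system$atoms
    epsij <- sqrt(a$lj_epsilon[pairs$i] * a$lj_epsilon[pairs$j])
    rmin <- a$lj_rmin_half[pairs$i] + a$lj_rmin_half[pairs$j]
    s6 <- ifelse(epsij > 0, (rmin / r)^6, 0)
    attr(out, "pairs") <- tibble::tibble(
      i = pairs$i, j = pairs$j,
      ele = bfe_constants$kcoul * pairs$scale_ee *
        a$charge[pairs$i] * a$charge[pairs$j] / (eps_in * r),
      vdw = pairs$scale_lj * epsij * (s6^2 - 2 * s6)
    )
  }
  out
}
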