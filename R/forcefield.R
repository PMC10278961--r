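# Cached toy-force-field evaluator: precomputes bonded tables and the
# nonbonded pair list once per system and exposes fast energy and
# analytic-gradient closures. Used by minimization and normal-mode
# analysis, where the potential is evaluated many thousands of times.
make_ff <- function(system) {
  n <- n_atoms(system)
  b <- system$bonds
  g <- system$angles
  dh <- system$dihedrals
  pairs <- if (n > 1) {
    nonbonded_pairs(system, seq_len(n), seq_len(n))
  } else {
    tibble::tibble(i = integer(), j = integer(), scale_ee = double(),
                   scale_lj = double())
  }
  a <- system$atoms
  qq <- bfe_constants$kcoul * a$charge[pairs$i] * a$charge[pairs$j] *
    pairs$scale_ee
  epsij <- sqrt(a$lj_epsilon[pairs$i] * a$lj_epsilon[pairs$j]) *
    pairs$scale_lj
  rmin <- a$lj_rmin_half[pairs$i] + a$lj_rmin_half[pairs$j]
  live <- qq != 0 | epsij != 0
  pi_idx <- pairs$i[live]; pj_idx <- pairs$j[live]
  qq <- qq[live]; epsij <- epsij[live]; rmin <- rmin[live]

  energy <- function(x) {
    fr <- matrix(x, ncol = 3)
    e <- 0
    if (nrow(b)) {
      d <- fr[b$i, , drop = FALSE] - fr[b$j, , drop = FALSE]
      r <- sqrt(rowSums(d^2))
      e <- e + sum(b$k * (r - b$r0)^2)
    }
    if (nrow(g)) {
      v1 <- fr[g$i, , drop = FALSE] - fr[g$j, , drop = FALSE]
      v2 <- fr[g$k_atom, , drop = FALSE] - fr[g$j, , drop = FALSE]
      th <- acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
                                (sqrt(rowSums(v1^2)) *
                                   sqrt(rowSums(v2^2))))))
      e <- e + sum(g$force_k * (th - g$theta0)^2)
    }
    if (nrow(dh)) {
      phi <- dihedral_angle(fr, dh$i, dh$j, dh$k_atom, dh$l)
      e <- e + sum((dh$vn / 2) * (1 + cos(dh$period * phi - dh$phase)))
    }
    if (length(pi_idx)) {
      d <- fr[pi_idx, , drop = FALSE] - fr[pj_idx, , drop = FALSE]
      r <- sqrt(rowSums(d^2))
      s6 <- (rmin / r)^6
      e <- e + sum(qq / r) + sum(epsij * (s6^2 - 2 * s6))
    }
    e
  }

  gradient <- function(x) {
    fr <- matrix(x, ncol = 3)
    grad <- matrix(0, n, 3)
    acc <- function(idx, val) {
      # accumulate rows of val into grad at atom indices idx
      for (ax in 1:3) {
        s <- rowsum(val[, ax, drop = FALSE], idx)
        rows <- as.integer(rownames(s))
        grad[rows, ax] <<- grad[rows, ax] + s[, 1]
      }
    }
    if (nrow(b)) {
      d <- fr[b$i, , drop = FALSE] - fr[b$j, , drop = FALSE]
      r <- sqrt(rowSums(d^2))
      coef <- 2 * b$k * (r - b$r0) / r
      acc(b$i, coef * d)
      acc(b$j, -coef * d)
    }
    if (nrow(g)) {
      v1 <- fr[g$i, , drop = FALSE] - fr[g$j, , drop = FALSE]
      v2 <- fr[g$k_atom, , drop = FALSE] - fr[g$j, , drop = FALSE]
      l1 <- sqrt(rowSums(v1^2)); l2 <- sqrt(rowSums(v2^2))
      cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12,
                                  rowSums(v1 * v2) / (l1 * l2)))
      th <- acos(cth)
      sth <- sqrt(1 - cth^2)
      dEdth <- 2 * g$force_k * (th - g$theta0)
      # d(cos)/dv1 = v2/(l1 l2) - cth v1/l1^2 ; dth = -1/sin * dcos
      dci <- v2 / (l1 * l2) - cth * v1 / l1^2
      dck <- v1 / (l1 * l2) - cth * v2 / l2^2
      fi <- (-dEdth / sth) * dci
      fk <- (-dEdth / sth) * dck
      acc(g$i, fi)
      acc(g$k_atom, fk)
      acc(g$j, -(fi + fk))
    }
    if (nrow(dh)) {
      b1 <- fr[dh$j, , drop = FALSE] - fr[dh$i, , drop = FALSE]
      b2 <- fr[dh$k_atom, , drop = FALSE] - fr[dh$j, , drop = FALSE]
      b3 <- fr[dh$l, , drop = FALSE] - fr[dh$k_atom, , drop = FALSE]
      cross <- function(a1, a2) {
        cbind(a1[, 2] * a2[, 3] - a1[, 3] * a2[, 2],
              a1[, 3] * a2[, 1] - a1[, 1] * a2[, 3],
              a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1])
      }
      n1 <- cross(b1, b2); n2 <- cross(b2, b3)
      n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
      lb2 <- sqrt(rowSums(b2^2))
      phi <- dihedral_angle(fr, dh$i, dh$j, dh$k_atom, dh$l)
      dEdphi <- -(dh$vn / 2) * dh$period * sin(dh$period * phi - dh$phase)
      dpdi <- (lb2 / n1sq) * n1
      dpdl <- -(lb2 / n2sq) * n2
      c12 <- rowSums(b1 * b2) / lb2^2
      c32 <- rowSums(b3 * b2) / lb2^2
      dpdj <- -(1 + c12) * dpdi + c32 * dpdl
      dpdk <- -(1 + c32) * dpdl + c12 * dpdi
      acc(dh$i, dEdphi * dpdi)
      acc(dh$j, dEdphi * dpdj)
      acc(dh$k_atom, dEdphi * dpdk)
      acc(dh$l, dEdphi * dpdl)
    }
    if (length(pi_idx)) {
      d <- fr[pi_idx, , drop = FALSE] - fr[pj_idx, , drop = FALSE]
      r2 <- rowSums(d^2)
      r <- sqrt(r2)
      s6 <- (rmin / r)^6
      # dE/dr: coulomb -qq/r^2 ; LJ 12 eps (s6 - s12)/r
      dEdr <- -qq / r2 + 12 * epsij * (s6 - s6^2) / r
      coef <- dEdr / r
      acc(pi_idx, coef * d)
      acc(pj_idx, -coef * d)
    }
    as.vector(grad)
  }

  list(energy = energy, gradient = gradient)
}
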