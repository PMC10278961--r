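# Finite-difference linearized Poisson-Boltzmann solver (zero ionic
# strength). Potentials are in kcal/(mol e); the Coulomb constant is folded
# into the source term so that a point charge in uniform dielectric gives
# phi = 332.0637 q / (eps r).

pb_grid <- function(center, half_width, spacing) {
  n_cells <- ceiling(2 * half_width / spacing)
  n <- n_cells + 1
  half <- n_cells * spacing / 2
  list(
    x = center[1] + seq(-half, half, length.out = n),
    y = center[2] + seq(-half, half, length.out = n),
    z = center[3] + seq(-half, half, length.out = n),
    n = n, h = spacing
  )
}

# indicator of points inside the solute (any atom sphere)
pb_inside <- function(px, py, pz, coords, radii) {
  inside <- array(FALSE, dim = dim(px))
  for (k in seq_len(nrow(coords))) {
    if (radii[k] <= 0) next
    d2 <- (px - coords[k, 1])^2 + (py - coords[k, 2])^2 +
      (pz - coords[k, 3])^2
    inside <- inside | (d2 <= radii[k]^2)
  }
  inside
}

pb_mesh <- function(gx, gy, gz) {
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  list(px = array(rep(gx, times = ny * nz), dim = c(nx, ny, nz)),
       py = array(rep(rep(gy, each = nx), times = nz),
                  dim = c(nx, ny, nz)),
       pz = array(rep(gz, each = nx * ny), dim = c(nx, ny, nz)))
}

# Edge dielectric along one axis: harmonic (series) average of eps over
# the edge segment, using the exact fraction of the segment inside the
# solute. For each atom sphere the segment-sphere intersection interval
# is computed analytically; overlapping spheres combine by the maximum
# fraction (exact for edges crossing a single boundary, the common case).
pb_edge_eps <- function(grid, axis, coords, radii, eps_in, eps_out) {
  gx <- grid$x; gy <- grid$y; gz <- grid$z
  if (axis == 1) gx <- gx[-length(gx)]
  if (axis == 2) gy <- gy[-length(gy)]
  if (axis == 3) gz <- gz[-length(gz)]
  m <- pb_mesh(gx, gy, gz)
  h <- grid$h
  frac <- array(0, dim = dim(m$px))
  along <- list(m$px, m$py, m$pz)[[axis]]
  for (k in seq_len(nrow(coords))) {
    if (radii[k] <= 0) next
    perp2 <- if (axis == 1) {
      (m$py - coords[k, 2])^2 + (m$pz - coords[k, 3])^2
    } else if (axis == 2) {
      (m$px - coords[k, 1])^2 + (m$pz - coords[k, 3])^2
    } else {
      (m$px - coords[k, 1])^2 + (m$py - coords[k, 2])^2
    }
    disc <- radii[k]^2 - perp2
    hit <- disc > 0
    if (!any(hit)) next
    half <- sqrt(pmax(disc, 0))
    c_ax <- coords[k, axis]
    t0 <- ((c_ax - half) - along) / h
    t1 <- ((c_ax + half) - along) / h
    fk <- pmin(pmax(t1, 0), 1) - pmin(pmax(t0, 0), 1)
    fk[!hit] <- 0
    frac <- pmax(frac, fk)
  }
  1 / (frac / eps_in + (1 - frac) / eps_out)
}

# trilinear spread of charges onto grid nodes
pb_spread_charges <- function(grid, coords, q) {
  n <- grid$n
  rho <- array(0, dim = c(n, n, n))
  for (k in seq_along(q)) {
    if (q[k] == 0) next
    fx <- (coords[k, 1] - grid$x[1]) / grid$h
    fy <- (coords[k, 2] - grid$y[1]) / grid$h
    fz <- (coords[k, 3] - grid$z[1]) / grid$h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= n - 1 || j0 >= n - 1 ||
        k0 >= n - 1) {
      stop("charge ", k, " outside PB grid")
    }
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
        (if (dk) wz else 1 - wz)
      rho[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] <-
        rho[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] + w * q[k]
    }
  }
  rho
}

# analytic Coulomb/Debye-Hueckel boundary potential (kcal/mol/e)
pb_boundary_phi <- function(grid, coords, q, eps) {
  m <- pb_mesh(grid$x, grid$y, grid$z)
  phi <- array(0, dim = dim(m$px))
  for (k in seq_along(q)) {
    if (q[k] == 0) next
    d <- sqrt((m$px - coords[k, 1])^2 + (m$py - coords[k, 2])^2 +
                (m$pz - coords[k, 3])^2)
    d <- pmax(d, grid$h / 2)
    phi <- phi + bfe_constants$kcoul * q[k] / (eps * d)
  }
  phi
}

# (A phi)_node = sum_edges eps_edge (phi_node - phi_neighbor)
pb_apply <- function(phi, ex, ey, ez) {
  n <- dim(phi)[1]
  out <- array(0, dim = dim(phi))
  fx <- ex * (phi[2:n, , ] - phi[1:(n - 1), , ])
  out[1:(n - 1), , ] <- out[1:(n - 1), , ] - fx
  out[2:n, , ] <- out[2:n, , ] + fx
  fy <- ey * (phi[, 2:n, ] - phi[, 1:(n - 1), ])
  out[, 1:(n - 1), ] <- out[, 1:(n - 1), ] - fy
  out[, 2:n, ] <- out[, 2:n, ] + fy
  fz <- ez * (phi[, , 2:n] - phi[, , 1:(n - 1)])
  out[, , 1:(n - 1)] <- out[, , 1:(n - 1)] - fz
  out[, , 2:n] <- out[, , 2:n] + fz
  out
}

pb_solve_grid <- function(grid, coords, radii, q, eps_in, eps_out,
                          uniform = FALSE, boundary = NULL,
                          tol = 1e-6, max_iter = 10000) {
  n <- grid$n
  if (uniform) {
    ex <- array(eps_in, dim = c(n - 1, n, n))
    ey <- array(eps_in, dim = c(n, n - 1, n))
    ez <- array(eps_in, dim = c(n, n, n - 1))
  } else {
    ex <- pb_edge_eps(grid, 1, coords, radii, eps_in, eps_out)
    ey <- pb_edge_eps(grid, 2, coords, radii, eps_in, eps_out)
    ez <- pb_edge_eps(grid, 3, coords, radii, eps_in, eps_out)
  }
  if (is.null(boundary)) {
    boundary <- pb_boundary_phi(grid, coords, q,
                                if (uniform) eps_in else eps_out)
  }
  b <- 4 * pi * bfe_constants$kcoul *
    pb_spread_charges(grid, coords, q) / grid$h

  interior <- array(TRUE, dim = c(n, n, n))
  interior[c(1, n), , ] <- FALSE
  interior[, c(1, n), ] <- FALSE
  interior[, , c(1, n)] <- FALSE
  mask0 <- function(u) { u[!interior] <- 0; u }

  phi_b <- boundary
  phi_b[interior] <- 0
  # diagonal of A for Jacobi preconditioning
  dia <- array(0, dim = c(n, n, n))
  dia[1:(n - 1), , ] <- dia[1:(n - 1), , ] + ex
  dia[2:n, , ] <- dia[2:n, , ] + ex
  dia[, 1:(n - 1), ] <- dia[, 1:(n - 1), ] + ey
  dia[, 2:n, ] <- dia[, 2:n, ] + ey
  dia[, , 1:(n - 1)] <- dia[, , 1:(n - 1)] + ez
  dia[, , 2:n] <- dia[, , 2:n] + ez

  r <- mask0(b - pb_apply(phi_b, ex, ey, ez))
  u <- array(0, dim = c(n, n, n))
  z <- mask0(r / dia)
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(mask0(b)^2))
  if (bnorm == 0) bnorm <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ap <- mask0(pb_apply(p, ex, ey, ez))
    alpha <- rz / sum(p * ap)
    u <- u + alpha * p
    r <- r - alpha * ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res < tol) { converged <- TRUE; break }
    z <- mask0(r / dia)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (!converged) {
    stop("PB solver did not converge in ", max_iter,
         " iterations (relative residual ", signif(res, 3), ")")
  }
  phi <- u
  phi[!interior] <- boundary[!interior]
  phi
}

pb_interp <- function(grid, phi, coords) {
  vapply(seq_len(nrow(coords)), function(k) {
    fx <- (coords[k, 1] - grid$x[1]) / grid$h
    fy <- (coords[k, 2] - grid$y[1]) / grid$h
    fz <- (coords[k, 3] - grid$z[1]) / grid$h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    v <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
        (if (dk) wz else 1 - wz)
      v <- v + w * phi[i0 + di + 1, j0 + dj + 1, k0 + dk + 1]
    }
    v
  }, numeric(1))
}

#' Poisson-Boltzmann polar solvation energy
#'
#' Reaction-field energy `0.5 sum_i q_i (phi_solvated - phi_reference)_i`
#' from a finite-difference solve of the linearized, zero-ionic-strength
#' Poisson-Boltzmann equation on a cubic grid. The dielectric is assigned
#' from atom radii (inside any sphere: `eps_in`) with 3-point harmonic
#' smoothing on grid edges; boundary conditions are analytic
#' Coulomb/Debye-Hueckel sums; a coarse-then-fine focusing pass refines the
#' solute region; the reference solve (uniform `eps_in`, same grid and
#' charge spreading) cancels the grid self-energy.
#'
#' @param system A `molecular_system`.
#' @param frame n x 3 coordinate matrix.
#' @param config A [solvation_config()]; `pb_grid_spacing` is the fine-grid
#'   spacing and must be <= 1 Angstrom.
#' @param atoms Solute atom indices (default all).
#' @param radii Optional cavity radii (default: the atoms' `gb_radius`).
#' @return Polar solvation energy, kcal/mol.
#' @export
pb_energy <- function(system, frame, config = solvation_config("PB"),
                      atoms = seq_len(n_atoms(system)), radii = NULL) {
  check_frame(system, frame)
  if (config$pb_grid_spacing > 1.0) {
    stop("pb_grid_spacing must be <= 1.0 Angstrom")
  }
  q <- system$atoms$charge[atoms]
  if (any(is.na(q))) stop("missing charges for solute atoms")
  if (all(q == 0)) return(0)
  coords <- frame[atoms, , drop = FALSE]
  if (is.null(radii)) radii <- system$atoms$gb_radius[atoms]
  if (any(is.na(radii) | radii < 0) || all(radii == 0)) {
    stop("missing/negative PB cavity radii (zero allowed for atoms that ",
         "contribute charge but no cavity volume)")
  }
  center <- (apply(coords, 2, max) + apply(coords, 2, min)) / 2
  extent <- max(apply(coords, 2, max) - apply(coords, 2, min)) / 2
  h <- config$pb_grid_spacing
  half_full <- extent + max(radii) + config$pb_padding

  if (config$pb_focus) {
    h_coarse <- max(2 * h, 1.0)
    grid_c <- pb_grid(center, half_full, h_coarse)
    phi_c <- pb_solve_grid(grid_c, coords, radii, q, config$eps_in,
                           config$eps_out, tol = config$pb_tolerance,
                           max_iter = config$pb_max_iterations)
    half_fine <- extent + max(radii) + 3
    grid_f <- pb_grid(center, half_fine, h)
    m <- pb_mesh(grid_f$x, grid_f$y, grid_f$z)
    # interpolate coarse solution onto fine boundary nodes
    bpts <- cbind(as.vector(m$px), as.vector(m$py), as.vector(m$pz))
    bound <- array(pb_interp(grid_c, phi_c, bpts), dim = dim(m$px))
  } else {
    grid_f <- pb_grid(center, half_full, h)
    bound <- NULL
  }
  phi_s <- pb_solve_grid(grid_f, coords, radii, q, config$eps_in,
                         config$eps_out, boundary = bound,
                         tol = config$pb_tolerance,
                         max_iter = config$pb_max_iterations)
  phi_r <- pb_solve_grid(grid_f, coords, radii, q, config$eps_in,
                         config$eps_out, uniform = TRUE,
                         tol = config$pb_tolerance,
                         max_iter = config$pb_max_iterations)
  0.5 * sum(q * (pb_interp(grid_f, phi_s, coords) -
                   pb_interp(grid_f, phi_r, coords)))
}
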