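#' Solvation configuration
#'
#' Settings for the polar (GB or PB) and nonpolar (surface-area) solvation
#' terms of the end-point protocol.
#'
#' @param model `"GB"` (pairwise generalized Born, OBC1 radii) or `"PB"`
#'   (finite-difference linearized Poisson-Boltzmann).
#' @param eps_in Solute (interior) dielectric constant; the protocol
#'   compares 1, 2 and 4.
#' @param eps_out Solvent dielectric constant (default 80).
#' @param gamma Surface-tension coefficient, kcal/(mol A^2) (default 0.0072).
#' @param b Nonpolar offset, kcal/mol (default 0).
#' @param probe_radius Water-probe radius for SASA, Angstrom.
#' @param pb_grid_spacing Fine-grid spacing for the PB solver, Angstrom.
#' @param pb_tolerance Relative residual for the PB linear solve.
#' @param pb_max_iterations Iteration cap for the PB linear solve.
#' @param pb_padding Grid padding beyond the solute envelope, Angstrom.
#' @param pb_focus Use a coarse-then-fine focusing pass.
#' @return A list of class `solvation_config`.
#' @export
solvation_config <- function(model = c("GB", "PB"), eps_in = 1,
                             eps_out = 80, gamma = 0.0072, b = 0,
                             probe_radius = 1.4, pb_grid_spacing = 0.5,
                             pb_tolerance = 1e-6,
                             pb_max_iterations = 10000,
                             pb_padding = 8, pb_focus = TRUE) {
  model <- match.arg(model)
  if (!(eps_out > eps_in && eps_in > 0)) {
    stop("need eps_out > eps_in > 0")
  }
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(model = model, eps_in = eps_in, eps_out = eps_out,
                 gamma = gamma, b = b, probe_radius = probe_radius,
                 pb_grid_spacing = pb_grid_spacing,
                 pb_tolerance = pb_tolerance,
                 pb_max_iterations = pb_max_iterations,
                 pb_padding = pb_padding, pb_focus = pb_focus),
            class = "solvation_config")
}

# OBC1 ("igb=2") rescaling constants and intrinsic-radius offset
.obc <- list(alpha = 0.8, beta = 0.0, gamma = 2.909125, offset = 0.09)

# HCT pairwise descreening integral of 1/x^4 over neighbor sphere
# (radius s at distance r), excluding the region inside radius rho of the
# descreened atom. Exact for non-overlapping spheres.
hct_integral <- function(r, s, rho) {
  if (rho >= r + s) return(0)
  L <- max(rho, abs(r - s))
  U <- r + s
  val <- 0.5 * (1 / L - 1 / U + 0.25 * (r - s^2 / r) *
                  (1 / U^2 - 1 / L^2) + 0.5 / r * log(L / U))
  if (rho < s - r) val <- val + 1 / rho - 1 / L
  val
}

#' Effective Born radii (OBC1)
#'
#' Pairwise descreening integrals with tanh rescaling
#' (`alpha = 0.8, beta = 0, gamma = 2.909125`, 0.09 A intrinsic-radius
#' offset). An isolated atom gets an effective radius equal to its reduced
#' intrinsic radius (`gb_radius - 0.09`).
#'
#' @param system A `molecular_system` with `gb_radius` and `gb_screen` set.
#' @param frame n x 3 coordinate matrix.
#' @param atoms Atom indices to treat as the solute (default all); both the
#'   descreened atoms and the descreening neighbors are drawn from this set.
#' @return Numeric vector of effective radii (Angstrom) for `atoms`.
#' @export
effective_born_radii <- function(system, frame,
                                 atoms = seq_len(n_atoms(system))) {
  check_frame(system, frame)
  a <- system$atoms
  if (any(is.na(a$gb_radius[atoms])) || any(is.na(a$gb_screen[atoms]))) {
    stop("missing GB parameters (gb_radius/gb_screen) for solute atoms")
  }
  rho <- a$gb_radius[atoms]
  rhot <- rho - .obc$offset
  if (any(rhot <= 0)) stop("gb_radius must exceed the 0.09 A offset")
  scr <- a$gb_screen[atoms]
  x <- frame[atoms, , drop = FALSE]
  n <- length(atoms)
  reff <- numeric(n)
  d <- as.matrix(stats::dist(x))
  for (ii in seq_len(n)) {
    I <- 0
    for (jj in seq_len(n)) {
      if (jj == ii) next
      I <- I + hct_integral(d[ii, jj], scr[jj] * rhot[jj], rhot[ii])
    }
    psi <- I * rhot[ii]
    tanh_arg <- .obc$alpha * psi - .obc$beta * psi^2 + .obc$gamma * psi^3
    inv <- 1 / rhot[ii] - tanh(tanh_arg) / rho[ii]
    if (inv <= 0) stop("non-positive effective Born radius for atom ",
                       atoms[ii])
    reff[ii] <- 1 / inv
  }
  reff
}

gb_fgb <- function(r, ri, rj) {
  rirj <- ri * rj
  sqrt(r^2 + rirj * exp(-r^2 / (4 * rirj)))
}

# Symmetric matrix of pairwise GB energies; diagonal = Born self terms.
# Total polar energy = sum(upper triangle) + sum(diagonal).
gb_pair_energies <- function(charges, coords, radii, eps_in, eps_out) {
  if (any(radii <= 0)) stop("non-positive effective Born radius")
  n <- length(charges)
  fac <- -bfe_constants$kcoul * (1 / eps_in - 1 / eps_out)
  d <- as.matrix(stats::dist(coords))
  rr <- outer(radii, radii)
  fgb <- sqrt(d^2 + rr * exp(-d^2 / (4 * rr)))
  e <- fac * outer(charges, charges) / fgb
  diag(e) <- diag(e) / 2          # self terms enter once with the 1/2
  e
}

#' Generalized Born polar solvation energy
#'
#' Still-type pairwise sum with OBC1 effective radii:
#' `dG = -(332.0637/2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB`,
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`. A single ion of
#' charge q and effective radius a reduces exactly to the Born equation.
#'
#' @param system A `molecular_system`.
#' @param frame n x 3 coordinate matrix.
#' @param config A [solvation_config()].
#' @param atoms Solute atom indices (default all); radii are descreened
#'   within this set only, so receptor-only and ligand-only evaluations of
#'   the same coordinates differ from the complex, as they must.
#' @param radii Optional precomputed effective radii for `atoms`.
#' @return Polar solvation energy, kcal/mol.
#' @export
gb_energy <- function(system, frame, config = solvation_config(),
                      atoms = seq_len(n_atoms(system)), radii = NULL) {
  check_frame(system, frame)
  if (is.null(radii)) radii <- effective_born_radii(system, frame, atoms)
  q <- system$atoms$charge[atoms]
  if (any(is.na(q))) stop("missing charges for solute atoms")
  e <- gb_pair_energies(q, frame[atoms, , drop = FALSE], radii,
                        config$eps_in, config$eps_out)
  sum(e[upper.tri(e)]) + sum(diag(e))
}
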