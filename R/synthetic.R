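# Seeded generators producing every input the pipeline consumes, with the
# planted ground truth attached, so each analysis stage can be tested
# closed-loop. All generators are pure functions of their arguments:
# the RNG state is saved, seeded, and restored around each call.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

rotate_z <- function(v, angle) {
  c(cos(angle) * v[1] - sin(angle) * v[2],
    sin(angle) * v[1] + cos(angle) * v[2], v[3])
}

#' Generate a toy protein-ligand complex
#'
#' A bead-scale emulation of an inhibitor bound in a kinase pocket: a ring
#' of 3-bead "residues" (N-CA-CB) around a small ligand cluster, fully
#' parameterized (charges, Lennard-Jones, GB, bonds, angles) with the
#' receptor/ligand masks set. One pocket residue is the designated
#' mutation site: its CB bead carries an attractive charge toward the
#' ligand's central bead in the wild type and a like-signed (repulsive)
#' charge in the mutant, emulating the direct steric/electrostatic clash
#' of an in-pocket resistance mutation.
#'
#' @param n_residues Number of receptor residues on the pocket ring
#'   (default 8).
#' @param ligand_atoms Number of ligand beads (3-10, default 5).
#' @param mutate Generate the mutant variant (default `FALSE`).
#' @param far_residues Extra residues planted ~25 A away (outside any
#'   9-A truncation sphere; default 0).
#' @param seed RNG seed.
#' @return List: `system` (a `molecular_system`), `frame`,
#'   `mutation_site` (residue id).
#' @export
make_toy_complex <- function(n_residues = 8, ligand_atoms = 5,
                             mutate = FALSE, far_residues = 0, seed = 1) {
  if (ligand_atoms < 3 || ligand_atoms > 10) {
    stop("ligand_atoms must be in 3..10")
  }
  with_local_seed(seed, {
    atoms <- list(); coords <- list()
    bonds <- list(); angles <- list()
    ring_radius <- 6.5
    total_res <- n_residues + far_residues
    mutation_site <- 1L
    for (r in seq_len(total_res)) {
      far <- r > n_residues
      ang <- 2 * pi * ((r - 1) %% n_residues) / n_residues
      radius <- if (far) 25 else ring_radius
      base <- c(radius * cos(ang), radius * sin(ang),
                stats::runif(1, -0.5, 0.5))
      # CB points inward toward the pocket so it contacts the ligand
      inward <- -c(cos(ang), sin(ang), 0)
      p_ca <- base
      p_n <- base + rotate_z(c(1.45, 0, 0), ang + pi / 2)
      p_cb <- base + 1.5 * inward
      i0 <- 3 * (r - 1)
      q_cb <- stats::runif(1, -0.2, 0.2)
      if (r == mutation_site) {
        q_cb <- if (mutate) 0.45 else -0.45
      }
      atoms[[r]] <- tibble::tibble(
        name = c("N", "CA", "CB"), element = c("N", "C", "C"),
        residue_id = r, residue_name = if (r == mutation_site)
          (if (mutate) "MUT" else "WTR") else "RES",
        chain_id = "A",
        charge = c(stats::runif(1, -0.2, 0.2),
                   stats::runif(1, -0.2, 0.2), q_cb),
        lj_rmin_half = stats::runif(3, 1.7, 2.0),
        lj_epsilon = stats::runif(3, 0.05, 0.15),
        gb_radius = stats::runif(3, 1.4, 1.8),
        gb_screen = rep(0.8, 3)
      )
      coords[[r]] <- rbind(p_n, p_ca, p_cb)
      bonds[[r]] <- tibble::tibble(
        i = c(i0 + 1, i0 + 2),
        j = c(i0 + 2, i0 + 3),
        k = stats::runif(2, 200, 400), r0 = c(1.45, 1.5)
      )
      angles[[r]] <- tibble::tibble(
        i = i0 + 1, j = i0 + 2, k_atom = i0 + 3,
        force_k = stats::runif(1, 40, 80), theta0 = NA_real_)
    }
    n_rec <- 3 * total_res
    # ligand cluster: central bead at the origin, petals around it
    lig_coords <- matrix(0, ligand_atoms, 3)
    for (k in seq_len(ligand_atoms - 1)) {
      ang <- 2 * pi * k / (ligand_atoms - 1)
      lig_coords[k + 1, ] <- c(1.4 * cos(ang), 1.4 * sin(ang),
                               stats::runif(1, -0.3, 0.3))
    }
    q_lig <- stats::runif(ligand_atoms, -0.25, 0.25)
    q_lig[1] <- 0.35                       # pairs with the site charge
    q_lig <- q_lig - (sum(q_lig) - 0.35) / (ligand_atoms - 1) *
      c(0, rep(1, ligand_atoms - 1))       # neutral tail, charged head
    lig <- tibble::tibble(
      name = paste0("L", seq_len(ligand_atoms)),
      element = c("C", rep(c("C", "N", "O"),
                           length.out = ligand_atoms - 1)),
      residue_id = total_res + 1L, residue_name = "LIG", chain_id = "B",
      charge = q_lig,
      lj_rmin_half = stats::runif(ligand_atoms, 1.6, 1.9),
      lj_epsilon = stats::runif(ligand_atoms, 0.08, 0.18),
      gb_radius = stats::runif(ligand_atoms, 1.3, 1.7),
      gb_screen = rep(0.8, ligand_atoms)
    )
    lig_bonds <- tibble::tibble(
      i = n_rec + 1, j = n_rec + 1 + seq_len(ligand_atoms - 1),
      k = stats::runif(ligand_atoms - 1, 200, 400), r0 = NA_real_)

    atoms <- dplyr::bind_rows(c(atoms, list(lig)))
    frame <- rbind(do.call(rbind, coords), lig_coords)
    dimnames(frame) <- list(NULL, c("x", "y", "z"))
    bonds <- dplyr::bind_rows(c(bonds, list(lig_bonds)))
    # equilibrium values from the built geometry (start near a minimum)
    dvec <- frame[bonds$i, , drop = FALSE] - frame[bonds$j, , drop = FALSE]
    bonds$r0 <- round(sqrt(rowSums(dvec^2)), 3)
    angles <- dplyr::bind_rows(angles)
    v1 <- frame[angles$i, , drop = FALSE] - frame[angles$j, , drop = FALSE]
    v2 <- frame[angles$k_atom, , drop = FALSE] -
      frame[angles$j, , drop = FALSE]
    angles$theta0 <- round(acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))))), 4)

    sys <- molecular_system(
      atoms = atoms, bonds = bonds, angles = angles,
      ligand = n_rec + seq_len(ligand_atoms),
      receptor = seq_len(n_rec)
    )
    list(system = sys, frame = frame, mutation_site = mutation_site)
  })
}

#' Generate a trajectory with planted correlated-motion communities
#'
#' Single-bead residues arranged as compact clusters (one per group,
#' emulating densely packed structural domains) placed around a common
#' center so that only the cluster faces touch (bridging contacts).
#' Within each group every residue shares one latent Gaussian
#' displacement per frame (scale `sigma_latent`) plus independent noise
#' (`sigma_noise`); groups move independently, planting the community
#' structure that the correlation -> -log|C| -> Girvan-Newman pipeline
#' should recover.
#'
#' @param n_groups Number of planted communities (default 2).
#' @param residues_per_group Residues per community (default 6).
#' @param n_frames Number of frames (default 120).
#' @param sigma_latent,sigma_noise Latent and per-residue noise scales,
#'   Angstrom (defaults 0.5 and 0.05: strong cooperativity).
#' @param seed RNG seed.
#' @return List: `system`, `traj` (a [trajectory()]), `labels` (tibble
#'   `residue_id`, `group`), `node_atoms`.
#' @export
make_correlated_trajectory <- function(n_groups = 2,
                                       residues_per_group = 6,
                                       n_frames = 120,
                                       sigma_latent = 0.5,
                                       sigma_noise = 0.05, seed = 1) {
  with_local_seed(seed, {
    nres <- n_groups * residues_per_group
    base <- matrix(0, nres, 3)
    group <- integer(nres)
    # cluster template: one central bead, the rest on rings of radius
    # 2.4 A, giving each residue several intra-group contacts
    template <- function(m) {
      pos <- matrix(0, m, 3)
      if (m > 1) {
        ring <- m - 1
        ang <- 2 * pi * seq_len(ring) / ring
        pos[-1, ] <- cbind(2.4 * cos(ang), 2.4 * sin(ang),
                           rep_len(c(-0.6, 0.6), ring))
      }
      pos
    }
    # group centers spaced so neighboring cluster faces sit ~4.2 A apart
    r_centers <- if (n_groups == 1) 0 else 4.55 / sin(pi / n_groups)
    r <- 0
    for (g in seq_len(n_groups)) {
      ang_g <- 2 * pi * (g - 1) / n_groups
      center <- r_centers * c(cos(ang_g), sin(ang_g), 0)
      pos <- template(residues_per_group)
      for (k in seq_len(residues_per_group)) {
        r <- r + 1
        base[r, ] <- center + pos[k, ] +
          stats::runif(3, -0.15, 0.15)
        group[r] <- g
      }
    }
    atoms <- tibble::tibble(
      name = "CA", element = "C", residue_id = seq_len(nres),
      residue_name = "RES", chain_id = "A", charge = 0,
      lj_rmin_half = 1.9, lj_epsilon = 0.1, gb_radius = 1.7,
      gb_screen = 0.8
    )
    sys <- molecular_system(atoms, receptor = seq_len(nres))
    frames <- lapply(seq_len(n_frames), function(t) {
      disp <- matrix(stats::rnorm(nres * 3, sd = sigma_noise), nres, 3)
      for (g in seq_len(n_groups)) {
        latent <- stats::rnorm(3, sd = sigma_latent)
        disp[group == g, ] <- sweep(disp[group == g, , drop = FALSE],
                                    2, latent, "+")
      }
      base + disp
    })
    list(system = sys, traj = trajectory(frames),
         labels = tibble::tibble(residue_id = seq_len(nres),
                                 group = group),
         node_atoms = seq_len(nres))
  })
}

metropolis_1d <- function(energy_fn, x0, n, kT, burn_frac = 0.1,
                          step0 = 0.3) {
  n_burn <- ceiling(burn_frac * n)
  x <- x0
  e <- energy_fn(x)
  step <- step0
  out <- numeric(n)
  acc_win <- 0
  for (it in seq_len(n_burn + n)) {
    xp <- x + stats::runif(1, -step, step)
    ep <- energy_fn(xp)
    if (ep <= e || stats::runif(1) < exp(-(ep - e) / kT)) {
      x <- xp; e <- ep; acc_win <- acc_win + 1
    }
    if (it <= n_burn && it %% 50 == 0) {
      # tune toward the 30-50% acceptance band
      rate <- acc_win / 50
      if (rate < 0.3) step <- step * 0.8
      if (rate > 0.5) step <- step * 1.25
      acc_win <- 0
    }
    if (it > n_burn) out[it - n_burn] <- x
  }
  out
}

#' Default umbrella window layout
#'
#' 41 windows covering 0.5 A each along the dissociation coordinate,
#' restraint centers spaced 0.5 A from 12.5 A (bound) to 32.5 A (bulk),
#' elastic constant 5 kcal/(mol A^2). Each restraint sits at the middle
#' of its window, so the 41 centers span the stated 12.5-32.5 A range
#' inclusively.
#'
#' @return Tibble with columns `window`, `xi_ref`, `K`.
#' @export
umbrella_layout <- function() {
  tibble::tibble(window = 1:41,
                 xi_ref = 12.5 + 0.5 * (0:40),
                 K = 5)
}

#' Generate umbrella-sampling window data from a known PMF
#'
#' Per window, a Metropolis chain samples `exp(-(U_true + bias)/kB T)`
#' (step size auto-tuned to 30-50% acceptance, 10% burn-in discarded);
#' rounds are independent chains. Early rounds can carry a decaying
#' drift term added to the true PMF, emulating slow equilibration across
#' successive rounds.
#'
#' @param true_pmf Function of xi giving the true PMF (kcal/mol); default
#'   a harmonic well `0.5 (xi - 20)^2`.
#' @param layout Window layout (default [umbrella_layout()]).
#' @param n_samples Samples kept per window per round (default 1000).
#' @param n_rounds Number of rounds (default 1; the reference protocol
#'   runs 18).
#' @param T Temperature, K.
#' @param drift_amp Amplitude (kcal/mol) of the round-decaying drift
#'   (default 0).
#' @param drift_decay Per-round decay factor of the drift (default 0.65).
#' @param zero_temperature If `TRUE`, samples collapse to the minimum of
#'   `U_true + bias` in each window (the T -> 0 limit).
#' @param seed RNG seed.
#' @return List of rounds (each a list of [umbrella_window()]s) with
#'   attribute `truth` (the `true_pmf` function) and `layout`.
#' @export
make_umbrella_dataset <- function(true_pmf = function(xi)
                                    0.5 * (xi - 20)^2,
                                  layout = umbrella_layout(),
                                  n_samples = 1000, n_rounds = 1,
                                  T = 300, drift_amp = 0,
                                  drift_decay = 0.65,
                                  zero_temperature = FALSE, seed = 1) {
  kT <- bfe_constants$kB * T
  rounds <- with_local_seed(seed, {
    lapply(seq_len(n_rounds), function(r) {
      drift <- function(xi) {
        drift_amp * drift_decay^(r - 1) * sin(0.6 * xi)
      }
      u_round <- function(xi) true_pmf(xi) + drift(xi)
      lapply(seq_len(nrow(layout)), function(w) {
        xi_ref <- layout$xi_ref[w]; K <- layout$K[w]
        etot <- function(xi) u_round(xi) + bias_potential(xi, xi_ref, K)
        if (zero_temperature) {
          xm <- stats::optimize(etot, xi_ref + c(-5, 5))$minimum
          samples <- rep(xm, n_samples)
        } else {
          samples <- metropolis_1d(etot, xi_ref, n_samples, kT)
        }
        umbrella_window(xi_ref, K, samples)
      })
    })
  })
  attr(rounds, "truth") <- true_pmf
  attr(rounds, "layout") <- layout
  rounds
}

#' Generate lambda-window TI data with a known integral
#'
#' Per lambda, Gaussian samples about the true `<dU/dlambda>` curve; the
#' planted ground truth `dG = integral of the curve over [0, 1]` is
#' attached.
#'
#' @param dudl_fun True `<dU/dlambda>`(lambda) function, kcal/mol.
#' @param lambdas Lambda grid (default [ti_lambda_schedule()]).
#' @param n_samples Samples per window (default 1000).
#' @param noise_sd Gaussian sample noise, kcal/mol (default 1).
#' @param n_replicas Number of replicas (default 5).
#' @param seed RNG seed.
#' @return List of replicas (lists of [lambda_window()]s) with attributes
#'   `truth` (exact integral) and `lambdas`.
#' @export
make_ti_dataset <- function(dudl_fun = function(l) 6 * l^2 - 2 * l,
                            lambdas = ti_lambda_schedule(),
                            n_samples = 1000, noise_sd = 1,
                            n_replicas = 5, seed = 1) {
  truth <- stats::integrate(dudl_fun, 0, 1, rel.tol = 1e-10)$value
  reps <- with_local_seed(seed, {
    lapply(seq_len(n_replicas), function(r) {
      lapply(lambdas, function(l) {
        lambda_window(l, dudl_fun(l) +
                        stats::rnorm(n_samples, sd = noise_sd))
      })
    })
  })
  attr(reps, "truth") <- truth
  attr(reps, "lambdas") <- lambdas
  reps
}

#' Generate experimental-vs-predicted ddG benchmark pairs
#'
#' Bivariate normal pairs with population correlation `rho`, centered on
#' typical resistance-shift magnitudes.
#'
#' @param n Number of mutant systems.
#' @param rho Population correlation between experiment and prediction.
#' @param mean_ddg,sd_ddg Marginal mean and SD of both columns (kcal/mol;
#'   defaults 2 and 1.5, the scale of reported resistance shifts).
#' @param seed RNG seed.
#' @return Tibble `ddg_exp`, `ddg_pred` with attribute `rho`.
#' @export
make_benchmark_pairs <- function(n = 10, rho = 0.6, mean_ddg = 2,
                                 sd_ddg = 1.5, seed = 1) {
  with_local_seed(seed, {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    out <- tibble::tibble(ddg_exp = mean_ddg + sd_ddg * x,
                          ddg_pred = mean_ddg + sd_ddg * y)
    attr(out, "rho") <- rho
    out
  })
}
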