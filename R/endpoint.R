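bonded_terms <- function(system, frame) {
  # per-term energy vectors, used for exact term-by-term cancellation
  out <- list(bond = numeric(0), angle = numeric(0), dihedral = numeric(0))
  b <- system$bonds
  if (nrow(b)) {
    d <- frame[b$i, , drop = FALSE] - frame[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    out$bond <- b$k * (r - b$r0)^2
  }
  g <- system$angles
  if (nrow(g)) {
    v1 <- frame[g$i, , drop = FALSE] - frame[g$j, , drop = FALSE]
    v2 <- frame[g$k_atom, , drop = FALSE] - frame[g$j, , drop = FALSE]
    theta <- acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
                                 (sqrt(rowSums(v1^2)) *
                                    sqrt(rowSums(v2^2))))))
    out$angle <- g$force_k * (theta - g$theta0)^2
  }
  d <- system$dihedrals
  if (nrow(d)) {
    phi <- dihedral_angle(frame, d$i, d$j, d$k_atom, d$l)
    out$dihedral <- (d$vn / 2) * (1 + cos(d$period * phi - d$phase))
  }
  out
}

# rows of each bonded table lying entirely within an atom set
bonded_rows_in <- function(system, set) {
  list(
    bond = which(system$bonds$i %in% set & system$bonds$j %in% set),
    angle = which(system$angles$i %in% set & system$angles$j %in% set &
                    system$angles$k_atom %in% set),
    dihedral = which(system$dihedrals$i %in% set &
                       system$dihedrals$j %in% set &
                       system$dihedrals$k_atom %in% set &
                       system$dihedrals$l %in% set)
  )
}

check_partition_bonded <- function(system) {
  rl <- bonded_rows_in(system, system$receptor)
  ll <- bonded_rows_in(system, system$ligand)
  if (length(rl$bond) + length(ll$bond) != nrow(system$bonds) ||
      length(rl$angle) + length(ll$angle) != nrow(system$angles) ||
      length(rl$dihedral) + length(ll$dihedral) != nrow(system$dihedrals)) {
    stop("bonded term crosses the ligand/receptor partition; ",
         "the single-trajectory protocol requires a clean split")
  }
  invisible(TRUE)
}

#' End-point binding free energy (MM/PB(GB)SA)
#'
#' Single-trajectory protocol: for every frame, complex, receptor-only and
#' ligand-only energies are evaluated from the same coordinates and
#' differenced (`dX = X_complex - X_receptor - X_ligand`). Bonded terms
#' cancel term-by-term exactly and are reported as the (zero) residual of
#' that cancellation. The enthalpy is
#' `dH = dE_ele + dE_vdW + dG_polar + dG_SA`; adding a `-T dS` entropy
#' estimate (see [nme_binding_entropy()]) gives `dG_bind = dH - T dS`.
#'
#' @param system A fully parameterized `molecular_system` with both masks.
#' @param traj A [trajectory()] (or a single n x 3 frame).
#' @param config A [solvation_config()]; `model` selects GB or PB polar
#'   solvation.
#' @param minus_tds Optional `-T dS` value (kcal/mol) to fold into
#'   `dG_bind`.
#' @return An object of class `endpoint_result`: per-frame term tibble,
#'   mean/SD summary, and metadata.
#' @export
endpoint_bfe <- function(system, traj, config = solvation_config(),
                         minus_tds = NULL) {
  if (is.matrix(traj)) traj <- trajectory(list(traj))
  if (length(traj$frames) == 0) stop("empty trajectory")
  if (length(system$ligand) == 0 || length(system$receptor) == 0) {
    stop("both ligand and receptor masks must be set")
  }
  check_partition_bonded(system)
  rec <- system$receptor; lig <- system$ligand
  sys_rec <- subset_system(system, rec)
  sys_lig <- subset_system(system, lig)
  rec_rows <- bonded_rows_in(system, rec)
  lig_rows <- bonded_rows_in(system, lig)

  per_frame <- purrr::map_dfr(seq_along(traj$frames), function(f) {
    frame <- traj$frames[[f]]
    inter <- interaction_energy(system, frame, config$eps_in)

    # exact bonded cancellation: same term, same coordinates, differenced
    tc <- bonded_terms(system, frame)
    tr <- bonded_terms(sys_rec, frame[rec, , drop = FALSE])
    tl <- bonded_terms(sys_lig, frame[lig, , drop = FALSE])
    d_bonded <- sum(tc$bond[rec_rows$bond] - tr$bond,
                    tc$bond[lig_rows$bond] - tl$bond,
                    tc$angle[rec_rows$angle] - tr$angle,
                    tc$angle[lig_rows$angle] - tl$angle,
                    tc$dihedral[rec_rows$dihedral] - tr$dihedral,
                    tc$dihedral[lig_rows$dihedral] - tl$dihedral)

    polar_fun <- if (config$model == "GB") gb_energy else pb_energy
    all_atoms <- seq_len(n_atoms(system))
    polar <- polar_fun(system, frame, config, all_atoms) -
      polar_fun(system, frame, config, rec) -
      polar_fun(system, frame, config, lig)

    sa <- nonpolar_energy(lcpo_sasa(system, frame, config$probe_radius),
                          config) -
      nonpolar_energy(lcpo_sasa(system, frame, config$probe_radius,
                                atoms = rec), config) -
      nonpolar_energy(lcpo_sasa(system, frame, config$probe_radius,
                                atoms = lig), config)

    vals <- c(inter$ele, inter$vdw, d_bonded, polar, sa)
    if (any(!is.finite(vals))) {
      stop("non-finite energy in frame ", f)
    }
    tibble::tibble(frame = f, ele = inter$ele, vdw = inter$vdw,
                   bonded = d_bonded, polar = polar, nonpolar = sa,
                   dh = inter$ele + inter$vdw + polar + sa)
  })

  summary <- per_frame |>
    tidyr::pivot_longer(-"frame", names_to = "term",
                        values_to = "value") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value)
                          else NA_real_,
                     .groups = "drop")

  dh_mean <- summary$mean[summary$term == "dh"]
  structure(list(per_frame = per_frame, summary = summary,
                 model = config$model, eps_in = config$eps_in,
                 n_frames = nrow(per_frame),
                 minus_tds = minus_tds,
                 dg_bind = dh_mean + (minus_tds %||% 0)),
            class = "endpoint_result")
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat("<endpoint_result> MM/", x$model, "SA, eps_in = ", x$eps_in,
      ", ", x$n_frames, " frame(s)\n", sep = "")
  s <- x$summary
  for (term in c("ele", "vdw", "bonded", "polar", "nonpolar", "dh")) {
    row <- s[s$term == term, ]
    cat(sprintf("  %-9s %10.4f +/- %s kcal/mol\n", term, row$mean,
                ifelse(is.na(row$sd), "NA", sprintf("%.4f", row$sd))))
  }
  if (!is.null(x$minus_tds)) {
    cat(sprintf("  %-9s %10.4f kcal/mol\n", "-TdS", x$minus_tds))
  }
  cat(sprintf("  dG_bind   %10.4f kcal/mol\n", x$dg_bind))
  invisible(x)
}

#' Per-residue decomposition of the binding enthalpy
#'
#' Cross-term pair energies are split half/half between the two residues
#' involved; GB polar terms are decomposed pairwise the same way (self
#' terms go to their own residue); nonpolar terms are assigned per atom
#' from the per-atom SASA change. Residue sums reconstruct the complex
#' totals exactly. Under `model = "PB"` the polar column is still the GB
#' pairwise decomposition (finite-difference PB is not pairwise
#' decomposable); this is reported via a message.
#'
#' @inheritParams endpoint_bfe
#' @return A tibble of class `decomposition_table`: one row per residue
#'   with columns `residue_id`, `residue_name`, `ele`, `vdw`, `polar`,
#'   `nonpolar`, `total` (kcal/mol, averaged over frames).
#' @export
per_residue_decomposition <- function(system, traj,
                                      config = solvation_config()) {
  if (is.matrix(traj)) traj <- trajectory(list(traj))
  if (config$model == "PB") {
    message("per-residue polar decomposition uses the GB pairwise form; ",
            "PB enters totals only")
  }
  a <- system$atoms
  rec <- system$receptor; lig <- system$ligand
  res_ids <- unique(a$residue_id)
  res_of_atom <- match(a$residue_id, res_ids)
  nres <- length(res_ids)
  acc <- matrix(0, nres, 4,
                dimnames = list(NULL, c("ele", "vdw", "polar", "nonpolar")))

  add_half <- function(acc, col, i, j, e) {
    ri <- res_of_atom[i]; rj <- res_of_atom[j]
    for (k in seq_along(e)) {
      acc[ri[k], col] <- acc[ri[k], col] + e[k] / 2
      acc[rj[k], col] <- acc[rj[k], col] + e[k] / 2
    }
    acc
  }

  nf <- length(traj$frames)
  for (f in seq_len(nf)) {
    frame <- traj$frames[[f]]
    inter <- interaction_energy(system, frame, config$eps_in,
                                breakdown = TRUE)
    pr <- attr(inter, "pairs")
    acc <- add_half(acc, "ele", pr$i, pr$j, pr$ele)
    acc <- add_half(acc, "vdw", pr$i, pr$j, pr$vdw)

    # GB pairwise decomposition of the binding polar term
    all_atoms <- seq_len(n_atoms(system))
    e_c <- gb_pair_energies(a$charge, frame,
                            effective_born_radii(system, frame),
                            config$eps_in, config$eps_out)
    de <- e_c
    for (grp in list(rec, lig)) {
      e_s <- gb_pair_energies(a$charge[grp], frame[grp, , drop = FALSE],
                              effective_born_radii(system, frame, grp),
                              config$eps_in, config$eps_out)
      de[grp, grp] <- de[grp, grp] - e_s
    }
    idx <- which(upper.tri(de, diag = TRUE) & de != 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      acc <- add_half(acc, "polar", idx[, 1], idx[, 2],
                      de[idx])
    }

    sa_c <- lcpo_sasa(system, frame, config$probe_radius)$per_atom
    sa_r <- lcpo_sasa(system, frame, config$probe_radius,
                      atoms = rec)$per_atom
    sa_l <- lcpo_sasa(system, frame, config$probe_radius,
                      atoms = lig)$per_atom
    d_sa <- config$gamma * (sa_c - sa_r - sa_l)
    for (i in which(d_sa != 0)) {
      acc[res_of_atom[i], "nonpolar"] <-
        acc[res_of_atom[i], "nonpolar"] + d_sa[i]
    }
  }
  acc <- acc / nf
  out <- tibble::tibble(
    residue_id = res_ids,
    residue_name = a$residue_name[match(res_ids, a$residue_id)],
    ele = acc[, "ele"], vdw = acc[, "vdw"], polar = acc[, "polar"],
    nonpolar = acc[, "nonpolar"],
    total = rowSums(acc)
  )
  class(out) <- c("decomposition_table", class(out))
  out
}

#' Truncate a complex around the ligand for entropy estimation
#'
#' Keeps the full ligand plus every receptor residue with any heavy atom
#' within `cutoff` of any ligand heavy atom; qualifying residues are
#' included whole. Residues left with a missing sequence neighbor are
#' recorded as discontinuous termini in the `termini` element (metadata
#' only; toy systems carry no chemical caps).
#'
#' @param system A `molecular_system` with the ligand mask set.
#' @param frame n x 3 coordinate matrix.
#' @param cutoff Truncation radius, Angstrom (default 9).
#' @return List: `system` (truncated `molecular_system`), `atoms` (kept
#'   original indices), `termini` (tibble of residues adjacent to removed
#'   sequence neighbors).
#' @export
truncate_for_entropy <- function(system, frame, cutoff = 9) {
  if (length(system$ligand) == 0) stop("ligand mask is empty")
  check_frame(system, frame)
  near <- select_atoms(system, frame,
                       sprintf("within %.10g of ligand", cutoff),
                       complete_residues = TRUE)
  keep <- sort(union(near, system$ligand))
  if (length(keep) == 0) stop("empty truncation selection")
  a <- system$atoms
  kept_res <- sort(unique(a$residue_id[keep]))
  removed_res <- setdiff(unique(a$residue_id), kept_res)
  termini <- tibble::tibble(
    residue_id = kept_res[(kept_res - 1) %in% removed_res |
                            (kept_res + 1) %in% removed_res]
  )
  list(system = subset_system(system, keep), atoms = keep,
       termini = termini)
}

#' Binding free energy change upon mutation
#'
#' `ddG = dG_mutant - dG_wildtype`; positive values mean weakened binding
#' (drug resistance).
#'
#' @param result_mut,result_wt `endpoint_result` objects on the same model
#'   and dielectric, or bare numeric binding free energies (kcal/mol).
#' @return ddG in kcal/mol.
#' @export
delta_delta_g <- function(result_mut, result_wt) {
  dg <- function(x) {
    if (inherits(x, "endpoint_result")) x$dg_bind else as.numeric(x)
  }
  if (inherits(result_mut, "endpoint_result") &&
      inherits(result_wt, "endpoint_result")) {
    if (result_mut$model != result_wt$model ||
        result_mut$eps_in != result_wt$eps_in) {
      stop("mismatched configurations: ", result_mut$model, "/eps ",
           result_mut$eps_in, " vs ", result_wt$model, "/eps ",
           result_wt$eps_in)
    }
  }
  dg(result_mut) - dg(result_wt)
}

#' Mean and spread of repeated ddG estimates
#'
#' Bookkeeping for repeated computations of the same mutation effect:
#' given paired mutant/wild-type binding free energies from independent
#' repeats, returns the per-repeat ddG values with mean and sample SD.
#'
#' @param dg_mut,dg_wt Numeric vectors of binding free energies (kcal/mol),
#'   one entry per repeat.
#' @return A tibble with one row per repeat plus attributes `mean` and `sd`.
#' @export
ddg_repeats <- function(dg_mut, dg_wt) {
  if (length(dg_mut) != length(dg_wt)) stop("length mismatch")
  dd <- mapply(delta_delta_g, dg_mut, dg_wt)
  out <- tibble::tibble(repeat_id = seq_along(dd), ddg = dd)
  attr(out, "mean") <- mean(dd)
  attr(out, "sd") <- if (length(dd) > 1) stats::sd(dd) else NA_real_
  out
}
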