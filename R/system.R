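#' Construct a molecular system
#'
#' A molecular system bundles an atom table (partial charges, Lennard-Jones and
#' generalized Born parameters), bonded terms (harmonic bonds and angles,
#' cosine dihedrals), nonbonded exclusions, and a disjoint receptor/ligand
#' partition of the solute atoms. It is the container every analysis stage
#' (MM energies, solvation, end-point binding free energies, normal-mode
#' entropy) consumes. All atom indices are 1-based.
#'
#' @param atoms Tibble/data frame with one row per atom. Required columns:
#'   `name`, `element`, `residue_id`, `residue_name`; parameter columns
#'   `charge` (e), `lj_rmin_half` (A), `lj_epsilon` (kcal/mol),
#'   `gb_radius` (A), `gb_screen` (dimensionless) may be `NA` for structure
#'   skeletons read from PDB. Optional `chain_id` (default `"A"`).
#' @param bonds Data frame with columns `i`, `j`, `k` (kcal/mol/A^2, AMBER
#'   convention `E = k (r - r0)^2`), `r0` (A); may be empty.
#' @param angles Data frame with columns `i`, `j`, `k_atom`, `force_k`
#'   (kcal/mol/rad^2, `E = k (theta - theta0)^2`), `theta0` (radians).
#' @param dihedrals Data frame with columns `i`, `j`, `k_atom`, `l`, `vn`
#'   (barrier, kcal/mol), `period` (integer), `phase` (radians):
#'   `E = (vn/2) (1 + cos(period * phi - phase))`.
#' @param ligand,receptor Integer vectors of 1-based atom indices; must be
#'   disjoint. Together they normally cover all solute atoms.
#' @param scale_ee,scale_lj 1-4 nonbonded scale factors (AMBER defaults
#'   1/1.2 and 1/2).
#' @param exclusions Optional data frame `i`, `j` of extra excluded pairs;
#'   1-2 and 1-3 exclusions and scaled 1-4 pairs are derived from the bond
#'   graph automatically.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds = NULL, angles = NULL,
                             dihedrals = NULL, ligand = integer(),
                             receptor = integer(),
                             scale_ee = 1 / 1.2, scale_lj = 1 / 2,
                             exclusions = NULL) {
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  required <- c("name", "element", "residue_id", "residue_name")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("charge", "lj_rmin_half", "lj_epsilon", "gb_radius",
                "gb_screen")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  if (!"chain_id" %in% names(atoms)) atoms$chain_id <- "A"
  atoms$index <- seq_len(n)

  if (any(!is.na(atoms$lj_epsilon) & atoms$lj_epsilon < 0)) {
    stop("lj_epsilon must be >= 0")
  }
  if (any(!is.na(atoms$gb_radius) & atoms$gb_radius <= 0)) {
    stop("gb_radius must be > 0")
  }

  empty_bonds <- tibble::tibble(i = integer(), j = integer(),
                                k = double(), r0 = double())
  empty_angles <- tibble::tibble(i = integer(), j = integer(),
                                 k_atom = integer(), force_k = double(),
                                 theta0 = double())
  empty_dihedrals <- tibble::tibble(i = integer(), j = integer(),
                                    k_atom = integer(), l = integer(),
                                    vn = double(), period = double(),
                                    phase = double())
  bonds <- if (is.null(bonds)) empty_bonds else tibble::as_tibble(bonds)
  angles <- if (is.null(angles)) empty_angles else tibble::as_tibble(angles)
  dihedrals <- if (is.null(dihedrals)) empty_dihedrals else
    tibble::as_tibble(dihedrals)

  idx_cols <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k_atom,
                dihedrals$i, dihedrals$j, dihedrals$k_atom, dihedrals$l)
  if (length(idx_cols) > 0 && (min(idx_cols) < 1 || max(idx_cols) > n)) {
    stop("bonded term references atom index outside 1..", n)
  }
  ligand <- as.integer(ligand)
  receptor <- as.integer(receptor)
  if (length(intersect(ligand, receptor)) > 0) {
    stop("ligand and receptor masks overlap: atoms ",
         paste(intersect(ligand, receptor), collapse = ", "))
  }
  if (length(c(ligand, receptor)) > 0 &&
      (min(c(ligand, receptor)) < 1 || max(c(ligand, receptor)) > n)) {
    stop("mask references atom index outside 1..", n)
  }

  sys <- structure(
    list(atoms = atoms, bonds = bonds, angles = angles,
         dihedrals = dihedrals, ligand = ligand, receptor = receptor,
         scale_ee = scale_ee, scale_lj = scale_lj,
         extra_exclusions = if (is.null(exclusions)) NULL else
           tibble::as_tibble(exclusions)),
    class = "molecular_system"
  )
  sys$exclusions <- derive_exclusions(sys)
  sys
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$residue_id)), " residues, ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, ",
      nrow(x$dihedrals), " dihedrals\n", sep = "")
  cat("  ligand: ", length(x$ligand), " atoms; receptor: ",
      length(x$receptor), " atoms\n", sep = "")
  invisible(x)
}

n_atoms <- function(system) nrow(system$atoms)

# 1-2 / 1-3 excluded pairs and scaled 1-4 pairs from the bond graph.
# Returns tibble(i, j, scale_ee, scale_lj) with i < j; scale 0 = excluded.
derive_exclusions <- function(system) {
  n <- n_atoms(system)
  b <- system$bonds
  pair_key <- function(i, j) pmin(i, j) * (n + 1) + pmax(i, j)
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  p12 <- if (nrow(b)) cbind(pmin(b$i, b$j), pmax(b$i, b$j)) else
    matrix(integer(), ncol = 2)
  p13 <- matrix(integer(), ncol = 2)
  p14 <- matrix(integer(), ncol = 2)
  for (a in seq_len(n)) {
    for (m1 in adj[[a]]) for (m2 in adj[[m1]]) {
      if (m2 != a) p13 <- rbind(p13, c(min(a, m2), max(a, m2)))
    }
  }
  for (a in seq_len(n)) {
    for (m1 in adj[[a]]) for (m2 in adj[[m1]]) {
      if (m2 == a) next
      for (m3 in adj[[m2]]) {
        if (m3 != a && m3 != m1) p14 <- rbind(p14, c(min(a, m3), max(a, m3)))
      }
    }
  }
  dedup <- function(m) {
    if (nrow(m) == 0) return(m)
    m[!duplicated(pair_key(m[, 1], m[, 2])), , drop = FALSE]
  }
  p12 <- dedup(p12); p13 <- dedup(p13); p14 <- dedup(p14)
  k12 <- pair_key(p12[, 1], p12[, 2])
  k13 <- setdiff(pair_key(p13[, 1], p13[, 2]), k12)
  p13 <- p13[pair_key(p13[, 1], p13[, 2]) %in% k13, , drop = FALSE]
  p13 <- dedup(p13)
  k14 <- setdiff(pair_key(p14[, 1], p14[, 2]), c(k12, k13))
  p14 <- p14[pair_key(p14[, 1], p14[, 2]) %in% k14, , drop = FALSE]
  p14 <- dedup(p14)

  out <- tibble::tibble(
    i = c(p12[, 1], p13[, 1], p14[, 1]),
    j = c(p12[, 2], p13[, 2], p14[, 2]),
    scale_ee = c(rep(0, nrow(p12) + nrow(p13)),
                 rep(system$scale_ee, nrow(p14))),
    scale_lj = c(rep(0, nrow(p12) + nrow(p13)),
                 rep(system$scale_lj, nrow(p14)))
  )
  ex <- system$extra_exclusions
  if (!is.null(ex) && nrow(ex) > 0) {
    extra <- tibble::tibble(i = pmin(ex$i, ex$j), j = pmax(ex$i, ex$j),
                            scale_ee = 0, scale_lj = 0)
    keep <- !(pair_key(out$i, out$j) %in% pair_key(extra$i, extra$j))
    out <- dplyr::bind_rows(extra, out[keep, ])
  }
  out
}

#' Extract a sub-system
#'
#' Keeps the given atoms and every bonded term falling entirely inside the
#' subset; masks are intersected and re-indexed. Used by the entropy
#' truncation step and by receptor/ligand-only energy evaluations.
#'
#' @param system A `molecular_system`.
#' @param keep Integer vector of 1-based atom indices to retain.
#' @return A `molecular_system` over the retained atoms (indices remapped).
#' @export
subset_system <- function(system, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0) stop("empty atom subset")
  map <- integer(n_atoms(system))
  map[keep] <- seq_along(keep)
  remap <- function(df, cols) {
    inside <- rowSums(!matrix(unlist(df[cols]) %in% keep,
                              nrow = nrow(df))) == 0
    df <- df[inside, , drop = FALSE]
    for (cl in cols) df[[cl]] <- map[df[[cl]]]
    df
  }
  molecular_system(
    atoms = system$atoms[keep, setdiff(names(system$atoms), "index")],
    bonds = remap(system$bonds, c("i", "j")),
    angles = remap(system$angles, c("i", "j", "k_atom")),
    dihedrals = remap(system$dihedrals, c("i", "j", "k_atom", "l")),
    ligand = map[intersect(system$ligand, keep)],
    receptor = map[intersect(system$receptor, keep)],
    scale_ee = system$scale_ee, scale_lj = system$scale_lj,
    exclusions = if (is.null(system$extra_exclusions)) NULL else
      remap(system$extra_exclusions, c("i", "j"))
  )
}

#' Construct a trajectory
#'
#' An ordered list of coordinate frames (n_atoms x 3 matrices, Angstrom)
#' over a fixed atom list.
#'
#' @param frames List of numeric matrices, each `n_atoms` x 3.
#' @param frame_interval Sampling interval in ps (metadata only).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, frame_interval = NA_real_) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("frames must be a non-empty list of coordinate matrices")
  }
  nat <- nrow(frames[[1]])
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (!is.matrix(fr) || ncol(fr) != 3 || nrow(fr) != nat) {
      stop("frame ", f, " is not an ", nat, " x 3 coordinate matrix")
    }
    if (!all(is.finite(fr))) stop("frame ", f, " contains non-finite coordinates")
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frames x ",
      nrow(x$frames[[1]]), " atoms", sep = "")
  if (!is.na(x$frame_interval)) cat(" (", x$frame_interval, " ps/frame)",
                                    sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

check_frame <- function(system, frame) {
  if (!is.matrix(frame) || ncol(frame) != 3) {
    stop("frame must be an n x 3 coordinate matrix")
  }
  if (nrow(frame) != n_atoms(system)) {
    stop("frame has ", nrow(frame), " atoms; system has ", n_atoms(system))
  }
  if (!all(is.finite(frame))) stop("frame contains non-finite coordinates")
  invisible(frame)
}
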