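#' Select atoms by query
#'
#' Small selection grammar shared by the truncation and network stages.
#' Supported queries:
#' \itemize{
#'   \item `"all"`, `"ligand"`, `"receptor"`
#'   \item `"resid 3:7"` / `"resid 2 5 9"` residue-id ranges and lists
#'   \item `"name CA CB"` atom-name match
#'   \item `"element C N"` element match
#'   \item `"within <R> of <subquery>"` distance selection: heavy atoms
#'     within `R` Angstrom of any heavy atom of the subquery set
#'     (hydrogens are ignored on both sides; `R = Inf` selects all atoms)
#' }
#'
#' @param system A `molecular_system`.
#' @param frame n x 3 coordinate matrix (needed for `within` queries).
#' @param query Query string.
#' @param complete_residues If `TRUE`, any residue with at least one selected
#'   atom is included whole (all its atoms, hydrogens included).
#' @return Sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(system, frame = NULL, query,
                         complete_residues = FALSE) {
  a <- system$atoms
  q <- trimws(query)
  idx <- if (grepl("^within\\s", q)) {
    m <- regmatches(q, regexec("^within\\s+(\\S+)\\s+of\\s+(.+)$", q))[[1]]
    if (length(m) != 3) stop("malformed 'within' query: ", query)
    r <- suppressWarnings(as.numeric(m[2]))
    if (is.na(r)) {
      if (m[2] %in% c("Inf", "inf")) r <- Inf else
        stop("bad distance in query: ", m[2])
    }
    ref <- select_atoms(system, frame, m[3])
    if (is.infinite(r)) {
      seq_len(nrow(a))
    } else {
      if (is.null(frame)) stop("'within' query requires a frame")
      check_frame(system, frame)
      heavy <- which(is_heavy(a$element))
      ref_h <- intersect(ref, heavy)
      if (length(ref_h) == 0) stop("reference set has no heavy atoms")
      d2 <- outer(rowSums(frame[heavy, , drop = FALSE]^2),
                  rowSums(frame[ref_h, , drop = FALSE]^2), "+") -
        2 * frame[heavy, , drop = FALSE] %*% t(frame[ref_h, , drop = FALSE])
      heavy[apply(d2, 1, min) <= r^2 + 1e-12]
    }
  } else if (q == "all") {
    seq_len(nrow(a))
  } else if (q == "ligand") {
    if (length(system$ligand) == 0) stop("ligand mask is empty")
    system$ligand
  } else if (q == "receptor") {
    if (length(system$receptor) == 0) stop("receptor mask is empty")
    system$receptor
  } else if (grepl("^resid\\s", q)) {
    ids <- integer()
    for (tok in strsplit(sub("^resid\\s+", "", q), "\\s+")[[1]]) {
      if (grepl(":", tok)) {
        ab <- as.integer(strsplit(tok, ":")[[1]])
        ids <- c(ids, seq(ab[1], ab[2]))
      } else ids <- c(ids, as.integer(tok))
    }
    unknown <- setdiff(ids, a$residue_id)
    if (length(unknown) > 0) {
      stop("unknown residue id(s): ", paste(unknown, collapse = ", "))
    }
    which(a$residue_id %in% ids)
  } else if (grepl("^name\\s", q)) {
    nm <- strsplit(sub("^name\\s+", "", q), "\\s+")[[1]]
    which(a$name %in% nm)
  } else if (grepl("^element\\s", q)) {
    el <- strsplit(sub("^element\\s+", "", q), "\\s+")[[1]]
    which(toupper(a$element) %in% toupper(el))
  } else {
    stop("unparseable selection query: ", query)
  }
  if (complete_residues && length(idx) > 0) {
    idx <- which(a$residue_id %in% unique(a$residue_id[idx]))
  }
  sort(unique(idx))
}

#' Least-squares superposition of two frames
#'
#' Kabsch (SVD) fit of `mobile` onto `reference` using the atoms in
#' `fit_set`; the optimal rigid rotation + translation is applied to all
#' atoms of `mobile`.
#'
#' @param mobile,reference n x 3 coordinate matrices over the same atoms.
#' @param fit_set Integer vector of atom indices to fit on (default: all);
#'   at least 3 non-collinear atoms.
#' @return List with `frame` (fitted copy of `mobile`) and `rmsd`
#'   (coordinate RMSD over `fit_set` after fitting, Angstrom).
#' @export
superpose <- function(mobile, reference, fit_set = NULL) {
  if (is.null(fit_set)) fit_set <- seq_len(nrow(mobile))
  if (length(fit_set) < 3) stop("superposition needs at least 3 fit atoms")
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference have different atom counts")
  }
  m <- mobile[fit_set, , drop = FALSE]
  r <- reference[fit_set, , drop = FALSE]
  mc <- colMeans(m); rc <- colMeans(r)
  m0 <- sweep(m, 2, mc); r0 <- sweep(r, 2, rc)
  sv <- svd(crossprod(m0, r0))
  if (sv$d[2] < 1e-10) stop("fit atoms are (near-)collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(sweep(mobile, 2, mc) %*% t(rot), 2, rc, "+")
  rmsd <- sqrt(mean(rowSums((fitted[fit_set, , drop = FALSE] - r)^2)))
  list(frame = fitted, rmsd = rmsd)
}
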