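#' Read a toy topology file
#'
#' The toy topology is a plain-text, section-based format carrying everything
#' a desk-scale system needs: per-atom charges, Lennard-Jones and generalized
#' Born parameters, bonded terms, extra exclusions, and the receptor/ligand
#' partition. Lines starting with `#` are comments. Sections:
#'
#' \preformatted{
#' [atoms]      index name element residue_id residue_name chain_id
#'              charge lj_rmin_half lj_epsilon gb_radius gb_screen
#' [bonds]      i j k r0
#' [angles]     i j k force_k theta0_deg
#' [dihedrals]  i j k l vn period phase_deg
#' [exclusions] i j
#' [masks]      ligand <ids>; receptor <ids>   (ids: "1 2 3" or "4:10")
#' [options]    scale_ee <x>; scale_lj <x>
#' }
#'
#' All indices are 1-based. Angles/phases are degrees on disk, radians in
#' memory. Missing charge/LJ/GB fields for any atom are a validation error.
#'
#' @param path Path to a topology file.
#' @return A `molecular_system`.
#' @export
read_toy_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  buckets <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("[][]", "", ln)
      buckets[[section]] <- character()
    } else {
      if (is.na(section)) stop("content before first [section] in ", path)
      buckets[[section]] <- c(buckets[[section]], ln)
    }
  }
  parse_table <- function(sec, cols, numeric_from = 1) {
    rows <- buckets[[sec]]
    if (is.null(rows) || length(rows) == 0) return(NULL)
    parts <- strsplit(rows, "\\s+")
    bad <- which(vapply(parts, length, 1L) != length(cols))
    if (length(bad) > 0) {
      stop("section [", sec, "] row ", bad[1], " has ",
           length(parts[[bad[1]]]), " fields; expected ", length(cols))
    }
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(df) <- cols
    for (k in seq_along(cols)) {
      if (k >= numeric_from) df[[k]] <- as.numeric(df[[k]])
    }
    tibble::as_tibble(df)
  }

  if (is.null(buckets[["atoms"]])) stop("missing [atoms] section in ", path)
  atoms <- parse_table("atoms",
                       c("index", "name", "element", "residue_id",
                         "residue_name", "chain_id", "charge",
                         "lj_rmin_half", "lj_epsilon", "gb_radius",
                         "gb_screen"), numeric_from = 7)
  atoms$index <- as.integer(atoms$index)
  atoms$residue_id <- as.integer(atoms$residue_id)
  if (any(atoms$index != seq_len(nrow(atoms)))) {
    stop("[atoms] indices must be 1..n in order")
  }
  par_na <- !stats::complete.cases(atoms[, c("charge", "lj_rmin_half",
                                             "lj_epsilon", "gb_radius",
                                             "gb_screen")])
  if (any(par_na)) {
    stop("missing charge/LJ/GB parameter(s) for atom(s): ",
         paste(atoms$index[par_na], collapse = ", "))
  }

  bonds <- parse_table("bonds", c("i", "j", "k", "r0"))
  angles <- parse_table("angles",
                        c("i", "j", "k_atom", "force_k", "theta0"))
  if (!is.null(angles)) angles$theta0 <- angles$theta0 * pi / 180
  dihedrals <- parse_table("dihedrals",
                           c("i", "j", "k_atom", "l", "vn", "period",
                             "phase"))
  if (!is.null(dihedrals)) dihedrals$phase <- dihedrals$phase * pi / 180
  exclusions <- parse_table("exclusions", c("i", "j"))
  for (nm in c("bonds", "angles", "dihedrals", "exclusions")) {
    obj <- get(nm)
    if (!is.null(obj)) {
      for (cl in intersect(names(obj), c("i", "j", "k_atom", "l"))) {
        obj[[cl]] <- as.integer(obj[[cl]])
      }
      assign(nm, obj)
    }
  }

  parse_ids <- function(txt) {
    out <- integer()
    for (tok in strsplit(txt, "\\s+")[[1]]) {
      if (grepl(":", tok)) {
        ab <- as.integer(strsplit(tok, ":")[[1]])
        out <- c(out, seq(ab[1], ab[2]))
      } else out <- c(out, as.integer(tok))
    }
    out
  }
  ligand <- integer(); receptor <- integer()
  for (ln in buckets[["masks"]] %||% character()) {
    key <- sub("\\s.*$", "", ln)
    val <- sub("^\\S+\\s*", "", ln)
    if (key == "ligand") ligand <- parse_ids(val)
    else if (key == "receptor") receptor <- parse_ids(val)
    else stop("unknown mask '", key, "' in [masks]")
  }
  scale_ee <- 1 / 1.2; scale_lj <- 1 / 2
  for (ln in buckets[["options"]] %||% character()) {
    key <- sub("\\s.*$", "", ln)
    val <- as.numeric(sub("^\\S+\\s*", "", ln))
    if (key == "scale_ee") scale_ee <- val
    else if (key == "scale_lj") scale_lj <- val
    else stop("unknown option '", key, "'")
  }

  molecular_system(atoms = atoms[, -1], bonds = bonds, angles = angles,
                   dihedrals = dihedrals, ligand = ligand,
                   receptor = receptor, scale_ee = scale_ee,
                   scale_lj = scale_lj, exclusions = exclusions)
}

#' Write a toy topology file
#'
#' Inverse of [read_toy_topology()]; `read_toy_topology(write_toy_topology(x))`
#' reproduces the system.
#'
#' @param system A fully parameterized `molecular_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_topology <- function(system, path) {
  a <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) formatC(x, format = "g", digits = 10)
  w("# toy topology")
  w("[atoms]")
  for (r in seq_len(nrow(a))) {
    w("%d %s %s %d %s %s %s %s %s %s %s", a$index[r], a$name[r],
      a$element[r], a$residue_id[r], a$residue_name[r], a$chain_id[r],
      num(a$charge[r]), num(a$lj_rmin_half[r]), num(a$lj_epsilon[r]),
      num(a$gb_radius[r]), num(a$gb_screen[r]))
  }
  if (nrow(system$bonds)) {
    w("[bonds]")
    b <- system$bonds
    for (r in seq_len(nrow(b))) {
      w("%d %d %s %s", b$i[r], b$j[r], num(b$k[r]), num(b$r0[r]))
    }
  }
  if (nrow(system$angles)) {
    w("[angles]")
    g <- system$angles
    for (r in seq_len(nrow(g))) {
      w("%d %d %d %s %s", g$i[r], g$j[r], g$k_atom[r], num(g$force_k[r]),
        num(g$theta0[r] * 180 / pi))
    }
  }
  if (nrow(system$dihedrals)) {
    w("[dihedrals]")
    d <- system$dihedrals
    for (r in seq_len(nrow(d))) {
      w("%d %d %d %d %s %s %s", d$i[r], d$j[r], d$k_atom[r], d$l[r],
        num(d$vn[r]), num(d$period[r]), num(d$phase[r] * 180 / pi))
    }
  }
  ex <- system$extra_exclusions
  if (!is.null(ex) && nrow(ex)) {
    w("[exclusions]")
    for (r in seq_len(nrow(ex))) w("%d %d", ex$i[r], ex$j[r])
  }
  w("[masks]")
  if (length(system$ligand)) {
    w("ligand %s", paste(system$ligand, collapse = " "))
  }
  if (length(system$receptor)) {
    w("receptor %s", paste(system$receptor, collapse = " "))
  }
  w("[options]")
  w("scale_ee %s", num(system$scale_ee))
  w("scale_lj %s", num(system$scale_lj))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
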