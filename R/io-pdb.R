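#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (via bio3d) into a `molecular_system` skeleton
#' plus one coordinate frame. Force-field fields (charges, LJ, GB) are left
#' `NA`; use [read_toy_topology()] for fully parameterized systems.
#'
#' @param path Path to a PDB file.
#' @return A list with elements `system` (a `molecular_system` skeleton) and
#'   `frame` (n x 3 coordinate matrix, Angstrom).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path, ": empty system")
  # diagnose malformed coordinate fields before delegating to bio3d
  for (ln in which(rec)) {
    fields <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
                substr(lines[ln], 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(fields))))) {
      stop("malformed ATOM/HETATM record at line ", ln, " of ", path)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  atoms <- tibble::tibble(
    name = trimws(at$elety),
    element = trimws(element),
    residue_id = at$resno,
    residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain), "A", at$chain)
  )
  frame <- cbind(at$x, at$y, at$z)
  colnames(frame) <- c("x", "y", "z")
  list(system = molecular_system(atoms), frame = frame)
}

#' Write a PDB structure
#'
#' @param system A `molecular_system`.
#' @param frame n x 3 coordinate matrix (Angstrom).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, frame, path) {
  check_frame(system, frame)
  a <- system$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(frame)),
    resno = a$residue_id, resid = a$residue_name,
    eleno = a$index, elety = a$name, chain = a$chain_id,
    elesy = a$element
  )
  invisible(path)
}

#' Read a trajectory
#'
#' Two mandatory plain-text formats are supported: multi-model PDB
#' (`MODEL`/`ENDMDL` blocks) and a whitespace xyz table with one row per
#' atom per frame (columns `frame x y z`, frames numbered from 1;
#' `#` comments tolerated).
#'
#' @param path Path to a multi-model PDB (`format = "pdb"`) or xyz table
#'   (`format = "xyz"`); guessed from the extension by default.
#' @param n_atoms Atom count, required for `format = "xyz"`.
#' @param frame_interval Optional sampling interval in ps.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            n_atoms = NULL, frame_interval = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    frames <- lapply(seq_len(nrow(xyz)), function(m) {
      matrix(xyz[m, ], ncol = 3, byrow = TRUE,
             dimnames = list(NULL, c("x", "y", "z")))
    })
  } else {
    tab <- utils::read.table(path, comment.char = "#",
                             col.names = c("frame", "x", "y", "z"))
    if (is.null(n_atoms)) {
      n_atoms <- sum(tab$frame == tab$frame[1])
    }
    if (nrow(tab) %% n_atoms != 0) {
      stop("xyz table row count ", nrow(tab),
           " is not a multiple of n_atoms = ", n_atoms)
    }
    frames <- lapply(split(seq_len(nrow(tab)),
                           rep(seq_len(nrow(tab) / n_atoms),
                               each = n_atoms)),
                     function(rows) {
                       m <- as.matrix(tab[rows, c("x", "y", "z")])
                       dimnames(m) <- list(NULL, c("x", "y", "z"))
                       m
                     })
    names(frames) <- NULL
  }
  trajectory(frames, frame_interval = frame_interval)
}

#' Write a trajectory
#'
#' @param system A `molecular_system` (atom metadata for PDB output).
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param format `"pdb"` (multi-model) or `"xyz"` (whitespace table).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(system, traj, path,
                             format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "pdb") {
    con <- file(path, "w")
    on.exit(close(con))
    tmp <- tempfile(fileext = ".pdb")
    for (m in seq_along(traj$frames)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      write_pdb(system, traj$frames[[m]], tmp)
      body <- readLines(tmp, warn = FALSE)
      writeLines(body[grepl("^(ATOM|HETATM|TER)", body)], con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    unlink(tmp)
  } else {
    rows <- do.call(rbind, lapply(seq_along(traj$frames), function(m) {
      cbind(frame = m, traj$frames[[m]])
    }))
    utils::write.table(rows, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
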