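#' Lambda window of dU/dlambda samples
#'
#' @param lam Coupling parameter, in `[0, 1]`.
#' @param samples Ordered dU/dlambda observations (kcal/mol).
#' @return List of class `lambda_window`.
#' @export
lambda_window <- function(lam, samples) {
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("lambda window has no samples")
  structure(list(lam = lam, samples = samples), class = "lambda_window")
}

#' The 14-lambda schedule used by the reference protocol
#'
#' `0, 0.0001, 0.001, 0.01, 0.1, 0.2, ..., 0.9, 1.0`: dense near the
#' endpoint where softcore-decoupled derivatives vary fastest.
#'
#' @return Numeric vector of 14 lambda values.
#' @export
ti_lambda_schedule <- function() {
  c(0, 0.0001, 0.001, 0.01, seq(0.1, 1.0, by = 0.1))
}

#' Trapezoidal-rule thermodynamic integration (TRA)
#'
#' `dG = sum 0.5 (m_i + m_{i+1}) (lambda_{i+1} - lambda_i)` over per-window
#' sample means `m_i`. Exact for integrands piecewise linear on the grid.
#'
#' @param windows List of [lambda_window()] objects covering `lambda = 0`
#'   and `lambda = 1` (any order; sorted internally).
#' @param discard Equilibration fraction discarded from the start of each
#'   window's samples (default 0).
#' @return dG in kcal/mol.
#' @export
trapezoid_integrate <- function(windows, discard = 0) {
  lam <- vapply(windows, function(w) w$lam, numeric(1))
  if (anyDuplicated(lam)) {
    stop("duplicate lambda value(s): ",
         paste(unique(lam[duplicated(lam)]), collapse = ", "))
  }
  ord <- order(lam)
  lam <- lam[ord]
  if (lam[1] != 0 || lam[length(lam)] != 1) {
    stop("lambda grid must include both endpoints 0 and 1")
  }
  means <- vapply(windows[ord], function(w) {
    s <- w$samples
    if (discard > 0) s <- s[-seq_len(floor(discard * length(s)))]
    mean(s)
  }, numeric(1))
  sum(0.5 * (means[-1] + means[-length(means)]) * diff(lam))
}

#' Replica statistics for TI estimates
#'
#' Integrates each replica's lambda windows with [trapezoid_integrate()]
#' and reports the across-replica mean and sample standard deviation.
#'
#' @param replicas List of replicas, each a list of [lambda_window()]s on
#'   an identical lambda grid.
#' @param discard Passed to [trapezoid_integrate()].
#' @return List of class `ti_result`: `per_replica` tibble, `mean`, `sd`
#'   (NA with a single replica), `lambdas`.
#' @export
replica_statistics <- function(replicas, discard = 0) {
  if (length(replicas) < 1) stop("need at least one replica")
  grids <- lapply(replicas, function(r) {
    sort(vapply(r, function(w) w$lam, numeric(1)))
  })
  for (k in seq_along(grids)[-1]) {
    if (!isTRUE(all.equal(grids[[1]], grids[[k]]))) {
      stop("replica ", k, " has a different lambda grid")
    }
  }
  dg <- vapply(replicas, trapezoid_integrate, numeric(1),
               discard = discard)
  structure(list(
    per_replica = tibble::tibble(replica = seq_along(dg), dg = dg),
    mean = mean(dg),
    sd = if (length(dg) > 1) stats::sd(dg) else NA_real_,
    lambdas = grids[[1]]
  ), class = "ti_result")
}

#' @export
print.ti_result <- function(x, ...) {
  cat("<ti_result> ", nrow(x$per_replica), " replica(s), ",
      length(x$lambdas), " lambda windows\n", sep = "")
  cat(sprintf("  dG = %.4f +/- %s kcal/mol\n", x$mean,
              ifelse(is.na(x$sd), "NA (single replica)",
                     sprintf("%.4f", x$sd))))
  invisible(x)
}

#' Double-decoupling ddG cycle
#'
#' `ddG = dG_holo - dG_apo` for the same alchemical transformation run in
#' the bound (holo) and free (apo) states; positive values mean the
#' mutation weakens binding.
#'
#' @param dg_holo,dg_apo Leg free energies (numeric or `ti_result`).
#' @return ddG in kcal/mol.
#' @export
ddg_cycle <- function(dg_holo, dg_apo) {
  val <- function(x) if (inherits(x, "ti_result")) x$mean else
    as.numeric(x)
  val(dg_holo) - val(dg_apo)
}

#' Read a TI dataset from disk
#'
#' Layout: one directory per replica (`replica_1`, `replica_2`, ...), each
#' containing two-column text files `lambda_<value>.dat` (step, dU/dlambda;
#' `#` comments tolerated).
#'
#' @param path Dataset directory.
#' @return List of replicas, each a list of [lambda_window()]s.
#' @export
read_ti_dataset <- function(path) {
  reps <- sort(list.dirs(path, recursive = FALSE))
  reps <- reps[grepl("replica_", basename(reps))]
  if (length(reps) == 0) stop("no replica_* directories under ", path)
  lapply(reps, function(rd) {
    files <- sort(list.files(rd, pattern = "^lambda_.*\\.dat$",
                             full.names = TRUE))
    lapply(files, function(f) {
      lam <- as.numeric(sub("^lambda_(.*)\\.dat$", "\\1", basename(f)))
      tab <- utils::read.table(f, comment.char = "#",
                               col.names = c("step", "dudl"))
      lambda_window(lam, tab$dudl)
    })
  })
}

#' Write a TI dataset to disk
#'
#' Inverse of [read_ti_dataset()].
#'
#' @param replicas List of replicas (lists of [lambda_window()]s).
#' @param path Output directory (created).
#' @return `path`, invisibly.
#' @export
write_ti_dataset <- function(replicas, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(replicas)) {
    rd <- file.path(path, sprintf("replica_%d", r))
    dir.create(rd, showWarnings = FALSE)
    for (w in replicas[[r]]) {
      f <- file.path(rd, sprintf("lambda_%s.dat",
                                 format(w$lam, scientific = FALSE)))
      utils::write.table(
        data.frame(step = seq_along(w$samples), dudl = w$samples),
        f, row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}
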