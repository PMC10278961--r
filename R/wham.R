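#' Harmonic umbrella bias potential
#'
#' `w(xi) = (K/2) (xi - xi_ref)^2`.
#'
#' @param xi Reaction-coordinate value(s), Angstrom.
#' @param xi_ref Window reference position, Angstrom.
#' @param K Elastic constant, kcal/(mol A^2) (the reference layout uses 5).
#' @return Bias energy, kcal/mol.
#' @export
bias_potential <- function(xi, xi_ref, K) {
  (K / 2) * (xi - xi_ref)^2
}

#' Umbrella window
#'
#' @param xi_ref Reference reaction-coordinate value, Angstrom.
#' @param K Elastic constant, kcal/(mol A^2); must be positive (use a tiny
#'   value for an effectively unbiased window).
#' @param samples Observed reaction-coordinate values, Angstrom.
#' @return List of class `umbrella_window`.
#' @export
umbrella_window <- function(xi_ref, K, samples) {
  if (K <= 0) stop("K must be > 0")
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("umbrella window has no samples")
  structure(list(xi_ref = xi_ref, K = K, samples = samples),
            class = "umbrella_window")
}

#' WHAM reconstruction of a PMF from umbrella windows
#'
#' Iterates the self-consistent WHAM equations on the per-window free
#' energy offsets `f_i` until `max |delta f| < tolerance`, then reports
#' `PMF = -kB T log(unbiased density)` anchored so its minimum is 0.
#' Bins inside the sampled range that received no samples are masked and
#' reported via the `masked_bins` attribute.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param bin_width Histogram bin width, Angstrom (default 0.1: five bins
#'   per 0.5-A window of the reference layout).
#' @param T Temperature, K (default 300).
#' @param tolerance Convergence threshold on offsets, kcal/mol.
#' @param max_iter Iteration cap.
#' @return A tibble of class `pmf_profile` with columns `xi` (bin
#'   centers), `free_energy` (kcal/mol, min 0), `count`; attributes
#'   `temperature`, `offsets`, `masked_bins`, `prob_total`.
#' @export
wham <- function(windows, bin_width = 0.1, T = 300, tolerance = 1e-6,
                 max_iter = 100000) {
  if (length(windows) < 1) stop("need at least one window")
  kT <- bfe_constants$kB * T
  xs <- unlist(lapply(windows, function(w) w$samples))
  lo <- floor(min(xs) / bin_width) * bin_width
  hi <- ceiling(max(xs) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  nb <- length(centers)
  nw <- length(windows)

  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    h <- hist(windows[[i]]$samples, breaks = edges, plot = FALSE)
    counts[i, ] <- h$counts
  }
  if (nw > 1) {
    refs <- vapply(windows, function(w) w$xi_ref, numeric(1))
    ord <- order(refs)
    for (k in seq_len(nw - 1)) {
      a <- counts[ord[k], ] > 0
      b <- counts[ord[k + 1], ] > 0
      if (!any(a & b)) {
        warning("windows at xi_ref ", refs[ord[k]], " and ",
                refs[ord[k + 1]], " share no occupied bin")
        break
      }
    }
  }
  n_i <- rowSums(counts)
  n_k <- colSums(counts)
  bias <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    bias[i, ] <- bias_potential(centers, windows[[i]]$xi_ref,
                                windows[[i]]$K)
  }
  B <- exp(-bias / kT)

  f <- numeric(nw)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- colSums(n_i * B * exp(f / kT))
    p <- ifelse(denom > 0, n_k / denom, 0)
    f_new <- -kT * log(pmax(B %*% p, .Machine$double.xmin))[, 1]
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("WHAM did not converge in ", max_iter,
         " iterations (last max |delta f| = ", signif(delta, 3),
         "); offsets: ", paste(signif(f, 4), collapse = ", "))
  }
  denom <- colSums(n_i * B * exp(f / kT))
  p <- ifelse(denom > 0, n_k / denom, 0)
  prob_total <- sum(p)
  p <- p / prob_total

  occupied <- n_k > 0
  masked <- centers[!occupied & centers > min(xs) & centers < max(xs)]
  g <- rep(NA_real_, nb)
  g[occupied] <- -kT * log(p[occupied])
  g <- g - min(g, na.rm = TRUE)

  out <- tibble::tibble(xi = centers[occupied],
                        free_energy = g[occupied],
                        count = n_k[occupied])
  class(out) <- c("pmf_profile", class(out))
  attr(out, "temperature") <- T
  attr(out, "offsets") <- f
  attr(out, "masked_bins") <- masked
  attr(out, "prob_total") <- sum(p[occupied])
  out
}

#' Round-averaged PMF
#'
#' Per-bin arithmetic mean (and SD) of the last `last_n` round profiles
#' after re-anchoring each profile's minimum to 0, mirroring the
#' last-10-of-18-rounds averaging used to declare umbrella-sampling
#' convergence.
#'
#' @param round_profiles List of `pmf_profile`s on identical bins,
#'   ordered by round.
#' @param last_n Number of trailing rounds to average (default 10).
#' @return A `pmf_profile` tibble with an extra `sd` column.
#' @export
average_pmf <- function(round_profiles, last_n = 10) {
  n <- length(round_profiles)
  if (n < last_n) stop("need at least ", last_n, " rounds, got ", n)
  use <- round_profiles[(n - last_n + 1):n]
  xi <- use[[1]]$xi
  for (p in use[-1]) {
    if (length(p$xi) != length(xi) || any(p$xi != xi)) {
      stop("round profiles are on different bins")
    }
  }
  mat <- vapply(use, function(p) p$free_energy - min(p$free_energy),
                numeric(length(xi)))
  out <- tibble::tibble(
    xi = xi,
    free_energy = rowMeans(mat),
    sd = apply(mat, 1, stats::sd),
    count = rowSums(vapply(use, function(p) as.numeric(p$count),
                           numeric(length(xi))))
  )
  out$free_energy <- out$free_energy - min(out$free_energy)
  class(out) <- c("pmf_profile", class(out))
  attr(out, "temperature") <- attr(use[[1]], "temperature")
  out
}

#' Binding free energy from a PMF
#'
#' `dG = mean(free energy over the bulk region) - min(free energy over the
#' bound region)`. The difference of two profiles' dG values gives a
#' PMF-based ddG; rigid vertical shifts cancel.
#'
#' @param profile A `pmf_profile`.
#' @param bound_region,bulk_region Length-2 numeric ranges on the reaction
#'   coordinate, Angstrom.
#' @return dG in kcal/mol.
#' @export
pmf_delta <- function(profile, bound_region, bulk_region) {
  sel <- function(rg) {
    k <- profile$xi >= rg[1] & profile$xi <= rg[2]
    if (!any(k)) stop("region [", rg[1], ", ", rg[2],
                      "] contains no PMF bins")
    k
  }
  mean(profile$free_energy[sel(bulk_region)]) -
    min(profile$free_energy[sel(bound_region)])
}

#' Read an umbrella dataset from disk
#'
#' Layout: a `windows.txt` metadata file (columns `window xi_ref K`) plus
#' one sample file per window per round (`round_<r>/window_<w>.dat`,
#' one xi value per line; `#` comments tolerated).
#'
#' @param path Dataset directory.
#' @return List of rounds, each a list of [umbrella_window()]s.
#' @export
read_umbrella_dataset <- function(path) {
  meta <- utils::read.table(file.path(path, "windows.txt"),
                            comment.char = "#",
                            col.names = c("window", "xi_ref", "K"))
  rounds <- sort(list.dirs(path, recursive = FALSE))
  rounds <- rounds[grepl("round_", basename(rounds))]
  if (length(rounds) == 0) stop("no round_* directories under ", path)
  ord <- order(as.integer(sub("round_", "", basename(rounds))))
  lapply(rounds[ord], function(rd) {
    lapply(seq_len(nrow(meta)), function(w) {
      f <- file.path(rd, sprintf("window_%d.dat", meta$window[w]))
      umbrella_window(meta$xi_ref[w], meta$K[w],
                      scan(f, quiet = TRUE, comment.char = "#"))
    })
  })
}

#' Write an umbrella dataset to disk
#'
#' Inverse of [read_umbrella_dataset()].
#'
#' @param rounds List of rounds (lists of [umbrella_window()]s).
#' @param path Output directory (created).
#' @return `path`, invisibly.
#' @export
write_umbrella_dataset <- function(rounds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w1 <- rounds[[1]]
  meta <- data.frame(window = seq_along(w1),
                     xi_ref = vapply(w1, function(w) w$xi_ref, numeric(1)),
                     K = vapply(w1, function(w) w$K, numeric(1)))
  utils::write.table(meta, file.path(path, "windows.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  for (r in seq_along(rounds)) {
    rd <- file.path(path, sprintf("round_%d", r))
    dir.create(rd, showWarnings = FALSE)
    for (w in seq_along(rounds[[r]])) {
      writeLines(format(rounds[[r]][[w]]$samples, trim = TRUE),
                 file.path(rd, sprintf("window_%d.dat", w)))
    }
  }
  invisible(path)
}
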