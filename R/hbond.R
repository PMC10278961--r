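#' Hydrogen-bond occupancy over a trajectory
#'
#' A donor-H...acceptor triple counts as hydrogen bonded in a frame when
#' the donor-heavy-to-acceptor distance is `<= d_cut` AND the
#' donor-H...acceptor angle is `>= angle_cut`. Defaults (3.0 A, 135
#' degrees) match the conventional trajectory-analysis settings. Hydrogens
#' are resolved from the bond graph; a donor without an attached hydrogen
#' is an error.
#'
#' @param system A `molecular_system`.
#' @param traj A [trajectory()].
#' @param donor_set Heavy-atom indices of candidate donors.
#' @param acceptor_set Heavy-atom indices of candidate acceptors.
#' @param d_cut Heavy-heavy distance cutoff, Angstrom (default 3.0).
#' @param angle_cut D-H...A angle cutoff, degrees (default 135).
#' @return A tibble of class `hbond_series`: one row per
#'   donor/hydrogen/acceptor triple with `occupancy`, `n_frames`, and
#'   list-columns `present` (per-frame logical) and `distance` (per-frame
#'   heavy-heavy distance).
#' @export
hbond_occupancy <- function(system, traj, donor_set, acceptor_set,
                            d_cut = 3.0, angle_cut = 135) {
  a <- system$atoms
  b <- system$bonds
  attached_h <- function(d) {
    nb <- c(b$j[b$i == d], b$i[b$j == d])
    nb[!is_heavy(a$element[nb])]
  }
  triples <- list()
  for (d in donor_set) {
    hs <- attached_h(d)
    if (length(hs) == 0) {
      stop("donor atom ", d, " has no attached hydrogen")
    }
    for (h in hs) for (acc in setdiff(acceptor_set, d)) {
      triples[[length(triples) + 1]] <- c(d, h, acc)
    }
  }
  nf <- length(traj$frames)
  rows <- purrr::map_dfr(triples, function(tr) {
    d <- tr[1]; h <- tr[2]; acc <- tr[3]
    dist <- numeric(nf); present <- logical(nf)
    for (f in seq_len(nf)) {
      fr <- traj$frames[[f]]
      da <- sqrt(sum((fr[d, ] - fr[acc, ])^2))
      v1 <- fr[d, ] - fr[h, ]
      v2 <- fr[acc, ] - fr[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) *
        180 / pi
      dist[f] <- da
      present[f] <- da <= d_cut && ang >= angle_cut
    }
    tibble::tibble(donor = d, hydrogen = h, acceptor = acc,
                   occupancy = mean(present), n_frames = nf,
                   present = list(present), distance = list(dist))
  })
  class(rows) <- c("hbond_series", class(rows))
  rows
}
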