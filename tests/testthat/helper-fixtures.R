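# Shared fixtures and independent oracles. Oracles are deliberately
# written as naive second implementations (double loops, numeric
# integration, exhaustive enumeration) so they cannot share bugs with the
# vectorized code paths they check.

atom_tbl <- function(n, element = "C", residue_id = 1L, charge = 0,
                     rmin_half = 1.8, eps = 0.1, gb_radius = 1.7,
                     gb_screen = 0.8, name = NULL,
                     residue_name = "TOY") {
  tibble::tibble(
    name = name %||% paste0("X", seq_len(n)),
    element = rep_len(element, n),
    residue_id = rep_len(as.integer(residue_id), n),
    residue_name = rep_len(residue_name, n),
    chain_id = "A",
    charge = rep_len(charge, n),
    lj_rmin_half = rep_len(rmin_half, n),
    lj_epsilon = rep_len(eps, n),
    gb_radius = rep_len(gb_radius, n),
    gb_screen = rep_len(gb_screen, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_single_ion <- function(q = 1, gb_radius = 2.09) {
  molecular_system(atom_tbl(1, charge = q, gb_radius = gb_radius),
                   receptor = 1L)
}

make_diatomic <- function(k = 300, r0 = 1.5, elements = c("C", "O")) {
  sys <- molecular_system(
    atom_tbl(2, element = elements, charge = 0, eps = 0),
    bonds = data.frame(i = 1, j = 2, k = k, r0 = r0), receptor = 1:2)
  list(system = sys, frame = rbind(c(0, 0, 0), c(r0, 0, 0)))
}

# n nonbonded atoms with random charges/LJ at random well-separated
# positions
make_random_cloud <- function(n, seed, q_scale = 0.5, spread = 6) {
  set.seed(seed)
  repeat {
    fr <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
    if (n < 2 || min(stats::dist(fr)) > 1.2) break
  }
  at <- atom_tbl(n, charge = stats::runif(n, -q_scale, q_scale),
                 rmin_half = stats::runif(n, 1.5, 2.0),
                 eps = stats::runif(n, 0.05, 0.2),
                 gb_radius = stats::runif(n, 1.3, 1.9))
  list(system = molecular_system(at, receptor = seq_len(n)), frame = fr)
}

# bonded bead chain (for SASA / LCPO atom typing)
make_bead_chain <- function(n, seed) {
  set.seed(seed)
  fr <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    repeat {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2)) * stats::runif(1, 1.4, 1.6)
      cand <- fr[i - 1, ] + d
      if (i < 3 ||
          min(sqrt(rowSums(sweep(fr[1:(i - 2), , drop = FALSE], 2,
                                 cand)^2))) > 2.2) break
    }
    fr[i, ] <- cand
  }
  at <- atom_tbl(n, element = sample(c("C", "N", "O"), n, replace = TRUE),
                 rmin_half = stats::runif(n, 1.5, 1.9))
  sys <- molecular_system(at, bonds = data.frame(i = seq_len(n - 1),
                                                 j = seq_len(n - 1) + 1,
                                                 k = 300, r0 = 1.5),
                          receptor = seq_len(n))
  list(system = sys, frame = fr)
}

## --- independent oracles ---------------------------------------------

oracle_coulomb <- function(q, fr, eps = 1, pairs_scale = NULL) {
  n <- length(q)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- if (is.null(pairs_scale)) 1 else pairs_scale[i, j]
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
    e <- e + 332.0637 * s * q[i] * q[j] / (eps * r)
  }
  e
}

oracle_lj <- function(rmh, epsv, fr, pairs_scale = NULL) {
  n <- length(epsv)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- if (is.null(pairs_scale)) 1 else pairs_scale[i, j]
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
    rm <- rmh[i] + rmh[j]
    ee <- sqrt(epsv[i] * epsv[j])
    e <- e + s * ee * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

# numeric descreening integral: (1/4pi) int over sphere (radius s at
# distance r) of 1/x^4, excluding the region within rho of the origin
oracle_descreen <- function(r, s, rho, n = 400) {
  u <- seq(-s, s, length.out = n)
  h <- u[2] - u[1]
  tot <- 0
  for (z in u) {
    rho_max <- sqrt(max(s^2 - z^2, 0))
    if (rho_max <= 0) next
    rr <- seq(0, rho_max, length.out = n)
    hr <- rr[2] - rr[1]
    x2 <- (r + z)^2 + rr^2
    f <- ifelse(x2 > rho^2, rr / x2^2, 0)
    tot <- tot + sum((f[-1] + f[-n]) / 2) * hr * h
  }
  tot * 2 * pi / (4 * pi)
}

oracle_gb <- function(q, fr, radii, eps_in, eps_out) {
  n <- length(q)
  fac <- -332.0637 * (1 / eps_in - 1 / eps_out)
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((fr[i, ] - fr[j, ])^2)
    fgb <- sqrt(r2 + radii[i] * radii[j] *
                  exp(-r2 / (4 * radii[i] * radii[j])))
    e <- e + fac / 2 * q[i] * q[j] / fgb
  }
  e
}

# Kirkwood reaction-field energy of one charge at offset d inside a
# sphere of radius a
oracle_kirkwood <- function(q, d, a, eps_in, eps_out, lmax = 80) {
  s <- 0
  for (l in 0:lmax) {
    s <- s + ((l + 1) * (eps_in - eps_out) /
                (eps_in * ((l + 1) * eps_out + l * eps_in))) *
      d^(2 * l) / a^(2 * l + 1)
  }
  332.0637 / 2 * q^2 * s
}

# quaternion-based optimal RMSD (Kearsley), independent of the SVD path
oracle_quaternion_rmsd <- function(mobile, reference) {
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(reference, 2, colMeans(reference))
  xm <- m[, 1]; ym <- m[, 2]; zm <- m[, 3]
  xr <- r[, 1]; yr <- r[, 2]; zr <- r[, 3]
  xp <- xm + xr; yp <- ym + yr; zp <- zm + zr
  xq <- xr - xm; yq <- yr - ym; zq <- zr - zm
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xq^2 + yq^2 + zq^2)
  K[2, 2] <- sum(xq^2 + yp^2 + zp^2)
  K[3, 3] <- sum(xp^2 + yq^2 + zp^2)
  K[4, 4] <- sum(xp^2 + yp^2 + zq^2)
  K[1, 2] <- K[2, 1] <- sum(yp * zq - yq * zp)
  K[1, 3] <- K[3, 1] <- sum(xq * zp - xp * zq)
  K[1, 4] <- K[4, 1] <- sum(xp * yq - xq * yp)
  K[2, 3] <- K[3, 2] <- sum(xq * yq - xp * yp)
  K[2, 4] <- K[4, 2] <- sum(xq * zq - xp * zp)
  K[3, 4] <- K[4, 3] <- sum(yq * zq - yp * zp)
  lam <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(lam, 0) / nrow(mobile))
}

# exhaustive shortest-path enumeration on a small weighted graph
oracle_shortest_path <- function(edges, source, sink) {
  # edges: data.frame(from, to, weight) undirected
  nodes <- unique(c(edges$from, edges$to))
  best <- Inf
  walk <- function(at, visited, len) {
    if (len >= best) return()
    if (at == sink) { best <<- len; return() }
    for (r in seq_len(nrow(edges))) {
      nxt <- if (edges$from[r] == at) edges$to[r]
        else if (edges$to[r] == at) edges$from[r] else next
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), len + edges$weight[r])
    }
  }
  walk(source, source, 0)
  best
}

rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / total
}

# RMSD between two free-energy profiles after the optimal constant shift
# (free energies are defined up to an additive constant)
profile_rmsd <- function(g, truth) {
  d <- g - truth
  sqrt(mean((d - mean(d))^2))
}
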