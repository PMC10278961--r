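test_that("identical motion gives perfect correlation and zero edge
           weight", {
  base <- rbind(c(0, 0, 0), c(3, 0, 0))
  set.seed(1)
  frames <- lapply(1:50, function(t) {
    base + matrix(rnorm(3, sd = 0.4), 2, 3, byrow = TRUE)
  })
  C <- displacement_correlation(trajectory(frames), 1:2, fit = FALSE)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  adj <- matrix(TRUE, 2, 2); diag(adj) <- FALSE
  g <- build_network(C, adj, node_ids = c("a", "b"))
  expect_equal(igraph::E(g)$weight, 0, tolerance = 1e-12)
})

test_that("independent noise decorrelates with many frames", {
  set.seed(12)
  frames <- lapply(1:10000, function(t) {
    matrix(rnorm(6, sd = 0.3), 2, 3) + rbind(c(0, 0, 0), c(8, 0, 0))
  })
  C <- displacement_correlation(trajectory(frames), 1:2, fit = FALSE)
  expect_lt(abs(C[1, 2]), 0.1)
})

test_that("correlation matrix matches the direct covariance oracle and
           its invariants", {
  net <- make_correlated_trajectory(n_groups = 2,
                                    residues_per_group = 4,
                                    n_frames = 60, seed = 5)
  C <- displacement_correlation(net$traj, net$node_atoms, fit = FALSE)
  # naive covariance re-computation
  nf <- length(net$traj$frames)
  n <- length(net$node_atoms)
  xs <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) xs[f, , ] <- net$traj$frames[[f]]
  mu <- apply(xs, c(2, 3), mean)
  oracle <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    di <- sweep(xs[, i, ], 2, mu[i, ])
    dj <- sweep(xs[, j, ], 2, mu[j, ])
    oracle[i, j] <- mean(rowSums(di * dj))
  }
  v <- diag(oracle)
  oracle <- oracle / sqrt(outer(v, v))
  expect_equal(unname(C), oracle, tolerance = 1e-10)
  expect_true(isSymmetric(unname(C)))
  expect_equal(unname(diag(C)), rep(1, n))
  expect_true(all(abs(C) <= 1 + 1e-12))

  expect_error(displacement_correlation(
    trajectory(net$traj$frames[1:5]), net$node_atoms), "at least 10")
})

test_that("zero-variance nodes are reported by name", {
  frames <- lapply(1:20, function(t) {
    rbind(c(0, 0, 0), c(3 + rnorm(1, sd = 0.1), 0, 0))
  })
  expect_error(displacement_correlation(trajectory(frames), 1:2,
                                        fit = FALSE),
               "zero-variance node")
})

test_that("contact adjacency applies cutoff and occupancy rules", {
  at <- dplyr::bind_rows(atom_tbl(1, residue_id = 1L),
                         atom_tbl(1, residue_id = 2L),
                         atom_tbl(1, residue_id = 3L))
  at$name <- c("A", "B", "C")
  sys <- molecular_system(at, receptor = 1:3)
  # residues 1-2 permanently 3 A apart; residue 3 at 20 A;
  # 1-2 vs 3: in 60% of frames residue 3 swings to 4 A of residue 2
  frames <- lapply(1:10, function(t) {
    third <- if (t <= 6) c(7, 0, 0) else c(23, 0, 0)
    rbind(c(0, 0, 0), c(3, 0, 0), third)
  })
  res <- contact_adjacency(sys, trajectory(frames),
                           occupancy_min = 0.75)
  expect_true(res$adjacency[1, 2])
  expect_equal(res$occupancy[1, 2], 1.0)
  expect_false(res$adjacency[1, 3])
  expect_false(res$adjacency[2, 3])   # 0.6 occupancy < 0.75
  expect_equal(res$occupancy[2, 3], 0.6)

  strict <- contact_adjacency(sys, trajectory(frames),
                              calpha_strict = TRUE, node_atoms = 1:3)
  expect_true(strict$adjacency[1, 2])
})

test_that("network edges encode -log|C| with adjacency gating", {
  C <- matrix(c(1, 0.1, 0.9,
                0.1, 1, -0.5,
                0.9, -0.5, 1), 3, 3)
  adj <- matrix(c(FALSE, TRUE, FALSE,
                  TRUE, FALSE, TRUE,
                  FALSE, TRUE, FALSE), 3, 3)
  g <- build_network(C, adj, node_ids = c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 2)
  eb <- igraph::as_data_frame(g)
  ab <- eb[eb$from == "a" & eb$to == "b", ]
  expect_equal(ab$weight, -log(0.1), tolerance = 1e-12)
  bc <- eb[(eb$from == "b" & eb$to == "c") |
             (eb$from == "c" & eb$to == "b"), ]
  expect_equal(bc$weight, -log(0.5), tolerance = 1e-12)
  expect_true(bc$negative)
  # high-correlation non-adjacent pair carries no edge
  expect_false(igraph::are_adjacent(g, "a", "c"))
  # weight decreases with |C|
  expect_gt(ab$weight, bc$weight)
})

test_that("Girvan-Newman splits two cliques at the bridge and keeps a
           uniform clique whole", {
  el <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)), c(5, 6))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], weight = 1,
               correlation = exp(-1), negative = FALSE,
               occupancy = 1),
    directed = FALSE)
  part <- girvan_newman(g)
  expect_equal(attr(part, "n_communities"), 2)
  memb <- setNames(part$community, part$node)
  expect_length(unique(memb[as.character(1:5)]), 1)
  expect_length(unique(memb[as.character(6:10)]), 1)
  expect_false(memb[["1"]] == memb[["10"]])

  clique <- igraph::make_full_graph(6)
  igraph::E(clique)$weight <- 1
  igraph::V(clique)$name <- letters[1:6]
  expect_equal(attr(girvan_newman(clique), "n_communities"), 1)
  expect_error(girvan_newman(igraph::make_empty_graph(0,
                                                      directed = FALSE)),
               "empty")
})

test_that("the full pipeline recovers planted communities across
           seeds", {
  for (s in 1:10) {
    n_groups <- 2 + s %% 2          # alternate 2- and 3-block plants
    net <- make_correlated_trajectory(n_groups = n_groups,
                                      residues_per_group = 5,
                                      n_frames = 80, seed = 100 + s)
    C <- displacement_correlation(net$traj, net$node_atoms)
    adj <- contact_adjacency(net$system, net$traj)
    part <- girvan_newman(build_network(C, adj))
    ri <- rand_index(part$community[order(as.integer(part$node))],
                     net$labels$group)
    expect_gte(ri, 0.9)
  }
})

test_that("optimal paths equal exhaustive enumeration on small
           graphs", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    repeat {
      full <- t(combn(seq_len(n), 2))
      keep <- runif(nrow(full)) < 0.55
      el <- full[keep, , drop = FALSE]
      g0 <- igraph::graph_from_edgelist(apply(el, 2, as.character),
                                        directed = FALSE)
      if (igraph::vcount(g0) == n && igraph::is_connected(g0)) break
    }
    w <- runif(nrow(el), 0.2, 3)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(el[, 1]),
                 to = as.character(el[, 2]), weight = w),
      directed = FALSE)
    res <- optimal_path(g, "1", as.character(n))
    oracle <- oracle_shortest_path(
      data.frame(from = as.character(el[, 1]),
                 to = as.character(el[, 2]), weight = w),
      "1", as.character(n))
    expect_equal(res$length[1], oracle, tolerance = 1e-12)
  }
})

test_that("path extraction handles direct edges, self paths, and
           disconnection", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               weight = c(0.5, 4, 4)), directed = FALSE)
  res <- optimal_path(g, "a", "b")
  expect_equal(res$nodes[[1]], c("a", "b"))
  expect_equal(res$length[1], 0.5)

  self <- optimal_path(g, "a", "a")
  expect_equal(self$length, 0)

  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b", weight = 1), directed = FALSE,
    vertices = data.frame(name = c("a", "b", "z")))
  none <- optimal_path(g2, "a", "z")
  expect_false(attr(none, "found"))
  expect_equal(nrow(none), 0)

  # suboptimal paths come out ranked
  sub <- optimal_path(g, "a", "c", n_suboptimal = 1)
  expect_equal(nrow(sub), 2)
  expect_true(all(diff(sub$length) >= 0))
})

test_that("hydrogen bonds follow the distance-and-angle criterion", {
  at <- atom_tbl(3, element = c("O", "H", "O"))
  at$name <- c("OD", "HD", "OA")
  sys <- molecular_system(at, bonds = data.frame(i = 1, j = 2, k = 400,
                                                 r0 = 1.0),
                          receptor = 1:3)
  linear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(4.0, 0, 0))
  hb1 <- hbond_occupancy(sys, trajectory(list(linear, linear)), 1, 3)
  expect_equal(hb1$occupancy, 1.0)
  hb2 <- hbond_occupancy(sys, trajectory(list(far, far)), 1, 3)
  expect_equal(hb2$occupancy, 0)
  # bent geometry below the angle cutoff fails even at short range
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.5, 0))
  hb3 <- hbond_occupancy(sys, trajectory(list(bent, bent)), 1, 3)
  expect_equal(hb3$occupancy, 0)
  expect_error(hbond_occupancy(sys, trajectory(list(linear)), 3, 1),
               "no attached hydrogen")
})

test_that("a constructed 2000-frame series counts 927 bonded frames", {
  at <- atom_tbl(3, element = c("O", "H", "O"))
  sys <- molecular_system(at, bonds = data.frame(i = 1, j = 2, k = 400,
                                                 r0 = 1.0),
                          receptor = 1:3)
  frames <- lapply(1:2000, function(t) {
    d <- if (t <= 927) 2.8 else 5.5
    rbind(c(0, 0, 0), c(1, 0, 0), c(d, 0, 0))
  })
  hb <- hbond_occupancy(sys, trajectory(frames), 1, 3)
  expect_equal(hb$occupancy, 927 / 2000)
  # occupancy is invariant under frame reordering
  set.seed(8)
  hb2 <- hbond_occupancy(sys, trajectory(sample(frames)), 1, 3)
  expect_equal(hb2$occupancy, hb$occupancy)
})
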