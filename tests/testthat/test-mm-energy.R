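test_that("bonded terms match their closed forms", {
  dia <- make_diatomic(k = 250, r0 = 1.5)
  e <- bonded_energy(dia$system, dia$frame)
  expect_equal(e$e_bond, 0)                       # at the minimum
  fr <- dia$frame
  fr[2, 1] <- 1.7
  expect_equal(bonded_energy(dia$system, fr)$e_bond, 250 * 0.2^2,
               tolerance = 1e-12)

  # dihedral V=2, n=1, gamma=0 at phi=0 contributes (2/2)(1+cos0) = 2
  at <- atom_tbl(4)
  sys <- molecular_system(
    at, dihedrals = data.frame(i = 1, j = 2, k_atom = 3, l = 4,
                               vn = 2, period = 1, phase = 0),
    receptor = 1:4)
  # cis-planar: phi = 0
  fr <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1, 0))
  expect_equal(bonded_energy(sys, fr)$e_dihedral, 2.0, tolerance = 1e-12)

  expect_error(bonded_energy(dia$system,
                             rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero-length")
})

test_that("random 6-atom bonded system matches a term-by-term oracle", {
  set.seed(19)
  fr <- matrix(rnorm(18, sd = 2), 6, 3)
  bonds <- data.frame(i = 1:5, j = 2:6,
                      k = runif(5, 100, 500), r0 = runif(5, 1.2, 1.8))
  angles <- data.frame(i = 1:4, j = 2:5, k_atom = 3:6,
                       force_k = runif(4, 30, 90),
                       theta0 = runif(4, 1.5, 2.5))
  dihedrals <- data.frame(i = 1:3, j = 2:4, k_atom = 3:5, l = 4:6,
                          vn = runif(3, 1, 4),
                          period = sample(1:4, 3, replace = TRUE),
                          phase = runif(3, 0, pi))
  sys <- molecular_system(atom_tbl(6), bonds = bonds, angles = angles,
                          dihedrals = dihedrals, receptor = 1:6)
  e <- bonded_energy(sys, fr)

  # naive per-term re-evaluation
  eb <- 0
  for (r in 1:5) {
    d <- sqrt(sum((fr[bonds$i[r], ] - fr[bonds$j[r], ])^2))
    eb <- eb + bonds$k[r] * (d - bonds$r0[r])^2
  }
  ea <- 0
  for (r in 1:4) {
    v1 <- fr[angles$i[r], ] - fr[angles$j[r], ]
    v2 <- fr[angles$k_atom[r], ] - fr[angles$j[r], ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    ea <- ea + angles$force_k[r] * (th - angles$theta0[r])^2
  }
  ed <- 0
  for (r in 1:3) {
    p1 <- fr[dihedrals$i[r], ]; p2 <- fr[dihedrals$j[r], ]
    p3 <- fr[dihedrals$k_atom[r], ]; p4 <- fr[dihedrals$l[r], ]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
            b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
            n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    ed <- ed + dihedrals$vn[r] / 2 *
      (1 + cos(dihedrals$period[r] * phi - dihedrals$phase[r]))
  }
  expect_equal(e$e_bond, eb, tolerance = 1e-10)
  expect_equal(e$e_angle, ea, tolerance = 1e-10)
  expect_equal(e$e_dihedral, ed, tolerance = 1e-10)
})

test_that("coulomb energy reproduces the constant and 1/eps scaling", {
  at <- atom_tbl(2, charge = 1)
  sys <- molecular_system(at, receptor = 1:2)
  fr <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(coulomb_energy(sys, fr, eps_in = 1), 332.0637)
  expect_equal(coulomb_energy(sys, fr, eps_in = 4), 332.0637 / 4)
  expect_equal(coulomb_energy(sys, fr, eps_in = 2),
               coulomb_energy(sys, fr, eps_in = 1) / 2)
  expect_error(coulomb_energy(sys, rbind(c(0, 0, 0), c(0, 0, 0))),
               "coincident")
})

test_that("nonbonded energies equal the brute-force double loop", {
  cl <- make_random_cloud(10, seed = 77)
  q <- cl$system$atoms$charge
  expect_equal(coulomb_energy(cl$system, cl$frame),
               oracle_coulomb(q, cl$frame), tolerance = 1e-10)
  expect_equal(lj_energy(cl$system, cl$frame),
               oracle_lj(cl$system$atoms$lj_rmin_half,
                         cl$system$atoms$lj_epsilon, cl$frame),
               tolerance = 1e-10)
})

test_that("LJ minimum and long-range limit behave", {
  at <- atom_tbl(2, rmin_half = 1.7, eps = 0.12)
  sys <- molecular_system(at, receptor = 1:2)
  fr <- rbind(c(0, 0, 0), c(3.4, 0, 0))   # r = Rmin
  expect_equal(lj_energy(sys, fr), -0.12, tolerance = 1e-12)
  fr[2, 1] <- 600
  expect_lt(abs(lj_energy(sys, fr)), 1e-12)
})

test_that("1-2/1-3 exclusions and 1-4 scaling follow the bond graph", {
  # linear 4-atom chain: pairs (1,2),(2,3),(3,4) excluded; (1,3),(2,4)
  # excluded; (1,4) scaled
  at <- atom_tbl(4, charge = c(0.4, -0.3, 0.2, -0.5), eps = 0.1)
  sys <- molecular_system(at,
                          bonds = data.frame(i = 1:3, j = 2:4, k = 300,
                                             r0 = 1.5), receptor = 1:4)
  fr <- cbind(seq(0, 4.5, by = 1.5), 0, 0)
  e <- coulomb_energy(sys, fr)
  expected <- 332.0637 * (1 / 1.2) * 0.4 * (-0.5) / 4.5
  expect_equal(e, expected, tolerance = 1e-12)
  scale_m <- matrix(0, 4, 4)
  scale_m[1, 4] <- scale_m[4, 1] <- 0.5
  expect_equal(lj_energy(sys, fr),
               oracle_lj(at$lj_rmin_half, at$lj_epsilon, fr, scale_m),
               tolerance = 1e-12)
})

test_that("ligand-receptor interaction energy has both routes agree", {
  toy <- make_toy_complex(seed = 4)
  sys <- toy$system
  inter <- interaction_energy(sys, toy$frame, breakdown = TRUE)
  # route 2: complex minus parts over the same coordinates
  all_idx <- seq_len(nrow(sys$atoms))
  d_ele <- coulomb_energy(sys, toy$frame, 1, all_idx, all_idx) -
    coulomb_energy(sys, toy$frame, 1, sys$receptor, sys$receptor) -
    coulomb_energy(sys, toy$frame, 1, sys$ligand, sys$ligand)
  d_vdw <- lj_energy(sys, toy$frame, all_idx, all_idx) -
    lj_energy(sys, toy$frame, sys$receptor, sys$receptor) -
    lj_energy(sys, toy$frame, sys$ligand, sys$ligand)
  expect_equal(inter$ele, d_ele, tolerance = 1e-10)
  expect_equal(inter$vdw, d_vdw, tolerance = 1e-10)
  # pair-sum conservation
  pairs <- attr(inter, "pairs")
  expect_equal(sum(pairs$ele), inter$ele, tolerance = 1e-10)
  expect_equal(sum(pairs$vdw), inter$vdw, tolerance = 1e-10)
})

test_that("a neutral LJ-free distant ligand has zero interaction", {
  at <- dplyr::bind_rows(
    atom_tbl(3, charge = c(0.3, -0.2, -0.1)),
    atom_tbl(2, charge = 0, eps = 0, residue_id = 2L,
             residue_name = "LIG"))
  at$name <- paste0("X", 1:5)
  sys <- molecular_system(at, ligand = 4:5, receptor = 1:3)
  fr <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0),
              c(500, 0, 0), c(501.5, 0, 0))
  inter <- interaction_energy(sys, fr)
  expect_equal(inter$ele, 0)
  expect_lt(abs(inter$vdw), 1e-15)
})

test_that("planted in-pocket repulsion weakens the electrostatics", {
  wt <- make_toy_complex(seed = 9)
  mut <- make_toy_complex(seed = 9, mutate = TRUE)
  e_wt <- interaction_energy(wt$system, wt$frame)$ele
  e_mut <- interaction_energy(mut$system, mut$frame)$ele
  expect_gt(e_mut, e_wt)   # mutant less favorable
})
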