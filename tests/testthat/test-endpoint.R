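test_that("bonded terms cancel exactly on every frame", {
  toy <- make_toy_complex(seed = 13)
  traj <- trajectory(list(toy$frame, toy$frame + 0.3,
                          toy$frame * 1.02))
  res <- endpoint_bfe(toy$system, traj, solvation_config("GB"))
  expect_identical(res$per_frame$bonded, rep(0, 3))
})

test_that("a non-interacting neutral ligand binds with ~zero energy", {
  at <- dplyr::bind_rows(
    atom_tbl(3, charge = c(0.3, -0.3, 0.1)),
    atom_tbl(2, charge = 0, eps = 0, residue_id = 2L,
             residue_name = "LIG"))
  at$name <- paste0("X", 1:5)
  sys <- molecular_system(at, ligand = 4:5, receptor = 1:3)
  fr <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(0, 1.6, 0),
              c(400, 0, 0), c(401.6, 0, 0))
  res <- endpoint_bfe(sys, fr, solvation_config("GB"))
  terms <- setNames(res$summary$mean, res$summary$term)
  expect_equal(unname(terms["ele"]), 0)
  expect_lt(abs(terms["vdw"]), 1e-12)
  expect_lt(abs(terms["polar"]), 1e-6)   # no cross-descreening at 400 A
  expect_lt(abs(terms["nonpolar"]), 1e-9)
})

test_that("one-frame enthalpy equals the hand-composed module oracle", {
  toy <- make_toy_complex(seed = 6)
  sys <- toy$system
  fr <- toy$frame
  cfg <- solvation_config("GB")
  res <- endpoint_bfe(sys, fr, cfg)

  inter <- interaction_energy(sys, fr)
  all_idx <- seq_len(nrow(sys$atoms))
  polar <- gb_energy(sys, fr, cfg, all_idx) -
    gb_energy(sys, fr, cfg, sys$receptor) -
    gb_energy(sys, fr, cfg, sys$ligand)
  sa <- 0.0072 * (lcpo_sasa(sys, fr)$total -
                    lcpo_sasa(sys, fr, atoms = sys$receptor)$total -
                    lcpo_sasa(sys, fr, atoms = sys$ligand)$total)
  expect_equal(res$per_frame$dh,
               inter$ele + inter$vdw + polar + sa, tolerance = 1e-10)
})

test_that("trajectory averaging is permutation-invariant", {
  toy <- make_toy_complex(seed = 23)
  frames <- list(toy$frame, toy$frame + 0.2, toy$frame - 0.15,
                 toy$frame * 1.01)
  r1 <- endpoint_bfe(toy$system, trajectory(frames),
                     solvation_config("GB"))
  r2 <- endpoint_bfe(toy$system, trajectory(frames[c(3, 1, 4, 2)]),
                     solvation_config("GB"))
  expect_equal(r1$summary$mean, r2$summary$mean, tolerance = 1e-12)
  expect_equal(r1$summary$sd, r2$summary$sd, tolerance = 1e-12)
})

test_that("per-residue decomposition conserves every component", {
  toy <- make_toy_complex(seed = 17)
  traj <- trajectory(list(toy$frame, toy$frame + 0.25))
  cfg <- solvation_config("GB")
  res <- endpoint_bfe(toy$system, traj, cfg)
  dec <- per_residue_decomposition(toy$system, traj, cfg)
  terms <- setNames(res$summary$mean, res$summary$term)
  expect_lt(abs(sum(dec$ele) - terms["ele"]), 1e-6)
  expect_lt(abs(sum(dec$vdw) - terms["vdw"]), 1e-6)
  expect_lt(abs(sum(dec$polar) - terms["polar"]), 1e-6)
  expect_lt(abs(sum(dec$nonpolar) - terms["nonpolar"]), 1e-6)
  expect_lt(abs(sum(dec$total) - terms["dh"]), 1e-6)
})

test_that("electrostatic contributions localize to the charged residue", {
  at <- dplyr::bind_rows(
    atom_tbl(1, residue_id = 1L, charge = 0.5, eps = 0),
    atom_tbl(1, residue_id = 2L, charge = 0, eps = 0),
    atom_tbl(1, residue_id = 3L, charge = -0.5, eps = 0,
             residue_name = "LIG"))
  at$name <- c("A", "B", "L")
  sys <- molecular_system(at, ligand = 3L, receptor = 1:2)
  fr <- rbind(c(0, 0, 0), c(4, 4, 0), c(3, 0, 0))
  dec <- per_residue_decomposition(sys, fr, solvation_config("GB"))
  # residue 2 is uncharged: no ele; the pair energy splits A/ligand
  expect_equal(dec$ele[dec$residue_id == 2], 0)
  pair_e <- 332.0637 * 0.5 * (-0.5) / 3
  expect_equal(dec$ele[dec$residue_id == 1], pair_e / 2,
               tolerance = 1e-10)
  expect_equal(dec$ele[dec$residue_id == 3], pair_e / 2,
               tolerance = 1e-10)
})

test_that("mutant-vs-wild per-residue shift equals the hand difference
           of two decompositions", {
  wt <- make_toy_complex(seed = 10)
  mut <- make_toy_complex(seed = 10, mutate = TRUE)
  cfg <- solvation_config("GB")
  d_wt <- per_residue_decomposition(wt$system, wt$frame, cfg)
  d_mut <- per_residue_decomposition(mut$system, mut$frame, cfg)
  ddg <- d_mut$total - d_wt$total
  # the mutation site dominates the shift and is repulsive
  site <- wt$mutation_site
  expect_equal(which.max(abs(ddg)), which(d_wt$residue_id == site))
  expect_gt(ddg[d_wt$residue_id == site], 0)
})

test_that("truncation keeps whole residues inside the cutoff only", {
  toy <- make_toy_complex(n_residues = 6, far_residues = 2, seed = 12)
  tr <- truncate_for_entropy(toy$system, toy$frame, cutoff = 9)
  kept_res <- unique(toy$system$atoms$residue_id[tr$atoms])
  expect_setequal(kept_res, c(1:6, 9))      # 9 = ligand residue id
  expect_false(any(c(7, 8) %in% kept_res))  # planted far residues out

  # all residues inside the cutoff -> identity truncation
  tr_all <- truncate_for_entropy(toy$system, toy$frame, cutoff = 50)
  expect_equal(tr_all$atoms, seq_len(nrow(toy$system$atoms)))

  # a single boundary atom at 8.99 A pulls in its whole residue
  at <- dplyr::bind_rows(
    atom_tbl(2, residue_id = 1L),
    atom_tbl(1, residue_id = 2L, residue_name = "LIG"))
  at$name <- c("A", "B", "L")
  sys <- molecular_system(at, ligand = 3L, receptor = 1:2)
  fr <- rbind(c(8.99, 0, 0), c(30, 0, 0), c(0, 0, 0))
  tr2 <- truncate_for_entropy(sys, fr, cutoff = 9)
  expect_setequal(tr2$atoms, 1:3)
})

test_that("ddG sign convention marks resistance as positive", {
  expect_equal(delta_delta_g(-8, -10), 2)
  expect_equal(delta_delta_g(-10, -10), 0)
  rep_tbl <- ddg_repeats(dg_mut = c(-8.14, -9.15, -8.19),
                         dg_wt = c(-10.0, -10.0, -10.0))
  expect_equal(rep_tbl$ddg, c(1.86, 0.85, 1.81))
  expect_equal(attr(rep_tbl, "mean"), mean(c(1.86, 0.85, 1.81)))
  expect_equal(attr(rep_tbl, "sd"), sd(c(1.86, 0.85, 1.81)))
})

test_that("ddG between endpoint results requires matching configs", {
  toy <- make_toy_complex(seed = 3)
  r1 <- endpoint_bfe(toy$system, toy$frame, solvation_config("GB"))
  r2 <- endpoint_bfe(toy$system, toy$frame,
                     solvation_config("GB", eps_in = 4))
  expect_error(delta_delta_g(r1, r2), "mismatched")
  expect_equal(delta_delta_g(r1, r1), 0)
})

test_that("broom-style accessors expose the result tables", {
  toy <- make_toy_complex(seed = 3)
  res <- endpoint_bfe(toy$system, toy$frame, solvation_config("GB"))
  td <- tidy(res)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$model, "GB")
  expect_equal(gl$dg_bind, res$dg_bind)
})
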