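test_that("PDB round-trip preserves atoms, order, and coordinates", {
  toy <- make_toy_complex(n_residues = 3, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$system, toy$frame, p1)
  rd <- read_pdb(p1)
  expect_equal(nrow(rd$system$atoms), nrow(toy$system$atoms))
  expect_equal(rd$system$atoms$name, toy$system$atoms$name)
  expect_equal(rd$system$atoms$residue_id, toy$system$atoms$residue_id)
  expect_equal(unname(rd$frame), unname(toy$frame), tolerance = 1e-3)
  # write(read(x)) is byte-identical in the coordinate fields
  write_pdb(rd$system, rd$frame, p2)
  coords <- function(p) {
    l <- readLines(p)
    substr(l[grepl("^(ATOM|HETATM)", l)], 31, 54)
  }
  expect_identical(coords(p2), coords(p1))
})

test_that("PDB reader rejects empty and malformed files", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER  test", "END"), p)
  expect_error(read_pdb(p), "empty system")
  writeLines(c("ATOM      1  CA  ALA A   1      xxx.000   0.000   0.000"),
             p)
  expect_error(read_pdb(p), "line 1")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("toy topology round-trips and validates", {
  toy <- make_toy_complex(seed = 5)
  p <- withr::local_tempfile(fileext = ".top")
  write_toy_topology(toy$system, p)
  back <- read_toy_topology(p)
  for (col in c("charge", "lj_rmin_half", "lj_epsilon", "gb_radius",
                "gb_screen")) {
    expect_equal(back$atoms[[col]], toy$system$atoms[[col]],
                 tolerance = 1e-9)
  }
  expect_equal(back$bonds$k, toy$system$bonds$k, tolerance = 1e-9)
  expect_equal(back$angles$theta0, toy$system$angles$theta0,
               tolerance = 1e-9)
  expect_equal(back$ligand, toy$system$ligand)
  expect_equal(back$receptor, toy$system$receptor)

  # diatomic fixture: one bond, charges as written
  dia <- withr::local_tempfile(fileext = ".top")
  writeLines(c(
    "[atoms]",
    "1 A1 C 1 DIA A 0.25 1.8 0.1 1.7 0.8",
    "2 A2 O 1 DIA A -0.25 1.6 0.2 1.5 0.8",
    "[bonds]", "1 2 300 1.5",
    "[masks]", "receptor 1:2"), dia)
  s <- read_toy_topology(dia)
  expect_equal(nrow(s$bonds), 1)
  expect_equal(s$atoms$charge, c(0.25, -0.25))
})

test_that("topology validation catches missing parameters and bad masks", {
  p <- withr::local_tempfile(fileext = ".top")
  writeLines(c("[atoms]", "1 A1 C 1 DIA A 0.25 1.8 0.1 1.7"), p)
  expect_error(read_toy_topology(p), "expected 11")
  # overlapping masks
  writeLines(c("[atoms]",
               "1 A1 C 1 DIA A 0.0 1.8 0.1 1.7 0.8",
               "2 A2 C 1 DIA A 0.0 1.8 0.1 1.7 0.8",
               "[masks]", "ligand 1 2", "receptor 2"), p)
  expect_error(read_toy_topology(p), "overlap")
})

test_that("trajectory xyz and multi-model PDB formats round-trip", {
  toy <- make_toy_complex(n_residues = 3, seed = 2)
  frames <- list(toy$frame, toy$frame + 0.25, toy$frame - 0.5)
  traj <- trajectory(frames, frame_interval = 5)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(toy$system, traj, xyz, format = "xyz")
  back <- read_trajectory(xyz, n_atoms = nrow(toy$frame))
  expect_equal(length(back), 3)
  expect_equal(back$frames[[2]], unname(frames[[2]]), tolerance = 1e-9,
               ignore_attr = TRUE)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(toy$system, traj, pdb, format = "pdb")
  back2 <- read_trajectory(pdb)
  expect_equal(length(back2), 3)
  expect_equal(unname(back2$frames[[3]]), unname(frames[[3]]),
               tolerance = 1e-3)
})

test_that("trajectory and system constructors enforce invariants", {
  expect_error(trajectory(list()), "non-empty")
  expect_error(trajectory(list(matrix(0, 2, 3), matrix(0, 3, 3))),
               "frame 2")
  expect_error(trajectory(list(matrix(c(0, 0, 0, 0, 0, NaN), 2, 3))),
               "non-finite")
  expect_error(molecular_system(atom_tbl(2), ligand = 1:2,
                                receptor = 2L), "overlap")
  expect_error(molecular_system(atom_tbl(2),
                                bonds = data.frame(i = 1, j = 5,
                                                   k = 1, r0 = 1)),
               "outside")
})
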