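pdb_atom_line <- function(serial, atom, resname, chain, resid, x, y, z) {
  an <- if (nchar(atom) < 4) sprintf(" %-3s", atom) else sprintf("%-4s", atom)
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, an, resname, chain, resid, x, y, z, 1, 0)
}

two_model_pdb <- function(path, cryst = "CRYST1   70.000   70.000  120.000  90.00  90.00  90.00") {
  atoms1 <- c(pdb_atom_line(1, "P", "LIP", "A", 1, 1, 2, 3),
              pdb_atom_line(2, "P", "LIP", "A", 2, 4, 5, 6),
              pdb_atom_line(3, "P", "LIP", "A", 3, 7, 8, 9),
              pdb_atom_line(4, "P", "LIP", "A", 4, 10, 11, 12))
  atoms2 <- c(pdb_atom_line(1, "P", "LIP", "A", 1, 1.5, 2, 3),
              pdb_atom_line(2, "P", "LIP", "A", 2, 4, 5.5, 6),
              pdb_atom_line(3, "P", "LIP", "A", 3, 7, 8, 9.5),
              pdb_atom_line(4, "P", "LIP", "A", 4, 10.5, 11, 12))
  writeLines(c(cryst, "MODEL        1", atoms1, "ENDMDL",
               "MODEL        2", atoms2, "ENDMDL", "END"), path)
  path
}

test_that("read_trajectory extracts frames, sites and box from multi-model PDB", {
  path <- two_model_pdb(withr::local_tempfile(fileext = ".pdb"))
  fs <- read_trajectory(path, "pdb", dt = 10)
  expect_equal(n_frames(fs), 2)
  expect_equal(n_sites(fs), 4)
  expect_equal(fs$box, matrix(c(70, 70, 120), 2, 3, byrow = TRUE))
  expect_equal(fs$coords[1, 2, ], c(4, 5, 6))
  expect_equal(fs$coords[2, 1, ], c(1.5, 2, 3))
  expect_equal(fs$times, c(0, 10))
  expect_equal(fs$site_meta$resid, 1:4)
  # format auto-detection from the extension gives the same result
  expect_equal(read_trajectory(path, dt = 10), fs)
})

test_that("GRO frames convert nm to Angstrom, including the box line", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("toy frame",
               "    2",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "SOL", "OW", 1L,
                       0.5, 0.6, 0.7),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2L, "SOL", "OW", 2L,
                       1.5, 1.6, 1.7),
               "   7.00000   7.00000  12.00000"), path)
  fs <- read_trajectory(path, "gro")
  expect_equal(fs$box[1, ], c(70, 70, 120))
  expect_equal(fs$coords[1, 1, ], c(5, 6, 7))
  expect_equal(fs$coords[1, 2, ], c(15, 16, 17))
})

test_that("malformed trajectory inputs raise the contracted errors", {
  tric <- two_model_pdb(withr::local_tempfile(fileext = ".pdb"),
    cryst = "CRYST1   70.000   70.000  120.000  90.00  90.00  60.00")
  expect_error(read_trajectory(tric, "pdb"), "unsupported geometry")
  nobox <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", pdb_atom_line(1, "P", "LIP", "A", 1, 1, 2, 3),
               "ENDMDL"), nobox)
  expect_error(read_trajectory(nobox, "pdb"), "CRYST1")
  expect_error(read_trajectory(withr::local_tempfile(fileext = ".pdb"), "pdb"),
               "not found")
  # inconsistent atom counts across models
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("CRYST1   70.000   70.000  120.000  90.00  90.00  90.00",
               "MODEL        1", pdb_atom_line(1, "P", "LIP", "A", 1, 1, 2, 3),
               pdb_atom_line(2, "P", "LIP", "A", 2, 4, 5, 6), "ENDMDL",
               "MODEL        2", pdb_atom_line(1, "P", "LIP", "A", 1, 1, 2, 3),
               "ENDMDL"), bad)
  expect_error(read_trajectory(bad, "pdb"), "format error")
  # triclinic GRO box line (9 components, non-zero off-diagonals)
  grot <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "SOL", "OW", 1L,
                       .5, .5, .5),
               "   7.0   7.0  12.0   0.0   0.0   1.2   0.0   0.0   0.0"), grot)
  expect_error(read_trajectory(grot, "gro"), "unsupported geometry")
})

make_popc_system <- function(n_res = 128) {
  # three atoms per lipid; only P should survive selection
  meta <- data.frame(resid = rep(seq_len(n_res), each = 3),
                     resname = "POPC",
                     atom = rep(c("N", "P", "C1"), n_res),
                     chain = "A")
  ns <- nrow(meta)
  coords <- array(rep(seq_len(ns), each = 1), c(1, ns, 3))
  frame_series(0, coords, matrix(c(70, 70, 120), 1, 3), meta)
}

test_that("select_representatives keeps one named atom per matched residue", {
  fs <- make_popc_system(128)
  sel <- select_representatives(fs, selection_spec(POPC = "P"))
  expect_equal(n_sites(sel), 128)
  expect_equal(unique(sel$site_meta$atom), "P")
  expect_equal(sel$site_meta$resid, 1:128)
  expect_equal(sel$box, fs$box)
  # idempotent: applying the same spec to the selection is a no-op
  expect_equal(select_representatives(sel, selection_spec(POPC = "P")), sel)
})

test_that("selection edge cases: empty spec, waters, missing atom", {
  fs <- make_popc_system(4)
  empty <- select_representatives(fs, selection_spec())
  expect_equal(n_sites(empty), 0)
  # 3-site waters keep only the oxygen
  wmeta <- data.frame(resid = rep(1:3, each = 3), resname = "SOL",
                      atom = rep(c("OW", "HW1", "HW2"), 3), chain = "A")
  wat <- frame_series(0, array(seq_len(27), c(1, 9, 3)),
                      matrix(c(30, 30, 30), 1, 3), wmeta)
  wsel <- select_representatives(wat, selection_spec(SOL = "OW"))
  expect_equal(n_sites(wsel), 3)
  expect_true(all(wsel$site_meta$atom == "OW"))
  # a matched residue lacking the representative atom is an error naming it
  expect_error(select_representatives(fs, selection_spec(POPC = "OW")),
               "selection error")
  expect_error(selection_spec(POPC = "P", POPC = "N"), "at most one rule")
})

test_that("trim_frames implements the 0-based inclusive stride contract", {
  ns1 <- static_frameseries(matrix(1:3, 1, 3), nf = 12)
  tr <- trim_frames(ns1, 0, 9, 3)
  expect_equal(n_frames(tr), 4)
  expect_equal(tr$times, c(0, 3, 6, 9))
  one <- trim_frames(ns1, 5, 5, 7)
  expect_equal(n_frames(one), 1)
  expect_equal(one$times, 5)  # times preserved, not re-zeroed
  expect_error(trim_frames(ns1, 0, 12, 1), "bounds error")
  expect_error(trim_frames(ns1, -1, 3, 1), "bounds error")
})

test_that("1-based window flag matches published GROMACS frame counts", {
  long <- static_frameseries(matrix(1:3, 1, 3), nf = 2257)
  win <- trim_frames(long, 2001, 2256, 1, one_based = TRUE)
  expect_equal(n_frames(win), 256)
})

test_that("write_heat_structure rescales heat into the B-factor column", {
  fs <- static_frameseries(matrix(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
                                  3, 3, byrow = TRUE), nf = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_heat_structure(fs, 0, heat_map(c(1, 2, 4)), path)
  b <- as.numeric(substr(grep("^ATOM", readLines(path), value = TRUE), 61, 66))
  expect_equal(b, c(25, 50, 99.99), tolerance = 0.011)
  write_heat_structure(fs, 0, heat_map(c(0, 0, 0)), path)
  b0 <- as.numeric(substr(grep("^ATOM", readLines(path), value = TRUE), 61, 66))
  expect_equal(b0, c(0, 0, 0))
  expect_error(write_heat_structure(fs, 2, heat_map(c(0, 0, 0)), path),
               "bounds error")
  expect_error(write_heat_structure(fs, 0, heat_map(c(1, 2)), path),
               "dimension error")
})

test_that("heat-structure round trip preserves coordinates and site order", {
  sim <- make_pore_trajectory(small_pore_params(seed = 4))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_heat_structure(sim$traj, 3, heat_map(runif(n_sites(sim$traj))), path)
  back <- read_trajectory(path, "pdb")
  expect_equal(back$coords[1, , ], sim$traj$coords[4, , ], tolerance = 1e-3)
  expect_equal(back$site_meta$resid, sim$traj$site_meta$resid)
  expect_equal(back$box[1, ], sim$traj$box[4, ], tolerance = 1e-3)
})

test_that("multi-model PDB and GRO writers round-trip the synthetic trajectory", {
  sim <- make_pore_trajectory(small_pore_params(seed = 2))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  gro <- withr::local_tempfile(fileext = ".gro")
  write_trajectory_pdb(sim$traj, pdb)
  write_trajectory_gro(sim$traj, gro)
  b1 <- read_trajectory(pdb, "pdb", dt = 10)
  b2 <- read_trajectory(gro, "gro", dt = 10)
  expect_equal(dim(b1$coords), dim(sim$traj$coords))
  expect_equal(b1$coords, sim$traj$coords, tolerance = 1e-3)
  expect_equal(b1$box, sim$traj$box, tolerance = 1e-3)
  # per-frame CRYST1 survives: the box deforms after onset
  expect_true(sd(b1$box[, 3]) > 0)
  expect_equal(b2$coords, sim$traj$coords, tolerance = 1e-2)  # GRO: 0.001 nm
  expect_equal(b2$times, sim$traj$times)  # from the t= title stamps
})
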