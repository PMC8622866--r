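# Structure and trajectory I/O: fixed-column PDB, multi-frame GRO, and the
# box-aware xyzb dialect.

test_that("PDB ATOM parsing converts Angstrom to nm", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ASP A   1       1.000   2.000   3.000  1.00  0.00           N",
    "END"), p)
  r <- read_pdb(p)
  expect_equal(as.vector(r$frame$coords), c(0.1, 0.2, 0.3))
  expect_equal(r$topology$atoms$atom_name, "N")
  expect_equal(r$topology$atoms$resname, "ASP")
  expect_equal(r$topology$units$species, "monomer")
})

test_that("PDB round trip preserves names, residue numbers and coordinates", {
  fx <- make_coordination_fixture("dimer_bridge", 0.21)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$topology, fx$frame, p)
  r <- read_pdb(p, chain_map = c(A = "dim", B = "dim"))
  expect_equal(r$topology$atoms$atom_name, fx$topology$atoms$atom_name)
  expect_equal(r$topology$atoms$resseq, fx$topology$atoms$resseq)
  expect_equal(r$topology$atoms$resname, fx$topology$atoms$resname)
  expect_equal(r$topology$units$species, fx$topology$units$species)
  # 3-decimal Angstrom => 5e-4 nm bound
  expect_lt(max(abs(r$frame$coords - fx$frame$coords)), 5e-4)
  expect_equal(r$frame$box_edge, fx$frame$box_edge, tolerance = 1e-6)

  # write -> read -> write is byte-identical
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(r$topology, r$frame, p2)
  expect_identical(readLines(p2), readLines(p))
})

test_that("generated dimer + zinc system maps to the expected units", {
  fx <- make_coordination_fixture("dimer_bridge", 0.21)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$topology, fx$frame, p)
  r <- read_pdb(p, chain_map = c(A = "dim", B = "dim"))
  expect_equal(sort(r$topology$units$species), sort(c("dimer", "zinc_ion")))
  expect_equal(n_atoms(r$topology), n_atoms(fx$topology))
  # default chain map: one chain, one monomer unit
  r2 <- read_pdb(p)
  expect_equal(sum(r2$topology$units$species == "monomer"), 2L)
})

test_that("PDB reader reports malformed records and empty input", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ASP A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ASP A   1       x.abc   2.000   3.000  1.00  0.00           C"),
    p)
  expect_error(read_pdb(p), "line 2", class = "zincagg_parse")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(), p2)
  expect_error(read_pdb(p2), class = "zincagg_empty")
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", p3)
  expect_error(read_pdb(p3), class = "zincagg_empty")
})

test_that("multi-model PDB selects the requested model", {
  fx <- make_coordination_fixture("monomer_closed", 0.22)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$topology, fx$frame, p)
  body <- readLines(p)
  atoms <- body[grepl("^(ATOM|HETATM|TER)", body)]
  writeLines(c(body[1], "MODEL        1", atoms, "ENDMDL",
               "MODEL        2", atoms, "ENDMDL", "END"), p)
  r1 <- read_pdb(p, model = 1)
  r2 <- read_pdb(p, model = 2)
  expect_equal(r1$frame$coords, r2$frame$coords)
  expect_error(read_pdb(p, model = 3), class = "zincagg_io")
})

test_that("xyzb single frame and concatenation read in time order", {
  p <- withr::local_tempfile(fileext = ".xyzb")
  sys <- point_system(rbind(c(1, 1, 1), c(2, 2, 2)), box_edge = 15)
  writeLines(c("2 0 15.0", "1 1 1 1", "2 2 2 2"), p)
  tr <- read_trajectory(p, sys$topology, "xyzb")
  expect_equal(n_frames(tr), 1L)
  expect_equal(tr$frames[[1]]$box_edge, 15.0)
  expect_equal(tr$frames[[1]]$coords, matrix(c(1, 1, 1, 2, 2, 2), 2, 3,
                                             byrow = TRUE))
  # concatenate two one-frame files
  writeLines(c("2 0 15.0", "1 1 1 1", "2 2 2 2",
               "2 10 15.0", "1 1.5 1 1", "2 2 2.5 2"), p)
  tr2 <- read_trajectory(p, sys$topology, "xyzb")
  expect_equal(n_frames(tr2), 2L)
  expect_equal(vapply(tr2$frames, function(f) f$time, numeric(1)), c(0, 10))
})

test_that("simulator output re-read through xyzb is bit-identical", {
  p <- sim_params(n_dimer = 3, n_monomer_free = 2, n_steps = 30, stride = 10,
                  seed = 11)
  sys <- build_system(p)
  tr <- simulate_aggregation(sys$topology, sys$frame, p)
  f <- withr::local_tempfile(fileext = ".xyzb")
  write_trajectory(tr, f, "xyzb")
  tr2 <- read_trajectory(f, sys$topology, "xyzb")
  expect_equal(n_frames(tr2), n_frames(tr))
  for (i in seq_len(n_frames(tr))) {
    expect_identical(tr2$frames[[i]]$coords, tr$frames[[i]]$coords)
    expect_identical(tr2$frames[[i]]$time, tr$frames[[i]]$time)
  }
})

test_that("GRO round trip holds coordinates to format precision", {
  p <- sim_params(n_dimer = 2, n_monomer_free = 1, n_zinc_free = 1,
                  n_steps = 20, stride = 10, seed = 5)
  sys <- build_system(p)
  tr <- simulate_aggregation(sys$topology, sys$frame, p)
  f <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(tr, f, "gro")
  tr2 <- read_trajectory(f, sys$topology, "gro")
  expect_equal(n_frames(tr2), n_frames(tr))
  for (i in seq_len(n_frames(tr))) {
    expect_lt(max(abs(tr2$frames[[i]]$coords - tr$frames[[i]]$coords)), 5.1e-4)
  }
})

test_that("40-unit system survives a PDB write/read cycle within precision", {
  p <- sim_params(n_dimer = 19, n_monomer_free = 20, n_zinc_free = 1,
                  n_steps = 1, stride = 1, seed = 2)
  sys <- build_system(p)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys$topology, sys$frame, f)
  cm <- setNames(rep(paste0("u", sys$topology$atoms$unit_id), 1),
                 sys$topology$atoms$chain_id)
  cm <- cm[!duplicated(names(cm))]
  r <- read_pdb(f, chain_map = cm)
  expect_equal(n_atoms(r$topology), n_atoms(sys$topology))
  expect_lt(max(abs(r$frame$coords - sys$frame$coords)), 5e-4)
  expect_equal(sum(r$topology$units$species == "dimer"), 19L)
  expect_equal(sum(r$topology$units$species == "zinc_ion"), 1L)
})

test_that("structural errors carry the offending frame", {
  sys <- point_system(rbind(c(1, 1, 1), c(2, 2, 2)), box_edge = 15)
  p <- withr::local_tempfile(fileext = ".xyzb")
  writeLines(c("2 0 15.0", "1 1 1 1", "2 2 2 2",
               "3 10 15.0", "1 1 1 1", "2 2 2 2", "3 3 3 3"), p)
  expect_error(read_trajectory(p, sys$topology, "xyzb"), "frame 2",
               class = "zincagg_structural")
  # GRO with a missing box line
  g <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t= 0", "    2",
               "    1GLY    CA    1   1.000   1.000   1.000",
               "    1GLY    CA    2   2.000   2.000   2.000"), g)
  expect_error(read_trajectory(g, sys$topology, "gro"),
               class = "zincagg_format")
})

test_that("written PDB is readable by an independent parser", {
  fx <- make_coordination_fixture("dimer_bridge", 0.21)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$topology, fx$frame, p)
  b <- bio3d::read.pdb(p)
  expect_equal(nrow(b$atom), n_atoms(fx$topology))
  xyz <- matrix(b$xyz, ncol = 3, byrow = TRUE) / 10   # Angstrom -> nm
  expect_lt(max(abs(xyz - fx$frame$coords)), 5e-4)
  expect_equal(b$atom$resid[b$atom$type == "HETATM"], "ZN")
  expect_equal(sum(b$atom$elety == "OE1"), 2L)
})
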