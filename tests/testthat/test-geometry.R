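# Superposition RMSD, radius of gyration, and backbone dihedrals.

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) |>
    (\(q) q * det(q))()   # force a proper rotation
}

test_that("kabsch_rmsd is zero for identical and rigidly moved clouds", {
  set.seed(1)
  x <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(x, x), 0, tolerance = 1e-12)
  rot <- random_rotation()
  y <- x %*% t(rot) + matrix(rep(c(1, -2, 3), each = 10), 10, 3)
  expect_lt(kabsch_rmsd(x, y), 1e-10)
})

test_that("kabsch_rmsd matches brute-force rotation minimisation", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(stats::rnorm(30), 10, 3)
    y <- matrix(stats::rnorm(30), 10, 3)
    expect_equal(kabsch_rmsd(x, y), oracle_min_rmsd(x, y), tolerance = 1e-3)
  }
})

test_that("kabsch_rmsd never applies a reflection", {
  set.seed(3)
  x <- matrix(stats::rnorm(36), 12, 3)
  y <- x %*% diag(c(1, 1, -1))   # mirror image
  r <- kabsch_rmsd(x, y)
  expect_gt(r, 0.1)              # cannot be superposed without reflecting
  expect_equal(r, oracle_min_rmsd(x, y), tolerance = 1e-3)
})

test_that("kabsch_rmsd rejects degenerate input", {
  expect_error(kabsch_rmsd(matrix(1:6, 2, 3), matrix(1:6, 2, 3)),
               class = "zincagg_degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_rmsd(line, line), class = "zincagg_degenerate")
})

test_that("kabsch_rmsd behaves as a pseudo-metric on random triples", {
  set.seed(11)
  for (rep in 1:10) {
    x <- matrix(stats::rnorm(24), 8, 3)
    y <- matrix(stats::rnorm(24), 8, 3)
    z <- matrix(stats::rnorm(24), 8, 3)
    dxy <- kabsch_rmsd(x, y); dyx <- kabsch_rmsd(y, x)
    expect_equal(dxy, dyx, tolerance = 1e-9)
    expect_lte(kabsch_rmsd(x, z), dxy + kabsch_rmsd(y, z) + 1e-9)
  }
})

test_that("radius of gyration matches its closed form", {
  two <- rbind(c(0, 0, 0), c(0, 0, 1.6))
  expect_equal(radius_of_gyration(two), 0.8, tolerance = 1e-12)
  expect_equal(radius_of_gyration(matrix(2, 5, 3)), 0, tolerance = 1e-12)
  expect_error(radius_of_gyration(two, selection = integer()),
               class = "zincagg_empty")
  set.seed(5)
  for (rep in 1:20) {
    x <- matrix(stats::rnorm(45), 15, 3)
    m <- stats::runif(15, 0.5, 2)
    com <- colSums(x * m) / sum(m)
    direct <- sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
    expect_equal(radius_of_gyration(x, masses = m), direct,
                 tolerance = 1e-12)
  }
})

# build a backbone topology + frame from explicit N/CA/C positions
backbone_system <- function(positions) {
  nres <- nrow(positions) / 3
  atoms <- tibble::tibble(
    atom_id = seq_len(nrow(positions)),
    unit_id = 1L, chain_id = "A",
    resseq = rep(seq_len(nres), each = 3),
    resname = "ALA",
    atom_name = rep(c("N", "CA", "C"), nres),
    element = rep(c("N", "C", "C"), nres))
  topo <- topology(tibble::tibble(unit_id = 1L, species = "monomer",
                                  zinc_bound = FALSE), atoms)
  list(topology = topo, frame = frame(positions, box_edge = 50))
}

test_that("a planar trans zigzag has 180-degree dihedrals", {
  # all backbone atoms in the xy-plane, alternating +/- y: every torsion 180
  nres <- 4
  n_at <- nres * 3
  xs <- seq(0, by = 0.14, length.out = n_at)
  ys <- rep(c(0, 0.05), length.out = n_at)
  sys <- backbone_system(cbind(xs, ys, 0))
  pp <- phi_psi(sys$frame, sys$topology)
  expect_equal(nrow(pp), nres)
  expect_true(all(abs(abs(stats::na.omit(pp$phi)) - 180) < 1e-6))
  expect_true(all(abs(abs(stats::na.omit(pp$psi)) - 180) < 1e-6))
})

test_that("a 2-residue chain yields exactly one phi and one psi", {
  set.seed(9)
  sys <- backbone_system(matrix(stats::rnorm(18), 6, 3))
  pp <- phi_psi(sys$frame, sys$topology)
  expect_equal(nrow(pp), 2L)
  expect_equal(sum(!is.na(pp$phi)), 1L)
  expect_equal(sum(!is.na(pp$psi)), 1L)
  expect_true(is.na(pp$phi[1]))   # first residue: no phi
  expect_true(is.na(pp$psi[2]))   # last residue: no psi
})

test_that("random backbones match the explicit torsion oracle", {
  set.seed(13)
  for (rep in 1:10) {
    nres <- 5
    pos <- matrix(stats::rnorm(nres * 9, sd = 0.5), nres * 3, 3) +
      cbind(seq_len(nres * 3) * 0.12, 0, 0)
    sys <- backbone_system(pos)
    pp <- phi_psi(sys$frame, sys$topology)
    at <- function(rs, nm) {
      pos[which(sys$topology$atoms$resseq == rs &
                  sys$topology$atoms$atom_name == nm), ]
    }
    for (k in 2:nres) {
      expect_equal(pp$phi[pp$resseq == k],
                   oracle_torsion(at(k - 1, "C"), at(k, "N"),
                                  at(k, "CA"), at(k, "C")),
                   tolerance = 1e-9)
    }
    for (k in 1:(nres - 1)) {
      expect_equal(pp$psi[pp$resseq == k],
                   oracle_torsion(at(k, "N"), at(k, "CA"),
                                  at(k, "C"), at(k + 1, "N")),
                   tolerance = 1e-9)
    }
  }
})

test_that("residues with missing backbone atoms are skipped with a warning", {
  sys <- backbone_system(matrix(seq(0.1, by = 0.13, length.out = 27), 9, 3) +
                           matrix(stats::rnorm(27, sd = 0.02), 9, 3))
  topo <- sys$topology
  keep <- !(topo$atoms$resseq == 2 & topo$atoms$atom_name == "CA")
  atoms2 <- topo$atoms[keep, ]
  atoms2$atom_id <- seq_len(nrow(atoms2))
  topo2 <- topology(topo$units, atoms2)
  fr2 <- frame(sys$frame$coords[keep, ], box_edge = 50)
  expect_warning(pp <- phi_psi(fr2, topo2), "missing backbone")
  expect_false(2 %in% pp$resseq)
})

test_that("pairwise RMSD matrices are symmetric and elementwise exact", {
  set.seed(17)
  base <- matrix(stats::rnorm(30), 10, 3)
  ens <- c(list(base, base),
           lapply(1:4, function(i) base + matrix(stats::rnorm(30, sd = 0.3),
                                                 10, 3)))
  m <- pairwise_rmsd_matrix(ens)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(diag(m), rep(0, 6))
  expect_equal(m[1, 2], 0, tolerance = 1e-12)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], kabsch_rmsd(ens[[i]], ens[[j]]), tolerance = 1e-12)
  }
})
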