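# Zinc coordination shells, motif classification, and recapture events.

test_that("fixture shells contain exactly the manifest contacts", {
  fx <- make_coordination_fixture("dimer_bridge", 0.21)
  sh <- coordination_shell(fx$frame, fx$topology, cutoff = 0.30)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$motif, "dimer_bridge")
  got <- sh$contacts[[1]]
  expect_equal(nrow(got), 4L)
  expect_setequal(paste(got$chain_id, got$resseq, got$atom_name),
                  paste(fx$manifest$chain_id, fx$manifest$resseq,
                        fx$manifest$atom_name))
  expect_equal(got$distance, rep(0.21, 4), tolerance = 1e-10)
  expect_false(is.unsorted(got$distance))
})

test_that("an isolated zinc is unbound; missing zinc warns", {
  fx <- make_coordination_fixture("custom")
  sh <- coordination_shell(fx$frame, fx$topology, cutoff = 0.30)
  expect_equal(sh$motif, "unbound")
  expect_equal(sh$n_contacts, 0L)
  sys <- point_system(rbind(c(1, 1, 1)), box_edge = 10)
  expect_warning(out <- coordination_shell(sys$frame, sys$topology, 0.3),
                 "no zinc")
  expect_equal(nrow(out), 0L)
})

test_that("randomized shells equal a brute-force donor scan", {
  donor_pool <- tibble::tribble(
    ~resseq, ~atom_name,
    1L, "N", 1L, "OD1", 1L, "OD2",
    3L, "OE1", 3L, "OE2",
    6L, "ND1", 6L, "NE2",
    7L, "OD1", 7L, "OD2",
    11L, "OE1", 11L, "OE2",
    13L, "ND1", 13L, "NE2",
    14L, "ND1", 14L, "NE2")
  cutoff <- 0.30
  for (s in 1:100) {
    set.seed(s)
    k <- sample(0:6, 1)
    pick <- donor_pool[sample(nrow(donor_pool), k), ]
    pick$chain_id <- sample(c("A", "B"), k, replace = TRUE)
    pick <- dplyr::distinct(pick)
    dists <- stats::runif(nrow(pick), 0.15, 0.45)
    fx <- make_coordination_fixture("custom", distance = dists,
                                    donors = pick, cutoff = cutoff)
    sh <- coordination_shell(fx$frame, fx$topology, cutoff = cutoff)
    got <- sh$contacts[[1]]
    # independent scan: every His N / Asp O / Glu O / N-terminal N atom
    a <- fx$topology$atoms
    donors <- (a$resname == "HIS" & a$atom_name %in% c("ND1", "NE2")) |
      (a$resname == "ASP" & a$atom_name %in% c("OD1", "OD2")) |
      (a$resname == "GLU" & a$atom_name %in% c("OE1", "OE2")) |
      (a$resseq == 1L & a$atom_name == "N")
    zn <- which(a$atom_name == "ZN")
    expected <- integer()
    for (i in which(donors & a$unit_id != a$unit_id[zn])) {
      d <- fx$frame$coords[i, ] - fx$frame$coords[zn, ]
      d <- d - fx$frame$box_edge * round(d / fx$frame$box_edge)
      if (sqrt(sum(d^2)) <= cutoff) expected <- c(expected, i)
    }
    expect_equal(nrow(got), length(expected))
    expect_setequal(paste(got$chain_id, got$resseq, got$atom_name),
                    paste(a$chain_id[expected], a$resseq[expected],
                          a$atom_name[expected]))
  }
})

test_that("shells grow monotonically with the cutoff", {
  fx <- make_coordination_fixture(
    "custom",
    distance = c(0.18, 0.22, 0.28, 0.35),
    donors = tibble::tibble(chain_id = c("A", "A", "B", "B"),
                            resseq = c(11L, 14L, 11L, 14L),
                            atom_name = c("OE1", "NE2", "OE2", "ND1")),
    cutoff = 0.4)
  counts <- vapply(c(0.2, 0.25, 0.3, 0.4), function(co) {
    coordination_shell(fx$frame, fx$topology, cutoff = co)$n_contacts
  }, integer(1))
  expect_equal(counts, c(1L, 2L, 3L, 4L))
})

test_that("motif classification covers the observed site variants", {
  mk <- function(chain, resseq) {
    rn <- ab16_sequence()[resseq]
    tibble::tibble(chain_id = chain, resseq = resseq, resname = rn,
                   atom_name = "X", distance = 0.21)
  }
  # canonical bridge: Glu11 + His14 on both chains
  expect_equal(classify_motif(mk(c("A", "B", "A", "B"), c(11, 11, 14, 14))),
               "dimer_bridge")
  # Asp1 replacing one glutamate
  expect_equal(classify_motif(mk(c("A", "B", "A", "B"), c(1, 11, 14, 14))),
               "dimer_bridge")
  # additional His13 bond
  expect_equal(classify_motif(mk(c("A", "B", "A", "B", "A"),
                                 c(11, 11, 14, 14, 13))), "dimer_bridge")
  # closed monomeric site
  expect_equal(classify_motif(mk(rep("A", 4), c(6, 11, 13, 14))),
               "monomer_closed")
  expect_equal(classify_motif(mk(rep("A", 3), c(6, 11, 14))),
               "monomer_closed")
  # His6 contact disqualifies a bridge
  expect_equal(classify_motif(mk(c("A", "B", "A", "B", "A"),
                                 c(11, 11, 14, 14, 6))), "other")
  # single chain without His6 is not closed
  expect_equal(classify_motif(mk(rep("A", 2), c(11, 14))), "other")
  expect_equal(classify_motif(mk(character(), integer())), "unbound")
  # totality over random contact sets: always exactly one known label
  for (s in 1:50) {
    set.seed(400 + s)
    k <- sample(0:5, 1)
    contacts <- mk(sample(c("A", "B"), k, replace = TRUE),
                   sample(c(1L, 3L, 6L, 7L, 11L, 13L, 14L), k, replace = TRUE))
    lab <- classify_motif(dplyr::distinct(contacts))
    expect_true(lab %in% c("dimer_bridge", "monomer_closed", "other",
                           "unbound"))
  }
})

test_that("recapture events respect cutoff and persistence", {
  # one peptide chain with a Glu11 donor site and one zinc that hops closer
  fx <- make_coordination_fixture(
    "custom", distance = 0.2,
    donors = tibble::tibble(chain_id = "A", resseq = 11L, atom_name = "OE1"))
  topo <- fx$topology
  site <- tibble::tibble(chain_id = "A", resseq = 11L, atom_name = "OE1")
  zn_atom <- which(topo$atoms$atom_name == "ZN")
  site_atom <- which(topo$atoms$atom_name == "OE1")
  mk_traj <- function(dists) {
    frames <- lapply(seq_along(dists), function(i) {
      co <- fx$frame$coords
      co[zn_atom, ] <- co[site_atom, ] + c(dists[i], 0, 0)
      frame(co, box_edge = fx$frame$box_edge, time = i - 1)
    })
    trajectory(topo, frames)
  }
  zid <- topo$units$unit_id[topo$units$species == "zinc_ion"]
  # 50 frames far, 50 close: one event at frame 51 dwelling 50 frames
  tr <- mk_traj(c(rep(0.6, 50), rep(0.2, 50)))
  ev <- recapture_events(tr, zid, site, capture_cutoff = 0.3,
                         min_persistence = 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 51L)
  expect_equal(ev$dwell, 50L)
  # never below the cutoff: no events
  expect_equal(nrow(recapture_events(mk_traj(rep(0.5, 40)), zid, site,
                                     0.3, 5)), 0L)
  # a single-frame dip is suppressed by the persistence filter
  dip <- rep(0.6, 41); dip[20] <- 0.2
  expect_equal(nrow(recapture_events(mk_traj(dip), zid, site, 0.3, 5)), 0L)
  # events are disjoint and ordered
  two <- c(rep(0.2, 8), rep(0.6, 10), rep(0.25, 6), rep(0.6, 5))
  ev2 <- recapture_events(mk_traj(two), zid, site, 0.3, 5)
  expect_equal(ev2$onset, c(1L, 19L))
  expect_equal(ev2$dwell, c(8L, 6L))
  expect_true(all(diff(ev2$onset) > 0))
  expect_error(recapture_events(tr, 1L, site), class = "zincagg_invalid")
})
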