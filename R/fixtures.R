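# Geometric coordination fixtures: a zinc ion with chosen donor atoms placed
# at exact distances, everything else kept well outside the coordination
# cutoff. Used to exercise shell detection and motif classification with a
# known ground truth (the emitted manifest).

donor_directions <- function() {
  d <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1), c(1, 1, 1) / sqrt(3),
             c(-1, -1, 1) / sqrt(3))
  d
}

motif_donor_table <- function(motif) {
  switch(motif,
    # zinc bridging two chains via Glu11 carboxylates and His14 imidazoles
    dimer_bridge = tibble(
      chain_id = c("A", "B", "A", "B"),
      resseq = c(11L, 11L, 14L, 14L),
      atom_name = c("OE1", "OE1", "NE2", "NE2")),
    # closed monomeric site: His6, Glu11, His13, His14 of one chain
    monomer_closed = tibble(
      chain_id = c("A", "A", "A", "A"),
      resseq = c(6L, 11L, 13L, 14L),
      atom_name = c("NE2", "OE1", "NE2", "NE2"))
  )
}

#' Build a zinc coordination fixture
#'
#' Places a zinc ion at the box center with the requested donor atoms at
#' exact distances (each along a distinct direction) and every other atom
#' beyond twice the coordination cutoff, so the intended coordination shell
#' is known by construction.
#'
#' @param motif `"dimer_bridge"` (Glu11/His14 of two chains bridged by one
#'   zinc), `"monomer_closed"` (His6/Glu11/His13/His14 of a single chain), or
#'   `"custom"` with an explicit `donors` table.
#' @param distance Donor-zinc distance(s) in nm, recycled over donors.
#'   Typical Zn-N/O bonds are 0.20-0.23 nm.
#' @param donors For `motif = "custom"`: tibble with columns `chain_id`,
#'   `resseq`, `atom_name` (may have zero rows for an unbound zinc).
#' @param cutoff Coordination cutoff the fixture is built against (controls
#'   how far "all other atoms" are kept), nm.
#' @param box_edge Cubic box edge, nm.
#' @return List with `topology`, `frame`, and `manifest` (tibble of intended
#'   contacts: `chain_id`, `resseq`, `resname`, `atom_name`, `distance`).
#' @export
make_coordination_fixture <- function(motif = c("dimer_bridge",
                                                "monomer_closed", "custom"),
                                      distance = 0.21, donors = NULL,
                                      cutoff = 0.30, box_edge = 6) {
  motif <- match.arg(motif)
  if (any(distance <= 0)) stopf("zincagg_invalid", "distances must be positive")
  if (motif == "custom") {
    if (is.null(donors)) donors <- tibble(chain_id = character(),
                                          resseq = integer(),
                                          atom_name = character())
    donors <- as_tibble(donors)
  } else {
    donors <- motif_donor_table(motif)
  }
  nd <- nrow(donors)
  if (nd > nrow(donor_directions())) {
    stopf("zincagg_fixture",
          "cannot place %d donors in distinct directions (max %d)",
          nd, nrow(donor_directions()))
  }
  distance <- rep_len(distance, max(nd, 1L))
  if (nd > 0 && any(distance[seq_len(nd)] >= box_edge / 2)) {
    stopf("zincagg_fixture", "donor distance exceeds half the box")
  }

  center <- rep(box_edge / 2, 3)
  chains <- if (motif == "dimer_bridge") c("A", "B") else
    unique(c("A", donors$chain_id))
  seqs <- ab16_sequence()

  atom_rows <- list(); coords <- list()
  aid <- 0L
  # far scaffold centers, one per chain, placed around the zinc at 2 nm
  far_dirs <- donor_directions()
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    sc_center <- center + 2.0 * far_dirs[((ci - 1L) %% 8L) + 1L, ]
    offs <- chain_scaffold_offsets(0)
    dch <- donors[donors$chain_id == ch, , drop = FALSE]
    for (rs in 1:16) {
      aid <- aid + 1L
      atom_rows[[length(atom_rows) + 1L]] <- tibble(
        atom_id = aid, unit_id = 1L, chain_id = ch, resseq = rs,
        resname = seqs[rs], atom_name = "CA", element = "C")
      coords[[length(coords) + 1L]] <- sc_center + offs[rs, ]
      hit <- which(dch$resseq == rs)
      for (h in hit) {
        gidx <- which(donors$chain_id == ch)[h]
        aid <- aid + 1L
        atom_rows[[length(atom_rows) + 1L]] <- tibble(
          atom_id = aid, unit_id = 1L, chain_id = ch, resseq = rs,
          resname = seqs[rs], atom_name = dch$atom_name[h],
          element = substr(dch$atom_name[h], 1, 1))
        coords[[length(coords) + 1L]] <-
          center + distance[gidx] * donor_directions()[gidx, ]
      }
    }
  }
  # the zinc unit
  zn_unit <- 2L
  aid <- aid + 1L
  atom_rows[[length(atom_rows) + 1L]] <- tibble(
    atom_id = aid, unit_id = zn_unit, chain_id = "Z.zn1", resseq = 1L,
    resname = "ZN", atom_name = "ZN", element = "ZN")
  coords[[length(coords) + 1L]] <- center

  pep_species <- if (length(chains) == 2L) "dimer" else "monomer"
  units <- tibble(unit_id = c(1L, 2L),
                  species = c(pep_species, "zinc_ion"),
                  zinc_bound = c(TRUE, NA))
  topo <- topology(units, bind_rows(atom_rows))
  fr <- frame(do.call(rbind, coords), box_edge = box_edge)

  manifest <- if (nd > 0) {
    tibble(chain_id = donors$chain_id, resseq = donors$resseq,
           resname = seqs[donors$resseq], atom_name = donors$atom_name,
           distance = distance[seq_len(nd)]) %>%
      arrange(.data$distance, .data$chain_id, .data$resseq)
  } else {
    tibble(chain_id = character(), resseq = integer(), resname = character(),
           atom_name = character(), distance = numeric())
  }
  # verify the construction: nothing else may sit within 2x cutoff
  d_all <- min_image_dist(fr$coords, rbind(center), box_edge)
  near <- which(d_all <= 2 * cutoff & d_all > 0)
  nd_near <- if (nd > 0) sum(distance[seq_len(nd)] <= 2 * cutoff) else 0L
  if (length(near) != nd_near) {
    stopf("zincagg_fixture", "geometric placement conflict: %d atoms within 2x cutoff, expected %d",
          length(near), nd_near)
  }
  list(topology = topo, frame = fr, manifest = manifest)
}
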