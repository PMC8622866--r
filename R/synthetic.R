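# Coarse-grained synthetic aggregation: units are rigid pseudo-atom scaffolds
# whose centers undergo overdamped Brownian motion in a periodic cubic box,
# with irreversible sticky binding on contact. This generates trajectories
# with the statistical structure the analysis modules assume (species-
# dependent aggregation propensity, mass conservation, monotone cluster
# growth) without running atomistic MD.

sim_species <- c("dimer", "monomer_free", "monomer_zn", "zinc_ion")

#' Per-species binding propensities as a species-pair probability map
#'
#' Builds the symmetric species-pair binding-probability matrix the simulator
#' consumes. The pair probability is the geometric mean of the two per-species
#' propensities, so a pair binds per contact per step with
#' `sqrt(p_a * p_b)`; any species with propensity 0 (zinc ions by default)
#' never binds. The default ordering dimer > zinc-free monomer >
#' zinc-saturated monomer encodes dimer-nucleated aggregation: zinc-bridged
#' dimers are the stickiest species, monomers whose coordination sites are
#' already saturated by zinc the least sticky.
#'
#' @param dimer,monomer_free,monomer_zn,zinc_ion Per-species propensities in
#'   `[0, 1]` (probability per contact per step).
#' @return 4x4 numeric matrix with species dimnames.
#' @export
default_bind_prob <- function(dimer = 0.9, monomer_free = 0.05,
                              monomer_zn = 0.005, zinc_ion = 0) {
  p <- c(dimer = dimer, monomer_free = monomer_free,
         monomer_zn = monomer_zn, zinc_ion = zinc_ion)
  if (any(p < 0 | p > 1)) stopf("zincagg_invalid", "bind_prob must be in [0,1]")
  m <- sqrt(outer(p, p))
  dimnames(m) <- list(sim_species, sim_species)
  m
}

#' Default per-species diffusion coefficients (nm^2/ps)
#'
#' Stokes-scale values for a 16-residue peptide monomer (~2e-4), its dimer
#' (~1.5e-4) and a bare zinc ion (~7e-4) in water at 300 K.
#'
#' @return Named numeric vector over the four species classes.
#' @export
default_diffusion <- function() {
  c(dimer = 1.5e-4, monomer_free = 2e-4, monomer_zn = 2e-4, zinc_ion = 7e-4)
}

#' Simulation parameters for the coarse-grained aggregation model
#'
#' @param n_dimer,n_monomer_free,n_monomer_zn,n_zinc_free Unit counts:
#'   zinc-bridged peptide dimers (each counted as one molecule unit),
#'   zinc-free monomers, monomers with a zinc ion saturating the coordination
#'   center, and free zinc ions.
#' @param box_edge Cubic periodic box edge, nm (default 15).
#' @param min_separation Minimum initial pairwise minimum-image distance
#'   between unit centers, nm. The study systems use 2.4-4.1 nm so that the
#'   initial arrangement does not bias the resulting complexes.
#' @param contact_radius Center-to-center binding radius, nm.
#' @param bind_prob Species-pair binding probability matrix, as from
#'   [default_bind_prob()].
#' @param diffusion Named per-species diffusion coefficients, nm^2/ps.
#' @param dt Time step, ps.
#' @param n_steps Number of Brownian steps.
#' @param stride Emit a frame every `stride` steps (frame 1 is the initial
#'   state).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_dimer = 0, n_monomer_free = 0, n_monomer_zn = 0,
                       n_zinc_free = 0, box_edge = 15, min_separation = 2.4,
                       contact_radius = 1.5, bind_prob = default_bind_prob(),
                       diffusion = default_diffusion(), dt = 100,
                       n_steps = 1000, stride = 10, seed = 1) {
  counts <- c(n_dimer, n_monomer_free, n_monomer_zn, n_zinc_free)
  if (any(counts < 0)) stopf("zincagg_invalid", "unit counts must be >= 0")
  if (sum(counts) == 0) stopf("zincagg_empty", "no units requested")
  if (dt <= 0) stopf("zincagg_invalid", "dt must be positive")
  if (min_separation >= box_edge / 2) {
    stopf("zincagg_invalid", "min_separation must be < box_edge/2")
  }
  if (any(bind_prob < 0 | bind_prob > 1)) {
    stopf("zincagg_invalid", "bind_prob entries must be in [0,1]")
  }
  if (!all(sim_species %in% names(diffusion))) {
    stopf("zincagg_invalid", "diffusion must name all species classes")
  }
  structure(list(
    n_dimer = as.integer(n_dimer), n_monomer_free = as.integer(n_monomer_free),
    n_monomer_zn = as.integer(n_monomer_zn), n_zinc_free = as.integer(n_zinc_free),
    box_edge = box_edge, min_separation = min_separation,
    contact_radius = contact_radius, bind_prob = bind_prob,
    diffusion = diffusion, dt = dt, n_steps = as.integer(n_steps),
    stride = as.integer(stride), seed = as.integer(seed)
  ), class = "sim_params")
}

# deterministic compact scaffold: one pseudo-atom per residue on a spiral of
# radius <= 0.5 nm around the unit center so units have finite size for
# atom-level contact detection without atomistic detail
chain_scaffold_offsets <- function(z_shift = 0) {
  t <- seq_len(16)
  th <- t * 2.399963  # golden angle, spreads atoms over the shell
  r <- 0.45
  cbind(r * cos(th), r * sin(th),
        z_shift + seq(-0.25, 0.25, length.out = 16))
}

unit_scaffold <- function(species) {
  switch(species,
    monomer = list(chain_scaffold_offsets(0)),
    dimer = list(chain_scaffold_offsets(-0.22), chain_scaffold_offsets(0.22)),
    zinc_ion = list(matrix(0, 1, 3))
  )
}

#' Build a synthetic starting system
#'
#' Places unit centers uniformly in the periodic box by rejection sampling
#' subject to a pairwise minimum-image separation, then materializes a
#' per-residue pseudo-atom scaffold (Asp1...Lys16 per chain) around each
#' center. Deterministic for a fixed seed.
#'
#' @param params A [sim_params()] object.
#' @param max_attempts Rejection-sampling cap per unit before a placement
#'   error is raised.
#' @return List with elements `topology` and `frame`.
#' @export
build_system <- function(params, max_attempts = 1e5) {
  stopifnot(inherits(params, "sim_params"))
  species <- rep(c("dimer", "monomer", "monomer", "zinc_ion"),
                 c(params$n_dimer, params$n_monomer_free,
                   params$n_monomer_zn, params$n_zinc_free))
  zn_bound <- rep(c(TRUE, FALSE, TRUE, NA),
                  c(params$n_dimer, params$n_monomer_free,
                    params$n_monomer_zn, params$n_zinc_free))
  nu <- length(species)
  centers <- with_seed(params$seed, {
    cn <- matrix(NA_real_, nu, 3)
    for (i in seq_len(nu)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        cand <- stats::runif(3, 0, params$box_edge)
        if (i == 1L ||
            all(min_image_dist(rbind(cand), cn[seq_len(i - 1L), , drop = FALSE],
                               params$box_edge) >= params$min_separation)) {
          cn[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stopf("zincagg_placement",
              "could not place unit %d of %d at separation %.2f nm in a %.1f nm box after %d attempts",
              i, nu, params$min_separation, params$box_edge, max_attempts)
      }
    }
    cn
  })

  units <- tibble(unit_id = seq_len(nu), species = species,
                  zinc_bound = zn_bound)
  atom_rows <- list(); coord_rows <- list()
  # unique single-character chain ids (PDB's chain field is one column);
  # systems beyond 62 peptide chains cannot round-trip through PDB
  chain_pool <- c(LETTERS, letters, as.character(0:9))
  chain_counter <- 0L
  aid <- 0L
  for (i in seq_len(nu)) {
    offs <- unit_scaffold(species[i])
    for (ci in seq_along(offs)) {
      chain_counter <- chain_counter + 1L
      cid <- chain_pool[(chain_counter - 1L) %% length(chain_pool) + 1L]
      if (species[i] == "zinc_ion") {
        aid <- aid + 1L
        atom_rows[[length(atom_rows) + 1L]] <- tibble(
          atom_id = aid, unit_id = i, chain_id = sprintf("Z%d", i),
          resseq = 1L, resname = "ZN", atom_name = "ZN", element = "ZN")
      } else {
        rows <- peptide_chain_rows(cid, i)
        rows$atom_id <- aid + seq_len(nrow(rows))
        aid <- aid + nrow(rows)
        atom_rows[[length(atom_rows) + 1L]] <- rows[, c(
          "atom_id", "unit_id", "chain_id", "resseq", "resname",
          "atom_name", "element")]
      }
      coord_rows[[length(coord_rows) + 1L]] <-
        sweep(offs[[ci]], 2, centers[i, ], "+")
    }
  }
  topo <- topology(units, bind_rows(atom_rows))
  list(topology = topo,
       frame = frame(do.call(rbind, coord_rows), box_edge = params$box_edge))
}

#' Simulate coarse-grained Brownian aggregation
#'
#' Overdamped Brownian dynamics on unit centers: each bound cluster takes an
#' isotropic Gaussian step of per-axis variance `2 * D * dt`, where the
#' cluster diffusion coefficient is the mean member coefficient scaled by
#' `size^(-1/3)` (Stokes-like). When two units in different clusters come
#' within `contact_radius` (minimum image, center to center) they bind
#' irreversibly with the species-pair probability; clusters then move
#' rigidly. Unit internal geometry is frozen, so atom positions follow the
#' cluster translation. Fully reproducible from `params$seed`.
#'
#' @param topology,start Topology and starting frame, as from
#'   [build_system()].
#' @param params A [sim_params()] object.
#' @return A `zincagg_trajectory` whose first frame is the starting state.
#'   The attribute `"bonds"` is a tibble of irreversible binding events
#'   (`step`, `unit_i`, `unit_j`), and `"cluster_sizes"` a list of per-frame
#'   bound-cluster size multisets.
#' @export
simulate_aggregation <- function(topology, start, params) {
  stopifnot(inherits(params, "sim_params"))
  nu <- n_units(topology)
  box <- params$box_edge
  cls <- species_class(topology$units)
  dbase <- params$diffusion[cls]
  pmat <- params$bind_prob

  centers <- unit_centers(start, topology)
  offsets <- start$coords - centers[topology$atoms$unit_id, , drop = FALSE]
  uidx <- topology$atoms$unit_id

  parent <- seq_len(nu)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  emit <- function(step) {
    frame(centers[uidx, , drop = FALSE] + offsets, box_edge = box,
          time = step * params$dt)
  }

  bonds <- list()
  frames <- list(emit(0L))
  cluster_log <- list(tabulate_sizes(parent, nu))

  with_seed(params$seed + 1L, {
    for (step in seq_len(params$n_steps)) {
      roots <- vapply(seq_len(nu), find_root, integer(1))
      sizes <- table(roots)
      uroots <- as.integer(names(sizes))
      dmean <- vapply(uroots, function(r) mean(dbase[roots == r]), numeric(1))
      dcl <- dmean * as.vector(sizes)^(-1 / 3)
      disp <- matrix(rnorm(length(uroots) * 3L,
                           sd = sqrt(2 * dcl * params$dt)), ncol = 3L)
      centers <- centers + disp[match(roots, uroots), , drop = FALSE]
      centers <- wrap_box(centers, box)

      # candidate binding pairs across clusters
      dmat <- min_image_dist(centers, centers, box)
      within <- which(dmat <= params$contact_radius & upper.tri(dmat),
                      arr.ind = TRUE)
      if (nrow(within)) {
        # deterministic order: by row then column
        ord <- order(within[, 1], within[, 2])
        for (k in ord) {
          i <- within[k, 1]; j <- within[k, 2]
          ri <- find_root(i); rj <- find_root(j)
          if (ri != rj) {
            p <- pmat[cls[i], cls[j]]
            if (p > 0 && stats::runif(1) < p) {
              parent[max(ri, rj)] <- min(ri, rj)
              bonds[[length(bonds) + 1L]] <- c(step, i, j)
            }
          }
        }
      }
      if (step %% params$stride == 0L || step == params$n_steps) {
        frames[[length(frames) + 1L]] <- emit(step)
        roots2 <- vapply(seq_len(nu), find_root, integer(1))
        cluster_log[[length(cluster_log) + 1L]] <- tabulate_sizes(roots2, nu)
      }
    }
  })

  traj <- trajectory(topology, frames)
  bond_tbl <- if (length(bonds)) {
    b <- do.call(rbind, bonds)
    tibble(step = b[, 1], unit_i = b[, 2], unit_j = b[, 3])
  } else {
    tibble(step = integer(), unit_i = integer(), unit_j = integer())
  }
  attr(traj, "bonds") <- bond_tbl
  attr(traj, "cluster_sizes") <- cluster_log
  traj
}

tabulate_sizes <- function(roots, nu) {
  sort(as.integer(table(vapply(seq_len(nu), function(i) {
    while (roots[i] != i) i <- roots[i]
    i
  }, integer(1)))), decreasing = TRUE)
}

#' Random composition of an integer into parts
#'
#' Draws a uniform random composition of `total` into `n_parts` positive
#' integer parts (stars and bars), returned as a complex-size multiset for
#' exercising the aggregation statistics.
#'
#' @param total Total number of molecule units.
#' @param n_parts Number of complexes.
#' @param seed Integer seed.
#' @return A [composition()] of `n_parts` sizes summing to `total`.
#' @export
make_partition <- function(total, n_parts, seed = 1) {
  if (n_parts < 1 || n_parts > total) {
    stopf("zincagg_invalid", "need 1 <= n_parts (%d) <= total (%d)",
          n_parts, total)
  }
  sizes <- with_seed(seed, {
    if (n_parts == 1L) total
    else diff(c(0L, sort(sample.int(total - 1L, n_parts - 1L)), total))
  })
  composition(sizes)
}
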