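# Molecular system description: units (the molecules aggregation statistics
# count), chains, residues and named atoms. A zinc-bridged peptide dimer is a
# single unit with two chains; a free zinc ion is a single-atom unit.

#' One-letter per-residue sequence of the amyloid-beta 1-16 domain
#'
#' Three-letter residue names for Asp1...Lys16 (DAEFRHDSGYEVHHQK), the
#' N-terminal zinc-binding domain of the amyloid-beta peptide.
#'
#' @return Character vector of 16 residue names.
#' @export
ab16_sequence <- function() {
  c("ASP", "ALA", "GLU", "PHE", "ARG", "HIS", "ASP", "SER",
    "GLY", "TYR", "GLU", "VAL", "HIS", "HIS", "GLN", "LYS")
}

unit_species_levels <- c("monomer", "dimer", "zinc_ion")

#' Construct a molecular topology
#'
#' @param units Tibble with columns `unit_id` (integer, contiguous from 1),
#'   `species` (one of `"monomer"`, `"dimer"`, `"zinc_ion"`) and `zinc_bound`
#'   (logical; whether a peptide unit carries a zinc ion in its coordination
#'   center — drives the species-dependent aggregation propensity).
#' @param atoms Tibble with columns `atom_id`, `unit_id`, `chain_id`,
#'   `resseq` (1-based), `resname`, `atom_name`, `element`. Zinc-ion units own
#'   exactly one ZN atom; dimer units own exactly two chains.
#' @return A `zincagg_topology` object.
#' @export
topology <- function(units, atoms) {
  units <- as_tibble(units)
  atoms <- as_tibble(atoms)
  if (!"zinc_bound" %in% names(units)) {
    units$zinc_bound <- units$species == "dimer"
  }
  units <- units[, c("unit_id", "species", "zinc_bound")]
  atoms <- atoms[, c("atom_id", "unit_id", "chain_id", "resseq",
                     "resname", "atom_name", "element")]
  x <- structure(list(units = units, atoms = atoms),
                 class = "zincagg_topology")
  validate_topology(x)
}

validate_topology <- function(x) {
  u <- x$units; a <- x$atoms
  if (nrow(u) == 0L) stopf("zincagg_empty", "topology has no units")
  if (!identical(sort(u$unit_id), seq_len(nrow(u)))) {
    stopf("zincagg_invalid", "unit_ids must be unique and contiguous from 1")
  }
  if (!all(u$species %in% unit_species_levels)) {
    stopf("zincagg_invalid", "unknown species: %s",
          paste(setdiff(u$species, unit_species_levels), collapse = ", "))
  }
  if (nrow(a) == 0L) stopf("zincagg_empty", "topology has no atoms")
  if (anyDuplicated(a$atom_id) || !identical(sort(a$atom_id), seq_len(nrow(a)))) {
    stopf("zincagg_invalid", "atom_ids must be unique and contiguous from 1")
  }
  if (!all(a$unit_id %in% u$unit_id)) {
    stopf("zincagg_invalid", "atom references unknown unit_id")
  }
  # a chain belongs to exactly one unit
  cu <- distinct(a, .data$chain_id, .data$unit_id)
  if (anyDuplicated(cu$chain_id)) {
    stopf("zincagg_invalid", "chain %s maps to more than one unit",
          cu$chain_id[duplicated(cu$chain_id)][1])
  }
  # dimers own exactly two peptide chains, monomers one
  n_chains <- table(cu$unit_id[cu$unit_id %in% u$unit_id])
  for (i in seq_len(nrow(u))) {
    nc <- sum(cu$unit_id == u$unit_id[i])
    want <- switch(u$species[i], monomer = 1L, dimer = 2L, zinc_ion = 1L)
    if (nc != want) {
      stopf("zincagg_invalid", "unit %d (%s) owns %d chains, expected %d",
            u$unit_id[i], u$species[i], nc, want)
    }
  }
  # resseq strictly increasing within a peptide chain
  pep <- a[a$unit_id %in% u$unit_id[u$species != "zinc_ion"], ]
  if (nrow(pep)) {
    bad <- pep %>%
      group_by(.data$chain_id) %>%
      summarise(ok = all(diff(unique(.data$resseq)) > 0) &&
                  !is.unsorted(.data$resseq), .groups = "drop") %>%
      filter(!.data$ok)
    if (nrow(bad)) {
      stopf("zincagg_invalid", "resseq not increasing in chain %s",
            bad$chain_id[1])
    }
  }
  x
}

#' @export
print.zincagg_topology <- function(x, ...) {
  sp <- table(factor(x$units$species, unit_species_levels))
  cat(sprintf("<zincagg_topology> %d units (%s), %d atoms\n",
              nrow(x$units),
              paste(sprintf("%d %s", sp, names(sp))[sp > 0], collapse = ", "),
              nrow(x$atoms)))
  invisible(x)
}

#' @export
as_tibble.zincagg_topology <- function(x, ...) {
  left_join(x$atoms, x$units, by = "unit_id")
}

#' Number of atoms / units in a topology
#' @param topology A `zincagg_topology`.
#' @return Integer count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' @rdname n_atoms
#' @export
n_units <- function(topology) nrow(topology$units)

# propensity class used by the simulator's binding-probability map
species_class <- function(units) {
  ifelse(units$species == "dimer", "dimer",
  ifelse(units$species == "zinc_ion", "zinc_ion",
  ifelse(units$zinc_bound, "monomer_zn", "monomer_free")))
}

# rows of `atoms` for peptide chains of a unit, one pseudo-atom per residue
peptide_chain_rows <- function(chain_id, unit_id, atom_name = "CA",
                               element = "C") {
  tibble(
    unit_id = unit_id, chain_id = chain_id,
    resseq = 1:16, resname = ab16_sequence(),
    atom_name = atom_name, element = element
  )
}
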