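# Fixed-column PDB reading and writing. Internal coordinates are nm; PDB
# files are Angstrom, converted on the way in and out. The box edge travels
# in a CRYST1 record.

NM_PER_ANGSTROM <- 0.1

parse_pdb_atom <- function(line, lineno) {
  if (nchar(line) < 54) {
    stopf("zincagg_parse", "malformed ATOM/HETATM record at line %d: too short",
          lineno)
  }
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz)) {
    stopf("zincagg_parse",
          "malformed ATOM/HETATM record at line %d: non-numeric coordinates",
          lineno)
  }
  resseq <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (is.na(resseq)) {
    stopf("zincagg_parse",
          "malformed ATOM/HETATM record at line %d: bad residue number", lineno)
  }
  list(
    record = trimws(substr(line, 1, 6)),
    atom_name = trimws(substr(line, 13, 16)),
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    resseq = resseq,
    xyz = xyz,
    element = trimws(substr(line, 77, 78))
  )
}

#' Read a PDB structure
#'
#' Parses fixed-column ATOM/HETATM records of one MODEL of a PDB file into a
#' topology and a coordinate frame. Coordinates are converted from Angstrom
#' to nm. HETATM zinc records (`ZN`) become single-atom `zinc_ion` units.
#' Peptide chains are grouped into units via `chain_map`; by default every
#' chain is its own monomer unit. A zinc-bridged dimer is expressed by
#' mapping its two chains to a common label.
#'
#' @param path Path to a PDB file.
#' @param model 1-based MODEL index to read (NMR ensembles are multi-model).
#' @param chain_map Optional named character vector mapping chain id to a
#'   unit label; chains sharing a label form one unit (two chains = dimer).
#' @param zinc_bound Logical, whether peptide monomer units read from the
#'   file should be flagged as carrying a coordinated zinc (not inferable
#'   from the file itself). Default `FALSE`; dimers are always flagged.
#' @return List with elements `topology` and `frame`.
#' @export
read_pdb <- function(path, model = 1, chain_map = NULL, zinc_bound = FALSE) {
  if (!file.exists(path)) stopf("zincagg_io", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("zincagg_empty", "empty PDB file: %s", path)

  # slice out the requested MODEL block (whole file if no MODEL records)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    if (model > length(model_starts)) {
      stopf("zincagg_io", "requested model %d, file has %d", model,
            length(model_starts))
    }
    ends <- grep("^ENDMDL", lines)
    end <- ends[ends > model_starts[model]][1]
    if (is.na(end)) end <- length(lines)
    idx <- seq(model_starts[model], end)
  } else {
    idx <- seq_along(lines)
  }

  box_edge <- NA_real_
  cr <- grep("^CRYST1", lines)
  if (length(cr)) {
    box_edge <- suppressWarnings(as.numeric(substr(lines[cr[1]], 7, 15))) *
      NM_PER_ANGSTROM
  }

  recs <- list()
  for (i in idx) {
    if (grepl("^(ATOM  |HETATM)", lines[i])) {
      recs[[length(recs) + 1L]] <- parse_pdb_atom(lines[i], i)
    }
  }
  if (!length(recs)) stopf("zincagg_empty", "no ATOM/HETATM records in %s", path)

  is_zn <- vapply(recs, function(r) {
    r$record == "HETATM" && (toupper(r$resname) == "ZN" ||
                             toupper(r$atom_name) == "ZN")
  }, logical(1))

  pep <- recs[!is_zn]
  zns <- recs[is_zn]

  pep_chains <- unique(vapply(pep, function(r) r$chain, character(1)))
  if (is.null(chain_map)) {
    chain_map <- setNames(pep_chains, pep_chains)
  }
  missing_chain <- setdiff(pep_chains, names(chain_map))
  if (length(missing_chain)) {
    stopf("zincagg_invalid", "chain_map missing chains: %s",
          paste(missing_chain, collapse = ", "))
  }
  unit_labels <- unique(unname(chain_map[pep_chains]))

  units <- list(); atoms <- list(); coords <- list()
  aid <- 0L
  for (ul in seq_along(unit_labels)) {
    lab <- unit_labels[ul]
    chains <- pep_chains[chain_map[pep_chains] == lab]
    species <- if (length(chains) == 2L) "dimer" else "monomer"
    if (length(chains) > 2L) {
      stopf("zincagg_invalid", "unit label %s maps %d chains; at most 2", lab,
            length(chains))
    }
    units[[ul]] <- tibble(unit_id = ul, species = species,
                          zinc_bound = species == "dimer" || isTRUE(zinc_bound))
    for (r in pep) {
      if (r$chain %in% chains) {
        aid <- aid + 1L
        atoms[[aid]] <- tibble(
          atom_id = aid, unit_id = ul, chain_id = r$chain,
          resseq = r$resseq, resname = r$resname, atom_name = r$atom_name,
          element = if (nzchar(r$element)) r$element else substr(r$atom_name, 1, 1)
        )
        coords[[aid]] <- r$xyz
      }
    }
  }
  nu <- length(unit_labels)
  for (k in seq_along(zns)) {
    r <- zns[[k]]
    nu <- nu + 1L
    aid <- aid + 1L
    ch <- if (nzchar(trimws(r$chain))) r$chain else "Z"
    units[[nu]] <- tibble(unit_id = nu, species = "zinc_ion", zinc_bound = NA)
    atoms[[aid]] <- tibble(atom_id = aid, unit_id = nu,
                           chain_id = sprintf("%s.zn%d", ch, k),
                           resseq = r$resseq, resname = "ZN",
                           atom_name = "ZN", element = "ZN")
    coords[[aid]] <- r$xyz
  }

  xyz <- do.call(rbind, coords) * NM_PER_ANGSTROM
  if (is.na(box_edge)) {
    # no CRYST1: enclose the structure with a 2 nm margin (deterministic)
    box_edge <- max(apply(xyz, 2, function(v) diff(range(v)))) + 2
  }
  topo <- topology(bind_rows(units), bind_rows(atoms))
  list(topology = topo, frame = frame(xyz, box_edge = box_edge))
}

format_pdb_name <- function(name) {
  if (nchar(name) <= 3) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write a PDB structure
#'
#' Emits fixed-column ATOM records for peptide atoms (TER after each chain)
#' and HETATM records for zinc-ion units, with a CRYST1 record carrying the
#' cubic box. Coordinates are converted nm to Angstrom at 3 decimals; output
#' is deterministic, so writing the same system twice gives identical bytes.
#'
#' @param topology A `zincagg_topology`.
#' @param frame A `zincagg_frame` with matching atom count.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, frame, path) {
  if (nrow(frame$coords) != n_atoms(topology)) {
    stopf("zincagg_structural", "frame/topology atom count mismatch")
  }
  pep_units <- topology$units$unit_id[topology$units$species != "zinc_ion"]
  for (u in pep_units) {
    if (!any(topology$atoms$unit_id == u)) {
      stopf("zincagg_invalid", "peptide unit %d has no chains/atoms", u)
    }
  }
  a <- topology$atoms %>% left_join(topology$units, by = "unit_id") %>%
    arrange(.data$atom_id)
  xyz <- frame$coords / NM_PER_ANGSTROM
  be <- frame$box_edge / NM_PER_ANGSTROM
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 be, be, be, 90, 90, 90)
  serial <- 0L
  prev_chain <- NULL
  for (i in seq_len(nrow(a))) {
    rec <- if (a$species[i] == "zinc_ion") "HETATM" else "ATOM  "
    if (!is.null(prev_chain) && a$chain_id[i] != prev_chain &&
        a$species[i] != "zinc_ion") {
      out <- c(out, "TER")
    }
    prev_chain <- a$chain_id[i]
    serial <- serial + 1L
    out <- c(out, sprintf(
      "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, serial, format_pdb_name(a$atom_name[i]), a$resname[i],
      substr(a$chain_id[i], 1, 1), a$resseq[i],
      xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
      toupper(substr(a$element[i], 1, 2))))
  }
  out <- c(out, "TER", "END")
  writeLines(out, path)
  invisible(path)
}
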