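# Trajectory formats: multi-frame GRO (fixed columns, nm) and the internal
# "xyzb" dialect. xyzb exists because plain XYZ has no box information, which
# periodic-boundary analysis needs; its layout is, per frame:
#
#   natoms time box_edge        (one header line, whitespace separated)
#   atom_id x y z               (natoms lines, coordinates in nm, full
#                                double precision so round-trips are exact)

#' Read a trajectory
#'
#' @param path Path to a multi-frame GRO or xyzb file.
#' @param topology The `zincagg_topology` the frames belong to; every frame's
#'   atom count must match.
#' @param format `"gro"` or `"xyzb"`.
#' @return A `zincagg_trajectory`.
#' @export
read_trajectory <- function(path, topology, format = c("gro", "xyzb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("zincagg_io", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stopf("zincagg_empty", "empty trajectory file: %s", path)
  frames <- switch(format,
    gro = parse_gro_frames(lines, path),
    xyzb = parse_xyzb_frames(lines, path)
  )
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != na) {
      stopf("zincagg_structural",
            "frame %d of %s has %d atoms, topology has %d",
            i, path, nrow(frames[[i]]$coords), na)
    }
  }
  trajectory(topology, frames)
}

parse_gro_frames <- function(lines, path) {
  frames <- list(); i <- 1L; fi <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    fi <- fi + 1L
    title <- lines[i]
    if (i + 1L > length(lines)) {
      stopf("zincagg_format", "truncated GRO frame %d in %s", fi, path)
    }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L) {
      stopf("zincagg_format", "bad atom count in GRO frame %d of %s", fi, path)
    }
    if (i + 1L + natoms + 1L > length(lines)) {
      stopf("zincagg_format", "missing box line in GRO frame %d of %s", fi, path)
    }
    block <- lines[(i + 2L):(i + 1L + natoms)]
    xyz <- matrix(NA_real_, natoms, 3L)
    for (k in seq_len(natoms)) {
      ln <- block[k]
      v <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
      if (anyNA(v)) {
        stopf("zincagg_format", "bad coordinate line %d in GRO frame %d of %s",
              k, fi, path)
      }
      xyz[k, ] <- v
    }
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(
      lines[i + 2L + natoms]), "\\s+")[[1]]))
    if (length(boxv) < 3L || anyNA(boxv[1:3])) {
      stopf("zincagg_format", "missing box line in GRO frame %d of %s", fi, path)
    }
    if (max(abs(boxv[1:3] - boxv[1])) > 1e-9) {
      stopf("zincagg_invalid", "non-cubic box in GRO frame %d of %s", fi, path)
    }
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    time <- if (length(tm) == 2L) as.numeric(tm[2]) else as.numeric(fi - 1L)
    frames[[fi]] <- frame(xyz, box_edge = boxv[1], time = time)
    i <- i + 2L + natoms + 1L
  }
  if (!length(frames)) stopf("zincagg_empty", "no frames in %s", path)
  frames
}

parse_xyzb_frames <- function(lines, path) {
  frames <- list(); i <- 1L; fi <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fi <- fi + 1L
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(hdr) != 3L || anyNA(hdr)) {
      stopf("zincagg_format",
            "xyzb frame %d of %s: header must be 'natoms time box_edge'",
            fi, path)
    }
    natoms <- as.integer(hdr[1])
    if (i + natoms > length(lines)) {
      stopf("zincagg_format", "truncated xyzb frame %d in %s", fi, path)
    }
    xyz <- matrix(NA_real_, natoms, 3L)
    for (k in seq_len(natoms)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + k]),
                                                "\\s+")[[1]]))
      if (length(v) != 4L || anyNA(v)) {
        stopf("zincagg_format", "bad atom line %d in xyzb frame %d of %s",
              k, fi, path)
      }
      xyz[v[1], ] <- v[2:4]
    }
    if (anyNA(xyz)) {
      stopf("zincagg_format", "atom ids of xyzb frame %d of %s do not cover 1..%d",
            fi, path, natoms)
    }
    frames[[fi]] <- frame(xyz, box_edge = hdr[3], time = hdr[2])
    i <- i + 1L + natoms
  }
  if (!length(frames)) stopf("zincagg_empty", "no frames in %s", path)
  frames
}

#' Write a trajectory
#'
#' @param trajectory A `zincagg_trajectory`.
#' @param path Output file path.
#' @param format `"gro"` (fixed-column, 3 decimals nm) or `"xyzb"` (full
#'   double precision; `read_trajectory()` recovers coordinates exactly).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = c("gro", "xyzb")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- trajectory$topology
  for (f in trajectory$frames) {
    if (format == "gro") {
      writeLines(gro_frame_lines(f, topo), con)
    } else {
      n <- nrow(f$coords)
      writeLines(sprintf("%d %.17g %.17g", n, f$time, f$box_edge), con)
      writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n),
                         f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
    }
  }
  invisible(path)
}

gro_frame_lines <- function(f, topo) {
  a <- topo$atoms
  # global residue counter across chains, GRO-style
  key <- paste(a$chain_id, a$resseq)
  resid <- cumsum(!duplicated(key))[match(key, key)]
  c(
    sprintf("zincagg t= %.5f", f$time),
    sprintf("%5d", nrow(f$coords)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid %% 100000L, substr(a$resname, 1, 5),
            substr(a$atom_name, 1, 5), a$atom_id %% 100000L,
            f$coords[, 1], f$coords[, 2], f$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", f$box_edge, f$box_edge, f$box_edge)
  )
}
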