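# Frames and trajectories. Coordinates are stored unwrapped, in nm, as
# n_atoms x 3 matrices; wrapping is applied at analysis time via the
# minimum-image convention (cubic boxes only).

#' Construct a coordinate frame
#'
#' @param coords Numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box_edge Cubic periodic box edge in nm.
#' @param time Time stamp in ps.
#' @return A `zincagg_frame` object.
#' @export
frame <- function(coords, box_edge, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stopf("zincagg_invalid", "coords must have 3 columns")
  if (!all(is.finite(coords))) stopf("zincagg_invalid", "non-finite coordinates")
  if (!is.finite(box_edge) || box_edge <= 0) {
    stopf("zincagg_invalid", "box_edge must be positive")
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, box_edge = as.numeric(box_edge),
                 time = as.numeric(time)),
            class = "zincagg_frame")
}

#' @export
print.zincagg_frame <- function(x, ...) {
  cat(sprintf("<zincagg_frame> %d atoms, box %.3f nm, t = %g ps\n",
              nrow(x$coords), x$box_edge, x$time))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology A `zincagg_topology` shared by all frames.
#' @param frames List of `zincagg_frame` objects ordered by non-decreasing
#'   time, each with as many coordinate rows as the topology has atoms.
#' @return A `zincagg_trajectory` object.
#' @export
trajectory <- function(topology, frames) {
  if (length(frames) < 1L) stopf("zincagg_empty", "trajectory needs >= 1 frame")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != na) {
      stopf("zincagg_structural",
            "frame %d has %d atoms, topology has %d",
            i, nrow(frames[[i]]$coords), na)
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (is.unsorted(times)) {
    stopf("zincagg_invalid", "frame times must be non-decreasing")
  }
  structure(list(topology = topology, frames = frames),
            class = "zincagg_trajectory")
}

#' @export
print.zincagg_trajectory <- function(x, ...) {
  times <- vapply(x$frames, function(f) f$time, numeric(1))
  cat(sprintf("<zincagg_trajectory> %d frames (t = %g..%g ps), %d units\n",
              length(x$frames), min(times), max(times), n_units(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `zincagg_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' @export
as_tibble.zincagg_trajectory <- function(x, ...) {
  tibble(
    frame = seq_along(x$frames),
    time = vapply(x$frames, function(f) f$time, numeric(1)),
    box_edge = vapply(x$frames, function(f) f$box_edge, numeric(1))
  )
}

# per-unit geometric centers of a frame (n_units x 3)
unit_centers <- function(frame, topology) {
  g <- topology$atoms$unit_id
  cx <- rowsum(frame$coords, g)
  cx / as.vector(table(g)[rownames(cx)])
}

# atom row indices per unit, as a list
unit_atom_index <- function(topology) {
  split(seq_len(nrow(topology$atoms)), topology$atoms$unit_id)
}
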