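# Complex detection: molecules (units) are nodes of a contact graph with an
# edge whenever any atom pair of two units lies within the cutoff under the
# minimum-image convention; complexes are the connected components. Zinc
# ions are never counted as molecules. A unit-center prefilter (triangle
# inequality on center distance minus unit radii) accelerates the all-pairs
# atom scan without changing its result.

#' Contact graph of a frame
#'
#' @param frame A `zincagg_frame`.
#' @param topology The matching `zincagg_topology`.
#' @param cutoff Atom-atom contact cutoff in nm (default 0.45, a typical
#'   heavy-atom contact distance; the detection distance is a reportable
#'   analysis choice, echoed in pipeline logs). Must be below half the box
#'   edge or the minimum image is ambiguous.
#' @param frame_index Optional frame label carried through to compositions.
#' @return A `zincagg_contact_graph`: non-zinc unit nodes, contact edges with
#'   minimum atom-pair distances, plus the frame/topology references the
#'   proximity merge needs.
#' @export
contact_graph <- function(frame, topology, cutoff = 0.45, frame_index = 1L) {
  if (cutoff <= 0) stopf("zincagg_invalid", "cutoff must be positive")
  if (cutoff >= frame$box_edge / 2) {
    stopf("zincagg_ambiguous",
          "cutoff %.3f >= box_edge/2 = %.3f: minimum image ambiguous",
          cutoff, frame$box_edge / 2)
  }
  if (nrow(frame$coords) != n_atoms(topology)) {
    stopf("zincagg_structural", "frame/topology atom count mismatch")
  }
  nodes <- topology$units$unit_id[topology$units$species != "zinc_ion"]
  box <- frame$box_edge
  aidx <- unit_atom_index(topology)
  centers <- unit_centers(frame, topology)
  radii <- vapply(seq_len(n_units(topology)), function(u) {
    d <- frame$coords[aidx[[as.character(u)]], , drop = FALSE]
    if (nrow(d) == 1L) return(0)
    c0 <- colMeans(d)
    sqrt(max(rowSums(sweep(d, 2, c0)^2)))
  }, numeric(1))

  edges <- list()
  if (length(nodes) >= 2L) {
    cd <- min_image_dist(centers[nodes, , drop = FALSE],
                         centers[nodes, , drop = FALSE], box)
    cand <- which(upper.tri(cd) &
                    cd <= cutoff + outer(radii[nodes], radii[nodes], "+"),
                  arr.ind = TRUE)
    for (k in seq_len(nrow(cand))) {
      u <- nodes[cand[k, 1]]; v <- nodes[cand[k, 2]]
      duv <- min(min_image_dist(
        frame$coords[aidx[[as.character(u)]], , drop = FALSE],
        frame$coords[aidx[[as.character(v)]], , drop = FALSE], box))
      if (duv <= cutoff) {
        edges[[length(edges) + 1L]] <- c(min(u, v), max(u, v), duv)
      }
    }
  }
  edge_tbl <- if (length(edges)) {
    e <- do.call(rbind, edges)
    tibble(i = as.integer(e[, 1]), j = as.integer(e[, 2]), dist = e[, 3]) %>%
      arrange(.data$i, .data$j)
  } else {
    tibble(i = integer(), j = integer(), dist = numeric())
  }
  structure(list(nodes = nodes, edges = edge_tbl, cutoff = cutoff,
                 frame = frame, topology = topology,
                 frame_index = as.integer(frame_index)),
            class = "zincagg_contact_graph")
}

#' @export
print.zincagg_contact_graph <- function(x, ...) {
  cat(sprintf("<zincagg_contact_graph> %d nodes, %d edges (cutoff %.3f nm)\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Complex composition: multiset of complex sizes
#'
#' @param sizes Positive integer complex sizes (in molecule units).
#' @param frame_index Optional frame label.
#' @param membership Optional named integer vector mapping unit_id to
#'   complex index.
#' @return A `zincagg_composition`: sizes sorted decreasingly, with the
#'   frame label and membership as attributes.
#' @export
composition <- function(sizes, frame_index = NA_integer_, membership = NULL) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) stopf("zincagg_empty", "empty composition")
  if (any(sizes < 1L)) stopf("zincagg_invalid", "complex sizes must be >= 1")
  structure(sort(sizes, decreasing = TRUE),
            frame_index = as.integer(frame_index),
            membership = membership,
            class = "zincagg_composition")
}

#' @export
print.zincagg_composition <- function(x, ...) {
  cat(sprintf("<zincagg_composition> {%s} (%d units, Lc = %.2f)\n",
              paste(unclass(x), collapse = ","), sum(x),
              connectivity_length(x)))
  invisible(x)
}

#' @export
tidy.zincagg_composition <- function(x, ...) {
  tibble(complex = seq_along(x), size = as.integer(unclass(x)))
}

#' Connected-component complexes of a contact graph
#'
#' @param graph A `zincagg_contact_graph`.
#' @return A [composition()] of component sizes (singletons included), with
#'   unit membership attached.
#' @export
complexes <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)
  membership <- setNames(as.integer(comp$membership),
                         igraph::V(g)$name)
  composition(as.integer(comp$csize), frame_index = graph$frame_index,
              membership = membership)
}

#' Merge proximal complexes
#'
#' Complexes whose minimum inter-complex atom distance (minimum image) is
#' within `merge_cutoff` are transitively merged, following the convention
#' that conglomerates sitting very close to each other are identified as a
#' single complex. With `merge_cutoff` equal to the contact cutoff the
#' composition is unchanged.
#'
#' @param comp A [composition()] with membership, as from [complexes()].
#' @param graph The `zincagg_contact_graph` the composition came from.
#' @param merge_cutoff Merge distance in nm (>= the contact cutoff; default
#'   1.0 nm).
#' @return A merged [composition()].
#' @export
merge_proximal <- function(comp, graph, merge_cutoff = 1.0) {
  if (merge_cutoff < graph$cutoff) {
    stopf("zincagg_invalid", "merge_cutoff must be >= contact cutoff")
  }
  membership <- attr(comp, "membership")
  if (is.null(membership)) {
    stopf("zincagg_invalid", "composition carries no unit membership")
  }
  ncomp <- max(membership)
  if (ncomp <= 1L) return(comp)
  box <- graph$frame$box_edge
  aidx <- unit_atom_index(graph$topology)
  comp_atoms <- lapply(seq_len(ncomp), function(ci) {
    units <- as.integer(names(membership)[membership == ci])
    do.call(rbind, lapply(units, function(u) {
      graph$frame$coords[aidx[[as.character(u)]], , drop = FALSE]
    }))
  })
  parent <- seq_len(ncomp)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(ncomp - 1L)) {
    for (b in seq(a + 1L, ncomp)) {
      if (min(min_image_dist(comp_atoms[[a]], comp_atoms[[b]], box)) <=
          merge_cutoff) {
        ra <- find_root(a); rb <- find_root(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(ncomp), find_root, integer(1))
  merged_membership <- setNames(match(roots[membership], sort(unique(roots))),
                                names(membership))
  csize <- tabulate(membership, nbins = ncomp)
  sizes <- vapply(sort(unique(roots)), function(r) {
    sum(csize[roots == r])
  }, integer(1))
  composition(sizes, frame_index = attr(comp, "frame_index"),
              membership = merged_membership)
}

#' Per-frame complex compositions of a trajectory
#'
#' @param trajectory A `zincagg_trajectory`.
#' @param cutoff Contact cutoff, nm.
#' @param merge_cutoff Optional proximity-merge cutoff, nm; `NULL` disables
#'   merging.
#' @return List of [composition()] objects, one per frame.
#' @export
composition_timeseries <- function(trajectory, cutoff = 0.45,
                                   merge_cutoff = NULL) {
  lapply(seq_along(trajectory$frames), function(i) {
    g <- contact_graph(trajectory$frames[[i]], trajectory$topology,
                       cutoff = cutoff, frame_index = i)
    cc <- complexes(g)
    if (!is.null(merge_cutoff)) cc <- merge_proximal(cc, g, merge_cutoff)
    cc
  })
}
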