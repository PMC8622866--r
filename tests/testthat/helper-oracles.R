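# Independent oracles: deliberately naive re-derivations used to check the
# package's accelerated or composite implementations. They share no code
# with the implementation paths they test.

# normalise an edge table/matrix for comparison (handles the 0-edge case)
edge_matrix <- function(e) {
  m <- as.matrix(e)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# all-pairs brute-force contact edges between non-zinc units
oracle_contact_edges <- function(frame, topology, cutoff) {
  box <- frame$box_edge
  nodes <- topology$units$unit_id[topology$units$species != "zinc_ion"]
  edges <- list()
  for (a in seq_along(nodes)) {
    for (b in seq_len(a - 1L)) {
      u <- nodes[b]; v <- nodes[a]
      iu <- which(topology$atoms$unit_id == u)
      iv <- which(topology$atoms$unit_id == v)
      dmin <- Inf
      for (i in iu) for (j in iv) {
        d <- frame$coords[i, ] - frame$coords[j, ]
        d <- d - box * round(d / box)
        dmin <- min(dmin, sqrt(sum(d^2)))
      }
      if (dmin <= cutoff) edges[[length(edges) + 1L]] <- c(u, v)
    }
  }
  if (!length(edges)) return(matrix(integer(), 0, 2))
  e <- do.call(rbind, edges)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# union-find connected-component sizes from an edge list over given nodes
oracle_component_sizes <- function(nodes, edges) {
  parent <- setNames(nodes, as.character(nodes))
  find <- function(x) {
    k <- as.character(x)
    while (parent[[k]] != as.integer(k)) k <- as.character(parent[[k]])
    as.integer(k)
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
      if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
    }
  }
  roots <- vapply(nodes, find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# RMSD after a given rotation matrix (no optimisation)
rmsd_given_rotation <- function(x, y, rot) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  sqrt(mean(rowSums((xc - yc %*% t(rot))^2)))
}

euler_rotation <- function(a, b, c) {
  rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# brute-force minimisation of RMSD over rotations: coarse random sampling of
# Euler angles followed by Nelder-Mead refinement from the best starts
oracle_min_rmsd <- function(x, y, n_random = 600, n_refine = 4) {
  obj <- function(p) rmsd_given_rotation(x, y, euler_rotation(p[1], p[2], p[3]))
  cand <- matrix(stats::runif(n_random * 3, -pi, pi), ncol = 3)
  vals <- apply(cand, 1, obj)
  best <- cand[order(vals)[seq_len(n_refine)], , drop = FALSE]
  mins <- apply(best, 1, function(p0) {
    stats::optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$value
  })
  min(mins)
}

# explicit vector-algebra torsion (independent formulation: projection onto
# the plane normal to the central bond, signed by the central-bond direction)
oracle_torsion <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- b2 / sqrt(sum(b2^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * u) * u
  v2 <- (p4 - p3) - sum((p4 - p3) * u) * u
  ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  s <- sign(sum(u * c(v1[2] * v2[3] - v1[3] * v2[2],
                      v1[3] * v2[1] - v1[1] * v2[3],
                      v1[1] * v2[2] - v1[2] * v2[1])))
  deg <- ang * 180 / pi * ifelse(s == 0, 1, s)
  if (deg <= -180) deg + 360 else deg
}

# exhaustive search over peeling orders for the maximum cluster size
oracle_max_cluster <- function(d, threshold) {
  best <- 0L
  recurse <- function(remaining) {
    if (length(remaining) < 2L) return(invisible(NULL))
    any_neighbor <- FALSE
    for (m in remaining) {
      members <- remaining[d[m, remaining] <= threshold]
      if (length(members) >= 2L) {
        any_neighbor <- TRUE
        best <<- max(best, length(members))
        recurse(setdiff(remaining, members))
      }
    }
    invisible(NULL)
  }
  recurse(seq_len(nrow(d)))
  best
}

# random small multi-atom-unit system for detection tests
random_unit_system <- function(n_units, box_edge = 12, seed = 1,
                               max_atoms = 4) {
  set.seed(seed)
  units <- tibble::tibble(unit_id = seq_len(n_units), species = "monomer",
                          zinc_bound = FALSE)
  atoms <- list(); coords <- list(); aid <- 0L
  for (u in seq_len(n_units)) {
    na <- sample.int(max_atoms, 1)
    center <- stats::runif(3, 0, box_edge)
    for (k in seq_len(na)) {
      aid <- aid + 1L
      atoms[[aid]] <- tibble::tibble(atom_id = aid, unit_id = u,
                                     chain_id = paste0("c", u), resseq = k,
                                     resname = "GLY", atom_name = "CA",
                                     element = "C")
      coords[[aid]] <- center + stats::runif(3, -0.5, 0.5)
    }
  }
  topo <- topology(units, dplyr::bind_rows(atoms))
  list(topology = topo,
       frame = frame(do.call(rbind, coords), box_edge = box_edge))
}

# single-atom-per-unit system at given positions (for hand-built geometries)
point_system <- function(centers, box_edge) {
  n <- nrow(centers)
  units <- tibble::tibble(unit_id = seq_len(n), species = "monomer",
                          zinc_bound = FALSE)
  atoms <- tibble::tibble(atom_id = seq_len(n), unit_id = seq_len(n),
                          chain_id = paste0("c", seq_len(n)), resseq = 1L,
                          resname = "GLY", atom_name = "CA", element = "C")
  list(topology = topology(units, atoms),
       frame = frame(centers, box_edge = box_edge))
}
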