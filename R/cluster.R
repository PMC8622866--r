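# Nearest-neighbor clustering of a conformational ensemble by iterative
# peeling of the densest neighborhood: find the member with the most
# neighbors within the RMSD threshold, emit it with those neighbors as a
# cluster, remove them, repeat. Stops when no remaining member has a
# neighbor; the remainder is reported unclustered. Because the first emitted
# cluster has size 1 + max degree, no peeling order can produce a larger
# cluster.

#' Nearest-neighbor ensemble clustering
#'
#' @param d Symmetric distance (RMSD) matrix, zero diagonal, as from
#'   [pairwise_rmsd_matrix()].
#' @param threshold Neighbor threshold in the units of `d` (> 0).
#' @return A `zincagg_nn_clusters` object: list with `clusters` (list of
#'   member index vectors, each headed by its center), `unclustered`
#'   (integer vector), and `threshold`. Ties on neighbor count break to the
#'   lowest member index.
#' @export
nn_cluster <- function(d, threshold) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stopf("zincagg_invalid", "distance matrix not square")
  if (max(abs(d - t(d))) > 1e-8) {
    stopf("zincagg_invalid", "distance matrix not symmetric")
  }
  if (threshold <= 0) stopf("zincagg_invalid", "threshold must be positive")
  remaining <- seq_len(nrow(d))
  clusters <- list()
  repeat {
    if (length(remaining) < 2L) break
    sub <- d[remaining, remaining, drop = FALSE]
    deg <- rowSums(sub <= threshold) - 1L
    if (max(deg) < 1L) break
    center_pos <- which.max(deg)  # which.max takes the first = lowest index
    members <- remaining[sub[center_pos, ] <= threshold]
    center <- remaining[center_pos]
    clusters[[length(clusters) + 1L]] <-
      c(center, setdiff(members, center))
    remaining <- setdiff(remaining, members)
  }
  structure(list(clusters = clusters, unclustered = remaining,
                 threshold = threshold),
            class = "zincagg_nn_clusters")
}

#' @export
print.zincagg_nn_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, length, integer(1))
  cat(sprintf("<zincagg_nn_clusters> %d cluster(s) (sizes %s), %d unclustered (threshold %g)\n",
              length(x$clusters),
              if (length(sizes)) paste(sizes, collapse = ",") else "-",
              length(x$unclustered), x$threshold))
  invisible(x)
}

#' @export
tidy.zincagg_nn_clusters <- function(x, ...) {
  rows <- list()
  for (ci in seq_along(x$clusters)) {
    rows[[ci]] <- tibble(member = x$clusters[[ci]], cluster = ci,
                         is_center = x$clusters[[ci]] == x$clusters[[ci]][1])
  }
  if (length(x$unclustered)) {
    rows[[length(rows) + 1L]] <- tibble(member = x$unclustered,
                                        cluster = NA_integer_,
                                        is_center = FALSE)
  }
  bind_rows(rows) %>% arrange(.data$member)
}
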