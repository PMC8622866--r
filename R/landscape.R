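# Free-energy landscapes over reaction-coordinate pairs (e.g. RMSD vs
# radius of gyration, or circular-mean phi vs psi). The surface is
# F = -ln(count / max count) in kT units, so the most populated bin sits at
# exactly 0 and empty bins are masked (NA), never reported as 0.

#' Build a 2D free-energy landscape
#'
#' @param x,y Equal-length reaction-coordinate series.
#' @param bins Number of bins per axis (default 32).
#' @param kT Thermal energy for display scaling; the stored surface is in
#'   kT units regardless.
#' @param padding Fractional range padding on each side (default 0.05).
#' @param x_name,y_name Axis labels (coordinate name and units).
#' @return A `zincagg_landscape`: bin edges, counts, `free_energy` matrix in
#'   kT units with empty bins `NA`.
#' @export
free_energy_landscape <- function(x, y, bins = 32, kT = 1, padding = 0.05,
                                  x_name = "x", y_name = "y") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L) stopf("zincagg_empty", "zero-length coordinate series")
  if (length(x) != length(y)) {
    stopf("zincagg_invalid", "coordinate series differ in length")
  }
  if (anyNA(x) || anyNA(y)) stopf("zincagg_invalid", "NA in coordinates")
  edges <- function(v) {
    r <- range(v)
    span <- diff(r)
    if (span == 0) span <- max(abs(r[1]), 1) * 0.1
    seq(r[1] - padding * span, r[2] + padding * span, length.out = bins + 1L)
  }
  xe <- edges(x); ye <- edges(y)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  fe <- matrix(NA_real_, bins, bins)
  occ <- counts > 0L
  fe[occ] <- -log(counts[occ] / max(counts))
  structure(list(x_name = x_name, y_name = y_name, x_edges = xe, y_edges = ye,
                 counts = counts, free_energy = fe, kT = kT,
                 bin_of = cbind(ix = ix, iy = iy)),
            class = "zincagg_landscape")
}

#' @export
print.zincagg_landscape <- function(x, ...) {
  cat(sprintf("<zincagg_landscape> %dx%d bins over %s vs %s, %d occupied, max F = %.2f kT\n",
              nrow(x$counts), ncol(x$counts), x$x_name, x$y_name,
              sum(x$counts > 0), max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.zincagg_landscape <- function(x, ...) {
  xc <- (head(x$x_edges, -1) + tail(x$x_edges, -1)) / 2
  yc <- (head(x$y_edges, -1) + tail(x$y_edges, -1)) / 2
  grid <- tidyr::expand_grid(ix = seq_along(xc), iy = seq_along(yc))
  grid$x <- xc[grid$ix]
  grid$y <- yc[grid$iy]
  grid$count <- x$counts[cbind(grid$ix, grid$iy)]
  grid$free_energy <- x$free_energy[cbind(grid$ix, grid$iy)]
  grid
}

#' @export
glance.zincagg_landscape <- function(x, ...) {
  tibble(n_samples = sum(x$counts), n_bins = length(x$counts),
         occupied = sum(x$counts > 0),
         min_free_energy = min(x$free_energy, na.rm = TRUE),
         max_free_energy = max(x$free_energy, na.rm = TRUE))
}

occupied_neighbors <- function(grid, i, j) {
  nb <- expand.grid(di = -1:1, dj = -1:1)
  nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
  ii <- i + nb$di; jj <- j + nb$dj
  ok <- ii >= 1 & ii <= nrow(grid$counts) & jj >= 1 & jj <= ncol(grid$counts)
  idx <- cbind(ii[ok], jj[ok])
  idx[grid$counts[idx] > 0L, , drop = FALSE]
}

#' Find local minima of a landscape
#'
#' A local minimum is an occupied bin whose free energy is less than or
#' equal to that of all occupied 8-neighbors and that lies at least `depth`
#' kT below its lowest occupied neighbor (the saddle estimate); isolated
#' occupied bins qualify unconditionally.
#'
#' @param grid A `zincagg_landscape`.
#' @param depth Minimum depth below the lowest neighboring bin, in kT
#'   (default 0: every non-strict local minimum is reported).
#' @return Tibble `ix`, `iy`, `x`, `y` (bin centers), `free_energy`,
#'   `depth`, sorted by free energy.
#' @export
find_minima <- function(grid, depth = 0) {
  xc <- (head(grid$x_edges, -1) + tail(grid$x_edges, -1)) / 2
  yc <- (head(grid$y_edges, -1) + tail(grid$y_edges, -1)) / 2
  rows <- list()
  for (i in seq_len(nrow(grid$counts))) {
    for (j in seq_len(ncol(grid$counts))) {
      if (grid$counts[i, j] == 0L) next
      fe <- grid$free_energy[i, j]
      nb <- occupied_neighbors(grid, i, j)
      if (nrow(nb) == 0L) {
        dep <- Inf
      } else {
        nfe <- grid$free_energy[nb]
        if (any(nfe < fe)) next
        dep <- min(nfe) - fe
      }
      if (dep >= depth) {
        rows[[length(rows) + 1L]] <- tibble(ix = i, iy = j, x = xc[i],
                                            y = yc[j], free_energy = fe,
                                            depth = dep)
      }
    }
  }
  if (!length(rows)) {
    return(tibble(ix = integer(), iy = integer(), x = numeric(),
                  y = numeric(), free_energy = numeric(), depth = numeric()))
  }
  bind_rows(rows) %>% arrange(.data$free_energy, .data$ix, .data$iy)
}

#' Representative frames of landscape minima
#'
#' For each minimum bin, returns the indices of the samples falling in it,
#' ordered by distance to the bin center (the first is the representative).
#'
#' @param grid A `zincagg_landscape` built from the same `x`/`y` series.
#' @param minima Tibble from [find_minima()].
#' @param x,y The coordinate series the landscape was built from.
#' @return Tibble `minimum` (row index into `minima`), `frame` (sample
#'   index), `x`, `y`, `rank` (1 = representative).
#' @export
representative_frames <- function(grid, minima, x, y) {
  xc <- (head(grid$x_edges, -1) + tail(grid$x_edges, -1)) / 2
  yc <- (head(grid$y_edges, -1) + tail(grid$y_edges, -1)) / 2
  sx <- diff(range(grid$x_edges)); sy <- diff(range(grid$y_edges))
  rows <- list()
  for (m in seq_len(nrow(minima))) {
    sel <- which(grid$bin_of[, "ix"] == minima$ix[m] &
                   grid$bin_of[, "iy"] == minima$iy[m])
    if (!length(sel)) next
    dd <- sqrt(((x[sel] - xc[minima$ix[m]]) / sx)^2 +
                 ((y[sel] - yc[minima$iy[m]]) / sy)^2)
    ord <- order(dd, sel)
    rows[[length(rows) + 1L]] <- tibble(minimum = m, frame = sel[ord],
                                        x = x[sel][ord], y = y[sel][ord],
                                        rank = seq_along(ord))
  }
  if (!length(rows)) {
    return(tibble(minimum = integer(), frame = integer(), x = numeric(),
                  y = numeric(), rank = integer()))
  }
  bind_rows(rows)
}

#' Frame indices belonging to landscape minima
#'
#' Convenience wrapper returning the set of sample indices that fall in any
#' minimum bin; intersect the results of two landscapes (base
#' [intersect()]) to find conformations shared by the minima of both.
#'
#' @inheritParams representative_frames
#' @return Sorted integer vector of sample indices.
#' @export
minima_frames <- function(grid, minima, x, y) {
  sort(unique(representative_frames(grid, minima, x, y)$frame))
}

#' Per-frame circular means of backbone dihedrals
#'
#' Reduces a set of per-residue phi/psi angles to one (phi, psi) pair per
#' frame via the circular mean, the reduction used for dihedral-space
#' landscapes.
#'
#' @param angles Numeric vector of angles in degrees.
#' @return Circular mean in degrees in (-180, 180].
#' @export
circular_mean <- function(angles) {
  a <- angles[!is.na(angles)] * pi / 180
  if (!length(a)) return(NA_real_)
  m <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  if (m <= -180) m + 360 else m
}
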