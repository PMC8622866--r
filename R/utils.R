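# Periodic-box geometry helpers. All coordinates are in nm; boxes are cubic.

#' Minimum-image displacement components
#'
#' Wraps displacement components into `[-box_edge/2, box_edge/2)` so that
#' distances are measured to the nearest periodic copy.
#'
#' @param d Numeric vector or matrix of displacement components (nm).
#' @param box_edge Cubic box edge length (nm).
#' @return Object of the same shape as `d`.
#' @export
min_image <- function(d, box_edge) {
  d - box_edge * round(d / box_edge)
}

#' Minimum-image distances between two coordinate sets
#'
#' @param a,b Numeric matrices with 3 columns (nm). `b` defaults to `a`.
#' @param box_edge Cubic box edge (nm).
#' @return Matrix of pairwise minimum-image distances, `nrow(a)` x `nrow(b)`.
#' @export
min_image_dist <- function(a, b = a, box_edge) {
  a <- rbind(a); b <- rbind(b)
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box_edge)
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box_edge)
  dz <- min_image(outer(a[, 3], b[, 3], "-"), box_edge)
  sqrt(dx^2 + dy^2 + dz^2)
}

# wrap absolute coordinates into [0, box_edge)
wrap_box <- function(x, box_edge) {
  x - box_edge * floor(x / box_edge)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "zincagg_error"))
}
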