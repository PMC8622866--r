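# Aggregation scoring. The connectivity length Lc = sum_i sqrt(N_i) over the
# complexes of a system (each zinc-bridged dimer counted as one molecule
# unit) measures how aggregated a system is: the smaller the value, the
# stronger the aggregation. For M units it ranges from sqrt(M) (one complex
# holding everything) to M (all monomers free). It is not normalized, so
# systems are only comparable at equal unit counts.

#' Connectivity length of a complex composition
#'
#' `Lc = sum_i sqrt(N_i)` over complex sizes `N_i`. Computed at full
#' precision; round to two decimals for presentation.
#'
#' @param composition A [composition()] or a bare vector of positive complex
#'   sizes.
#' @return The connectivity length (dimensionless).
#' @export
connectivity_length <- function(composition) {
  sizes <- as_sizes(composition)
  sum(sqrt(sizes))
}

as_sizes <- function(x) {
  if (inherits(x, "zincagg_composition")) return(as.numeric(unclass(x)))
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("zincagg_empty", "empty composition")
  if (any(!is.finite(x) | x < 1 | x != round(x))) {
    stopf("zincagg_invalid", "complex sizes must be positive integers")
  }
  x
}

#' Aggregation summary of a composition
#'
#' @param composition A [composition()] or a vector of complex sizes.
#' @return One-row tibble: `n_units`, `n_complexes`, `lc` (full precision),
#'   `lc_2dp` (presentation rounding, half-even), `largest`,
#'   `largest_fraction`, and `size_histogram` (list column, tibble of
#'   `size`/`count`).
#' @export
aggregation_report <- function(composition) {
  sizes <- as_sizes(composition)
  lc <- sum(sqrt(sizes))
  hist <- as.data.frame(table(sizes), stringsAsFactors = FALSE)
  hist <- tibble(size = as.integer(hist$sizes), count = as.integer(hist$Freq))
  tibble(
    n_units = sum(sizes),
    n_complexes = length(sizes),
    lc = lc,
    lc_2dp = round(lc, 2),
    largest = max(sizes),
    largest_fraction = max(sizes) / sum(sizes),
    size_histogram = list(hist)
  )
}

#' @export
glance.zincagg_composition <- function(x, ...) {
  aggregation_report(x)
}

#' Connectivity-length time series
#'
#' @param compositions List of [composition()] objects, as from
#'   [composition_timeseries()].
#' @return Tibble with one row per frame: `frame`, `n_complexes`, `largest`,
#'   `lc`.
#' @export
lc_timeseries <- function(compositions) {
  tibble(
    frame = vapply(seq_along(compositions), function(i) {
      fi <- attr(compositions[[i]], "frame_index")
      if (is.null(fi) || is.na(fi)) i else as.integer(fi)
    }, integer(1)),
    n_complexes = vapply(compositions, length, integer(1)),
    largest = vapply(compositions, function(x) max(as_sizes(x)), numeric(1)),
    lc = vapply(compositions, connectivity_length, numeric(1))
  )
}
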