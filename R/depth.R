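#' Local cortical column geometry
#'
#' Local inner (white) and outer (pial) boundary areas and thickness for a
#' cortical column, the inputs to equi-volume depth placement. The column
#' model interpolates local area linearly from `A_in` at normalized depth 0
#' to `A_out` at depth 1.
#'
#' @param A_in inner-boundary local area, mm^2 (> 0).
#' @param A_out outer-boundary local area, mm^2 (> 0).
#' @param thickness cortical thickness, mm (> 0).
#' @return An object of class `column_geometry`.
#' @export
column_geometry <- function(A_in, A_out, thickness = 1) {
  if (!all(is.finite(c(A_in, A_out, thickness))) ||
      A_in <= 0 || A_out <= 0 || thickness <= 0)
    stop_invalid("A_in, A_out and thickness must be positive and finite")
  structure(list(A_in = A_in, A_out = A_out, thickness = thickness),
            class = "column_geometry")
}

#' Read column geometry table from CSV
#'
#' Expects columns `column_id`, `A_in`, `A_out`, `thickness`.
#'
#' @param path CSV file path.
#' @return data.frame of geometries (one row per column).
#' @export
read_column_geometry <- function(path) {
  g <- read.csv(path)
  need <- c("column_id", "A_in", "A_out", "thickness")
  if (!all(need %in% names(g)))
    stop_invalid("geometry CSV must have columns %s", paste(need, collapse = ", "))
  g
}

#' Equi-volume depth placement
#'
#' Returns the normalized depth fraction `rho` (measured from the inner
#' boundary) at which the enclosed column volume equals `alpha` times the
#' total volume, under the linear-taper column model. Closed form:
#' `rho = (-A_in + sqrt(alpha * A_out^2 + (1 - alpha) * A_in^2)) / (A_out - A_in)`,
#' with the flat-cortex limit `rho = alpha` when `|A_out - A_in|` is below
#' `1e-9 * max(A_in, A_out)` (avoids catastrophic cancellation). In gyral
#' crowns (`A_out > A_in`) equal-volume surfaces sit deeper than
#' equidistant ones; in sulcal fundi the reverse.
#'
#' @param alpha volume fraction(s) in \[0, 1\] (vectorized).
#' @param geom a [column_geometry()].
#' @return depth fraction(s) `rho` in \[0, 1\].
#' @examples
#' equivolume_depth(0.5, column_geometry(1, 2))  # sqrt(2.5) - 1
#' @export
equivolume_depth <- function(alpha, geom) {
  stopifnot(inherits(geom, "column_geometry"))
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop_invalid("alpha must lie in [0, 1]")
  ain <- geom$A_in; aout <- geom$A_out
  if (abs(aout - ain) < 1e-9 * max(ain, aout)) return(alpha)
  (-ain + sqrt(alpha * aout^2 + (1 - alpha) * ain^2)) / (aout - ain)
}

#' Equi-volume depth bin boundaries
#'
#' Places `n_bins + 1` depth surfaces so each bin encloses exactly
#' `1/n_bins` of the column volume. Bin 1 is the deepest (adjacent to the
#' inner/white boundary); the direction convention is recorded in the
#' returned object.
#'
#' @param n_bins number of bins (>= 1).
#' @param geom a [column_geometry()].
#' @return An object of class `depth_binning` with fields `n_bins`,
#'   `boundaries` (length `n_bins + 1`, from 0 to 1), `trimmed`,
#'   `direction` (`"deep_to_superficial"`).
#' @export
bin_boundaries <- function(n_bins, geom) {
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 1 ||
      n_bins != round(n_bins))
    stop_invalid("n_bins must be an integer >= 1")
  b <- equivolume_depth(seq(0, 1, length.out = n_bins + 1), geom)
  structure(list(n_bins = as.integer(n_bins), boundaries = b, trimmed = FALSE,
                 direction = "deep_to_superficial", geom = geom),
            class = "depth_binning")
}

#' Trim a 7-bin solution to its middle 5 bins
#'
#' Drops the first (deepest) and last (most superficial) bins of a 7-bin
#' equi-volume solution — the bins most exposed to white-matter and
#' extra-cerebral contamination in imaging data — and renumbers the
#' retained bins 1..5 from deep to superficial.
#'
#' @param binning a `depth_binning` with exactly 7 untrimmed bins.
#' @return A `depth_binning` with 5 bins and `trimmed = TRUE`; its
#'   boundaries span the retained depth interval.
#' @export
trim_bins <- function(binning) {
  stopifnot(inherits(binning, "depth_binning"))
  if (binning$n_bins != 7L || isTRUE(binning$trimmed))
    stop_invalid("trim_bins expects an untrimmed 7-bin solution, got %d bins%s",
                 binning$n_bins, if (isTRUE(binning$trimmed)) " (already trimmed)" else "")
  structure(list(n_bins = 5L, boundaries = binning$boundaries[2:7], trimmed = TRUE,
                 direction = "deep_to_superficial", geom = binning$geom),
            class = "depth_binning")
}

#' @export
print.depth_binning <- function(x, ...) {
  cat(sprintf("depth_binning: %d bins%s, %s\n  boundaries: %s\n", x$n_bins,
              if (x$trimmed) " (trimmed from 7)" else "", x$direction,
              paste(signif(x$boundaries, 4), collapse = " ")))
  invisible(x)
}

#' Assign metric depths to equi-volume bins
#'
#' Maps normalized metric depths (0 = inner boundary, 1 = outer boundary)
#' to depth-bin labels. Bin `i` covers `[rho_{i-1}, rho_i)`; the last bin
#' is closed above. For trimmed binnings, depths outside the retained
#' interval get `NA`.
#'
#' @param depths numeric vector of normalized depths in \[0, 1\].
#' @param binning a `depth_binning`.
#' @return integer bin labels (1 = deepest retained bin), `NA` for depths
#'   outside a trimmed binning's retained interval.
#' @export
assign_depth_bins <- function(depths, binning) {
  stopifnot(inherits(binning, "depth_binning"))
  if (any(!is.finite(depths)) || any(depths < 0) || any(depths > 1))
    stop_invalid("depths must lie in [0, 1]")
  b <- binning$boundaries
  idx <- findInterval(depths, b, rightmost.closed = TRUE)
  idx[idx < 1L | idx > binning$n_bins] <- NA_integer_
  as.integer(idx)
}
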