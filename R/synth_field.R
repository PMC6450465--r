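#' Alternans ground-truth field
#'
#' A per-pixel signed alternans magnitude on the imaging grid: the magnitude
#' (absolute value, in [0, 1]) is the target normalized alternans magnitude
#' of that pixel and the sign its phase relative to even-indexed beats.
#' `alternans_field()` validates and wraps a signed matrix;
#' [make_uniform_field()] and [make_discordant_field()] are the common
#' constructors.
#'
#' @param signed numeric matrix with values in `[-1, 1]`.
#' @param bz_mask logical matrix of the same shape marking border-zone
#'   pixels (default: none).
#' @param nodal_geometry optional description of the zero-level curve(s), as
#'   produced by [make_discordant_field()] (a data.frame of points or a
#'   function of the row index).
#' @return An object of class `alternans_field`.
#' @export
alternans_field <- function(signed, bz_mask = NULL, nodal_geometry = NULL) {
  signed <- as.matrix(signed)
  if (any(!is.finite(signed)) || any(abs(signed) > 1)) {
    stop("signed magnitudes must be finite and within [-1, 1]")
  }
  if (is.null(bz_mask)) {
    bz_mask <- matrix(FALSE, nrow(signed), ncol(signed))
  }
  bz_mask <- as.matrix(bz_mask)
  if (!identical(dim(bz_mask), dim(signed))) {
    stop("bz_mask must match the grid of signed")
  }
  structure(list(signed = signed, bz_mask = bz_mask,
                 nodal_geometry = nodal_geometry),
            class = "alternans_field")
}

#' @export
print.alternans_field <- function(x, ...) {
  cat(sprintf(
    "<alternans_field> %dx%d grid, |s| in [%.3f, %.3f], %d BZ pixels%s\n",
    nrow(x$signed), ncol(x$signed), min(abs(x$signed)), max(abs(x$signed)),
    sum(x$bz_mask),
    if (is.null(x$nodal_geometry)) "" else ", with nodal line"))
  invisible(x)
}

#' Default border-zone mask
#'
#' One connected region along the left edge of the field of view, occupying
#' `fraction` of the grid width, with a straight or sinusoidally curved
#' boundary — emulating an imaging field positioned across the boundary
#' between border zone and non-infarcted myocardium.
#'
#' @param grid two-element integer vector `(rows, cols)`.
#' @param fraction fraction of the grid width covered by the border zone.
#' @param curve amplitude (in pixels) of a sinusoidal deviation of the
#'   boundary; 0 gives a straight vertical boundary.
#' @return Logical matrix, `TRUE` on border-zone pixels.
#' @export
default_bz_mask <- function(grid = c(32, 32), fraction = 0.4, curve = 0) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  edge <- fraction * grid[2] +
    curve * sin(seq(0, 2 * pi, length.out = grid[1]))
  outer(seq_len(grid[1]), seq_len(grid[2]),
        function(r, c) c <= edge[r])
}

#' Spatially uniform alternans field
#'
#' Every pixel carries the same signed alternans magnitude (optionally a
#' different one inside the border zone), emulating concordant alternans.
#'
#' @param grid two-element integer vector `(rows, cols)`.
#' @param signed_magnitude signed alternans magnitude in `[-1, 1]`.
#' @param bz_mask optional logical matrix of border-zone pixels.
#' @param bz_magnitude optional signed magnitude used on BZ pixels (defaults
#'   to `signed_magnitude`), for fields with stronger border-zone alternans.
#' @return An `alternans_field`.
#' @export
make_uniform_field <- function(grid = c(32, 32), signed_magnitude = 0.2,
                               bz_mask = NULL,
                               bz_magnitude = signed_magnitude) {
  s <- matrix(signed_magnitude, grid[1], grid[2])
  if (!is.null(bz_mask)) s[bz_mask] <- bz_magnitude
  alternans_field(s, bz_mask = bz_mask)
}

#' Discordant alternans field with a nodal line
#'
#' Builds a field whose signed magnitude is positive on one side of a nodal
#' curve and negative on the other, tapering smoothly (tanh profile) through
#' zero on the curve — the spatial pattern of discordant alternans, where
#' tissue regions alternate in opposite phase separated by a line of no
#' alternans.
#'
#' @param grid two-element integer vector `(rows, cols)`.
#' @param nodal_line either a single number (vertical line at that column) or
#'   a function mapping row index to the column of the curve.
#' @param peak_magnitude alternans magnitude far from the line, in (0, 1].
#' @param taper width of the tanh transition, pixels.
#' @param bz_mask optional logical matrix of border-zone pixels.
#' @return An `alternans_field` whose `nodal_geometry` is a data.frame with
#'   the curve's `(row, col)` coordinates.
#' @export
make_discordant_field <- function(grid = c(32, 32), nodal_line = NULL,
                                  peak_magnitude = 0.3, taper = 4,
                                  bz_mask = NULL) {
  if (peak_magnitude <= 0 || peak_magnitude > 1) {
    stop("peak_magnitude must be in (0, 1]")
  }
  if (is.null(nodal_line)) nodal_line <- (grid[2] + 1) / 2
  f <- if (is.function(nodal_line)) nodal_line else function(r) {
    rep(nodal_line[1], length(r))
  }
  edge <- f(seq_len(grid[1]))
  if (any(edge < 1) || any(edge > grid[2])) {
    stop("nodal_line must lie within the grid")
  }
  s <- outer(seq_len(grid[1]), seq_len(grid[2]),
             function(r, c) peak_magnitude * tanh((c - edge[r]) / taper))
  alternans_field(s, bz_mask = bz_mask,
                  nodal_geometry = data.frame(row = seq_len(grid[1]),
                                              col = edge))
}
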