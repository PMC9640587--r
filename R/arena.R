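#' Two-compartment CPP arena geometry
#'
#' Describes the conditioned place preference apparatus: two square
#' compartments joined side by side at the midline through a narrow door
#' opening. Coordinates are continuous centimetres with the origin at the
#' south-west corner of the left compartment; the arena spans
#' `[0, 2 * compartment_cm] x [0, compartment_cm]`.
#'
#' @param compartment_cm Side length of each square compartment in cm.
#' @param door_cm Width of the door opening at the midline in cm. Must be
#'   smaller than the compartment side.
#' @return An object of class `cpp_arena` with fields `width`, `height`,
#'   `midline` (x position of the partition) and `door` (y range of the
#'   opening).
#' @examples
#' arena <- arena_spec()
#' arena$midline
#' @export
arena_spec <- function(compartment_cm = 25, door_cm = 6.5) {
  stopifnot(compartment_cm > 0, door_cm > 0, door_cm < compartment_cm)
  structure(
    list(
      compartment_cm = compartment_cm,
      door_cm = door_cm,
      width = 2 * compartment_cm,
      height = compartment_cm,
      midline = compartment_cm,
      door = c(
        compartment_cm / 2 - door_cm / 2,
        compartment_cm / 2 + door_cm / 2
      )
    ),
    class = "cpp_arena"
  )
}

#' @export
print.cpp_arena <- function(x, ...) {
  cat(sprintf(
    "<cpp_arena> two %g x %g cm compartments, %g cm door at midline x = %g\n",
    x$compartment_cm, x$compartment_cm, x$door_cm, x$midline
  ))
  invisible(x)
}

#' Compartment membership of positions
#'
#' @param arena A [arena_spec()] object.
#' @param x Numeric vector of x positions in cm.
#' @return Character vector, `"left"` or `"right"`, by midline position.
#' @export
compartment_of <- function(arena, x) {
  ifelse(x < arena$midline, "left", "right")
}

# Spatial bin grid at a fixed pitch over the whole arena. Bins are
# half-open [lo, hi); the last row/column may extend past the wall.
bin_grid <- function(arena, bin_cm = 1.8) {
  nx <- as.integer(ceiling(arena$width / bin_cm - 1e-9))
  ny <- as.integer(ceiling(arena$height / bin_cm - 1e-9))
  list(
    bin_cm = bin_cm, nx = nx, ny = ny, nbins = nx * ny,
    xc = (seq_len(nx) - 0.5) * bin_cm,
    yc = (seq_len(ny) - 0.5) * bin_cm
  )
}

# Map positions to full-arena bin ids (column-major: id = ix + (iy-1)*nx).
bin_of <- function(grid, x, y) {
  ix <- pmin(grid$nx, pmax(1L, floor(x / grid$bin_cm) + 1L))
  iy <- pmin(grid$ny, pmax(1L, floor(y / grid$bin_cm) + 1L))
  as.integer(ix + (iy - 1L) * grid$nx)
}

# Centre coordinates (cm) of full-arena bin ids; returns a 2-column matrix.
bin_center <- function(grid, id) {
  ix <- ((id - 1L) %% grid$nx) + 1L
  iy <- ((id - 1L) %/% grid$nx) + 1L
  cbind(x = (ix - 0.5) * grid$bin_cm, y = (iy - 0.5) * grid$bin_cm)
}

# Within-compartment grid for transverse (left vs right) comparisons:
# positions are re-expressed relative to their own compartment so that
# homotopic bins share an id across compartments.
local_grid <- function(arena, bin_cm = 1.8) {
  nx <- as.integer(ceiling(arena$compartment_cm / bin_cm - 1e-9))
  ny <- as.integer(ceiling(arena$height / bin_cm - 1e-9))
  list(
    bin_cm = bin_cm, nx = nx, ny = ny, nbins = nx * ny,
    xc = (seq_len(nx) - 0.5) * bin_cm,
    yc = (seq_len(ny) - 0.5) * bin_cm
  )
}

local_bin_of <- function(arena, grid, x, y) {
  u <- ifelse(x < arena$midline, x, x - arena$midline)
  bin_of(grid, u, y)
}
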