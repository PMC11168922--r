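#' Planar equal-area analysis grid
#'
#' All raster computation in consgap happens on an abstract planar
#' equal-area grid. A grid is defined by its origin (lower-left corner),
#' the number of cells along x and y, and the cell edge length in km.
#' Cells are half-open intervals `[x, x + w) x [y, y + w)` so a point on a
#' shared edge belongs to exactly one cell.
#'
#' @param nx,ny number of cells along x and y.
#' @param cell_km cell edge length in kilometres; cell area is `cell_km^2`.
#' @param origin numeric length-2, coordinates of the lower-left corner (km).
#' @return an object of class `cg_grid`.
#' @examples
#' g <- cg_grid(20, 20, cell_km = 1)
#' cell_area_km2(g)
#' @export
cg_grid <- function(nx, ny, cell_km, origin = c(0, 0)) {
  stopifnot(length(nx) == 1, length(ny) == 1, nx >= 1, ny >= 1,
            nx == as.integer(nx), ny == as.integer(ny),
            is.numeric(cell_km), length(cell_km) == 1, cell_km > 0,
            is.numeric(origin), length(origin) == 2)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_km = as.numeric(cell_km),
                 origin = as.numeric(origin)),
            class = "cg_grid")
}

#' @export
print.cg_grid <- function(x, ...) {
  cat(sprintf("<cg_grid> %d x %d cells, %.6g km cells, origin (%g, %g)\n",
              x$nx, x$ny, x$cell_km, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @rdname cg_grid
#' @param grid a `cg_grid`.
#' @export
cell_area_km2 <- function(grid) grid$cell_km^2

#' @rdname cg_grid
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin[1], ymin = grid$origin[2],
    xmax = grid$origin[1] + grid$nx * grid$cell_km,
    ymax = grid$origin[2] + grid$ny * grid$cell_km)
}

# Cell-centre coordinate vectors.
cell_centers_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$cell_km
cell_centers_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$cell_km

#' Rectangle geometries
#'
#' Vector geometries (species ranges, protected areas, islands) are unions
#' of axis-aligned rectangles in the grid's planar coordinate system. A
#' rectangle table has columns `xmin`, `ymin`, `xmax`, `ymax` (km) and may
#' carry any identifier columns (`taxon_id`, `pa_id`, `island_id`,
#' `presence`, ...). Rectangle arithmetic — union area, pairwise
#' intersection area, per-cell coverage fraction — is exact, which keeps
#' the raster pipeline free of geometric approximation error.
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds (km); `xmin < xmax`,
#'   `ymin < ymax`.
#' @param ... additional columns recycled to the number of rectangles.
#' @return a tibble with class `cg_rects` prepended.
#' @examples
#' r <- cg_rects(xmin = 0, ymin = 0, xmax = 2, ymax = 1)
#' rect_union_area(r)
#' @export
cg_rects <- function(xmin, ymin, xmax, ymax, ...) {
  out <- tibble::tibble(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                        xmax = as.numeric(xmax), ymax = as.numeric(ymax), ...)
  validate_rects(out)
  class(out) <- c("cg_rects", class(out))
  out
}

validate_rects <- function(rects) {
  req <- c("xmin", "ymin", "xmax", "ymax")
  missing <- setdiff(req, names(rects))
  if (length(missing) > 0)
    stop("rectangle table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(rects$xmin >= rects$xmax | rects$ymin >= rects$ymax)
  if (length(bad) > 0)
    stop("degenerate rectangles (min >= max) at rows: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  invisible(rects)
}

#' @rdname cg_rects
#' @param rects a rectangle table.
#' @return `rect_union_area()`: the exact area (km^2) of the union.
#' @export
rect_union_area <- function(rects) {
  if (nrow(rects) == 0) return(0)
  validate_rects(rects)
  sum(decompose_cover(rects)$area)
}

#' @rdname cg_rects
#' @param rects_a,rects_b rectangle tables.
#' @return `rect_intersection_area()`: the exact area (km^2) of
#'   `union(rects_a)` intersected with `union(rects_b)`.
#' @export
rect_intersection_area <- function(rects_a, rects_b) {
  if (nrow(rects_a) == 0 || nrow(rects_b) == 0) return(0)
  validate_rects(rects_a); validate_rects(rects_b)
  both <- dplyr::bind_rows(rects_a[c("xmin", "ymin", "xmax", "ymax")],
                           rects_b[c("xmin", "ymin", "xmax", "ymax")])
  d <- decompose_grid(both)
  ca <- cover_mask(rects_a, d)
  cb <- cover_mask(rects_b, d)
  sum(d$area[ca & cb])
}

# Break the bounding box of `rects` into the atomic sub-rectangles induced
# by every rectangle edge. Returns centre coordinates and areas of the
# atoms; any rectangle in `rects` either fully contains or fully misses
# each atom, so centre-membership tests are exact.
decompose_grid <- function(rects, extra_x = numeric(0), extra_y = numeric(0)) {
  xs <- sort(unique(c(rects$xmin, rects$xmax, extra_x)))
  ys <- sort(unique(c(rects$ymin, rects$ymax, extra_y)))
  if (length(xs) < 2 || length(ys) < 2)
    return(list(xc = numeric(0), yc = numeric(0),
                wx = numeric(0), wy = numeric(0), area = numeric(0)))
  wx <- diff(xs); wy <- diff(ys)
  xc <- xs[-length(xs)] + wx / 2
  yc <- ys[-length(ys)] + wy / 2
  # atoms laid out with x varying fastest
  area <- as.vector(outer(wx, wy))
  list(xc = rep(xc, times = length(yc)),
       yc = rep(yc, each = length(xc)),
       nx = length(xc), ny = length(yc), area = area)
}

cover_mask <- function(rects, d) {
  covered <- logical(length(d$xc))
  for (k in seq_len(nrow(rects))) {
    covered <- covered |
      (d$xc >= rects$xmin[k] & d$xc < rects$xmax[k] &
       d$yc >= rects$ymin[k] & d$yc < rects$ymax[k])
  }
  covered
}

decompose_cover <- function(rects) {
  d <- decompose_grid(rects)
  keep <- cover_mask(rects, d)
  list(area = d$area[keep])
}

#' Exact per-cell coverage fraction of a rectangle union
#'
#' Computes, for every grid cell, the exact fraction of the cell's area
#' covered by the union of the supplied rectangles. Used for area-weighted
#' (fractional) protected-area coverage.
#'
#' @param rects a rectangle table (see [cg_rects()]).
#' @param grid a [cg_grid()].
#' @return an `nx` by `ny` numeric matrix of fractions in `[0, 1]`;
#'   element `[i, j]` is the cell in column `i` (x) and row `j` (y).
#' @export
coverage_fraction <- function(rects, grid) {
  out <- matrix(0, nrow = grid$nx, ncol = grid$ny)
  if (nrow(rects) == 0) return(out)
  validate_rects(rects)
  ext <- grid_extent(grid)
  gx <- ext["xmin"] + (0:grid$nx) * grid$cell_km
  gy <- ext["ymin"] + (0:grid$ny) * grid$cell_km
  # clip rectangles to the grid extent; drop those outside
  r <- rects
  r$xmin <- pmax(r$xmin, ext["xmin"]); r$xmax <- pmin(r$xmax, ext["xmax"])
  r$ymin <- pmax(r$ymin, ext["ymin"]); r$ymax <- pmin(r$ymax, ext["ymax"])
  r <- r[r$xmin < r$xmax & r$ymin < r$ymax, , drop = FALSE]
  if (nrow(r) == 0) return(out)
  d <- decompose_grid(r, extra_x = gx, extra_y = gy)
  covered <- cover_mask(r, d)
  if (!any(covered)) return(out)
  ix <- findInterval(d$xc[covered], gx, rightmost.closed = FALSE)
  iy <- findInterval(d$yc[covered], gy, rightmost.closed = FALSE)
  ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  a <- d$area[covered][ok]
  lin <- (iy[ok] - 1L) * grid$nx + ix[ok]
  agg <- rowsum(a, group = lin)
  out[as.integer(rownames(agg))] <- agg
  out / cell_area_km2(grid)
}

#' Cell-centre membership of a rectangle union
#'
#' Rasterizes a rectangle union by cell-centre membership: a cell belongs
#' to the geometry iff its centre lies inside some rectangle (half-open
#' test, consistent with the grid's cell convention). This is the
#' rasterization rule used for species ranges.
#'
#' @inheritParams coverage_fraction
#' @return an `nx` by `ny` logical matrix.
#' @export
cells_in_rects <- function(rects, grid) {
  out <- matrix(FALSE, nrow = grid$nx, ncol = grid$ny)
  if (nrow(rects) == 0) return(out)
  validate_rects(rects)
  xc <- cell_centers_x(grid); yc <- cell_centers_y(grid)
  for (k in seq_len(nrow(rects))) {
    inx <- xc >= rects$xmin[k] & xc < rects$xmax[k]
    iny <- yc >= rects$ymin[k] & yc < rects$ymax[k]
    if (any(inx) && any(iny)) out[inx, iny] <- TRUE
  }
  out
}

#' Distance from points to a rectangle union
#'
#' Euclidean distance from each point to the nearest rectangle (0 for
#' points inside one). Used by the occurrence-point buffer test.
#'
#' @param x,y point coordinates (km), equal length.
#' @param rects a rectangle table.
#' @return numeric vector of distances (km); `Inf` when `rects` is empty.
#' @export
point_rect_distance <- function(x, y, rects) {
  stopifnot(length(x) == length(y))
  if (nrow(rects) == 0) return(rep(Inf, length(x)))
  validate_rects(rects)
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(rects))) {
    dx <- pmax(rects$xmin[k] - x, 0, x - rects$xmax[k])
    dy <- pmax(rects$ymin[k] - y, 0, y - rects$ymax[k])
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}
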