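#' Voronoi cell areas of all cones
#'
#' Computes the global Voronoi (Dirichlet) tessellation of all cone centers
#' and returns the cell area of each cone. Cones whose cells are unbounded
#' (cells clipped by the tessellation window around the convex hull) are
#' flagged instead of being assigned a meaningful area; density queries that
#' would use them are invalidated downstream rather than biased by clipping.
#'
#' @param mosaic A [cone_mosaic] with at least 4 non-collinear cones.
#' @return A list with `areas` (um^2 per cone, `NA` where unbounded) and
#'   `unbounded` (logical per cone).
#' @export
voronoi_cell_areas <- function(mosaic) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  x <- mosaic$x; y <- mosaic$y
  n <- length(x)
  if (n < 4) stop("at least 4 cones are required for a Voronoi tessellation")
  if (abs(stats::cor(x, y)) > 1 - 1e-12 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cones are collinear; Voronoi tessellation is degenerate")
  dd <- deldir::deldir(x, y)
  areas <- dd$summary$dir.area
  # tiles clipped by the enclosing rectangular window have a tessellation
  # segment endpoint on the window boundary
  sg <- dd$dirsgs
  touched <- unique(c(sg$ind1[sg$bp1 | sg$bp2], sg$ind2[sg$bp1 | sg$bp2]))
  unbounded <- rep(FALSE, n)
  unbounded[touched] <- TRUE
  # guard: points on the convex hull always have unbounded cells
  hull <- grDevices::chull(x, y)
  unbounded[hull] <- TRUE
  areas[unbounded] <- NA_real_
  list(areas = areas, unbounded = unbounded)
}

# Vectorized k-nearest-cone Voronoi density (cones/mm^2) at query points.
# `cells` may be precomputed with voronoi_cell_areas().
knn_voronoi_density <- function(px, py, mosaic, k = 150, cells = NULL) {
  if (is.null(cells)) cells <- voronoi_cell_areas(mosaic)
  if (n_cones(mosaic) < k)
    stop(sprintf("mosaic has %d cones; k = %d nearest cones required",
                 n_cones(mosaic), k))
  nn <- RANN::nn2(cbind(mosaic$x, mosaic$y), cbind(px, py), k = k)
  a <- matrix(cells$areas[nn$nn.idx], nrow = length(px))
  tot <- rowSums(a)                     # NA if any selected cell unbounded
  k / tot * 1e6
}

#' Cone density at a point
#'
#' The 150-nearest-cone Voronoi density estimate: the `k` cones nearest to
#' the query point are selected by Euclidean distance and the density is
#' `k` divided by the total area of their Voronoi cells (equivalently, the
#' reciprocal mean cell area), in cones/mm^2. If any selected cell is
#' unbounded the point lies outside the reliable region and `NA` is
#' returned.
#'
#' @param p Numeric length-2 point `(x, y)` in um, or a two-column matrix of
#'   points.
#' @param mosaic A [cone_mosaic].
#' @param k Number of nearest cones (default 150).
#' @param cells Optional precomputed result of [voronoi_cell_areas()].
#' @return Density (cones/mm^2), `NA` where undefined.
#' @export
density_at_point <- function(p, mosaic, k = 150, cells = NULL) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  if (is.matrix(p)) knn_voronoi_density(p[, 1], p[, 2], mosaic, k, cells)
  else knn_voronoi_density(p[1], p[2], mosaic, k, cells)
}

#' Continuous cone density map
#'
#' Evaluates the k-nearest-cone Voronoi density on a regular grid. Grid
#' points whose estimate would involve an unbounded Voronoi cell are marked
#' invalid.
#'
#' @param mosaic A [cone_mosaic].
#' @param grid_spacing Grid spacing (um), default 1.
#' @param xlim,ylim Grid limits (um); default the coordinate bounding box.
#' @param k Number of nearest cones (default 150).
#' @return An object of class `density_map` with fields `x`, `y` (grid node
#'   coordinates), `values` (matrix `[i, j]` = density at `(x[i], y[j])`,
#'   `NA` where invalid), `valid` (logical matrix), `spacing`, `laterality`.
#' @export
compute_density_map <- function(mosaic, grid_spacing = 1,
                                xlim = NULL, ylim = NULL, k = 150) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  stop_if_not_number(grid_spacing, "grid_spacing", lower = 0,
                     strict_lower = TRUE)
  xlim <- xlim %||% range(mosaic$x)
  ylim <- ylim %||% range(mosaic$y)
  gx <- seq(xlim[1], xlim[2], by = grid_spacing)
  gy <- seq(ylim[1], ylim[2], by = grid_spacing)
  cells <- voronoi_cell_areas(mosaic)
  vals <- matrix(NA_real_, nrow = length(gx), ncol = length(gy))
  # chunk the grid queries to bound the k-NN index matrix memory
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  chunk <- 50000L
  for (start in seq(1L, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    vals[idx] <- knn_voronoi_density(grid[idx, 1], grid[idx, 2],
                                     mosaic, k, cells)
  }
  structure(list(x = gx, y = gy, values = vals, valid = is.finite(vals),
                 spacing = grid_spacing, laterality = mosaic$laterality),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map: %d x %d grid at %g um spacing; %.1f%% valid; max %.0f cones/mm^2\n",
              length(x$x), length(x$y), x$spacing,
              100 * mean(x$valid),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

# Bilinear interpolation of a density map at arbitrary points; NA if any
# surrounding node is invalid or the point is outside the grid.
map_interp <- function(map, px, py) {
  fx <- (px - map$x[1]) / map$spacing
  fy <- (py - map$y[1]) / map$spacing
  i <- floor(fx); j <- floor(fy)
  out <- rep(NA_real_, length(px))
  ok <- i >= 0 & j >= 0 & i <= length(map$x) - 2 & j <= length(map$y) - 2
  # clamp points sitting exactly on the top edge back into the last cell
  top_x <- abs(fx - (length(map$x) - 1)) < 1e-9
  top_y <- abs(fy - (length(map$y) - 1)) < 1e-9
  i[top_x] <- length(map$x) - 2; ok[top_x & j >= 0 & j <= length(map$y) - 2] <- TRUE
  j[top_y] <- length(map$y) - 2
  ok <- ok & i >= 0 & j >= 0 & i <= length(map$x) - 2 & j <= length(map$y) - 2
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  tx <- fx[ok] - i; ty <- fy[ok] - j
  v00 <- map$values[cbind(i + 1, j + 1)]
  v10 <- map$values[cbind(i + 2, j + 1)]
  v01 <- map$values[cbind(i + 1, j + 2)]
  v11 <- map$values[cbind(i + 2, j + 2)]
  out[ok] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

# 8-connected component of `mask` containing linear index `start_idx`.
connected_component <- function(mask, start_idx) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  if (!mask[start_idx]) return(comp)
  comp[start_idx] <- TRUE
  frontier <- start_idx
  off <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
  row_of <- function(idx) ((idx - 1) %% nr) + 1
  while (length(frontier)) {
    cand_all <- as.vector(outer(frontier, off, `+`))
    r0 <- rep(row_of(frontier), times = 8)
    keep <- cand_all >= 1 & cand_all <= nr * nc &
      abs(row_of(cand_all) - r0) <= 1
    cand <- unique(cand_all[keep])
    cand <- cand[mask[cand] & !comp[cand]]
    comp[cand] <- TRUE
    frontier <- cand
  }
  comp
}

#' Topography metrics: PCD, CDC, D0, top-20% iso-density area
#'
#' Locates the peak cone density (PCD, the single highest valid map value)
#' and the cone density centroid (CDC): the density-weighted centroid of the
#' connected region of grid points with density at least 80% of the PCD that
#' contains the PCD. `d0` is the map density at the CDC (bilinear
#' interpolation) and `isoa_top20` the area of the top-20% region.
#'
#' @param map A `density_map` (see [compute_density_map()]).
#' @return An object of class `topography_metrics` with fields `pcd`,
#'   `pcd_location`, `cdc_location`, `d0`, `isoa_top20` (um^2) and
#'   `border_warning` (`TRUE` when the top-20% region touches the valid-map
#'   border, indicating possible truncation).
#' @export
compute_cdc <- function(map) {
  stopifnot(inherits(map, "density_map"))
  if (!any(map$valid)) stop("density map has no valid points")
  pcd <- max(map$values[map$valid])
  pidx <- which(map$values == pcd & map$valid)[1]
  mask <- map$valid & !is.na(map$values) & map$values >= 0.8 * pcd
  mask[is.na(mask)] <- FALSE
  comp <- connected_component(mask, pidx)
  idx <- which(comp, arr.ind = TRUE)
  w <- map$values[comp]
  cx <- sum(map$x[idx[, 1]] * w) / sum(w)
  cy <- sum(map$y[idx[, 2]] * w) / sum(w)
  # border check: component pixel on grid edge or adjacent to invalid node
  nr <- nrow(comp); nc <- ncol(comp)
  on_edge <- any(idx[, 1] %in% c(1, nr)) || any(idx[, 2] %in% c(1, nc))
  if (!on_edge) {
    nbr_invalid <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nbr_invalid <- nbr_invalid ||
        any(!map$valid[cbind(idx[, 1] + di, idx[, 2] + dj)])
    }
    on_edge <- nbr_invalid
  }
  d0 <- map_interp(map, cx, cy)
  pr <- which(map$values == pcd & map$valid, arr.ind = TRUE)[1, ]
  structure(list(pcd = pcd,
                 pcd_location = c(map$x[pr[1]], map$y[pr[2]]),
                 cdc_location = c(cx, cy),
                 d0 = d0,
                 isoa_top20 = sum(comp) * map$spacing^2,
                 border_warning = on_edge),
            class = "topography_metrics")
}

#' @export
print.topography_metrics <- function(x, ...) {
  cat(sprintf("PCD = %.0f cones/mm^2 at (%.1f, %.1f) um\n",
              x$pcd, x$pcd_location[1], x$pcd_location[2]))
  cat(sprintf("CDC at (%.2f, %.2f) um; D0 = %.0f cones/mm^2 (%.2f%% below PCD)\n",
              x$cdc_location[1], x$cdc_location[2], x$d0,
              100 * (1 - x$d0 / x$pcd)))
  cat(sprintf("top-20%% iso-density area: %.0f um^2%s\n", x$isoa_top20,
              if (x$border_warning) " [touches map border]" else ""))
  invisible(x)
}

# extent of the contiguous super-level run through a point along one axis
line_extent <- function(map, level, cdc, horizontal = TRUE) {
  step <- map$spacing / 4
  if (horizontal) {
    lim <- range(map$x); s <- seq(lim[1], lim[2], by = step)
    v <- map_interp(map, s, rep(cdc[2], length(s)))
    pos <- s; at <- cdc[1]
  } else {
    lim <- range(map$y); s <- seq(lim[1], lim[2], by = step)
    v <- map_interp(map, rep(cdc[1], length(s)), s)
    pos <- s; at <- cdc[2]
  }
  above <- !is.na(v) & v >= level
  i0 <- which.min(abs(pos - at))
  if (!above[i0]) stop("point is not inside the requested super-level region")
  lo <- i0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(pos) && above[hi + 1]) hi <- hi + 1
  # refine crossings by linear interpolation
  left <- if (lo > 1 && !is.na(v[lo - 1]))
    pos[lo - 1] + (level - v[lo - 1]) / (v[lo] - v[lo - 1]) * step
  else pos[lo]
  right <- if (hi < length(pos) && !is.na(v[hi + 1]))
    pos[hi] + (v[hi] - level) / (v[hi] - v[hi + 1]) * step
  else pos[hi]
  right - left
}

#' Iso-density contour area and aspect ratio
#'
#' Area of the connected super-level region (density `>= level`) containing
#' the CDC, and the contour aspect ratio: the horizontal extent of the
#' region along the line through the CDC divided by the vertical extent.
#'
#' @param map A `density_map`.
#' @param level Density level (cones/mm^2), strictly between the valid map
#'   minimum and maximum.
#' @param cdc CDC location `(x, y)` in um (see [compute_cdc()]).
#' @return List with `area` (um^2) and `aspect_ratio`.
#' @export
iso_density_contour_metrics <- function(map, level, cdc) {
  stopifnot(inherits(map, "density_map"))
  vr <- range(map$values[map$valid])
  if (level <= vr[1] || level >= vr[2])
    stop(sprintf("level %g outside the valid map range (%g, %g)",
                 level, vr[1], vr[2]))
  ci <- which.min(abs(map$x - cdc[1]))
  cj <- which.min(abs(map$y - cdc[2]))
  mask <- map$valid & !is.na(map$values) & map$values >= level
  mask[is.na(mask)] <- FALSE
  start <- (cj - 1) * nrow(mask) + ci
  if (!mask[start]) stop("CDC is not inside any super-level region at this level")
  comp <- connected_component(mask, start)
  list(area = sum(comp) * map$spacing^2,
       aspect_ratio = line_extent(map, level, cdc, TRUE) /
         line_extent(map, level, cdc, FALSE))
}

#' Count cones in a circle or annulus
#'
#' Number of cones with `r_inner <= distance(center) < r_outer`.
#'
#' @param mosaic A [cone_mosaic].
#' @param center Center `(x, y)` in um.
#' @param r_inner,r_outer Annulus radii (um), `0 <= r_inner < r_outer`
#'   (`r_outer` may be `Inf`).
#' @return Integer count.
#' @export
cones_in_region <- function(mosaic, center = c(0, 0), r_inner = 0,
                            r_outer = Inf) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  if (r_inner < 0 || r_inner >= r_outer)
    stop("require 0 <= r_inner < r_outer")
  r <- sqrt((mosaic$x - center[1])^2 + (mosaic$y - center[2])^2)
  sum(r >= r_inner & r < r_outer)
}
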