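#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' Ray-casting containment test used to classify CT voxel centers against
#' per-slice contour polygons. Points lying exactly on a polygon edge or
#' vertex are classified inside, which makes voxel labeling deterministic
#' when contours pass through voxel centers.
#'
#' @param px,py Numeric vectors of point coordinates (mm).
#' @param poly Two-column matrix of polygon vertices (closed implicitly).
#' @return Logical vector, `TRUE` for points inside or on the boundary.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  out <- logical(length(px))
  for (p in seq_along(px)) {
    x <- px[p]; y <- py[p]
    inside <- FALSE
    on_edge <- FALSE
    for (e in seq_len(n)) {
      x1 <- xs[e]; y1 <- ys[e]; x2 <- xe[e]; y2 <- ye[e]
      # boundary: point collinear with and within the segment's bbox
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) {
        on_edge <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) inside <- !inside
      }
    }
    out[p] <- on_edge || inside
  }
  out
}

polygon_area_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    return(list(area = 0, centroid = c(mean(x), mean(y))))
  }
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}

#' Summarize structures of an RT structure set
#'
#' For each structure, computes the area-weighted centroid of its per-slice
#' contour polygons (slice areas weight the slice centroids, so equal
#' disjoint parts average symmetrically) and the bounding box over all
#' contour points. Structures without contour points are flagged degenerate
#' and carry NA geometry; callers exclude them from geometric checks.
#'
#' @param structures List of structures, each a list with `name`, `role`
#'   (`External`, `Target`, `OAR` or `Other`), `approval`, and `contours`
#'   (list of `list(z =, xy = <n x 2 matrix>)`).
#' @return data.frame: name, role, approval, degenerate, centroid_x/y/z,
#'   bbox_min_x/y/z, bbox_max_x/y/z (mm).
#' @export
#' @examples
#' ph <- generate_ct_phantom()
#' summarize_structures(list(ph$external))
summarize_structures <- function(structures) {
  rows <- lapply(structures, function(st) {
    role <- match.arg(st$role, c("External", "Target", "OAR", "Other"))
    pts <- do.call(rbind, lapply(st$contours, function(ct) {
      if (is.null(ct$xy) || nrow(ct$xy) == 0L) return(NULL)
      cbind(ct$xy, ct$z)
    }))
    if (is.null(pts) || nrow(pts) == 0L) {
      return(data.frame(name = st$name, role = role,
                        approval = isTRUE(st$approval), degenerate = TRUE,
                        centroid_x = NA_real_, centroid_y = NA_real_,
                        centroid_z = NA_real_,
                        bbox_min_x = NA_real_, bbox_min_y = NA_real_,
                        bbox_min_z = NA_real_, bbox_max_x = NA_real_,
                        bbox_max_y = NA_real_, bbox_max_z = NA_real_,
                        stringsAsFactors = FALSE))
    }
    per_slice <- lapply(st$contours, function(ct) {
      if (is.null(ct$xy) || nrow(ct$xy) < 3L) return(NULL)
      ac <- polygon_area_centroid(ct$xy)
      c(ac$area, ac$centroid, ct$z)
    })
    per_slice <- do.call(rbind, per_slice)
    w <- per_slice[, 1]
    if (sum(w) <= 0) w <- rep(1, length(w))  # degenerate-area fallback: plain mean
    centroid <- c(sum(w * per_slice[, 2]), sum(w * per_slice[, 3]),
                  sum(w * per_slice[, 4])) / sum(w)
    data.frame(name = st$name, role = role, approval = isTRUE(st$approval),
               degenerate = FALSE,
               centroid_x = centroid[1], centroid_y = centroid[2],
               centroid_z = centroid[3],
               bbox_min_x = min(pts[, 1]), bbox_min_y = min(pts[, 2]),
               bbox_min_z = min(pts[, 3]), bbox_max_x = max(pts[, 1]),
               bbox_max_y = max(pts[, 2]), bbox_max_z = max(pts[, 3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum HU inside and outside the External contour
#'
#' Labels every voxel of a CT grid as inside or outside the External (body)
#' structure by testing the voxel center against the contour polygon of the
#' nearest slice (contours are matched to slices within half a slice
#' thickness; boundary points count as inside), then reports the maximum HU
#' in each region. Slices with no matched contour are entirely outside.
#'
#' @param ct CT grid: list with `volume` (3D HU array), `origin`, `spacing`
#'   (mm), as produced by [generate_ct_phantom()].
#' @param external Structure with per-slice `contours`; must be the
#'   External/body outline.
#' @return List `max_hu_inside`, `max_hu_outside` (`NA` when the outside
#'   region is empty, i.e. the External covers the whole grid).
#' @export
compute_hu_stats <- function(ct, external) {
  if (is.null(external) || is.null(external$contours) ||
      length(external$contours) == 0L) {
    stop("compute_hu_stats: no External contour; check cannot run",
         call. = FALSE)
  }
  dims <- dim(ct$volume)
  xs <- ct$origin[1] + (seq_len(dims[1]) - 1) * ct$spacing[1]
  ys <- ct$origin[2] + (seq_len(dims[2]) - 1) * ct$spacing[2]
  zs <- ct$origin[3] + (seq_len(dims[3]) - 1) * ct$spacing[3]
  half_dz <- ct$spacing[3] / 2
  contour_z <- vapply(external$contours, `[[`, 0, "z")
  grid_xy <- expand.grid(x = xs, y = ys)  # column-major, matches volume[, , k]
  inside_any <- array(FALSE, dim = dims)
  for (k in seq_len(dims[3])) {
    dz <- abs(contour_z - zs[k])
    if (min(dz) > half_dz + 1e-9) next
    matched <- which(dz <= min(dz) + 1e-9)
    mask <- rep(FALSE, nrow(grid_xy))
    for (m in matched) {
      poly <- external$contours[[m]]$xy
      if (is.null(poly) || nrow(poly) < 3L) next
      mask <- mask | point_in_polygon(grid_xy$x, grid_xy$y, poly)
    }
    inside_any[, , k] <- mask
  }
  inside_vals <- ct$volume[inside_any]
  outside_vals <- ct$volume[!inside_any]
  list(
    max_hu_inside = if (length(inside_vals)) max(inside_vals) else NA_real_,
    max_hu_outside = if (length(outside_vals)) max(outside_vals) else NA_real_
  )
}

# axis-aligned bounding box of a grid (outer voxel edges), used by the
# dose-grid coverage check
grid_bbox <- function(grid) {
  dims <- dim(if (!is.null(grid$values)) grid$values else grid$volume)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (dims - 1) * grid$spacing + grid$spacing / 2
  list(min = lo, max = hi)
}
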