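# 3-D convex hull, planar sections and voxelized volume.
#
# Incremental hull over the (small) organ point grids: start from an extreme
# tetrahedron, then for each remaining point replace the visible faces by a
# fan over the horizon edges. Faces are kept outward-oriented relative to an
# interior point, which makes volume, containment and slicing direct.

#' 3-D convex hull of a point set
#'
#' @param points An N x 3 numeric matrix (N >= 4, not all coplanar).
#' @param tol Relative degeneracy tolerance.
#' @return A `hull3d` object: `points` (the input), `faces` (M x 3 vertex
#'   index matrix, outward-oriented), `normals`/`offsets` (the face plane
#'   equations `normal . p = offset`), `vertices` (indices of hull vertices)
#'   and `volume`.
#' @export
convex_hull_3d <- function(points, tol = 1e-9) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("convex_hull_3d: points must be N x 3")
  n <- nrow(pts)
  if (n < 4) stop("convex_hull_3d: need at least 4 points, got ", n)
  scale <- max(abs(pts), 1)
  eps <- tol * scale

  # Initial simplex from extreme points.
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < eps^2) stop("convex_hull_3d: all points coincide")
  e1 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * e1[3] - rel[, 3] * e1[2],
              rel[, 3] * e1[1] - rel[, 1] * e1[3],
              rel[, 1] * e1[2] - rel[, 2] * e1[1])
  d2 <- rowSums(cr^2)
  i3 <- which.max(d2)
  if (d2[i3] < (eps^2) * sum(e1^2)) stop("convex_hull_3d: points are collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  d3 <- abs(rel %*% nrm)
  i4 <- which.max(d3)
  if (d3[i4] < eps * sqrt(sum(nrm^2))) stop("convex_hull_3d: points are coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, pts = pts, interior = interior))

  used <- c(i1, i2, i3, i4)
  for (p in setdiff(seq_len(n), used)) {
    dists <- face_signed_dist(pts[p, ], pts, faces)
    visible <- which(dists > eps)
    if (!length(visible)) next
    # Horizon: edges of visible faces shared with a non-visible face (or
    # unshared), each spawning a new face with the apex p.
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    all_edges <- list()
    for (fi in seq_len(nrow(faces))) {
      fvis <- fi %in% visible
      f <- faces[fi, ]
      for (e in list(f[c(1, 2)], f[c(2, 3)], f[c(1, 3)])) {
        k <- edge_key(e[1], e[2])
        rec <- all_edges[[k]]
        if (is.null(rec)) rec <- c(0L, 0L)
        rec[if (fvis) 1 else 2] <- rec[if (fvis) 1 else 2] + 1L
        all_edges[[k]] <- rec
      }
    }
    horizon <- names(all_edges)[vapply(all_edges, function(rec) rec[1] == 1L, TRUE)]
    faces <- faces[-visible, , drop = FALSE]
    new_faces <- t(vapply(horizon, function(k) {
      v <- as.integer(strsplit(k, " ")[[1]])
      orient_face(c(v, p), pts, interior)
    }, integer(3)))
    faces <- rbind(faces, new_faces)
  }

  normals <- matrix(NA_real_, nrow(faces), 3)
  offsets <- numeric(nrow(faces))
  for (fi in seq_len(nrow(faces))) {
    f <- faces[fi, ]
    nv <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nv <- nv / sqrt(sum(nv^2))
    normals[fi, ] <- nv
    offsets[fi] <- sum(nv * pts[f[1], ])
  }
  vol <- 0
  for (fi in seq_len(nrow(faces))) {
    f <- faces[fi, ]
    a <- pts[f[1], ] - interior; b <- pts[f[2], ] - interior; c3 <- pts[f[3], ] - interior
    vol <- vol + abs(sum(a * cross3(b, c3))) / 6
  }
  h <- list(points = pts, faces = faces, normals = normals, offsets = offsets,
            vertices = sort(unique(as.vector(faces))), volume = vol,
            interior = interior, tol = eps)
  class(h) <- "hull3d"
  h
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Reorder a face's vertex triple so its normal points away from `interior`.
orient_face <- function(f, pts, interior) {
  nv <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  if (sum(nv * (pts[f[1], ] - interior)) < 0) f[c(1, 3)] <- f[c(3, 1)]
  as.integer(f)
}

face_signed_dist <- function(p, pts, faces) {
  vapply(seq_len(nrow(faces)), function(fi) {
    f <- faces[fi, ]
    nv <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    sum(nv * (p - pts[f[1], ])) / sqrt(sum(nv^2))
  }, 0)
}

#' Test points for containment in a convex hull
#'
#' @param hull A `hull3d`.
#' @param points An N x 3 matrix.
#' @param tol Absolute tolerance (same units as the hull).
#' @return Logical vector: `TRUE` where the point is inside or on the hull.
#' @export
point_in_hull <- function(hull, points, tol = 1e-9) {
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || length(pts) == 3) pts <- matrix(pts, 1, 3)
  d <- pts %*% t(hull$normals)
  apply(sweep(d, 2, hull$offsets) <= tol, 1, all)
}

# Unique undirected edges of the hull, as a 2-column index matrix.
hull_edges <- function(hull) {
  e <- rbind(hull$faces[, c(1, 2)], hull$faces[, c(2, 3)], hull$faces[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

#' Planar section of a convex hull
#'
#' Intersects the hull with the plane `coordinate[axis] = level` and returns
#' the convex cross-section polygon (vertices ordered counter-clockwise in
#' the remaining two coordinates), or `NULL` for an empty or degenerate
#' (tangent) intersection.
#'
#' @param hull A `hull3d`.
#' @param level Plane position along `axis`.
#' @param axis Which coordinate is fixed (default 3).
#' @return A K x 2 matrix of polygon vertices, or `NULL`.
#' @export
hull_section <- function(hull, level, axis = 3) {
  pts <- hull$points
  keep <- setdiff(1:3, axis)
  edges <- hull_edges(hull)
  sect <- matrix(numeric(0), 0, 2)
  for (ei in seq_len(nrow(edges))) {
    e <- edges[ei, ]
    a <- pts[e[1], ]; b <- pts[e[2], ]
    da <- a[axis] - level; db <- b[axis] - level
    if (abs(da) < hull$tol && abs(db) < hull$tol) {
      sect <- rbind(sect, a[keep], b[keep])
    } else if (abs(da) < hull$tol) {
      sect <- rbind(sect, a[keep])
    } else if (abs(db) < hull$tol) {
      sect <- rbind(sect, b[keep])
    } else if (da * db < 0) {
      t <- da / (da - db)
      sect <- rbind(sect, (a + t * (b - a))[keep])
    }
  }
  if (!nrow(sect)) return(NULL)
  sect <- unique(round(sect, 9))
  if (nrow(sect) < 3) return(NULL)
  ord <- grDevices::chull(sect[, 1], sect[, 2]) # clockwise in chull's convention
  poly <- sect[rev(ord), , drop = FALSE]        # reverse -> counter-clockwise
  if (nrow(poly) < 3 || abs(polygon_area(poly)) < hull$tol^2) return(NULL)
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

# Signed area (shoelace); positive for counter-clockwise winding.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Voxelized volume of a convex hull
#'
#' Counts voxel centres inside the hull on a grid anchored at the hull's
#' bounding-box minimum (centres at `min + (i + 0.5) * voxel`).
#'
#' @param hull A `hull3d` (coordinates in mm).
#' @param voxel Voxel edge length (mm).
#' @return Estimated volume in the cube of the hull's length unit.
#' @export
voxelized_hull_volume <- function(hull, voxel = 1) {
  stopifnot(voxel > 0)
  lims <- apply(hull$points, 2, range)
  centers <- lapply(1:3, function(j) {
    k <- ceiling((lims[2, j] - lims[1, j]) / voxel)
    if (k < 1) k <- 1
    lims[1, j] + (seq_len(k) - 0.5) * voxel
  })
  if (prod(lengths(centers)) > 5e7) {
    stop("voxel grid too large (", prod(lengths(centers)),
         " voxels); use a coarser voxel size")
  }
  grid <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
  sum(point_in_hull(hull, grid, tol = 1e-9)) * voxel^3
}
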