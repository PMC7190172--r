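#' Triangulated scalp surface with labeled fiducials
#'
#' A `head_surface` holds the skin-air boundary of a head as a triangle mesh
#' (vertices in mm, 1-based triangle index rows) together with the three
#' anatomical fiducials — nasion, left and right preauricular points — given
#' in the same (MRI) coordinate frame as the vertices. Fiducials may be
#' absent (`NULL`); operations that need them fail explicitly.
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param triangles M x 3 integer matrix of 1-based vertex indices.
#' @param fiducials `NULL`, or a named list with numeric length-3 entries
#'   `nasion`, `lpa`, `rpa` (mm, same frame as `vertices`).
#' @param check_fiducials if `TRUE` (default) require every fiducial to lie
#'   within 2 mm of the surface. Set to `FALSE` for de-faced surfaces, whose
#'   nasion may have been cut away.
#' @return an object of class `head_surface`.
#' @export
head_surface <- function(vertices, triangles, fiducials = NULL,
                         check_fiducials = TRUE) {
  vertices <- as_points_matrix(vertices)
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3) stop("triangles must be an M x 3 index matrix")
  storage.mode(triangles) <- "integer"
  if (nrow(triangles) < 1) stop("empty mesh")
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("triangle indices out of range")
  }
  areas <- triangle_areas(vertices, triangles)
  if (any(areas <= 1e-9)) stop("mesh contains degenerate (zero-area) triangles")
  s <- structure(list(vertices = vertices, triangles = triangles,
                      fiducials = NULL),
                 class = "head_surface")
  if (!is.null(fiducials)) {
    fiducials <- validate_fiducials(fiducials)
    if (isTRUE(check_fiducials)) {
      d <- nearest_surface_distances(do.call(rbind, fiducials), s)$distances
      if (any(d > 2)) {
        stop("fiducials must lie within 2 mm of the surface (worst: ",
             sprintf("%.2f", max(d)), " mm)")
      }
    }
    s$fiducials <- fiducials
  }
  s
}

validate_fiducials <- function(fiducials) {
  need <- c("nasion", "lpa", "rpa")
  if (!is.list(fiducials) || !all(need %in% names(fiducials))) {
    stop("fiducials must name nasion, lpa and rpa")
  }
  fiducials <- fiducials[need]
  ok <- vapply(fiducials, function(p) is.numeric(p) && length(p) == 3 &&
                 all(is.finite(p)), logical(1))
  if (!all(ok)) stop("each fiducial must be a finite length-3 coordinate")
  lapply(fiducials, as.numeric)
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  u <- vertices[triangles[, 2], , drop = FALSE] - a
  v <- vertices[triangles[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.head_surface <- function(x, ...) {
  cat(sprintf("<head_surface> %d vertices, %d triangles, fiducials %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$fiducials)) "absent" else "nasion/lpa/rpa"))
  invisible(x)
}

#' Digitized headshape point set
#'
#' Points recorded with a 3-D digitizer during MEG preparation, in head
#' coordinates (mm), each labeled by role: `fiducial` (nasion, lpa, rpa),
#' `hpi` (head-position indicator coil) or `headshape` (scalp point).
#' Only headshape-role points enter ICP fitting and the error metric.
#'
#' @param points n x 3 numeric matrix (mm, head frame).
#' @param roles character vector, one of `"fiducial"`, `"hpi"`,
#'   `"headshape"` per point.
#' @param fiducial_labels for the fiducial-role points, their labels in
#'   order of appearance; must contain exactly one each of `"nasion"`,
#'   `"lpa"`, `"rpa"`.
#' @return an object of class `headshape_set` with element `n` holding the
#'   headshape-role point count.
#' @export
headshape_set <- function(points, roles,
                          fiducial_labels = c("nasion", "lpa", "rpa")) {
  points <- as_points_matrix(points)
  roles <- as.character(roles)
  if (length(roles) != nrow(points)) stop("one role per point required")
  if (!all(roles %in% c("fiducial", "hpi", "headshape"))) {
    stop("roles must be fiducial, hpi or headshape")
  }
  if (sum(roles == "headshape") < 1) stop("need at least one headshape point")
  nfid <- sum(roles == "fiducial")
  if (nfid != 3 || !setequal(fiducial_labels, c("nasion", "lpa", "rpa")) ||
      length(fiducial_labels) != 3) {
    stop("need exactly one nasion, one lpa and one rpa fiducial")
  }
  structure(list(points = points, roles = roles,
                 fiducial_labels = as.character(fiducial_labels),
                 n = sum(roles == "headshape")),
            class = "headshape_set")
}

#' @export
print.headshape_set <- function(x, ...) {
  cat(sprintf("<headshape_set> %d headshape points, %d hpi, 3 fiducials\n",
              x$n, sum(x$roles == "hpi")))
  invisible(x)
}

# fiducial-role points as a named 3 x 3 matrix-ish list
headshape_fiducials <- function(hs) {
  idx <- which(hs$roles == "fiducial")
  stats::setNames(lapply(seq_along(idx),
                         function(i) hs$points[idx[i], ]),
                  hs$fiducial_labels)
}

headshape_points <- function(hs) {
  hs$points[hs$roles == "headshape", , drop = FALSE]
}

#' Exact distance from points to a triangle mesh
#'
#' For each query point, returns the Euclidean distance to the nearest point
#' anywhere on the surface — triangle interiors, edges and vertices all
#' considered — not merely the nearest vertex. Candidate triangles are pruned
#' with per-triangle bounding spheres; the pruning is lossless, so the result
#' equals an exhaustive scan over all triangles.
#'
#' @param points k x 3 numeric matrix of query coordinates (mm), in the same
#'   frame as the surface.
#' @param surface a `head_surface`.
#' @return a list with `distances` (length k, mm, >= 0) and `closest`
#'   (k x 3 matrix of nearest surface coordinates).
#' @export
nearest_surface_distances <- function(points, surface) {
  stopifnot(inherits(surface, "head_surface"))
  points <- as_points_matrix(points)
  if (nrow(points) < 1) stop("empty point set")
  cpp_nearest_on_mesh(points, surface$vertices, surface$triangles - 1L)
}

#' Head coordinate frame defined by the fiducials
#'
#' Builds the rigid transform taking coordinates from the frame the
#' fiducials are expressed in (e.g. MRI) into the MEG head frame: origin at
#' the midpoint of the preauricular points, +x toward the right preauricular
#' point, +y toward the nasion (orthogonalized), +z superior.
#'
#' @param fiducials named list with `nasion`, `lpa`, `rpa` coordinates (mm).
#' @return a `rigid_transform` (fiducial frame -> head frame).
#' @export
fiducial_frame <- function(fiducials) {
  f <- validate_fiducials(fiducials)
  origin <- (f$lpa + f$rpa) / 2
  ex <- f$rpa - f$lpa
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9) stop("preauricular points coincide")
  ex <- ex / nx
  ey <- f$nasion - origin
  ey <- ey - sum(ey * ex) * ex
  ny <- sqrt(sum(ey^2))
  if (ny < 1e-9) stop("nasion lies on the interaural axis")
  ey <- ey / ny
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)  # rows are head-frame axes in fiducial-frame coords
  dimnames(R) <- NULL
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- -R %*% origin
  rigid_transform(m)
}

#' Geometric de-facing of a head surface
#'
#' Emulates volume de-facing tools at the surface level: all vertices inside
#' the face block — further forward than 10 mm behind the nasion and lower
#' than 20 mm above it, measured in the fiducial-aligned head frame — are
#' removed together with their incident triangles. The nasion itself
#' typically no longer lies on the surface afterwards; the stored fiducial
#' coordinates are kept so the head frame remains defined.
#'
#' @param surface a `head_surface` with fiducials.
#' @param behind_nasion mm the block extends behind the nasion (default 10).
#' @param above_nasion mm the block extends above the nasion (default 20).
#' @param max_removed_fraction error if more than this fraction of vertices
#'   would be removed (default 0.6), guarding against degenerate geometry.
#' @return a de-faced `head_surface`.
#' @export
deface <- function(surface, behind_nasion = 10, above_nasion = 20,
                   max_removed_fraction = 0.6) {
  stopifnot(inherits(surface, "head_surface"))
  if (is.null(surface$fiducials)) stop("defacing requires fiducials")
  to_head <- fiducial_frame(surface$fiducials)
  vh <- apply_transform(to_head, surface$vertices)
  nas <- drop(apply_transform(to_head, matrix(surface$fiducials$nasion, 1)))
  drop_v <- vh[, 2] > nas[2] - behind_nasion & vh[, 3] < nas[3] + above_nasion
  if (mean(drop_v) > max_removed_fraction) {
    stop("defacing would remove >", round(100 * max_removed_fraction),
         "% of vertices: degenerate head geometry")
  }
  keep <- which(!drop_v)
  remap <- integer(nrow(surface$vertices))
  remap[keep] <- seq_along(keep)
  tri <- surface$triangles
  tri_keep <- !drop_v[tri[, 1]] & !drop_v[tri[, 2]] & !drop_v[tri[, 3]]
  tri <- tri[tri_keep, , drop = FALSE]
  if (nrow(tri) == 0) stop("defacing removed every triangle")
  tri[] <- remap[tri]
  out <- structure(list(vertices = surface$vertices[keep, , drop = FALSE],
                        triangles = tri,
                        fiducials = surface$fiducials),
                   class = "head_surface")
  out
}
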