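#' Rigid-body transforms for MEG-MRI co-registration
#'
#' A `rigid_transform` is a 4x4 homogeneous matrix whose upper-left 3x3 block
#' is a proper rotation (orthonormal, determinant +1) and whose fourth column
#' carries a translation in millimetres. Throughout the package, stored
#' transforms map MRI coordinates into the MEG head coordinate frame (origin
#' midway between the preauricular points, +x toward the right preauricular
#' point, +y toward the nasion, +z superior).
#'
#' @param m a 4x4 numeric matrix.
#' @param tol tolerance for the rigidity checks (orthonormality, unit
#'   determinant, exact bottom row).
#' @return an object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(diag(4))
#' t2 <- recompose(transform_params(tx = 1, pitch = 15))
#' compose(t2, invert(t2))
#' @export
rigid_transform <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m) || any(dim(m) != c(4L, 4L)) ||
      any(!is.finite(m))) {
    stop("rigid_transform requires a finite 4x4 numeric matrix")
  }
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) >= tol) {
    stop("rotation block is not orthonormal: matrix is not rigid")
  }
  if (abs(det(R) - 1) >= 1e-6) {
    stop("rotation block has determinant != +1 (reflection or scaling)")
  }
  if (!all(m[4, ] == c(0, 0, 0, 1))) {
    stop("bottom row must be exactly (0, 0, 0, 1)")
  }
  structure(list(matrix = m), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param x object to test or print.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
as.matrix.rigid_transform <- function(x, ...) x$matrix

#' @export
print.rigid_transform <- function(x, ...) {
  p <- decompose(x)
  cat("<rigid_transform>  (MRI -> head unless stated otherwise)\n")
  cat(sprintf("  translation (mm): x %+.3f  y %+.3f  z %+.3f\n",
              p$tx, p$ty, p$tz))
  cat(sprintf("  rotation  (deg) : pitch %+.3f  roll %+.3f  yaw %+.3f\n",
              p$pitch, p$roll, p$yaw))
  invisible(x)
}

#' Identity rigid transform
#' @return the identity `rigid_transform`.
#' @export
identity_transform <- function() rigid_transform(diag(4))

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first and then `a` (matrix product `a %*% b`).
#' The rotation block is re-orthonormalized through its polar factor so that
#' long chains of compositions cannot drift away from rigidity.
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  m <- a$matrix %*% b$matrix
  m[1:3, 1:3] <- nearest_rotation(m[1:3, 1:3])
  m[4, ] <- c(0, 0, 0, 1)
  rigid_transform(m)
}

#' Invert a rigid transform
#'
#' Uses the closed form inverse of a rigid motion: `R' = t(R)`,
#' `t' = -t(R) %*% t`.
#'
#' @param t a `rigid_transform`.
#' @return a `rigid_transform` such that `compose(t, invert(t))` is the
#'   identity.
#' @export
invert <- function(t) {
  stopifnot(is_rigid_transform(t))
  R <- t$matrix[1:3, 1:3]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -crossprod(R, t$matrix[1:3, 4])
  rigid_transform(m)
}

#' Apply a rigid transform to a set of points
#'
#' @param t a `rigid_transform`.
#' @param points an n x 3 numeric matrix of coordinates (mm).
#' @return an n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(t, points) {
  stopifnot(is_rigid_transform(t))
  points <- as_points_matrix(points)
  sweep(points %*% t(t$matrix[1:3, 1:3]), 2, t$matrix[1:3, 4], "+")
}

# Projects a near-rotation onto SO(3) (polar decomposition via SVD), forcing
# determinant +1.
nearest_rotation <- function(R) {
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3 || !is.numeric(points) || any(!is.finite(points))) {
    stop("points must be a finite n x 3 numeric matrix")
  }
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  points
}

#' Six-parameter description of a rigid transform
#'
#' Bundles translations (mm) and rotations (degrees) about the x, y and z
#' axes — pitch, roll and yaw of the head frame. The Euler convention is
#' extrinsic fixed-axes X-Y-Z: `R = Rz(yaw) Ry(roll) Rx(pitch)`, with roll
#' confined to \[-90, 90\] degrees so the decomposition is unique away from
#' gimbal lock.
#'
#' @param tx,ty,tz translations in mm.
#' @param pitch,roll,yaw rotations in degrees about x, y, z.
#' @return an object of class `transform_params`.
#' @export
transform_params <- function(tx = 0, ty = 0, tz = 0,
                             pitch = 0, roll = 0, yaw = 0) {
  p <- list(tx = tx, ty = ty, tz = tz,
            pitch = pitch, roll = roll, yaw = yaw)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1)))) {
    stop("all six parameters must be finite scalars")
  }
  structure(p, class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf(
    "<transform_params> t = (%.3f, %.3f, %.3f) mm; pitch/roll/yaw = (%.3f, %.3f, %.3f) deg\n",
    x$tx, x$ty, x$tz, x$pitch, x$roll, x$yaw))
  invisible(x)
}

#' Decompose a rigid transform into translations and Euler angles
#'
#' Extracts the six parameters reported in co-registration comparisons:
#' translation in mm along x, y, z and rotation in degrees about x, y, z
#' (pitch, roll, yaw), under the convention `R = Rz(yaw) Ry(roll) Rx(pitch)`.
#' At gimbal lock (`|roll| = 90` degrees, where pitch and yaw are not
#' separately identifiable) yaw is set to 0, pitch absorbs the remaining
#' rotation, and the result is flagged.
#'
#' @param t a `rigid_transform`.
#' @return a `transform_params` object with an extra logical attribute
#'   `gimbal_lock`.
#' @export
decompose <- function(t) {
  stopifnot(is_rigid_transform(t))
  R <- t$matrix[1:3, 1:3]
  if (max(abs(svd(R)$d - 1)) > 1e-6) {
    stop("matrix has singular values away from 1: not a rigid rotation")
  }
  tr <- t$matrix[1:3, 4]
  sr <- -R[3, 1]
  gimbal <- abs(abs(sr) - 1) < 1e-7
  if (gimbal) {
    roll <- 90 * sign(sr)
    yaw <- 0
    pitch <- atan2(-R[2, 3], R[2, 2]) * 180 / pi
  } else {
    roll <- asin(sr) * 180 / pi
    pitch <- atan2(R[3, 2], R[3, 3]) * 180 / pi
    yaw <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  }
  out <- transform_params(tx = tr[1], ty = tr[2], tz = tr[3],
                          pitch = pitch, roll = roll, yaw = yaw)
  attr(out, "gimbal_lock") <- gimbal
  out
}

#' Rebuild a rigid transform from its six parameters
#'
#' Inverse of [decompose()]: `R = Rz(yaw) Ry(roll) Rx(pitch)` with the
#' translation appended.
#'
#' @param p a `transform_params` object (or a list with fields `tx`, `ty`,
#'   `tz`, `pitch`, `roll`, `yaw`).
#' @return a `rigid_transform`.
#' @export
recompose <- function(p) {
  need <- c("tx", "ty", "tz", "pitch", "roll", "yaw")
  if (!all(need %in% names(p))) stop("missing transform parameters")
  ang <- function(a) a * pi / 180
  cp <- cos(ang(p$pitch)); sp <- sin(ang(p$pitch))
  cr <- cos(ang(p$roll));  sr <- sin(ang(p$roll))
  cy <- cos(ang(p$yaw));   sy <- sin(ang(p$yaw))
  Rx <- rbind(c(1, 0, 0), c(0, cp, -sp), c(0, sp, cp))
  Ry <- rbind(c(cr, 0, sr), c(0, 1, 0), c(-sr, 0, cr))
  Rz <- rbind(c(cy, -sy, 0), c(sy, cy, 0), c(0, 0, 1))
  m <- diag(4)
  m[1:3, 1:3] <- Rz %*% Ry %*% Rx
  m[1:3, 4] <- c(p$tx, p$ty, p$tz)
  rigid_transform(m)
}

#' Least-squares rigid fit between two labeled point sets
#'
#' Orthogonal Procrustes (Kabsch) estimation of the rigid transform mapping
#' `source` onto `target`: both sets are centred on their centroids, the
#' rotation is taken from the SVD of the cross-covariance with a sign flip of
#' the smallest singular vector if needed so that no reflection is ever
#' returned, and the translation follows from the centroids. Used for the
#' landmark-based initial fit (nasion and preauricular points) and for every
#' ICP refit.
#'
#' @param source n x 3 matrix of source coordinates (mm), n >= 3.
#' @param target n x 3 matrix of matching target coordinates.
#' @param weights optional non-negative per-pair weights (uniform when
#'   omitted).
#' @return a list with `transform` (a `rigid_transform` mapping source to
#'   target) and `rms` (weighted root-mean-square residual in mm).
#' @export
fit_landmarks <- function(source, target, weights = NULL) {
  source <- as_points_matrix(source)
  target <- as_points_matrix(target)
  if (nrow(source) != nrow(target)) stop("point sets must pair one-to-one")
  if (nrow(source) < 3) stop("degenerate geometry: need at least 3 point pairs")
  if (is.null(weights)) weights <- rep(1, nrow(source))
  if (length(weights) != nrow(source) || any(weights < 0) ||
      sum(weights > 0) < 3) {
    stop("weights must be non-negative with at least 3 positive entries")
  }
  w <- weights / sum(weights)
  cs <- colSums(source * w)
  ct <- colSums(target * w)
  X <- sweep(source, 2, cs)
  Y <- sweep(target, 2, ct)
  # collinearity check: rank of the centred source must be >= 2
  sv <- svd(X * sqrt(w))
  if (sum(sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 1)) < 2) {
    stop("degenerate geometry: source points are collinear")
  }
  H <- crossprod(X * w, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- ct - R %*% cs
  tr <- rigid_transform(m)
  resid <- apply_transform(tr, source) - target
  list(transform = tr, rms = sqrt(sum(w * rowSums(resid^2))))
}

#' Read or write a rigid transform as plain text
#'
#' The on-disk format is four lines of four whitespace-separated floats
#' (row-major 4x4 homogeneous matrix, mm). Lines starting with `#` are
#' ignored on read.
#'
#' @param path file path.
#' @return `read_transform` returns a `rigid_transform`; `write_transform`
#'   returns `path` invisibly.
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4) stop("transform file must hold exactly 4 data rows")
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != 4) || any(!is.finite(unlist(vals)))) {
    stop("each transform row must hold 4 finite numbers")
  }
  rigid_transform(do.call(rbind, vals))
}

#' @rdname read_transform
#' @param t a `rigid_transform` to write.
#' @export
write_transform <- function(t, path) {
  stopifnot(is_rigid_transform(t))
  rows <- apply(t$matrix, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}
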