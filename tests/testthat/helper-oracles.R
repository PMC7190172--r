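# Independent reference implementations used as oracles. These deliberately
# take different routes than the package code.

# closest point on a segment
oracle_closest_on_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- max(0, min(1, t))
  a + t * ab
}

# closest point on one triangle: plane projection if the barycentric
# coordinates are all non-negative, else the best of the three edges
oracle_closest_on_triangle <- function(p, a, b, c) {
  n <- pracma::cross(b - a, c - a)
  n <- n / sqrt(sum(n^2))
  proj <- p - sum((p - a) * n) * n
  # barycentric coordinates of proj
  m <- cbind(b - a, c - a)
  coef <- qr.solve(crossprod(m), crossprod(m, proj - a))
  cands <- list(oracle_closest_on_segment(p, a, b),
                oracle_closest_on_segment(p, b, c),
                oracle_closest_on_segment(p, c, a))
  if (all(coef >= 0) && sum(coef) <= 1) cands <- c(cands, list(proj))
  d <- vapply(cands, function(q) sum((p - q)^2), 0)
  cands[[which.min(d)]]
}

# exhaustive scan over every triangle of the mesh
oracle_mesh_distance <- function(points, surface) {
  V <- surface$vertices
  F_ <- surface$triangles
  apply(points, 1, function(p) {
    best <- Inf
    for (t in seq_len(nrow(F_))) {
      q <- oracle_closest_on_triangle(p, V[F_[t, 1], ], V[F_[t, 2], ],
                                      V[F_[t, 3], ])
      best <- min(best, sqrt(sum((p - q)^2)))
    }
    best
  })
}

# random proper rotation via QR with determinant fix
oracle_random_rigid <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qrd)
  R <- R %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- stats::rnorm(3, sd = 30)
  rigid_transform(m)
}

# explicit extrinsic X-Y-Z Euler product, degrees
oracle_euler_matrix <- function(pitch, roll, yaw) {
  r <- function(a) a * pi / 180
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(r(pitch)), -sin(r(pitch))),
              c(0, sin(r(pitch)), cos(r(pitch))))
  Ry <- rbind(c(cos(r(roll)), 0, sin(r(roll))),
              c(0, 1, 0),
              c(-sin(r(roll)), 0, cos(r(roll))))
  Rz <- rbind(c(cos(r(yaw)), -sin(r(yaw)), 0),
              c(sin(r(yaw)), cos(r(yaw)), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# ICC(3,1) through R's own ANOVA machinery
oracle_icc31_aov <- function(table) {
  n <- nrow(table)
  k <- ncol(table)
  df <- data.frame(y = as.vector(table),
                   subject = factor(rep(seq_len(n), k)),
                   method = factor(rep(seq_len(k), each = n)))
  tab <- suppressWarnings(
    stats::anova(stats::lm(y ~ subject + method, data = df)))
  msb <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msb - mse) / (msb + (k - 1) * mse)
}

# textbook Pearson correlation and its t-test, long-hand
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

params_vec <- function(t) {
  p <- decompose(t)
  c(tx = p$tx, ty = p$ty, tz = p$tz,
    pitch = p$pitch, roll = p$roll, yaw = p$yaw)
}
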