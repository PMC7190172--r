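#' Co-registration configuration
#'
#' Tunable parameters of the automated pipeline. Each ICP stage runs up to
#' its iteration cap (default 100) or until the root-mean-square
#' correspondence distance changes by less than `convergence_tol`; a 5 mm
#' outlier rejection threshold sits between the two stages, and a 2 mm
#' quality heuristic flags fits whose median error may be unacceptably
#' large. The iteration caps are deliberately generous: on smooth scalp
#' surfaces ICP creeps slowly along tangential directions, and stopping is
#' better governed by the convergence tolerance than by the cap.
#'
#' @param n_icp_initial iteration cap for the first ICP stage (default 100).
#' @param n_icp_final iteration cap for the final ICP stage (default 100).
#' @param convergence_tol mm; stop an ICP stage when the RMS correspondence
#'   distance changes by less than this (default 1e-6).
#' @param outlier_threshold mm; headshape points farther than this from the
#'   surface after the first stage are dropped from fitting (default 5).
#' @param quality_threshold mm; median errors above this raise the quality
#'   flag (default 2).
#' @param fiducial_weight weight given to each digitized fiducial, relative
#'   to one headshape point, when it joins the ICP fit as an ordinary
#'   surface-matched point (default 2; 0 excludes fiducials from fitting).
#'   The fiducials sit at the lateral and anterior extremes that headshape
#'   digitization leaves uncovered, so they stabilize the translation
#'   components a smooth scalp constrains only weakly. They never enter
#'   the error metric.
#' @return a `coreg_config` list.
#' @export
coreg_config <- function(n_icp_initial = 100L, n_icp_final = 100L,
                         convergence_tol = 1e-6, outlier_threshold = 5,
                         quality_threshold = 2, fiducial_weight = 2) {
  stopifnot(n_icp_initial >= 1, n_icp_final >= 1,
            convergence_tol > 0, outlier_threshold > 0,
            quality_threshold > 0, fiducial_weight >= 0)
  structure(list(n_icp_initial = as.integer(n_icp_initial),
                 n_icp_final = as.integer(n_icp_final),
                 convergence_tol = convergence_tol,
                 outlier_threshold = outlier_threshold,
                 quality_threshold = quality_threshold,
                 fiducial_weight = fiducial_weight),
            class = "coreg_config")
}

#' Map template-space fiducials into a subject's MRI space
#'
#' The automated pipeline starts from average fiducial coordinates defined
#' on a template head (MNI305); this transfers them into the individual MRI
#' frame through the template-to-subject affine.
#'
#' @param template_fiducials named list with `nasion`, `lpa`, `rpa` (mm,
#'   template space).
#' @param template_to_subject a 4x4 affine matrix (or `rigid_transform`)
#'   mapping template coordinates to subject MRI coordinates.
#' @return a named fiducial list in subject MRI coordinates.
#' @export
template_fiducials_to_subject <- function(template_fiducials,
                                          template_to_subject) {
  f <- validate_fiducials(template_fiducials)
  m <- if (is_rigid_transform(template_to_subject)) {
    template_to_subject$matrix
  } else {
    as.matrix(template_to_subject)
  }
  if (any(dim(m) != c(4, 4)) || any(!is.finite(m))) {
    stop("template_to_subject must be a finite 4x4 affine")
  }
  if (abs(det(m[1:3, 1:3])) < 1e-12) stop("singular affine")
  lapply(f, function(p) drop(m[1:3, 1:3] %*% p + m[1:3, 4]))
}

#' Iterative closest points against a triangulated surface
#'
#' Refines a rigid MRI-to-head transform by alternating (a) corresponding
#' each head-frame point, brought into MRI space with the current inverse
#' transform, to its exact nearest point on the surface, and (b) solving the
#' orthogonal Procrustes problem mapping those surface correspondences back
#' onto the head-frame points. Point-to-point correspondences with uniform
#' weights. The returned trace holds the root-mean-square correspondence
#' distance per iteration and is non-increasing.
#'
#' @param points k x 3 matrix of head-frame points (mm), k >= 3.
#' @param surface a `head_surface` (MRI frame).
#' @param init initial `rigid_transform` (MRI -> head).
#' @param n_iter maximum iterations.
#' @param tol mm; stop when RMS distance changes by less than this.
#' @param accelerate apply the classic ICP acceleration step: when
#'   successive pose updates point in a consistent direction, trial
#'   extrapolations along that direction are evaluated and the best
#'   strictly-improving one is kept. This shortcuts the slow linear crawl
#'   along tangential ("sliding") directions of smooth surfaces without
#'   ever letting the RMS trace increase. On by default.
#' @param weights optional non-negative per-point weights (uniform when
#'   omitted). The automated pipeline appends the three digitized
#'   fiducials to the headshape points with weight `fiducial_weight`; they
#'   sit at the lateral and anterior extremes the headshape sampling
#'   leaves uncovered, which stabilizes the translation components a
#'   smooth scalp constrains only weakly.
#' @return list with `transform` (MRI -> head) and `trace` (weighted RMS mm
#'   over correspondences per iteration, measured after each correspondence
#'   step).
#' @export
icp <- function(points, surface, init, n_iter = 20L, tol = 1e-6,
                accelerate = TRUE, weights = NULL) {
  points <- as_points_matrix(points)
  if (nrow(points) < 3) stop("ICP needs at least 3 points")
  if (max(apply(points, 2, stats::sd)) < 1e-12) {
    stop("degenerate geometry: all points coincident")
  }
  stopifnot(inherits(surface, "head_surface"), is_rigid_transform(init))
  if (is.null(weights)) weights <- rep(1, nrow(points))
  stopifnot(length(weights) == nrow(points), all(weights >= 0))
  wts <- weights / sum(weights)

  rms_of <- function(transform) {
    d <- nearest_surface_distances(apply_transform(invert(transform), points),
                                   surface)$distances
    sqrt(sum(wts * d^2))
  }
  params6 <- function(transform) {
    p <- decompose(transform)
    c(p$tx, p$ty, p$tz, p$pitch, p$roll, p$yaw)
  }
  from_params6 <- function(q) {
    recompose(transform_params(tx = q[1], ty = q[2], tz = q[3],
                               pitch = q[4], roll = q[5], yaw = q[6]))
  }

  transform <- init
  trace <- numeric(0)
  prev_dir <- NULL
  prev_q <- params6(transform)
  for (it in seq_len(n_iter)) {
    in_mri <- apply_transform(invert(transform), points)
    nn <- nearest_surface_distances(in_mri, surface)
    rms <- sqrt(sum(wts * nn$distances^2))
    trace <- c(trace, rms)
    if (it > 1 && abs(trace[it - 1] - rms) < tol) break
    refit <- fit_landmarks(nn$closest, points, weights = wts)$transform

    q_base <- params6(refit)
    dir <- q_base - prev_q
    best <- refit
    nd <- sqrt(sum(dir^2))
    if (isTRUE(accelerate) && !is.null(prev_dir) && nd > 0) {
      npd <- sqrt(sum(prev_dir^2))
      if (npd > 0 && sum(dir * prev_dir) / (nd * npd) > 0.9) {
        # quadratic line search along the consistent update direction:
        # sample the RMS at two extrapolation factors, fit a parabola and
        # jump to its minimum; keep the best strictly-improving candidate
        best_rms <- rms_of(refit)
        a1 <- 32; a2 <- 96
        d1 <- best_rms
        c1 <- try(from_params6(q_base + a1 * dir), silent = TRUE)
        c2 <- try(from_params6(q_base + a2 * dir), silent = TRUE)
        if (!inherits(c1, "try-error") && !inherits(c2, "try-error")) {
          d2 <- rms_of(c1)
          d3 <- rms_of(c2)
          cands <- list(list(t = c1, r = d2), list(t = c2, r = d3))
          denom <- (a2 - a1) * a1 * a2
          curv <- (d3 * a1 - d2 * a2 + d1 * (a2 - a1)) / denom
          if (is.finite(curv) && curv > 0) {
            slope <- (d2 - d1) / a1 - curv * a1
            a_star <- max(0, min(512, -slope / (2 * curv)))
            c3 <- try(from_params6(q_base + a_star * dir), silent = TRUE)
            if (!inherits(c3, "try-error")) {
              cands <- c(cands, list(list(t = c3, r = rms_of(c3))))
            }
          }
          for (cd in cands) {
            if (cd$r < best_rms) {
              best <- cd$t
              best_rms <- cd$r
            }
          }
        }
      }
    }
    prev_dir <- params6(best) - prev_q
    prev_q <- params6(best)
    transform <- best
  }
  list(transform = transform, trace = trace)
}

#' Reject headshape points far from the surface
#'
#' Implements the outlier-rejection step between the two ICP stages: points
#' whose distance to the surface under the current transform is strictly
#' greater than `threshold` are removed; points at exactly the threshold are
#' retained. Order is preserved.
#'
#' @param points k x 3 head-frame points (mm).
#' @param surface a `head_surface`.
#' @param transform current `rigid_transform` (MRI -> head).
#' @param threshold mm (default 5).
#' @return integer vector of retained point indices.
#' @export
remove_outliers <- function(points, surface, transform, threshold = 5) {
  points <- as_points_matrix(points)
  stopifnot(is_rigid_transform(transform), threshold > 0)
  d <- nearest_surface_distances(apply_transform(invert(transform), points),
                                 surface)$distances
  keep <- which(d <= threshold)
  if (length(keep) == 0) {
    stop("co-registration failed: every headshape point exceeded the ",
         threshold, " mm outlier threshold")
  }
  keep
}

#' Automated five-step co-registration
#'
#' Runs the full automated pipeline: (1) the caller supplies subject-space
#' fiducial estimates, typically from [template_fiducials_to_subject()];
#' (2) an initial rigid fit from those three landmarks to the digitized
#' fiducials; (3) an initial ICP stage over the headshape-role points;
#' (4) a single pass of outlier rejection at `outlier_threshold`; (5) a
#' final ICP stage on the retained points. Error summaries are computed over
#' ALL original headshape-role points under the final transform, so removed
#' outliers still count toward the reported error; inlier-only summaries are
#' kept as secondary fields.
#'
#' @param headshape a `headshape_set` (head frame).
#' @param surface a `head_surface` (MRI frame).
#' @param subject_fiducial_estimates named list with `nasion`, `lpa`, `rpa`
#'   in MRI coordinates.
#' @param config a [coreg_config()].
#' @return a `coreg_result`; see [evaluate_transform()] for the fields.
#' @export
auto_coregister <- function(headshape, surface, subject_fiducial_estimates,
                            config = coreg_config()) {
  stopifnot(inherits(headshape, "headshape_set"),
            inherits(surface, "head_surface"),
            inherits(config, "coreg_config"))
  fid_mri <- validate_fiducials(subject_fiducial_estimates)
  fid_head <- headshape_fiducials(headshape)
  pts <- headshape_points(headshape)

  # step 2: landmark fit, MRI -> head
  init <- fit_landmarks(do.call(rbind, fid_mri[c("nasion", "lpa", "rpa")]),
                        do.call(rbind, fid_head[c("nasion", "lpa", "rpa")]))

  # the digitized fiducials join the fit as weighted surface-matched
  # points: they cover the lateral/anterior extremes the headshape
  # sampling region misses (never the error metric)
  fid_pts <- do.call(rbind, fid_head[c("nasion", "lpa", "rpa")])
  with_fid <- function(p) {
    if (config$fiducial_weight > 0) rbind(p, fid_pts) else p
  }
  wts_for <- function(p) {
    if (config$fiducial_weight > 0) {
      c(rep(1, nrow(p)), rep(config$fiducial_weight, 3))
    }
  }

  # step 3: initial ICP on all headshape points
  stage1 <- icp(with_fid(pts), surface, init$transform,
                n_iter = config$n_icp_initial, tol = config$convergence_tol,
                weights = wts_for(pts))

  # step 4: single-pass outlier rejection (headshape points only)
  keep <- remove_outliers(pts, surface, stage1$transform,
                          threshold = config$outlier_threshold)
  outliers <- setdiff(seq_len(nrow(pts)), keep)

  # step 5: final ICP on retained points
  kept_pts <- pts[keep, , drop = FALSE]
  stage2 <- icp(with_fid(kept_pts), surface, stage1$transform,
                n_iter = config$n_icp_final, tol = config$convergence_tol,
                weights = wts_for(kept_pts))

  res <- evaluate_transform(headshape, surface, stage2$transform,
                            config = config)
  res$outlier_indices <- outliers
  res$iteration_trace <- list(initial = stage1$trace, final = stage2$trace)
  res$converged <- length(stage2$trace) < config$n_icp_final ||
    (length(stage2$trace) >= 2 &&
       abs(diff(utils::tail(stage2$trace, 2))) < config$convergence_tol)
  inl <- res$distances_all[keep]
  res$median_error_inliers <- stats::median(inl)
  res
}

#' Evaluate a given transform (e.g. a manual co-registration)
#'
#' Applies a fixed MRI-to-head transform to the digitized headshape and
#' computes the co-registration error: the distance from each
#' headshape-role point to the nearest point on the scalp surface, with the
#' median and the 25th/75th percentiles (linear interpolation between order
#' statistics) as summaries. No fitting is performed.
#'
#' @inheritParams auto_coregister
#' @param transform the `rigid_transform` (MRI -> head) to evaluate.
#' @return a `coreg_result` with fields `transform`, `distances_all` (per
#'   headshape-role point, mm), `median_error`, `iqr_low`, `iqr_high`,
#'   `outlier_indices` (empty here), `converged`, `iteration_trace`, and
#'   `quality_flag` (`TRUE` when `median_error > quality_threshold`).
#' @export
evaluate_transform <- function(headshape, surface, transform,
                               config = coreg_config()) {
  stopifnot(inherits(headshape, "headshape_set"),
            inherits(surface, "head_surface"),
            is_rigid_transform(transform),
            inherits(config, "coreg_config"))
  pts <- headshape_points(headshape)
  d <- nearest_surface_distances(apply_transform(invert(transform), pts),
                                 surface)$distances
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(transform = transform,
                 distances_all = d,
                 median_error = q[2],
                 iqr_low = q[1],
                 iqr_high = q[3],
                 outlier_indices = integer(0),
                 converged = TRUE,
                 iteration_trace = list(initial = numeric(0),
                                        final = numeric(0)),
                 quality_flag = q[2] > config$quality_threshold,
                 quality_threshold = config$quality_threshold,
                 n_headshape = nrow(pts)),
            class = "coreg_result")
}

#' @export
print.coreg_result <- function(x, ...) {
  cat(sprintf(
    "<coreg_result> median error %.3f mm (IQR %.3f-%.3f), %d points, %d outliers%s\n",
    x$median_error, x$iqr_low, x$iqr_high, x$n_headshape,
    length(x$outlier_indices),
    if (isTRUE(x$quality_flag)) sprintf(" [FLAG: > %.1f mm]",
                                        x$quality_threshold) else ""))
  invisible(x)
}

#' Diagnostic plot for a co-registration result
#'
#' Left: histogram of per-point distances with the median and quality
#' threshold marked. Right: RMS trace of both ICP stages, when present.
#'
#' @param x a `coreg_result`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.coreg_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$distances_all, main = "Point-to-surface distance",
                 xlab = "mm", ...)
  graphics::abline(v = x$median_error, col = "red", lwd = 2)
  graphics::abline(v = x$quality_threshold, col = "grey40", lty = 2)
  tr <- c(x$iteration_trace$initial, x$iteration_trace$final)
  if (length(tr)) {
    graphics::plot(seq_along(tr), tr, type = "b", xlab = "ICP iteration",
                   ylab = "RMS distance (mm)", main = "Convergence")
    graphics::abline(v = length(x$iteration_trace$initial) + 0.5, lty = 3)
  } else {
    graphics::plot.new()
  }
  invisible(x)
}
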