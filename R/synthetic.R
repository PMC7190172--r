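#' Synthetic head cohorts with known co-registration ground truth
#'
#' The generator builds parametric scalp surfaces (an ellipsoid with smooth
#' radial nose and brow bumps), places the three anatomical fiducials
#' analytically, samples a digitized headshape with digitizer noise and
#' occasional gross outliers, and draws a ground-truth MRI-to-head transform
#' whose decomposed parameters are centred on values typical of supine MRI
#' versus seated MEG coordinate frames (large negative z translation, a
#' pitch of roughly 14 degrees). A simulated "manual operator" perturbs the
#' ground truth so paired manual-versus-automated comparisons can be run
#' with the truth known.
#'
#' @name synthetic
NULL

# run code under a fixed RNG seed without disturbing the caller's stream
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic subject
#'
#' @param seed integer seed driving this subject's random draws
#'   (headshape sampling, noise, outliers).
#' @param axes length-3 head half-axes (x right, y anterior, z superior) of
#'   the base ellipsoid, mm. Defaults approximate adult head breadth,
#'   length and height.
#' @param nose_amplitude,brow_amplitude,occiput_amplitude,parietal_amplitude
#'   radial bump heights of the nose, brow ridge, occipital protuberance
#'   and parietal eminences, mm.
#' @param subdivisions icosphere subdivision level (4 gives 2562 vertices,
#'   5120 triangles).
#' @param ground_truth `rigid_transform`, MRI -> head; see
#'   [sample_ground_truth_transform()].
#' @param template_jitter_sd mm; SD of the error of template-transferred
#'   fiducial estimates relative to the true fiducials (default 5).
#' @param n_points number of headshape-role points to digitize.
#' @param noise_sd mm; digitizer error scale (default 1.5). The error has
#'   an isotropic Gaussian part with this SD plus an outward-biased
#'   half-normal part (see `noise_outward_frac`).
#' @param noise_outward_frac the outward (pen-standoff over hair) component
#'   is half-normal with SD `noise_outward_frac * noise_sd` (default 0.8);
#'   zero digitizer noise therefore means points exactly on the scalp.
#' @param outlier_fraction fraction of headshape points displaced outward as
#'   gross digitization errors (default 0.02).
#' @param outlier_magnitude mm; outward displacement of those points
#'   (default 12).
#' @return a `subject_spec` list.
#' @export
subject_spec <- function(seed = 1L,
                         axes = c(75, 93, 88),
                         nose_amplitude = 22,
                         brow_amplitude = 6,
                         occiput_amplitude = 10,
                         parietal_amplitude = 12,
                         subdivisions = 4L,
                         ground_truth = default_ground_truth(),
                         template_jitter_sd = 5,
                         n_points = 143L,
                         noise_sd = 1.5,
                         noise_outward_frac = 0.8,
                         outlier_fraction = 0.02,
                         outlier_magnitude = 12) {
  stopifnot(length(axes) == 3, all(axes > 0), noise_sd >= 0,
            noise_outward_frac >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            n_points >= 10, subdivisions >= 1,
            is_rigid_transform(ground_truth))
  structure(list(seed = as.integer(seed), axes = as.numeric(axes),
                 nose_amplitude = nose_amplitude,
                 brow_amplitude = brow_amplitude,
                 occiput_amplitude = occiput_amplitude,
                 parietal_amplitude = parietal_amplitude,
                 subdivisions = as.integer(subdivisions),
                 ground_truth = ground_truth,
                 template_jitter_sd = template_jitter_sd,
                 n_points = as.integer(n_points),
                 noise_sd = noise_sd,
                 noise_outward_frac = noise_outward_frac,
                 outlier_fraction = outlier_fraction,
                 outlier_magnitude = outlier_magnitude),
            class = "subject_spec")
}

# central MRI -> head transform: strong downward z shift and forward pitch
default_ground_truth <- function() {
  recompose(transform_params(tx = -2, ty = -5, tz = -70,
                             pitch = 14, roll = 1, yaw = -0.5))
}

# ---- icosphere ------------------------------------------------------------

.icosphere_cache <- new.env(parent = emptyenv())

icosphere <- function(subdivisions = 4L) {
  key <- as.character(subdivisions)
  cached <- .icosphere_cache[[key]]
  if (!is.null(cached)) return(cached)
  res <- icosphere_build(subdivisions)
  .icosphere_cache[[key]] <- res
  res
}

icosphere_build <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(i, j) if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    midpoints <- new.env(parent = emptyenv())
    verts <- vector("list", 0)
    get_mid <- function(i, j) {
      key <- edge_key(i, j)
      idx <- midpoints[[key]]
      if (is.null(idx)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts[[length(verts) + 1]] <<- m
        idx <- nv + length(verts)
        midpoints[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
      newf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- newf
  }
  list(vertices = v, triangles = f)
}

# anisotropic Gaussian bump in (azimuth, elevation) around a centre direction
angular_bump <- function(units, centre, width_az, width_el) {
  # units: n x 3 unit vectors; centre: unit vector with centre[1] == 0
  el <- asin(pmin(1, pmax(-1, units[, 3]))) -
    asin(pmin(1, pmax(-1, centre[3])))
  az <- atan2(units[, 1], units[, 2]) - atan2(centre[1], centre[2])
  az <- ((az + pi) %% (2 * pi)) - pi
  exp(-(az^2 / (2 * width_az^2) + el^2 / (2 * width_el^2)))
}

# smooth head radius field: ellipsoid plus radial bumps for the salient
# scalp features (nose, brow ridge, occipital protuberance, parietal
# eminences); facial bumps restricted to the front (y > 0)
head_point <- function(units, spec) {
  base <- cbind(units[, 1] * spec$axes[1],
                units[, 2] * spec$axes[2],
                units[, 3] * spec$axes[3])
  front <- pmax(0, units[, 2])
  dir3 <- function(x, y, z) { u <- c(x, y, z); u / sqrt(sum(u^2)) }
  nose <- spec$nose_amplitude *
    angular_bump(units, c(0, cos(-20 * pi / 180), sin(-20 * pi / 180)),
                 width_az = 0.16, width_el = 0.20) * front
  brow <- spec$brow_amplitude *
    angular_bump(units, c(0, cos(20 * pi / 180), sin(20 * pi / 180)),
                 width_az = 0.55, width_el = 0.25) * front
  occiput <- spec$occiput_amplitude *
    angular_bump(units, dir3(0, -0.94, 0.34), 0.50, 0.35) * pmax(0, -units[, 2])
  parietal <- spec$parietal_amplitude *
    (angular_bump(units, dir3(0.62, -0.18, 0.76), 0.35, 0.35) +
       angular_bump(units, dir3(-0.62, -0.18, 0.76), 0.35, 0.35))
  base + units * (nose + brow + occiput + parietal)
}

#' Generate a synthetic scalp surface
#'
#' Builds the subject's triangulated scalp in the MRI frame: an icosphere
#' deformed into an ellipsoid with radial nose and brow bumps, with the
#' nasion placed analytically at the nose-root saddle between the two bumps
#' and the preauricular points at the lateral extremes, all snapped onto the
#' triangulation. The anatomy is laid out in the head frame the fiducials
#' define and then carried into the MRI frame with the inverse of the
#' subject's ground-truth transform, so that `spec$ground_truth` maps the
#' returned surface exactly into head coordinates. The geometry depends only
#' on the shape parameters, never on `spec$seed`.
#'
#' @param spec a [subject_spec()].
#' @return a `head_surface` in MRI coordinates with fiducials set.
#' @export
generate_head_surface <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  ico <- icosphere(spec$subdivisions)
  verts <- head_point(ico$vertices, spec)

  # analytic fiducial directions: nose-root saddle and lateral extremes
  dir <- function(x, y, z) { u <- c(x, y, z); u / sqrt(sum(u^2)) }
  fid_dirs <- rbind(nasion = dir(0, cos(2 * pi / 180), sin(2 * pi / 180)),
                    lpa = dir(-0.99, -0.05, -0.12),
                    rpa = dir(0.99, -0.05, -0.12))
  fid_smooth <- head_point(fid_dirs, spec)

  surf0 <- structure(list(vertices = verts, triangles = ico$triangles,
                          fiducials = NULL), class = "head_surface")
  snapped <- nearest_surface_distances(fid_smooth, surf0)$closest
  fids <- list(nasion = snapped[1, ], lpa = snapped[2, ], rpa = snapped[3, ])

  # re-express everything in the MRI frame implied by the ground truth
  anat_to_head <- fiducial_frame(fids)
  head_to_mri <- compose(invert(spec$ground_truth), anat_to_head)
  verts_mri <- apply_transform(head_to_mri, verts)
  fids_mri <- lapply(fids, function(p) {
    drop(apply_transform(head_to_mri, matrix(p, 1)))
  })
  head_surface(verts_mri, ico$triangles, fids_mri)
}

# area-weighted uniform sampling of points on a mesh, with the outward unit
# normal of each sampled triangle
sample_on_surface <- function(surface, n) {
  areas <- triangle_areas(surface$vertices, surface$triangles)
  tri <- sample.int(nrow(surface$triangles), n, replace = TRUE,
                    prob = areas)
  u <- stats::runif(n)
  v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  a <- surface$vertices[surface$triangles[tri, 1], , drop = FALSE]
  b <- surface$vertices[surface$triangles[tri, 2], , drop = FALSE]
  c3 <- surface$vertices[surface$triangles[tri, 3], , drop = FALSE]
  pts <- a + u * (b - a) + v * (c3 - a)
  e1 <- b - a
  e2 <- c3 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # orient outward (away from the mesh centroid)
  ctr <- colMeans(surface$vertices)
  s <- sign(rowSums(nrm * sweep(pts, 2, ctr)))
  s[s == 0] <- 1
  list(points = pts, normals = nrm * s)
}

#' Digitize a synthetic headshape
#'
#' Samples `spec$n_points` headshape-role points on the scalp surface —
#' emulating digitization practice, about two thirds come from the skull
#' above the fiducial plane and one third from the brow and nose-bridge
#' patches — maps them into head coordinates with the ground-truth
#' transform, and adds isotropic Gaussian digitizer jitter (`noise_sd`).
#' A fraction `outlier_fraction` of points is additionally displaced
#' outward by `outlier_magnitude` mm (stray clicks, hair). The three
#' fiducials (noise-perturbed) are included with role `fiducial`, plus four
#' HPI-coil points; neither enters ICP fitting or the error metric.
#'
#' @param surface the subject's `head_surface` (MRI frame, fiducials set).
#' @param spec the matching [subject_spec()].
#' @return a `headshape_set` in head coordinates.
#' @export
generate_headshape <- function(surface, spec) {
  stopifnot(inherits(surface, "head_surface"), inherits(spec, "subject_spec"))
  if (is.null(surface$fiducials)) stop("surface must carry fiducials")
  truth <- spec$ground_truth
  with_rng(spec$seed, {
    nasion_head <- drop(apply_transform(
      truth, matrix(surface$fiducials$nasion, 1)))
    y_nas <- nasion_head[2]

    n <- spec$n_points
    n_face <- round(0.35 * n)
    n_skull <- n - n_face
    R_head <- spec$ground_truth$matrix[1:3, 1:3]
    skull <- matrix(0, 0, 3); skull_nrm <- matrix(0, 0, 3)
    face <- matrix(0, 0, 3); face_nrm <- matrix(0, 0, 3)
    guard <- 0
    while ((nrow(skull) < n_skull || nrow(face) < n_face) && guard < 60) {
      guard <- guard + 1
      smp <- sample_on_surface(surface, 4L * n)
      cand <- apply_transform(truth, smp$points)
      nrm <- smp$normals %*% t(R_head)  # rotate normals into head frame
      # skull coverage reaches below the widest lateral extent (digitizers
      # sweep down to the mastoid and occiput) but avoids the ears
      # (cartilage) and the lower face
      is_ear <- abs(cand[, 1]) > 55 & cand[, 2] > -35 & cand[, 2] < 15 &
        cand[, 3] < 5
      is_lower_face <- cand[, 3] < 0 & cand[, 2] > 40
      is_skull <- cand[, 3] > -25 & !is_ear & !is_lower_face
      is_face <- cand[, 2] > y_nas - 15 & cand[, 3] > -10 & cand[, 3] < 40 &
        abs(cand[, 1]) < 45
      skull <- rbind(skull, cand[is_skull & !is_face, , drop = FALSE])
      skull_nrm <- rbind(skull_nrm, nrm[is_skull & !is_face, , drop = FALSE])
      face <- rbind(face, cand[is_face, , drop = FALSE])
      face_nrm <- rbind(face_nrm, nrm[is_face, , drop = FALSE])
    }
    if (nrow(skull) < n_skull || nrow(face) < n_face) {
      stop("degenerate spec: headshape sampling region is (nearly) empty")
    }
    pts <- rbind(skull[seq_len(n_skull), , drop = FALSE],
                 face[seq_len(n_face), , drop = FALSE])
    nrm <- rbind(skull_nrm[seq_len(n_skull), , drop = FALSE],
                 face_nrm[seq_len(n_face), , drop = FALSE])
    ord <- sample.int(n)
    pts <- pts[ord, , drop = FALSE]
    nrm <- nrm[ord, , drop = FALSE]

    if (spec$noise_sd > 0) {
      # outward-biased component: the digitizer pen rides over hair, so the
      # recorded point sits above the scalp by a half-normal standoff along
      # the local surface normal
      if (spec$noise_outward_frac > 0) {
        standoff <- abs(stats::rnorm(n, sd = spec$noise_outward_frac *
                                       spec$noise_sd))
        pts <- pts + nrm * standoff
      }
      pts <- pts + matrix(stats::rnorm(3 * n, sd = spec$noise_sd), n, 3)
    }
    n_out <- floor(spec$outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      ctr <- colMeans(pts)
      for (i in idx) {
        u <- pts[i, ] - ctr
        pts[i, ] <- pts[i, ] + spec$outlier_magnitude * u / sqrt(sum(u^2))
      }
    }

    fid_head <- lapply(surface$fiducials, function(p) {
      drop(apply_transform(truth, matrix(p, 1))) +
        stats::rnorm(3, sd = spec$noise_sd)
    })
    hpi_mri <- sample_on_surface(surface, 4L)$points
    hpi <- apply_transform(truth, hpi_mri) +
      matrix(stats::rnorm(12, sd = spec$noise_sd), 4, 3)

    headshape_set(
      rbind(do.call(rbind, fid_head[c("nasion", "lpa", "rpa")]), hpi, pts),
      c(rep("fiducial", 3), rep("hpi", 4), rep("headshape", n)),
      fiducial_labels = c("nasion", "lpa", "rpa"))
  })
}

#' Draw a ground-truth MRI-to-head transform
#'
#' Samples the six transform parameters independently around configurable
#' centres — by default a translation near (-2, -5, -70) mm and rotations
#' near (14, 1, -0.5) degrees of pitch/roll/yaw, the regime typical of
#' supine MRI versus seated MEG frames — with between-subject SDs of 5 mm
#' and 5 degrees.
#'
#' @param seed integer seed; draws are independent of the caller's RNG
#'   state.
#' @param centre_translation,centre_rotation length-3 centres (mm, deg).
#' @param sd_translation,sd_rotation between-subject SDs (mm, deg).
#' @return a `rigid_transform`.
#' @export
sample_ground_truth_transform <- function(seed,
                                          centre_translation = c(-2, -5, -70),
                                          centre_rotation = c(14, 1, -0.5),
                                          sd_translation = 5,
                                          sd_rotation = 5) {
  with_rng(seed, {
    tr <- stats::rnorm(3, centre_translation, sd_translation)
    ro <- stats::rnorm(3, centre_rotation, sd_rotation)
    recompose(transform_params(tx = tr[1], ty = tr[2], tz = tr[3],
                               pitch = ro[1], roll = ro[2], yaw = ro[3]))
  })
}

#' Simulate a manual operator's co-registration
#'
#' A manual co-registration is modelled as the ground truth nudged in the
#' six parameters an operator actually adjusts (translation and rotation
#' sliders): each decomposed parameter receives independent N(0, sd) noise
#' and the transform is rebuilt. With both SDs zero the ground truth is
#' returned exactly.
#'
#' @param ground_truth the subject's true `rigid_transform`.
#' @param operator_sd_mm SD of the translation nudges, mm (default 1).
#' @param operator_sd_deg SD of the rotation nudges, degrees (default 1).
#' @param seed integer seed.
#' @return a `rigid_transform`.
#' @export
simulate_manual_transform <- function(ground_truth, operator_sd_mm = 1,
                                      operator_sd_deg = 1, seed = 1L) {
  stopifnot(is_rigid_transform(ground_truth),
            operator_sd_mm >= 0, operator_sd_deg >= 0)
  if (operator_sd_mm == 0 && operator_sd_deg == 0) return(ground_truth)
  with_rng(seed, {
    p <- decompose(ground_truth)
    recompose(transform_params(
      tx = p$tx + stats::rnorm(1, sd = operator_sd_mm),
      ty = p$ty + stats::rnorm(1, sd = operator_sd_mm),
      tz = p$tz + stats::rnorm(1, sd = operator_sd_mm),
      pitch = p$pitch + stats::rnorm(1, sd = operator_sd_deg),
      roll = p$roll + stats::rnorm(1, sd = operator_sd_deg),
      yaw = p$yaw + stats::rnorm(1, sd = operator_sd_deg)))
  })
}

#' Cohort-level generator settings
#'
#' Defaults emulate the statistical structure of a typical MEG study
#' cohort: headshape counts drawn from a triangular distribution on
#' \[83, 229\] with mode 128 (median about 143), digitizer noise varying
#' between subjects around 1.5 mm, template-fiducial transfer error of
#' 5 mm, and a manual operator with 1 mm / 1 degree precision.
#'
#' @param axes,nose_amplitude,brow_amplitude,occiput_amplitude,parietal_amplitude,subdivisions
#'   per-subject shape parameters, see [subject_spec()]. `axes_sd` adds
#'   between-subject head size variation (mm).
#' @param noise_outward_frac outward-biased digitizer error fraction, see
#'   [subject_spec()].
#' @param n_points_range `c(min, mode, max)` of the triangular draw.
#' @param noise_sd_mean,noise_sd_sd between-subject distribution of the
#'   digitizer noise SD (mm; truncated below at 0.5).
#' @param template_jitter_sd,outlier_fraction,outlier_magnitude see
#'   [subject_spec()].
#' @param operator_sd_mm,operator_sd_deg manual-operator precision.
#' @param centre_translation,centre_rotation,sd_translation,sd_rotation
#'   ground-truth transform distribution, see
#'   [sample_ground_truth_transform()].
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(axes = c(75, 93, 88), axes_sd = 4,
                          nose_amplitude = 22, brow_amplitude = 6,
                          occiput_amplitude = 10, parietal_amplitude = 12,
                          subdivisions = 4L,
                          n_points_range = c(83L, 128L, 229L),
                          noise_sd_mean = 1.5, noise_sd_sd = 0.25,
                          noise_outward_frac = 0.8,
                          template_jitter_sd = 5,
                          outlier_fraction = 0.02, outlier_magnitude = 12,
                          operator_sd_mm = 1, operator_sd_deg = 1,
                          centre_translation = c(-2, -5, -70),
                          centre_rotation = c(14, 1, -0.5),
                          sd_translation = 5, sd_rotation = 5) {
  stopifnot(length(n_points_range) == 3,
            n_points_range[1] <= n_points_range[2],
            n_points_range[2] <= n_points_range[3])
  structure(as.list(environment()), class = "cohort_config")
}

rtriangular <- function(n, a, c3, b) {
  u <- stats::runif(n)
  fc <- (c3 - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c3 - a)),
         b - sqrt((1 - u) * (b - a) * (b - c3)))
}

#' Generate a full synthetic cohort
#'
#' Draws `n_subjects` independent subjects (shape, ground-truth transform,
#' headshape, manual-operator transform, template-jittered fiducial
#' estimates) from a single master seed; regeneration from the same master
#' seed is bit-identical. Optionally writes each subject to
#' `out_dir/sub-XX/` as `surface.ply`, `fiducials.json`, `headshape.txt`,
#' `fiducial_estimates.json`, `truth_trans.txt` and `manual_trans.txt`, the
#' layout the command-line interface consumes.
#'
#' @param n_subjects number of subjects, >= 3.
#' @param master_seed integer master seed.
#' @param config a [cohort_config()].
#' @param out_dir optional output directory.
#' @return a `cohort_dataset`: list of subjects, each holding `spec`,
#'   `surface`, `headshape`, `ground_truth`, `manual`,
#'   `fiducial_estimates`; plus `master_seed` and `config`.
#' @export
generate_cohort <- function(n_subjects = 30L, master_seed = 1L,
                            config = cohort_config(), out_dir = NULL) {
  stopifnot(n_subjects >= 3, inherits(config, "cohort_config"))
  draws <- with_rng(master_seed, {
    list(seeds = sample.int(.Machine$integer.max, 3L * n_subjects),
         n_points = as.integer(round(rtriangular(
           n_subjects, config$n_points_range[1], config$n_points_range[2],
           config$n_points_range[3]))),
         noise_sd = pmax(0, stats::rnorm(n_subjects, config$noise_sd_mean,
                                         config$noise_sd_sd)),
         axes = matrix(stats::rnorm(3 * n_subjects, rep(config$axes,
                                                        each = n_subjects),
                                    config$axes_sd), n_subjects, 3))
  })
  subjects <- lapply(seq_len(n_subjects), function(i) {
    truth <- sample_ground_truth_transform(
      draws$seeds[i], config$centre_translation, config$centre_rotation,
      config$sd_translation, config$sd_rotation)
    spec <- subject_spec(
      seed = draws$seeds[n_subjects + i],
      axes = draws$axes[i, ],
      nose_amplitude = config$nose_amplitude,
      brow_amplitude = config$brow_amplitude,
      occiput_amplitude = config$occiput_amplitude,
      parietal_amplitude = config$parietal_amplitude,
      subdivisions = config$subdivisions,
      ground_truth = truth,
      template_jitter_sd = config$template_jitter_sd,
      n_points = draws$n_points[i],
      noise_sd = draws$noise_sd[i],
      noise_outward_frac = config$noise_outward_frac,
      outlier_fraction = config$outlier_fraction,
      outlier_magnitude = config$outlier_magnitude)
    surface <- generate_head_surface(spec)
    headshape <- generate_headshape(surface, spec)
    manual <- simulate_manual_transform(truth, config$operator_sd_mm,
                                        config$operator_sd_deg,
                                        seed = draws$seeds[2 * n_subjects + i])
    estimates <- with_rng(draws$seeds[2 * n_subjects + i] %% 1000000L + 7L, {
      lapply(surface$fiducials, function(p) {
        p + stats::rnorm(3, sd = spec$template_jitter_sd)
      })
    })
    list(spec = spec, surface = surface, headshape = headshape,
         ground_truth = truth, manual = manual,
         fiducial_estimates = estimates)
  })
  cohort <- structure(list(subjects = subjects, master_seed = master_seed,
                           config = config),
                      class = "cohort_dataset")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects, master seed %d\n",
              length(x$subjects), x$master_seed))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' @param cohort a `cohort_dataset`.
#' @param dir directory; one `sub-XX` folder per subject.
#' @return the directory (write) or a list of subject file sets (read),
#'   invisibly for write.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    sd_ <- file.path(dir, sprintf("sub-%02d", i))
    dir.create(sd_, showWarnings = FALSE)
    write_surface(s$surface, file.path(sd_, "surface.ply"),
                  fiducials_path = file.path(sd_, "fiducials.json"))
    write_headshape(s$headshape, file.path(sd_, "headshape.txt"))
    write_fiducials(s$fiducial_estimates,
                    file.path(sd_, "fiducial_estimates.json"))
    write_transform(s$ground_truth, file.path(sd_, "truth_trans.txt"))
    write_transform(s$manual, file.path(sd_, "manual_trans.txt"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_subjects <- function(dir) {
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  subdirs <- subdirs[grepl("sub-\\d+$", subdirs)]
  if (length(subdirs) == 0) stop("no sub-XX directories under ", dir)
  lapply(subdirs, function(sd_) {
    list(surface = read_surface(file.path(sd_, "surface.ply")),
         headshape = read_headshape(file.path(sd_, "headshape.txt")),
         fiducial_estimates =
           read_fiducials(file.path(sd_, "fiducial_estimates.json")),
         ground_truth = read_transform(file.path(sd_, "truth_trans.txt")),
         manual = read_transform(file.path(sd_, "manual_trans.txt")),
         path = sd_)
  })
}
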