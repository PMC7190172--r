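# Small geometric fixtures, all built in code.

# two triangles tiling the unit square in the z = 0 plane
unit_square_surface <- function() {
  head_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3), c(1, 3, 4)))
}

tetra_surface <- function() {
  head_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# regular icosahedron with edge length `edge`, centred at the origin
icosahedron_surface <- function(edge = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  head_surface(v * (edge / 2), f)
}

# one fast synthetic subject (coarser mesh than the cohort default)
tiny_subject <- function(seed = 1, noise_sd = 0, outlier_fraction = 0,
                         subdivisions = 3L, ...) {
  truth <- sample_ground_truth_transform(seed)
  spec <- subject_spec(seed = seed + 1000L, ground_truth = truth,
                       noise_sd = noise_sd,
                       outlier_fraction = outlier_fraction,
                       subdivisions = subdivisions, ...)
  surface <- generate_head_surface(spec)
  headshape <- generate_headshape(surface, spec)
  estimates <- coregkit:::with_rng(seed + 2000L, {
    lapply(surface$fiducials, function(p) {
      p + stats::rnorm(3, sd = spec$template_jitter_sd)
    })
  })
  list(spec = spec, truth = truth, surface = surface,
       headshape = headshape, estimates = estimates)
}

# a minimal coreg_result stub for statistics-level tests
fake_result <- function(median_error, transform = identity_transform(),
                        n_headshape = 100L) {
  structure(list(transform = transform,
                 distances_all = rep(median_error, n_headshape),
                 median_error = median_error,
                 iqr_low = median_error, iqr_high = median_error,
                 outlier_indices = integer(0), converged = TRUE,
                 iteration_trace = list(initial = numeric(0),
                                        final = numeric(0)),
                 quality_flag = median_error > 2,
                 quality_threshold = 2,
                 n_headshape = n_headshape),
            class = "coreg_result")
}
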