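test_that("template fiducials map through the affine exactly", {
  fid <- list(nasion = c(0, 95, 0), lpa = c(-72, 0, -5), rpa = c(72, 0, -5))
  expect_equal(template_fiducials_to_subject(fid, diag(4)), fid)

  shift <- diag(4); shift[2, 4] <- 10
  out <- template_fiducials_to_subject(fid, shift)
  expect_equal(out$nasion[2], fid$nasion[2] + 10)

  # a genuinely affine (scaled, sheared) template-to-subject matrix
  m <- diag(4)
  m[1:3, 1:3] <- rbind(c(1.1, 0.05, 0), c(0, 0.95, 0.02), c(0.01, 0, 1.04))
  m[1:3, 4] <- c(3, -2, 7)
  out <- template_fiducials_to_subject(fid, m)
  for (nm in names(fid)) {
    expect_equal(out[[nm]], drop(m[1:3, 1:3] %*% fid[[nm]] + m[1:3, 4]))
  }

  sing <- diag(4); sing[1, 1] <- 0
  expect_error(template_fiducials_to_subject(fid, sing), "singular")
})

test_that("ICP is a fixed point for on-surface points at the truth", {
  sub <- tiny_subject(seed = 2, noise_sd = 0)
  pts <- sub$headshape$points[sub$headshape$roles == "headshape", ]
  r <- icp(pts, sub$surface, sub$truth, n_iter = 5)
  expect_lt(r$trace[1], 1e-9)
  expect_lt(max(abs(as.matrix(r$transform) - as.matrix(sub$truth))), 1e-6)
})

test_that("ICP undoes a small known rigid perturbation", {
  sub <- tiny_subject(seed = 3, noise_sd = 0)
  pts <- sub$headshape$points[sub$headshape$roles == "headshape", ]
  nudge <- recompose(transform_params(tx = 3, ty = -2, tz = 1.5,
                                      pitch = 3, roll = -2, yaw = 2))
  init <- compose(nudge, sub$truth)
  r <- icp(pts, sub$surface, init, n_iter = 100, tol = 1e-9)
  err <- abs(params_vec(r$transform) - params_vec(sub$truth))
  expect_lt(max(err[1:3]), 0.1)  # mm
  expect_lt(max(err[4:6]), 0.1)  # degrees
})

test_that("ICP traces never increase and inputs are validated", {
  for (seed in 1:5) {
    sub <- tiny_subject(seed = seed, noise_sd = 1.5,
                        outlier_fraction = 0.02)
    res <- auto_coregister(sub$headshape, sub$surface, sub$estimates)
    for (tr in res$iteration_trace) {
      if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
    }
  }
  sub <- tiny_subject(seed = 1)
  expect_error(icp(matrix(1:6, 2, 3), sub$surface, sub$truth), "at least 3")
  expect_error(icp(matrix(1, 5, 3), sub$surface, sub$truth), "coincident")
})

test_that("outlier removal keeps exactly the points within threshold", {
  sq <- unit_square_surface()
  pts <- rbind(c(0.5, 0.5, 0), c(0.2, 0.2, 4.9), c(0.2, 0.8, 5.0),
               c(0.8, 0.2, 5.1), c(0.5, 0.5, 10))
  keep <- remove_outliers(pts, sq, identity_transform(), threshold = 5)
  expect_identical(keep, c(1L, 2L, 3L))

  # matches a brute-force count over oracle distances
  set.seed(91)
  s <- icosahedron_surface(3)
  q <- matrix(stats::rnorm(90, sd = 2), 30, 3)
  keep <- remove_outliers(q, s, identity_transform(), threshold = 1)
  d <- oracle_mesh_distance(q, s)
  expect_identical(keep, which(d <= 1))

  expect_error(remove_outliers(matrix(c(0, 0, 100), 1), sq,
                               identity_transform(), 5), "failed")
})

test_that("outlier pass is a no-op on outlier-free data", {
  sub <- tiny_subject(seed = 6, noise_sd = 0)
  a <- auto_coregister(sub$headshape, sub$surface, sub$estimates)
  big <- coreg_config(outlier_threshold = 1e6)
  b <- auto_coregister(sub$headshape, sub$surface, sub$estimates, big)
  expect_equal(length(a$outlier_indices), 0)
  expect_lt(max(abs(as.matrix(a$transform) - as.matrix(b$transform))), 1e-6)
})

test_that("noise-free auto co-registration recovers the ground truth", {
  sub <- tiny_subject(seed = 8, noise_sd = 0)
  res <- auto_coregister(sub$headshape, sub$surface, sub$estimates)
  expect_lt(res$median_error, 0.1)
  err <- abs(params_vec(res$transform) - params_vec(sub$truth))
  expect_lt(max(err[1:3]), 0.5)
  expect_lt(max(err[4:6]), 0.5)
  expect_false(res$quality_flag)
})

test_that("median error under noise matches a Monte-Carlo half-normal oracle", {
  # for isotropic digitizer noise on a locally flat surface the point-to-
  # surface residual is |N(0, sigma)| along the normal; simulate its median
  sigma <- 1
  set.seed(101)
  mc <- replicate(100, stats::median(abs(stats::rnorm(150, sd = sigma))))
  expected <- mean(mc)
  sub <- tiny_subject(seed = 10, noise_sd = sigma, subdivisions = 4L,
                      noise_outward_frac = 0)
  res <- auto_coregister(sub$headshape, sub$surface, sub$estimates)
  expect_lt(abs(res$median_error - expected) / expected, 0.2)
})

test_that("evaluate_transform is consistent with the pipeline metric", {
  sub <- tiny_subject(seed = 12, noise_sd = 1.5, outlier_fraction = 0.02)
  res <- auto_coregister(sub$headshape, sub$surface, sub$estimates)
  again <- evaluate_transform(sub$headshape, sub$surface, res$transform)
  expect_identical(again$distances_all, res$distances_all)
  expect_identical(again$median_error, res$median_error)
  expect_equal(res$median_error, stats::median(res$distances_all))
  expect_equal(c(res$iqr_low, res$iqr_high),
               unname(stats::quantile(res$distances_all, c(0.25, 0.75))))

  # ground truth on noise-free points scores zero
  clean <- tiny_subject(seed = 12, noise_sd = 0)
  perfect <- evaluate_transform(clean$headshape, clean$surface, clean$truth)
  expect_lt(perfect$median_error, 1e-9)
})

test_that("evaluating the identity on a displaced head shows the offset", {
  truth <- recompose(transform_params(tz = -70))
  spec <- subject_spec(seed = 14, ground_truth = truth, noise_sd = 0,
                       outlier_fraction = 0, subdivisions = 3L)
  surf <- generate_head_surface(spec)
  hs <- generate_headshape(surf, spec)
  res <- evaluate_transform(hs, surf, identity_transform())
  # independent check of the same distances
  pts <- hs$points[hs$roles == "headshape", ]
  expect_equal(res$distances_all, unname(oracle_mesh_distance(pts, surf)),
               tolerance = 1e-9)
  # the displaced head still overlaps the original, so typical distances are
  # large but well below the 70 mm shift itself
  expect_gt(res$median_error, 10)
  expect_lt(res$median_error, 70)
  expect_true(res$quality_flag)
})

test_that("the pipeline is deterministic for identical inputs", {
  sub <- tiny_subject(seed = 16, noise_sd = 1.5)
  a <- auto_coregister(sub$headshape, sub$surface, sub$estimates)
  b <- auto_coregister(sub$headshape, sub$surface, sub$estimates)
  expect_identical(a$transform$matrix, b$transform$matrix)
  expect_identical(a$distances_all, b$distances_all)
  expect_identical(a$iteration_trace, b$iteration_trace)
})
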