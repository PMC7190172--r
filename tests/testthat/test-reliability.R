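test_that("icc_3_1 matches the two-way ANOVA oracle", {
  # perfect consistency despite a constant method offset
  x <- cbind(c(1, 3, 5), c(2, 4, 6))
  expect_equal(icc_3_1(x), 1.0)
  expect_equal(icc_3_1(x), oracle_icc31_aov(x))

  base <- cbind(c(2, 7, 4, 9, 1), c(2.5, 6.5, 4.5, 8.0, 1.5))
  expect_equal(icc_3_1(base), oracle_icc31_aov(base), tolerance = 1e-12)

  set.seed(111)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    k <- sample(2:5, 1)
    tab <- matrix(stats::rnorm(n * k, sd = stats::runif(1, 0.5, 10)), n, k) +
      stats::rnorm(n)
    expect_equal(icc_3_1(tab), oracle_icc31_aov(tab), tolerance = 1e-10)
  }
})

test_that("icc_3_1 handles edge cases and invariances", {
  expect_error(icc_3_1(matrix(5, 4, 2)), "identical")
  expect_error(icc_3_1(matrix(1:4, 2, 2)), "3 subjects")

  set.seed(121)
  tab <- matrix(stats::rnorm(60), 20, 3) + stats::rnorm(20)
  # consistency: per-method constant offsets do not change the value
  shifted <- sweep(tab, 2, c(10, -3, 0.5), "+")
  expect_equal(icc_3_1(shifted), icc_3_1(tab), tolerance = 1e-12)
  # common positive rescaling does not change the value
  expect_equal(icc_3_1(tab * 7.3), icc_3_1(tab), tolerance = 1e-12)

  # independent columns at large n sit near zero
  big <- matrix(stats::rnorm(20000), 10000, 2)
  expect_lt(abs(icc_3_1(big)), 0.05)
})

test_that("icc calibration recovers the variance ratio", {
  set.seed(131)
  sb <- 2; se <- 1.2
  n <- 5000
  subj <- stats::rnorm(n, sd = sb)
  tab <- cbind(subj + stats::rnorm(n, sd = se),
               subj + stats::rnorm(n, sd = se))
  expect_lt(abs(icc_3_1(tab) - sb^2 / (sb^2 + se^2)), 0.05)
})

test_that("icc_2_1 penalizes systematic offsets where icc_3_1 does not", {
  set.seed(141)
  subj <- stats::rnorm(30, sd = 2)
  tab <- cbind(subj + stats::rnorm(30, sd = 0.5),
               subj + stats::rnorm(30, sd = 0.5) + 3)
  expect_lt(icc_2_1(tab), icc_3_1(tab))
  no_offset <- cbind(subj, subj)
  expect_equal(icc_2_1(no_offset), 1, tolerance = 1e-9)
})

test_that("pearson_r matches the textbook formula and t-test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_r(x, -x)$r, -1.0)

  set.seed(151)
  a <- stats::rnorm(40); b <- 0.4 * a + stats::rnorm(40)
  got <- pearson_r(a, b)
  ref <- oracle_pearson(a, b)
  expect_equal(got$r, ref$r, tolerance = 1e-12)
  expect_equal(got$p, ref$p, tolerance = 1e-12)

  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Cohen's d conversion is exact, odd and monotone", {
  expect_equal(round(cohens_d_from_r(0.541), 2), 1.29)
  expect_equal(cohens_d_from_r(0), 0)
  for (r in c(0.1, 0.35, 0.7, 0.95)) {
    expect_equal(cohens_d_from_r(-r), -cohens_d_from_r(r))
  }
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(vapply(rs, cohens_d_from_r, 0)) > 0))
  expect_error(cohens_d_from_r(1), "inside")
})

test_that("ICC bands follow the Cicchetti cut points", {
  expect_equal(classify_icc(0.472), "fair")
  expect_equal(classify_icc(0.903), "excellent")
  expect_equal(classify_icc(0.40), "fair")
  expect_equal(classify_icc(0.60), "good")
  expect_equal(classify_icc(0.75), "excellent")
  expect_equal(classify_icc(0.399), "poor")
  expect_equal(classify_icc(-0.2), "poor")
  expect_error(classify_icc(1.2), "\\[-1, 1\\]")
})

test_that("compare_methods on identical inputs is a perfect comparison", {
  set.seed(161)
  res <- lapply(c(1.2, 1.5, 1.1, 1.9, 1.4), function(e) {
    fake_result(e, oracle_random_rigid())
  })
  rep_ <- compare_methods(res, res, headshape_counts = c(90, 150, 120, 200, 101))
  expect_equal(rep_$measures$mean_diff, rep(0, 7))
  expect_equal(rep_$measures$icc, rep(1, 7))
  expect_equal(rep_$n_excluded, 0)
  expect_equal(rep_$icc_error_after_exclusion, 1)
})

test_that("the >2 mm exclusion drops exactly the offending subjects", {
  set.seed(171)
  tra <- replicate(3, oracle_random_rigid(), simplify = FALSE)
  a <- lapply(seq(3), function(i) fake_result(c(1.4, 1.6, 1.5)[i], tra[[i]]))
  b <- lapply(seq(3), function(i) fake_result(c(1.5, 2.5, 1.9)[i], tra[[i]]))
  rep_ <- compare_methods(a, b, headshape_counts = c(100, 140, 180))
  expect_equal(rep_$n_excluded, 1)
  expect_equal(rep_$excluded_subjects, 2L)
  # exactly at the threshold is not excluded
  b2 <- b; b2[[2]] <- fake_result(2.0, tra[[2]])
  expect_equal(compare_methods(a, b2, c(100, 140, 180))$n_excluded, 0)
})

test_that("every report field equals an independent scripted computation", {
  set.seed(181)
  n <- 12
  tra <- replicate(n, oracle_random_rigid(), simplify = FALSE)
  trb <- replicate(n, oracle_random_rigid(), simplify = FALSE)
  ea <- stats::runif(n, 0.8, 2.4)
  eb <- ea + stats::rnorm(n, sd = 0.3)
  counts <- sample(83:229, n)
  a <- lapply(seq(n), function(i) fake_result(ea[i], tra[[i]]))
  b <- lapply(seq(n), function(i) fake_result(eb[i], trb[[i]]))
  rep_ <- compare_methods(a, b, counts)

  # error row
  er <- rep_$measures[rep_$measures$measure == "error", ]
  expect_equal(er$median_a, stats::median(ea))
  expect_equal(er$median_b, stats::median(eb))
  expect_equal(er$mean_diff, mean(eb - ea))
  expect_equal(er$sd_diff, stats::sd(eb - ea))
  expect_equal(er$icc, oracle_icc31_aov(cbind(ea, eb)), tolerance = 1e-12)
  expect_equal(rep_$error_pearson$r, oracle_pearson(ea, eb)$r,
               tolerance = 1e-12)
  expect_equal(rep_$error_cohens_d,
               2 * rep_$error_pearson$r / sqrt(1 - rep_$error_pearson$r^2))

  # one decomposed parameter row, checked end to end
  pa <- vapply(tra, function(t) params_vec(t)["pitch"], 0)
  pb <- vapply(trb, function(t) params_vec(t)["pitch"], 0)
  pr <- rep_$measures[rep_$measures$measure == "pitch", ]
  expect_equal(pr$median_a, stats::median(pa))
  expect_equal(pr$iqr_b_low, unname(stats::quantile(pb, 0.25)))
  expect_equal(pr$icc, oracle_icc31_aov(cbind(pa, pb)), tolerance = 1e-12)

  # exclusion rerun
  kept <- which(eb <= 2)
  expect_equal(rep_$icc_error_after_exclusion,
               oracle_icc31_aov(cbind(ea[kept], eb[kept])), tolerance = 1e-12)
  expect_equal(rep_$n_excluded, sum(eb > 2))

  # headshape-count correlations
  expect_equal(rep_$headshape_count_correlation$a$r,
               oracle_pearson(ea, counts)$r, tolerance = 1e-12)
  expect_equal(rep_$headshape_count_correlation$b$p,
               oracle_pearson(eb, counts)$p, tolerance = 1e-12)

  expect_error(compare_methods(a, b[-1]), "mismatched")
})
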