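test_that("the blurring metric matches set arithmetic and its degenerate cases", {
  roi <- rep(c(TRUE, FALSE), length.out = 40)
  expect_equal(blurring_metric(list(roi, roi, roi))$B, 0)

  a <- c(rep(TRUE, 10), rep(FALSE, 30))
  b <- c(rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 20))
  two <- blurring_metric(list(a, b))
  expect_equal(two$B, 100)
  expect_equal(two$union_size, 20)
  expect_equal(two$mean_size, 10)

  set.seed(12)
  for (i in 1:20) {
    rois <- replicate(sample(2:8, 1),
                      runif(120) < runif(1, 0.05, 0.5), simplify = FALSE)
    if (all(!unlist(lapply(rois, any)))) next
    expect_equal(blurring_metric(rois)$B, oracle_blurring(rois),
                 tolerance = 1e-10)
  }
  expect_error(blurring_metric(list(logical(5), logical(5))), "empty")
})

test_that("central tendency evaluates its anchors, variants and monotonicity", {
  f <- c(1, 0.5, 0)
  expect_equal(central_tendency(f, c(1, 1, 0)), 1)             # covers support
  expect_equal(central_tendency(f, c(1, 0, 0)), 4 / 3)         # peak overlap
  expect_equal(central_tendency(f, c(0, 0, 1)), 0)             # no overlap
  expect_equal(central_tendency(c(1, 1, 0), c(1, 1, 0),
                                "overlap-fraction"), 1)
  expect_error(central_tendency(c(0, 0), c(1, 0)), "nonzero")

  # moving a fixed-size ROI from the periphery towards the peak never
  # decreases P (non-zero-mean variant)
  fpm <- c(0.1, 0.3, 0.6, 1, 0.6, 0.3, 0.1, 0, 0, 0)
  width <- 3
  p_along <- vapply(1:5, function(start) {
    d <- rep(0, 10)
    d[start:(start + width - 1)] <- 1
    central_tendency(fpm, d)
  }, numeric(1))
  expect_true(all(diff(p_along[1:3]) >= 0))   # approaching the peak
  expect_true(all(diff(p_along[4:5]) <= 0))   # leaving it

  set.seed(77)
  for (i in 1:20) {
    f <- runif(80) * rbinom(80, 1, 0.6)
    if (!any(f > 0)) next
    d <- runif(80) < 0.3
    for (v in c("nonzero-mean", "overlap-fraction"))
      expect_equal(central_tendency(f, d, v),
                   oracle_central_tendency(f, d, v), tolerance = 1e-10)
  }
})

test_that("leave-one-out central tendency is an identity for identical cohorts and order-invariant", {
  s <- make_cohort(2, jitter_sd = 0, digit_size_cv = 0, seed = 4)[[1]]
  dm <- digit_map(s$truth_labels, s$domain)
  same <- replicate(5, dm, simplify = FALSE)
  M <- loo_central_tendency(same, mode = "fpm")
  expect_equal(diag(M), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(M[upper.tri(M) | lower.tri(M)], rep(0, 20), tolerance = 1e-12)
  expect_identical(attr(M, "folds"), 5L)

  co <- make_cohort(6, jitter_sd = 1, digit_size_cv = 0.05, seed = 8)
  dms <- lapply(co, function(x) digit_map(x$truth_labels, x$domain))
  A <- loo_central_tendency(dms, mode = "fpm")
  B <- loo_central_tendency(dms[c(4, 2, 6, 1, 5, 3)], mode = "fpm")
  expect_equal(unclass(A)[, ], unclass(B)[, ], tolerance = 1e-12)

  # MPM mode defaults to the overlap-fraction variant and stays within [0, 1]
  Mm <- loo_central_tendency(dms, mode = "mpm")
  expect_true(all(Mm >= 0 & Mm <= 1))
  expect_identical(attr(Mm, "variant"), "overlap-fraction")
  expect_error(loo_central_tendency(dms[1:2]), "at least 3")
})

test_that("ROI sizes weight location counts by the domain measure", {
  dom <- sample_domain(c(5, 4, 1), spacing = c(2, 2, 2))
  labs <- integer(dom$n_loc)
  labs[1:10] <- 1L
  sz <- roi_sizes(list(digit_map(labs, dom)))
  expect_equal(sz$size[sz$digit == 1], 80)    # 10 voxels x 8 mm^3
  expect_equal(sz$size[sz$digit == 5], 0)

  vdom <- sample_domain(30, measure = runif(30, 0.5, 1.5), type = "surface")
  vlab <- sample(0:5, 30, replace = TRUE)
  vsz <- roi_sizes(list(structure(list(subject = "a", hand = "left",
                                       labels = vlab, domain = vdom),
                                  class = "digit_map")), vdom)
  for (d in 1:5) {
    acc <- 0
    for (v in 1:30) if (vlab[v] == d) acc <- acc + vdom$measure[v]
    expect_equal(vsz$size[vsz$digit == d], acc, tolerance = 1e-12)
  }
})

test_that("pairwise size tests equal a direct t-test oracle with Bonferroni-by-10", {
  set.seed(21)
  sizes <- data.frame(
    subject = rep(sprintf("S%02d", 1:12), each = 5),
    hand = "left", digit = rep(1:5, 12),
    size = 100 + rnorm(60, sd = 10))
  # shrink digit 5 to a third of the rest
  sizes$size[sizes$digit == 5] <- sizes$size[sizes$digit == 5] / 3
  M <- pairwise_size_tests(sizes)
  expect_equal(M, t(M), ignore_attr = TRUE)
  expect_equal(diag(M), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    p <- stats::t.test(sizes$size[sizes$digit == i],
                       sizes$size[sizes$digit == j],
                       var.equal = TRUE)$p.value
    expect_equal(M[i, j], log10(min(1, 10 * p)), tolerance = 1e-10)
  }
  expect_true(all(M[5, 1:4] < log10(0.05)))   # D5 significantly smaller

  # equal groups: corrected p caps at 1, log10 = 0
  flat <- sizes
  flat$size <- rep(c(99, 101), 30)
  expect_equal(max(abs(pairwise_size_tests(flat))), 0)
})

test_that("a generated small-D5 cohort flags all four D5 comparisons", {
  co <- make_cohort(22, jitter_sd = 1, digit_size_cv = 0.1, seed = 13,
                    digit_rel_widths = c(1, 1, 1, 1, 1 / 3))
  dms <- lapply(co, function(s) digit_map(s$truth_labels, s$domain,
                                          subject = s$id, hand = s$hand))
  M <- pairwise_size_tests(roi_sizes(dms))
  expect_true(all(M[5, 1:4] < log10(0.05)))
})

test_that("curvature variability reduces to two-point formulas and a sorting oracle", {
  n <- 50
  flat <- curvature_variability(list(rnorm(n), rnorm(n))[c(1, 1)])
  expect_equal(max(flat$sd), 0)

  two <- curvature_variability(list(rep(0, n), rep(1, n)),
                               rois = list(all = rep(TRUE, n)))
  expect_equal(unique(two$sd), sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(two$roi_median_sd["all"]), sqrt(0.5), tolerance = 1e-12)

  set.seed(3)
  maps <- replicate(4, rnorm(n), simplify = FALSE)
  roi <- runif(n) < 0.4
  cv <- curvature_variability(maps, rois = list(r = roi))
  sd_loop <- vapply(seq_len(n), function(v)
    stats::sd(c(maps[[1]][v], maps[[2]][v], maps[[3]][v], maps[[4]][v])),
    numeric(1))
  expect_equal(cv$sd, sd_loop, tolerance = 1e-12)
  inside <- sort(sd_loop[roi])
  m <- length(inside)
  med <- if (m %% 2 == 1) inside[(m + 1) / 2] else
    (inside[m / 2] + inside[m / 2 + 1]) / 2
  expect_equal(unname(cv$roi_median_sd["r"]), med, tolerance = 1e-12)
})

test_that("the handedness index is a bounded signed ratio", {
  expect_equal(handedness_index(10, 0)$H, 1)
  expect_equal(handedness_index(7, 7)$H, 0)
  expect_equal(handedness_index(0, 4)$H, -1)
  expect_error(handedness_index(0, 0), "positive")
  expect_error(handedness_index(-1, 2), "non-negative")
})
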