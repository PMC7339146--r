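rand_digit_map <- function(dom, hand = "left", p_zero = 0.5) {
  labs <- sample(0:5, dom$n_loc, replace = TRUE,
                 prob = c(p_zero, rep((1 - p_zero) / 5, 5)))
  digit_map(labs, dom, hand = hand)
}

test_that("FPM probabilities are per-location subject fractions", {
  dom <- tiny_domain()
  same <- replicate(4, digit_map(rep(c(1L, 0L), length.out = dom$n_loc), dom),
                    simplify = FALSE)
  fpm <- build_fpm(same)
  expect_equal(fpm$prob[1, 1], 1)
  expect_equal(max(fpm$prob[, 2:5]), 0)

  set.seed(5)
  cohort <- replicate(7, rand_digit_map(dom), simplify = FALSE)
  fpm <- build_fpm(cohort)
  labs <- lapply(cohort, `[[`, "labels")
  for (d in 1:5)
    expect_equal(fpm$prob[, d], oracle_fpm_tally(labs, d), tolerance = 1e-12)
  expect_true(all(abs(fpm$prob * 7 - round(fpm$prob * 7)) < 1e-9))
  expect_true(all(rowSums(fpm$prob) <= 1 + 1e-12))

  mixed <- cohort
  mixed[[2]]$hand <- "right"
  expect_error(build_fpm(mixed), "same hand")
  expect_error(build_fpm(cohort[1]), "at least 2")
})

test_that("the digit hand ROI uses a strict threshold", {
  dom <- sample_domain(c(3, 1, 1))
  fpm <- structure(list(prob = matrix(c(0.6, 0.5, 0, rep(0, 12)), nrow = 3),
                        n_subjects = 10, hand = "left", domain = dom),
                   class = "fpm_atlas")
  roi <- hand_roi(fpm, 0.5)
  expect_identical(roi$mask, c(TRUE, FALSE, FALSE))
  expect_false(any(hand_roi(structure(list(prob = matrix(0, 3, 5),
                                           n_subjects = 2, hand = "left",
                                           domain = dom),
                                      class = "fpm_atlas"))$mask))
})

test_that("the MPM is the tie-broken argmax inside the hand ROI", {
  dom <- sample_domain(c(3, 1, 1))
  prob <- rbind(c(0.1, 0.6, 0.2, 0, 0),
                c(0.3, 0.3, 0, 0, 0),
                c(0.9, 0, 0, 0, 0))
  fpm <- structure(list(prob = prob, n_subjects = 10, hand = "left",
                        domain = dom), class = "fpm_atlas")
  roi <- structure(list(mask = c(TRUE, TRUE, FALSE), threshold = 0.5,
                        domain = dom), class = "hand_roi")
  mpm <- build_mpm(fpm, roi)
  expect_identical(mpm$labels, c(2L, 1L, 0L))    # argmax, tie -> lowest, 0 outside
  expect_identical(mpm$ties, c(FALSE, TRUE, FALSE))
})

test_that("a cohort of identical digit maps reproduces itself exactly, order-independently", {
  s <- make_cohort(2, jitter_sd = 0, digit_size_cv = 0, seed = 9)[[1]]
  dm <- digit_map(s$truth_labels, s$domain)
  cohort <- replicate(6, dm, simplify = FALSE)
  fpm <- build_fpm(cohort)
  expect_true(all(fpm$prob %in% c(0, 1)))
  roi <- hand_roi(fpm)
  expect_identical(roi$mask, s$truth_labels > 0L)
  mpm <- build_mpm(fpm, roi)
  expect_identical(mpm$labels, s$truth_labels)

  set.seed(31)
  varied <- lapply(1:5, function(i) {
    labs <- s$truth_labels
    flip <- sample(which(labs > 0), 30)
    labs[flip] <- sample(1:5, 30, replace = TRUE)
    digit_map(labs, s$domain)
  })
  a <- build_mpm(build_fpm(varied), hand_roi(build_fpm(varied)))
  shuffled <- varied[c(3, 1, 5, 2, 4)]
  b <- build_mpm(build_fpm(shuffled), hand_roi(build_fpm(shuffled)))
  expect_identical(a$labels, b$labels)
})

test_that("nearest-neighbour resampling preserves values and matches the oracle", {
  from <- sample_domain(c(8, 8, 1))
  checker <- as.numeric((outer(1:8, 1:8, `+`) %% 2) == 0)
  expect_identical(resample_nearest(checker, from, from), checker)

  # half-resolution downsample (offset avoids equidistant ties)
  to <- sample_domain(c(4, 4, 1), spacing = c(2, 2, 1))
  shift <- function(p) p - 0.25
  got <- resample_nearest(checker, from, to, shift)
  expect_equal(got, oracle_nn(checker, from, to, shift), tolerance = 0)
  expect_true(all(got %in% checker))

  labels <- sample(0:5, from$n_loc, replace = TRUE)
  out <- resample_nearest(labels, from, to, function(p) p + 0.13)
  expect_true(all(out %in% 0:5))

  far <- function(p) p + 1000
  expect_error(resample_nearest(checker, from, to, far), "outside the source")
})

test_that("rebinarise keeps the inclusive 0.5 edge and is idempotent on binary maps", {
  expect_identical(rebinarise(c(0.5, 0.49, 1, 0)), c(1, 0, 1, 0))
  expect_identical(rebinarise(rep(0, 4)), rep(0, 4))
  b <- c(0, 1, 1, 0)
  expect_identical(rebinarise(b), b)
  expect_error(rebinarise(c(-0.1, 2)), "\\[0, 1\\]")
})

test_that("group phase maps summarise circular structure inside the MPM", {
  s <- make_cohort(2, jitter_sd = 0, digit_size_cv = 0, seed = 9)[[1]]
  dm <- digit_map(s$truth_labels, s$domain)
  fpm <- build_fpm(list(dm, dm, dm))
  mpm <- build_mpm(fpm, hand_roi(fpm))
  mk <- function(ph) structure(list(phase = rep(ph, s$domain$n_loc),
                                    domain = s$domain, subject = NA_character_),
                               class = "phase_map")
  same <- group_phase_maps(list(mk(1), mk(1)), mpm)
  expect_equal(max(same$sd[mpm$labels > 0]), 0, tolerance = 1e-9)
  mixed <- group_phase_maps(list(mk(0), mk(pi / 2)), mpm)
  expect_equal(unique(round(mixed$mean[mpm$labels > 0], 9)), round(pi / 4, 9))
  expect_true(all(is.na(mixed$mean[mpm$labels == 0])))

  # noiseless cohort: per-ROI mean phase falls inside each digit's bin
  rr <- make_runs(s, noise_sd = 0, drift_amp = 0, seed = 1)
  pm <- analyse_pair(rr)
  tab <- group_phase_maps(list(pm, pm), mpm)$table
  for (d in 1:5) {
    mp <- tab$mean_phase[tab$digit == d][1]
    expect_gte(mp, (d - 1) * 2 * pi / 5)
    expect_lt(mp, d * 2 * pi / 5)
  }
})
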