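# helper: wrap a bare locations x time matrix as a run
mat_run <- function(data, acq = acq_params(), direction = "forward") {
  dom <- sample_domain(c(nrow(data), 1, 1))
  structure(list(data = data, direction = direction, acq = acq,
                 domain = dom, subject = NA_character_, hp_cutoff = NULL),
            class = "tw_run")
}

test_that("preprocessing removes the mean, rescales to percent signal and kills drift", {
  acq <- acq_params()
  t_s <- (seq_len(acq$n_volumes) - 1) * acq$TR
  sig <- rbind(
    rep(100, acq$n_volumes),
    100 + 10 * sin(2 * pi * acq$stim_freq * t_s),
    100 + 5 * cos(2 * pi * 0.005 * t_s)
  )
  out <- preprocess_run(mat_run(sig), cutoff_hz = 0.01)
  expect_equal(out$data[1, ], rep(0, acq$n_volumes), tolerance = 1e-12)

  pm <- fourier_analyze(out)
  expect_equal(pm$amplitude[2], 10, tolerance = 1e-6)
  # sin(wt) = cos(wt - pi/2): percent-signal scaling must leave phase alone
  expect_equal(pm$phase[2], pi / 2, tolerance = 1e-9)
  # drift row: residual power at 0.005 Hz below 1% of input, matching a
  # direct DFT-zeroing oracle
  n <- acq$n_volumes
  X <- fft(out$data[3, ])
  k_slow <- 0.005 * n * acq$TR + 1
  expect_lt(Mod(X[k_slow])^2, 0.01 * Mod(fft(sig[3, ] - 100)[k_slow])^2)
  oracle <- {
    Y <- fft(100 * (sig[3, ] - mean(sig[3, ])) / mean(sig[3, ]))
    Y[c(k_slow, n + 2 - k_slow)] <- 0
    Re(fft(Y, inverse = TRUE)) / n
  }
  expect_equal(out$data[3, ], oracle, tolerance = 1e-9)

  expect_error(preprocess_run(mat_run(sig), cutoff_hz = 0.05),
               "below the stimulation frequency")
  neg <- sig
  neg[1, ] <- -1
  expect_error(preprocess_run(mat_run(neg)), "positive mean")
})

test_that("Fourier analysis recovers amplitude, phase and coherence of pure sinusoids", {
  acq <- acq_params()
  t_s <- (seq_len(acq$n_volumes) - 1) * acq$TR
  phases <- (0:31) * 2 * pi / 32
  sig <- t(vapply(phases, function(p)
    cos(2 * pi * acq$stim_freq * t_s - p), numeric(acq$n_volumes)))
  pm <- fourier_analyze(mat_run(sig))
  expect_lt(max(abs(wrap_to_pi(pm$phase - phases))), 1e-9)
  expect_equal(pm$coherence, rep(1, 32), tolerance = 1e-9)
  expect_equal(pm$amplitude, rep(1, 32), tolerance = 1e-9)

  # coherence is invariant to gain
  pm2 <- fourier_analyze(mat_run(2 * sig + matrix(rnorm(32 * 100, 0, 0.1) * 0, 32)))
  expect_equal(pm2$coherence, pm$coherence, tolerance = 1e-12)

  # a run that does not hold whole cycles is rejected
  bad <- mat_run(sig[, 1:97])
  bad$acq <- acq
  expect_error(fourier_analyze(bad), "whole cycles")
})

test_that("white-noise coherence matches an independent Monte-Carlo expectation", {
  acq <- acq_params(n_cycles = 4)   # 40 volumes
  n <- acq$n_volumes
  set.seed(101)
  pm <- fourier_analyze(mat_run(matrix(rnorm(10000 * n), ncol = n), acq))
  # independent oracle: explicit DFT by matrix multiplication on fresh draws
  set.seed(202)
  k <- acq$n_cycles
  t_i <- 0:(n - 1)
  basis <- exp(-2i * pi * outer(t_i, seq_len(n %/% 2)) / n)
  x <- matrix(rnorm(10000 * n), ncol = n)
  X <- x %*% basis
  coh_oracle <- Mod(X[, k]) / sqrt(rowSums(Mod(X)^2))
  expect_equal(mean(pm$coherence), mean(coh_oracle), tolerance = 0.02)
})

test_that("run combination cancels the haemodynamic delay for every tested delay", {
  for (delay in c(0, 2, 5, 8)) {
    s <- noiseless_subject(delay = delay)
    rr <- make_runs(s, noise_sd = 0, drift_amp = 0, seed = 1)
    pm <- analyse_pair(rr)
    resp <- s$truth_labels > 0
    expect_lt(max(abs(wrap_to_pi(pm$phase[resp] - truth_phase_of(s)[resp]))),
              1e-6)
    expect_equal(pm$delay_est_s, delay, tolerance = 1e-6)
  }
})

test_that("combining two identically-phased maps is the identity, and acq must match", {
  s <- noiseless_subject(delay = 0)
  rr <- make_runs(s, noise_sd = 0, drift_amp = 0, seed = 1)
  fwd <- fourier_analyze(preprocess_run(rr$forward))
  bwd <- fourier_analyze(preprocess_run(rr$backward))
  pm <- combine_runs(fwd, bwd)
  resp <- s$truth_labels > 0
  expect_lt(max(abs(wrap_to_pi(pm$phase[resp] - fwd$phase[resp]))), 1e-9)

  other <- fwd
  other$acq <- acq_params(n_cycles = 8)
  other$n_volumes <- other$acq$n_volumes
  expect_error(combine_runs(fwd, other), "acquisition")
})

test_that("coherence-to-t behaves at the null, at saturation, and monotonically", {
  acq <- acq_params()
  base <- structure(list(coherence = c(0, 0.3, 0.6, 0.9, 1),
                         n_volumes = acq$n_volumes, dof = acq$n_volumes - 3L,
                         acq = acq, domain = sample_domain(c(5, 1, 1))),
                    class = "phase_map")
  tm <- coherence_to_t(base)
  expect_equal(tm$t[1], 0)
  expect_true(all(diff(tm$t) > 0))
  expect_identical(tm$t[5], Inf)
  expect_equal(tm$dof, acq$n_volumes - 3L)
})

test_that("phase differences wrap through zero and reject empty masks", {
  dom <- sample_domain(c(3, 1, 1))
  mk <- function(ph) structure(list(phase = ph, domain = dom), class = "phase_map")
  a <- mk(c(0.1, 1, 3))
  b <- mk(c(2 * pi - 0.1, 1, 3))
  expect_equal(phase_difference(a, b, rep(TRUE, 3)), c(0.2, 0, 0),
               tolerance = 1e-12)
  expect_identical(phase_difference(a, a, rep(TRUE, 3)), rep(0, 3))
  expect_error(phase_difference(a, b, rep(FALSE, 3)), "empty mask")
})
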