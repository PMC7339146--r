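# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops and elementary arithmetic only.

oracle_circ <- function(angles) {
  s <- 0
  c_ <- 0
  for (a in angles) {
    s <- s + sin(a)
    c_ <- c_ + cos(a)
  }
  n <- length(angles)
  r <- sqrt((s / n)^2 + (c_ / n)^2)
  mu <- atan2(s, c_) %% (2 * pi)
  list(mean_direction = mu, r = r,
       circ_sd = if (r < 1e-12) Inf else sqrt(-2 * log(min(r, 1))))
}

oracle_vtest <- function(angles, mu0) {
  o <- oracle_circ(angles)
  n <- length(angles)
  V <- n * o$r * cos(o$mean_direction - mu0)
  u <- V * sqrt(2 / n)
  list(V = V, u = u, p = stats::pnorm(u, lower.tail = FALSE))
}

oracle_blurring <- function(rois) {
  n_loc <- length(rois[[1]])
  in_union <- logical(n_loc)
  total <- 0
  for (r in rois) {
    for (v in seq_len(n_loc)) if (r[v]) in_union[v] <- TRUE
    total <- total + sum(r)
  }
  mean_size <- total / length(rois)
  100 * (sum(in_union) - mean_size) / mean_size
}

oracle_central_tendency <- function(f, d, variant) {
  fd <- numeric(length(f))
  for (v in seq_along(f)) fd[v] <- f[v] * as.numeric(d[v])
  if (variant == "nonzero-mean") {
    num <- abs(fd[fd != 0])
    den <- abs(f[f != 0])
    if (length(num) == 0) return(0)
    mean(num) / mean(den)
  } else {
    sum(abs(fd)) / sum(abs(f))
  }
}

oracle_fpm_tally <- function(label_vectors, d) {
  n_loc <- length(label_vectors[[1]])
  counts <- integer(n_loc)
  for (lv in label_vectors)
    for (v in seq_len(n_loc)) if (lv[v] == d) counts[v] <- counts[v] + 1L
  counts / length(label_vectors)
}

# nearest-neighbour resampling by exhaustive search over source voxels
oracle_nn <- function(values, from, to, transform = NULL) {
  sc <- voxel_centers(from)
  tc <- voxel_centers(to)
  if (!is.null(transform)) tc <- transform(tc)
  out <- numeric(nrow(tc))
  half <- from$spacing / 2
  lo <- c(0, 0, 0)
  hi <- from$dim * from$spacing
  for (i in seq_len(nrow(tc))) {
    p <- tc[i, ]
    if (any(p < lo) || any(p > hi)) {
      # outside the grid: the package maps these to `outside` (0) unless the
      # rounded index still lands on a voxel; replicate that rule exactly by
      # distance to the nearest centre with a half-voxel tolerance
      d2 <- colSums((t(sc) - p)^2)
      j <- which.min(d2)
      out[i] <- if (all(abs(sc[j, ] - p) <= half + 1e-9)) values[j] else 0
    } else {
      d2 <- colSums((t(sc) - p)^2)
      out[i] <- values[which.min(d2)]
    }
  }
  out
}

# small helpers shared across test files -------------------------------------

tiny_domain <- function(nx = 8, ny = 6) sample_domain(c(nx, ny, 1))

noiseless_subject <- function(delay = 4, seed = 1) {
  make_cohort(2, jitter_sd = 0, digit_size_cv = 0, seed = seed,
              haemo_delay_s = delay)[[1]]
}

analyse_pair <- function(runs, cutoff = 0.01) {
  combine_runs(fourier_analyze(preprocess_run(runs$forward, cutoff)),
               fourier_analyze(preprocess_run(runs$backward, cutoff)))
}

truth_phase_of <- function(subject) {
  (subject$truth_labels - 0.5) * 2 * pi / 5
}

# a pure-noise "subject": baseline everywhere on the given domain
noise_subject <- function(domain, seed = 1) {
  s <- make_cohort(2, domain = domain, jitter_sd = 0, digit_size_cv = 0,
                   seed = seed)[[1]]
  s$truth_labels[] <- 0L
  s
}
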