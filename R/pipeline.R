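# End-to-end orchestration of the analysis flowchart:
# simulate -> phasemap -> bin -> atlas -> validate.

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[somatlas:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on a synthetic cohort: generate
#' subjects and travelling-wave runs, compute combined phase/coherence maps,
#' bin them into per-subject digit maps, build the group FPM/hand-ROI/MPM
#' atlas and compute the validation metrics. All randomness derives from
#' `config$seed`, so a rerun with the same configuration is byte-identical;
#' every written volume carries a provenance record (stage, seed and
#' configuration hash) in its header and a JSON sidecar is written next to
#' the outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed. `NULL` keeps
#'   everything in memory and writes nothing.
#' @param stages Character subset of
#'   `c("simulate", "phasemap", "bin", "atlas", "validate")`, in pipeline
#'   order. Later stages require the earlier ones in this in-memory
#'   orchestrator.
#' @return A results bundle: `subjects`, `phase_maps`, `digit_maps`, `fpm`,
#'   `hand_roi`, `mpm`, `metrics` (blurring table, leave-one-out matrix,
#'   size table, pairwise log-p matrix) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("simulate", "phasemap", "bin",
                                    "atlas", "validate")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "phasemap", "bin", "atlas", "validate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- seq_len(max(match(stages, all_stages)))
  stages <- all_stages[need]   # earlier stages feed the later ones
  hash <- .config_hash(config)
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list(config = config)

  .log_stage("simulate", "cohort of %d subjects (seed %d, jitter %g mm, noise %g)",
             config$n_subjects, config$seed, config$jitter_sd, config$noise_sd)
  subjects <- make_cohort(
    config$n_subjects, jitter_sd = config$jitter_sd,
    digit_size_cv = config$digit_size_cv, seed = config$seed,
    hand = config$hand)
  set.seed(if (is.null(config$noise_seed)) config$seed else config$noise_seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  runs <- lapply(seq_along(subjects), function(i)
    make_runs(subjects[[i]], config$acq, noise_sd = config$noise_sd,
              drift_amp = config$drift_amp, seed = run_seeds[i]))
  res$subjects <- subjects
  manifest <- data.frame(
    subject = vapply(subjects, `[[`, character(1), "id"),
    hand = config$hand, seed = run_seeds,
    jitter_tx = vapply(subjects, function(s) s$jitter$tx, numeric(1)),
    jitter_ty = vapply(subjects, function(s) s$jitter$ty, numeric(1)),
    scale = vapply(subjects, function(s) s$jitter$scale, numeric(1)),
    TR = config$TR, cycle_s = config$cycle_s, n_cycles = config$n_cycles)
  if (write_out) {
    dom <- subjects[[1]]$domain
    for (i in seq_along(subjects)) {
      s <- subjects[[i]]
      base <- file.path(out_dir, s$id)
      write_map(s$truth_labels, paste0(base, "_truth.nii"), domain = dom,
                kind = "label", stage = "simulate", cfg = hash)
      write_map(as.integer(s$manual_mask), paste0(base, "_manual_mask.nii"),
                domain = dom, kind = "mask", stage = "simulate", cfg = hash)
      write_map(as.integer(s$automatic_mask),
                paste0(base, "_automatic_mask.nii"),
                domain = dom, kind = "mask", stage = "simulate", cfg = hash)
      for (dir in c("forward", "backward")) {
        write_nifti(array(runs[[i]][[dir]]$data, dim = c(dom$dim, config$acq$n_volumes)),
                    paste0(base, "_", dir, ".nii"), spacing = dom$spacing,
                    tr = config$TR,
                    descrip = .descrip("bold", dir = substr(dir, 1, 3),
                                       seed = run_seeds[i], cfg = hash))
      }
    }
    manifest$path_forward <- paste0(manifest$subject, "_forward.nii")
    manifest$path_backward <- paste0(manifest$subject, "_backward.nii")
    manifest$path_truth <- paste0(manifest$subject, "_truth.nii")
    manifest$path_digit <- paste0(manifest$subject, "_digits.nii")
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  res$manifest <- manifest
  if (!"phasemap" %in% stages) return(.finish_pipeline(res, out_dir, hash))

  .log_stage("phasemap", "Fourier analysis at f0 = %g Hz, high-pass %g Hz",
             config$acq$stim_freq, config$cutoff_hz)
  phase_maps <- lapply(seq_along(subjects), function(i) {
    fwd <- fourier_analyze(preprocess_run(runs[[i]]$forward, config$cutoff_hz))
    bwd <- fourier_analyze(preprocess_run(runs[[i]]$backward, config$cutoff_hz))
    combine_runs(fwd, bwd)
  })
  res$phase_maps <- phase_maps
  if (write_out) {
    dom <- subjects[[1]]$domain
    for (i in seq_along(subjects)) {
      base <- file.path(out_dir, subjects[[i]]$id)
      pm <- phase_maps[[i]]
      write_map(pm$phase, paste0(base, "_phase.nii"), domain = dom,
                kind = "phase", stage = "phasemap", cfg = hash)
      write_map(pm$coherence, paste0(base, "_coherence.nii"), domain = dom,
                kind = "prob", stage = "phasemap", cfg = hash)
      tm <- coherence_to_t(pm)
      write_map(tm$t, paste0(base, "_tmap.nii"), domain = dom,
                kind = "tmap", dof = tm$dof, cfg = hash)
    }
  }
  if (!"bin" %in% stages) return(.finish_pipeline(res, out_dir, hash))

  .log_stage("bin", "%s masking, alpha %g, phase offset %g rad",
             config$mask_mode, config$alpha, config$phase_offset)
  digit_maps <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    tm <- coherence_to_t(phase_maps[[i]])
    anat <- if (config$mask_mode == "manual") s$manual_mask else s$automatic_mask
    final <- apply_masks(mask_set(statistical_mask(tm, config$alpha), anat,
                                  mode = config$mask_mode, domain = s$domain))
    bin_phases(phase_maps[[i]], final, phase_offset = config$phase_offset,
               subject = s$id, hand = s$hand)
  })
  res$digit_maps <- digit_maps
  if (write_out) {
    for (i in seq_along(subjects))
      write_map(digit_maps[[i]],
                file.path(out_dir, paste0(subjects[[i]]$id, "_digits.nii")))
  }
  if (!"atlas" %in% stages) return(.finish_pipeline(res, out_dir, hash))

  .log_stage("atlas", "FPM/MPM over %d subjects, hand ROI threshold %g",
             length(digit_maps), config$hand_threshold)
  fpm <- build_fpm(digit_maps)
  roi <- hand_roi(fpm, config$hand_threshold)
  mpm <- build_mpm(fpm, roi)
  res$fpm <- fpm
  res$hand_roi <- roi
  res$mpm <- mpm
  if (write_out) {
    write_map(fpm, file.path(out_dir, sprintf("fpm_%s.nii", config$hand)))
    write_map(roi, file.path(out_dir, sprintf("handroi_%s.nii", config$hand)))
    write_map(mpm, file.path(out_dir, sprintf("mpm_%s.nii", config$hand)))
  }
  if (!"validate" %in% stages) return(.finish_pipeline(res, out_dir, hash))

  .log_stage("validate", "blurring, leave-one-out central tendency, ROI sizes")
  blur <- data.frame(
    digit = 1:5,
    B = vapply(1:5, function(d)
      blurring_metric(lapply(digit_maps, digit_roi, d))$B, numeric(1)))
  loo <- if (length(digit_maps) >= 3)
    loo_central_tendency(digit_maps, mode = "fpm",
                         variant = config$ct_variant,
                         hand_threshold = config$hand_threshold)
  else NULL
  sizes <- roi_sizes(digit_maps)
  pairwise <- tryCatch(pairwise_size_tests(sizes), error = function(e) NULL)
  res$metrics <- list(blurring = blur, loo = loo, sizes = sizes,
                      pairwise_log10p = pairwise)
  if (write_out) {
    utils::write.csv(blur, file.path(out_dir, "blurring.csv"),
                     row.names = FALSE)
    if (!is.null(loo))
      utils::write.csv(as.data.frame(unclass(loo)[, ]),
                       file.path(out_dir, "loo_central_tendency.csv"))
    utils::write.csv(sizes, file.path(out_dir, "roi_sizes.csv"),
                     row.names = FALSE)
    if (!is.null(pairwise))
      utils::write.csv(as.data.frame(pairwise),
                       file.path(out_dir, "pairwise_log10p.csv"))
  }
  .finish_pipeline(res, out_dir, hash)
}

.finish_pipeline <- function(res, out_dir, hash) {
  if (!is.null(out_dir)) {
    prov <- c(res$config[setdiff(names(res$config), "acq")],
              list(config_hash = hash,
                   package_version = as.character(utils::packageVersion("somatlas"))))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
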