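#' Travelling-wave acquisition parameters
#'
#' Describes the periodic stimulation protocol: one cycle sweeps the five
#' digits in sequence, each digit being stimulated for `digit_dwell_s`
#' seconds, so `cycle_s = 5 * digit_dwell_s`. The stimulation fundamental is
#' `stim_freq = 1 / cycle_s` (0.05 Hz for the standard 20 s cycle). A run
#' consists of `n_cycles` whole cycles sampled every `TR` seconds, which must
#' give an integer number of volumes.
#'
#' @param TR Repetition time in seconds (volume sampling interval).
#' @param cycle_s Length of one stimulation cycle in seconds.
#' @param n_cycles Number of cycles per run.
#' @param digit_dwell_s Stimulation duration per digit in seconds; defaults
#'   to `cycle_s / 5` and must satisfy `cycle_s == 5 * digit_dwell_s`.
#'
#' @return An `acq_params` object with the derived fields `stim_freq` (Hz)
#'   and `n_volumes`.
#' @examples
#' acq <- acq_params(TR = 2, cycle_s = 20, n_cycles = 10)
#' acq$stim_freq   # 0.05 Hz
#' acq$n_volumes   # 100
#' @export
acq_params <- function(TR = 2, cycle_s = 20, n_cycles = 10,
                       digit_dwell_s = cycle_s / 5) {
  if (TR <= 0) stop("TR must be > 0")
  if (cycle_s <= 0 || n_cycles < 1) stop("cycle_s and n_cycles must be positive")
  if (abs(cycle_s - 5 * digit_dwell_s) > 1e-9)
    stop("cycle_s must equal 5 * digit_dwell_s")
  n_volumes <- n_cycles * cycle_s / TR
  if (abs(n_volumes - round(n_volumes)) > 1e-9)
    stop(sprintf("n_cycles * cycle_s / TR = %g is not an integer volume count",
                 n_volumes))
  structure(
    list(TR = TR, cycle_s = cycle_s, n_cycles = as.integer(n_cycles),
         digit_dwell_s = digit_dwell_s, stim_freq = 1 / cycle_s,
         n_volumes = as.integer(round(n_volumes))),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> TR %gs, cycle %gs (f0 = %g Hz), %d cycles -> %d volumes\n",
    x$TR, x$cycle_s, x$stim_freq, x$n_cycles, x$n_volumes))
  invisible(x)
}

.same_acq <- function(a, b) {
  isTRUE(all.equal(a$TR, b$TR)) && isTRUE(all.equal(a$cycle_s, b$cycle_s)) &&
    a$n_cycles == b$n_cycles
}
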