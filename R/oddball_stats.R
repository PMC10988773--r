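#' Specify a neighbouring-bin noise window
#'
#' The noise level at a target frequency is estimated from the bins
#' flanking the target.  Two conventions are used side by side:
#' \describe{
#'   \item{`snr`}{the 10 bins on each side of the target (20 bins), target
#'     excluded; used for the SNR denominator.}
#'   \item{`zscore`}{12 bins per side, dropping the bin immediately
#'     adjacent to the target on each side (22 left) and then the single
#'     global minimum and maximum bin (20 left); used for the
#'     baseline-subtracted amplitude and the Z-score.}
#' }
#' Both defaults leave exactly 20 noise bins.
#'
#' @param mode `"snr"` or `"zscore"`.
#' @param n_side bins per side.
#' @param exclude_adjacent bins dropped next to the target, per side.
#' @param exclude_extremes drop the global min and max bin of the window.
#' @return an object of class `fpvs_noise_window`.
#' @export
noise_window_spec <- function(mode = c("snr", "zscore"),
                              n_side = NULL, exclude_adjacent = NULL,
                              exclude_extremes = NULL) {
  mode <- match.arg(mode)
  if (mode == "snr") {
    if (is.null(n_side)) n_side <- 10L
    if (is.null(exclude_adjacent)) exclude_adjacent <- 0L
    if (is.null(exclude_extremes)) exclude_extremes <- FALSE
  } else {
    if (is.null(n_side)) n_side <- 12L
    if (is.null(exclude_adjacent)) exclude_adjacent <- 1L
    if (is.null(exclude_extremes)) exclude_extremes <- TRUE
  }
  stopifnot(n_side > exclude_adjacent)
  structure(list(mode = mode, n_side = as.integer(n_side),
                 exclude_adjacent = as.integer(exclude_adjacent),
                 exclude_extremes = isTRUE(exclude_extremes)),
            class = "fpvs_noise_window")
}

# positions of the single global min and max of a window; ties broken at
# the lowest index, and the max is always distinct from the min (so an
# all-equal window still loses exactly two bins)
.extreme_positions <- function(w) {
  i_min <- which.min(w)
  w2 <- w
  w2[i_min] <- -Inf
  c(i_min, which.max(w2))
}

# signed offsets of the candidate window (before extreme exclusion)
.window_offsets <- function(spec) {
  side <- (spec$exclude_adjacent + 1L):spec$n_side
  c(-rev(side), side)
}

#' Noise-bin indices around a target bin
#'
#' Applies a [noise_window_spec()] to an amplitude vector: returns the
#' flanking bin indices, never including the target, with the global
#' minimum and maximum dropped when the spec says so (ties broken at the
#' lowest bin index).
#'
#' @param amps numeric amplitude vector, or a single-channel
#'   `fpvs_spectrum`.
#' @param target_bin 1-based target bin index.
#' @param spec a `fpvs_noise_window`.
#' @return sorted integer vector of noise-bin indices.
#' @export
noise_bins <- function(amps, target_bin, spec = noise_window_spec("snr")) {
  a <- .spectrum_vector(amps)
  idx <- target_bin + .window_offsets(spec)
  if (min(idx) < 1L || max(idx) > length(a)) {
    stop("edge error: noise window around bin ", target_bin,
         " exceeds the spectrum (1..", length(a), ")")
  }
  if (spec$exclude_extremes) {
    idx <- idx[-.extreme_positions(a[idx])]
  }
  sort(idx)
}

#' Neighbouring-bin statistics at one target frequency
#'
#' Computes, from an amplitude spectrum, the target-bin amplitude, the
#' SNR (amplitude / mean of the SNR noise window), the baseline-subtracted
#' amplitude (amplitude - mean of the Z noise window) and the Z-score
#' `(amp - mean(noise)) / SD(noise)` using the sample SD (n - 1) of the Z
#' noise window.  A zero noise SD yields an infinite Z with a warning.
#'
#' @param spectrum single-channel `fpvs_spectrum` or amplitude vector.
#' @param f_target target frequency in Hz (a vector is ignored when
#'   `target_bin` is given).
#' @param snr_spec,z_spec noise windows, see [noise_window_spec()].
#' @param target_bin optional explicit bin index (overrides `f_target`).
#' @param df_hz bin spacing, required when `spectrum` is a bare vector.
#' @return a one-row data.frame: `f_hz`, `bin`, `amp`, `noise_mean`,
#'   `noise_sd`, `snr`, `corrected_amp`, `z`.
#' @export
bin_stats <- function(spectrum, f_target = NULL,
                      snr_spec = noise_window_spec("snr"),
                      z_spec = noise_window_spec("zscore"),
                      target_bin = NULL, df_hz = NULL) {
  a <- .spectrum_vector(spectrum)
  if (is.null(target_bin)) {
    if (inherits(spectrum, "fpvs_spectrum")) {
      target_bin <- bin_index(spectrum, f_target)
      df_hz <- spectrum$df_hz
    } else {
      stopifnot(!is.null(df_hz))
      target_bin <- as.integer(round(f_target / df_hz)) + 1L
    }
  }
  f_hz <- if (!is.null(df_hz)) (target_bin - 1L) * df_hz else NA_real_
  amp <- a[target_bin]
  snr_w <- a[noise_bins(a, target_bin, snr_spec)]
  z_w <- a[noise_bins(a, target_bin, z_spec)]
  noise_mean <- mean(z_w)
  noise_sd <- sd(z_w)
  corrected <- amp - noise_mean
  z <- if (noise_sd > 0) {
    corrected / noise_sd
  } else {
    warning("noise SD is zero at bin ", target_bin,
            "; z reported as +/-Inf")
    sign(corrected) * Inf
  }
  data.frame(f_hz = f_hz, bin = target_bin, amp = amp,
             noise_mean = noise_mean, noise_sd = noise_sd,
             snr = amp / mean(snr_w), corrected_amp = corrected, z = z)
}

#' SNR across the whole spectrum
#'
#' Element-wise SNR at every interior bin: bin amplitude divided by the
#' mean of the surrounding noise bins (default 10 per side).  Its baseline
#' level is 1 under pure noise.  Edge bins, where the window does not fit,
#' are `NA`.
#'
#' @param spectrum a `fpvs_spectrum`.
#' @param snr_spec noise window (extreme exclusion not supported here; the
#'   running window is a plain mean).
#' @return a `fpvs_spectrum`-shaped object whose `amps` hold SNR values.
#' @export
snr_spectrum <- function(spectrum, snr_spec = noise_window_spec("snr")) {
  if (snr_spec$exclude_extremes) {
    stop("snr_spectrum uses a running mean; extreme exclusion unsupported")
  }
  offs <- .window_offsets(snr_spec)
  amps <- spectrum$amps
  n <- ncol(amps)
  noise <- matrix(NA_real_, nrow(amps), n)
  lo <- 1L - min(offs)
  hi <- n - max(offs)
  if (hi >= lo) {
    acc <- matrix(0, nrow(amps), hi - lo + 1L)
    for (o in offs) acc <- acc + amps[, (lo:hi) + o, drop = FALSE]
    noise[, lo:hi] <- acc / length(offs)
  }
  out <- spectrum
  out$amps <- amps / noise
  out
}

#' Candidate harmonics of the oddball frequency
#'
#' All multiples of `f_fund` up to `f_max`, excluding every multiple of
#' the base stimulation rate (whose response reflects general visual
#' processing, not category discrimination).
#'
#' @param f_fund fundamental (oddball) frequency, Hz.
#' @param f_base base stimulation rate, Hz.
#' @param f_max highest frequency considered.
#' @param exclude_base set `FALSE` when listing base-rate harmonics
#'   themselves.
#' @return numeric vector of frequencies.
#' @examples
#' candidate_harmonics(2, 10, 8)    # 2 4 6 8
#' candidate_harmonics(2, 10, 20)   # 2 4 6 8 12 14 16 18
#' candidate_harmonics(10, 10, 40, exclude_base = FALSE)  # 10 20 30 40
#' @export
candidate_harmonics <- function(f_fund, f_base, f_max,
                                exclude_base = TRUE) {
  stopifnot(f_fund > 0, f_max >= f_fund)
  h <- seq(f_fund, f_max + 1e-9, by = f_fund)
  if (exclude_base) {
    is_base <- abs(h / f_base - round(h / f_base)) < 1e-9
    h <- h[!is_base]
  }
  h
}

#' Select significant harmonics on a group-level spectrum
#'
#' Harmonic selection is done once, on the designated group (grand-averaged,
#' usually ROI-averaged) spectrum, and the selected set is then applied to
#' every participant.  A harmonic is retained when its Z-score exceeds
#' `z_crit` (default 3.1, one-tailed p < .001).
#'
#' @param group_spectrum single-channel `fpvs_spectrum`.
#' @param candidates frequencies from [candidate_harmonics()].
#' @param z_spec Z noise window.
#' @param z_crit critical Z.
#' @return the significant subset of `candidates`.
#' @export
select_significant_harmonics <- function(group_spectrum, candidates,
                                         z_spec = noise_window_spec("zscore"),
                                         z_crit = 3.1) {
  z <- vapply(candidates, function(f) {
    bin_stats(group_spectrum, f, z_spec = z_spec)$z
  }, 0)
  candidates[z > z_crit]
}

#' Sum baseline-subtracted amplitudes over harmonics
#'
#' Quantifies a periodic response spread over several harmonics: the
#' baseline-subtracted amplitude at each selected harmonic is computed and
#' summed (negative per-harmonic values are retained, not floored).
#'
#' @param spectrum single-channel `fpvs_spectrum` (one participant /
#'   condition / ROI).
#' @param harmonics non-empty frequency vector (from
#'   [select_significant_harmonics()]).
#' @param z_spec noise window for the baseline.
#' @param snr_spec noise window for the per-harmonic SNR bookkeeping.
#' @return an object of class `fpvs_harmonic_summary`: list with
#'   `harmonics_used`, `summed_corrected_amp` (microvolts) and
#'   `per_harmonic` (data.frame of [bin_stats()] rows).
#' @export
sum_harmonics <- function(spectrum, harmonics,
                          z_spec = noise_window_spec("zscore"),
                          snr_spec = noise_window_spec("snr")) {
  if (length(harmonics) == 0) {
    stop("empty harmonic list: nothing to sum")
  }
  per <- do.call(rbind, lapply(harmonics, function(f) {
    bin_stats(spectrum, f, snr_spec = snr_spec, z_spec = z_spec)
  }))
  structure(list(harmonics_used = harmonics,
                 summed_corrected_amp = sum(per$corrected_amp),
                 per_harmonic = per),
            class = "fpvs_harmonic_summary")
}

#' @export
print.fpvs_harmonic_summary <- function(x, ...) {
  cat(sprintf("<fpvs_harmonic_summary> %s Hz: summed corrected amplitude %.4f uV\n",
              paste(x$harmonics_used, collapse = "/"),
              x$summed_corrected_amp))
  invisible(x)
}

#' Z-score of the summed response across harmonics
#'
#' Individual-level significance of a multi-harmonic response, computed on
#' non-corrected amplitudes.  With `method = "sum_bins"` (default) the
#' target-bin amplitudes of the selected harmonics are summed, a null
#' distribution is formed by summing, offset by offset, the corresponding
#' noise bins across the same harmonics (extreme summed values dropped
#' when the window spec says so), and the Z is the summed amplitude
#' against the mean/SD of those summed noise values.  With
#' `method = "mean_z"` the per-harmonic Z-scores are averaged.
#'
#' @param spectrum single-channel `fpvs_spectrum`.
#' @param harmonics frequencies of the selected harmonics.
#' @param z_spec noise window.
#' @param method aggregation rule.
#' @return one-row data.frame: `summed_amp`, `noise_mean`, `noise_sd`, `z`.
#' @export
summed_amplitude_z <- function(spectrum, harmonics,
                               z_spec = noise_window_spec("zscore"),
                               method = c("sum_bins", "mean_z")) {
  method <- match.arg(method)
  a <- .spectrum_vector(spectrum)
  bins <- vapply(harmonics, function(f) bin_index(spectrum, f), 0L)
  if (method == "mean_z") {
    z <- mean(vapply(harmonics, function(f) {
      bin_stats(spectrum, f, z_spec = z_spec)$z
    }, 0))
    return(data.frame(summed_amp = sum(a[bins]), noise_mean = NA_real_,
                      noise_sd = NA_real_, z = z))
  }
  offs <- .window_offsets(z_spec)
  if (min(bins) + min(offs) < 1L || max(bins) + max(offs) > length(a)) {
    stop("edge error: noise window exceeds the spectrum")
  }
  summed_noise <- vapply(offs, function(o) sum(a[bins + o]), 0)
  if (z_spec$exclude_extremes) {
    summed_noise <- summed_noise[-.extreme_positions(summed_noise)]
  }
  s <- sum(a[bins])
  m <- mean(summed_noise)
  sdn <- sd(summed_noise)
  z <- if (sdn > 0) (s - m) / sdn else sign(s - m) * Inf
  data.frame(summed_amp = s, noise_mean = m, noise_sd = sdn, z = z)
}
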