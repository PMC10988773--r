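#' Specify a periodic scalp response
#'
#' A steady-state response at a fundamental frequency and a set of its
#' harmonics, with per-harmonic amplitude and phase and a per-channel
#' topography weight in \[0, 1\].  The synthetic EEG generator injects
#' `amp[k] * weight[ch] * cos(2*pi*harmonic[k]*freq*t + phase[k])` during
#' the stimulation window.
#'
#' @param freq_hz fundamental frequency (2 Hz oddball, 10 Hz base rate).
#' @param harmonics integer harmonic indices (1 = fundamental).
#' @param amps peak amplitudes in microvolts, one per harmonic.
#' @param phases radians, one per harmonic (recycled).
#' @param topography named numeric vector of channel weights in \[0, 1\];
#'   channels not named get weight 0.
#' @return an object of class `fpvs_response`.
#' @export
response_spec <- function(freq_hz, harmonics = 1L, amps = 1,
                          phases = 0, topography) {
  stopifnot(freq_hz > 0, length(harmonics) == length(amps), all(amps >= 0))
  if (is.null(names(topography)) || !any(topography > 0)) {
    stop("topography must be a named weight vector with some weight > 0")
  }
  phases <- rep_len(phases, length(harmonics))
  structure(list(freq_hz = freq_hz, harmonics = as.integer(harmonics),
                 amps = as.numeric(amps), phases = as.numeric(phases),
                 topography = topography),
            class = "fpvs_response")
}

# gaussian topography falloff around a seed electrode, on the unit sphere
.gaussian_topography <- function(montage, centre, sigma_deg = 28,
                                 peak = 1) {
  pos <- .montage_positions(montage, montage$channel)
  c0 <- .montage_positions(montage, centre)[1, ]
  ang <- acos(pmin(1, pmax(-1, pos %*% c0)))  # angular distance, radians
  w <- peak * exp(-(ang * 180 / pi)^2 / (2 * sigma_deg^2))
  stats::setNames(as.numeric(w), montage$channel)
}

#' Default oddball (word-discrimination) response
#'
#' 2 Hz fundamental with energy over harmonics 2, 4, 6 and 8 Hz,
#' left-lateralized over occipito-temporal channels (peak around PO7, with
#' a weaker right-hemisphere counterpart around PO8).  Per-harmonic
#' amplitudes default to a profile peaking at the 6 Hz harmonic, as
#' commonly observed for word-selective oddball responses.
#'
#' @param montage montage data.frame, see [fpvs_montage()].
#' @param amps amplitudes (microvolts) for harmonics 2, 4, 6, 8 Hz.
#' @param rh_ratio right- relative to left-hemisphere peak weight.
#' @return `fpvs_response`.
#' @export
default_oddball_response <- function(montage = fpvs_montage(),
                                     amps = c(0.15, 0.15, 0.20, 0.10),
                                     rh_ratio = 0.3) {
  topo <- .gaussian_topography(montage, "PO7") +
    .gaussian_topography(montage, "PO8", peak = rh_ratio)
  topo <- pmin(topo, 1)
  response_spec(2, 1:4, amps, 0, topo)
}

#' Default base-rate (general visual) response
#'
#' 10 Hz fundamental with harmonics up to 40 Hz over medial-occipital
#' channels (peak around Oz).
#'
#' @param montage montage data.frame.
#' @param amps amplitudes (microvolts) for 10, 20, 30, 40 Hz.
#' @return `fpvs_response`.
#' @export
default_base_response <- function(montage = fpvs_montage(),
                                  amps = c(2.0, 0.8, 0.4, 0.2)) {
  topo <- pmin(.gaussian_topography(montage, "Oz", sigma_deg = 22), 1)
  response_spec(10, 1:4, amps, 0, topo)
}

#' Specify background noise
#'
#' 1/f ("pink") noise plus optional narrow-band alpha and white sensor
#' noise.  `pink_scale` is the square root of the one-sided power spectral
#' density at 1 Hz (microvolts per sqrt(Hz)); the PSD falls as
#' `1/f^pink_exponent`.  `alpha_amp` is the RMS amplitude (microvolts) of a
#' narrow-band component at `alpha_freq_hz`; `white_scale` is the
#' per-sample standard deviation of additive white noise.
#'
#' @param pink_exponent spectral slope of the power spectrum (default 1).
#' @param pink_scale microvolts/sqrt(Hz) at 1 Hz.
#' @param alpha_amp RMS microvolts (default 0 = off).
#' @param alpha_freq_hz alpha centre frequency.
#' @param alpha_bw_hz alpha bandwidth (Gaussian SD of the bump).
#' @param white_scale microvolts per sample.
#' @return an object of class `fpvs_noise`.
#' @export
noise_spec <- function(pink_exponent = 1, pink_scale = 1.4,
                       alpha_amp = 0, alpha_freq_hz = 10, alpha_bw_hz = 1,
                       white_scale = 0.05) {
  stopifnot(pink_scale >= 0, alpha_amp >= 0, white_scale >= 0,
            alpha_freq_hz > 0)
  structure(list(pink_exponent = pink_exponent, pink_scale = pink_scale,
                 alpha_amp = alpha_amp, alpha_freq_hz = alpha_freq_hz,
                 alpha_bw_hz = alpha_bw_hz, white_scale = white_scale),
            class = "fpvs_noise")
}

# shape white gaussian noise in the frequency domain so its one-sided PSD
# equals gain2(f) (in uV^2/Hz); DC removed
.spectrally_shaped_noise <- function(n, fs, gain2, seed = NULL) {
  gen <- function() {
    w <- rnorm(n)
    W <- fft(w)
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n  # folded frequency axis
    H <- numeric(n)
    pos <- f > 0
    # white noise of unit variance has one-sided PSD 2/fs
    H[pos] <- sqrt(gain2(f[pos]) * fs / 2)
    Re(fft(W * H, inverse = TRUE)) / n
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate 1/f (pink) noise
#'
#' Spectral shaping of white Gaussian noise: the one-sided power spectral
#' density is `scale^2 / f^exponent` (microvolts^2/Hz), DC excluded, so the
#' amplitude spectrum falls with slope `-exponent/2` on a log-log scale.
#'
#' @param n_samples number of samples.
#' @param fs_hz sampling rate, Hz.
#' @param exponent power-spectrum slope (0 = white).
#' @param scale microvolts/sqrt(Hz) at 1 Hz.
#' @param seed optional integer seed (deterministic output).
#' @return numeric vector of length `n_samples`, zero mean.
#' @examples
#' x <- make_pink_noise(1024, 256, seed = 1)
#' @export
make_pink_noise <- function(n_samples, fs_hz, exponent = 1, scale = 1,
                            seed = NULL) {
  stopifnot(n_samples > 0, fs_hz > 0)
  if (scale == 0) return(numeric(n_samples))
  .spectrally_shaped_noise(n_samples, fs_hz,
                           function(f) scale^2 / f^exponent, seed)
}

# narrow-band gaussian bump scaled to target RMS
.make_alpha_noise <- function(n, fs, freq, bw, rms) {
  if (rms == 0) return(numeric(n))
  x <- .spectrally_shaped_noise(n, fs,
                                function(f) exp(-(f - freq)^2 / (2 * bw^2)))
  x * rms / sd(x)
}

#' Synthesize a multi-channel FPVS recording
#'
#' Builds a recording for one planned sequence: baseline, fade-in,
#' stimulation window, fade-out and a post-sequence tail.  Injected
#' responses are phase-locked to stimulation onset, at full amplitude
#' within the stimulation window and ramped with a raised-cosine envelope
#' during the fades.  Independent noise (see [noise_spec()]) is added per
#' channel.  Event markers record sequence start, stimulation onset/offset,
#' fade-out end and every task event.
#'
#' @param plan a `fpvs_plan` from [plan_sequence()].
#' @param oddball,base `fpvs_response` specs ( `NULL` to omit).
#' @param noise `fpvs_noise` spec (`NULL` for a noiseless recording).
#' @param montage montage data.frame; defines the channel set.
#' @param fs_hz sampling rate (default 1024, must exceed twice the highest
#'   injected frequency).
#' @param pre_s baseline before fade-in; `pre_s + fade_in_s` must be >= the
#'   segmentation pre-window (2 s).
#' @param post_s tail after fade-out.
#' @param seed integer seed for the noise.
#' @return an object of class `fpvs_recording`: list with `data`
#'   (channels x samples matrix, microvolts), `fs_hz`, `channel_names`,
#'   `markers` (data.frame `sample`, `label`; 1-based sample indices) and
#'   `truth` (the injected specs, for test oracles).
#' @export
synthesize_recording <- function(plan,
                                 oddball = default_oddball_response(montage),
                                 base = default_base_response(montage),
                                 noise = noise_spec(),
                                 montage = fpvs_montage(),
                                 fs_hz = 1024, pre_s = 2.5, post_s = 0.5,
                                 seed = 1L) {
  responses <- Filter(Negate(is.null), list(oddball = oddball, base = base))
  fmax <- max(c(0, vapply(responses,
                          function(r) max(r$harmonics) * r$freq_hz, 0)))
  if (fs_hz < 2 * fmax) {
    stop("configuration error: fs_hz must be at least twice the highest ",
         "injected frequency (", fmax, " Hz)")
  }
  chans <- montage$channel
  n_ch <- length(chans)
  total_s <- pre_s + plan$fade_in_s + plan$duration_s + plan$fade_out_s +
    post_s
  n <- as.integer(round(total_s * fs_hz))
  i_onset <- as.integer(round((pre_s + plan$fade_in_s) * fs_hz))  # 0-based
  t <- (seq_len(n) - 1L) / fs_hz - (pre_s + plan$fade_in_s)  # rel. to onset

  # raised-cosine fade envelope around the stimulation window
  env <- numeric(n)
  env[t >= 0 & t < plan$duration_s] <- 1
  fi <- t >= -plan$fade_in_s & t < 0
  env[fi] <- 0.5 * (1 + cos(pi * t[fi] / plan$fade_in_s))
  fo <- t >= plan$duration_s & t < plan$duration_s + plan$fade_out_s
  env[fo] <- 0.5 * (1 + cos(pi * (t[fo] - plan$duration_s) /
                              plan$fade_out_s))

  data <- matrix(0, nrow = n_ch, ncol = n, dimnames = list(chans, NULL))
  for (r in responses) {
    s <- numeric(n)
    for (k in seq_along(r$harmonics)) {
      s <- s + r$amps[k] *
        cos(2 * pi * r$harmonics[k] * r$freq_hz * t + r$phases[k])
    }
    s <- s * env
    w <- r$topography[chans]
    w[is.na(w)] <- 0
    data <- data + outer(as.numeric(w), s)
  }

  if (!is.null(noise)) {
    with_seed(seed, {
      for (ci in seq_len(n_ch)) {
        x <- numeric(n)
        if (noise$pink_scale > 0) {
          x <- x + .spectrally_shaped_noise(
            n, fs_hz,
            function(f) noise$pink_scale^2 / f^noise$pink_exponent)
        }
        if (noise$alpha_amp > 0) {
          x <- x + .make_alpha_noise(n, fs_hz, noise$alpha_freq_hz,
                                     noise$alpha_bw_hz, noise$alpha_amp)
        }
        if (noise$white_scale > 0) x <- x + rnorm(n, sd = noise$white_scale)
        data[ci, ] <- data[ci, ] + x
      }
    })
  }

  markers <- data.frame(
    sample = c(1L,
               as.integer(round(pre_s * fs_hz)) + 1L,
               i_onset + 1L,
               i_onset + as.integer(round(plan$duration_s * fs_hz)) + 1L,
               i_onset + as.integer(round((plan$duration_s +
                                             plan$fade_out_s) * fs_hz)) + 1L),
    label = c("sequence_start", "fade_in_start", "stim_onset",
              "stim_offset", "fade_out_end"),
    stringsAsFactors = FALSE)
  if (nrow(plan$events) > 0) {
    ev <- data.frame(
      sample = i_onset + as.integer(round(plan$events$onset_s * fs_hz)) + 1L,
      label = paste0("task_", plan$events$kind),
      stringsAsFactors = FALSE)
    markers <- rbind(markers, ev)
    markers <- markers[order(markers$sample), ]
  }
  stopifnot(all(markers$sample >= 1L), all(markers$sample <= n))

  structure(list(data = data, fs_hz = fs_hz, channel_names = chans,
                 markers = markers,
                 truth = list(oddball = oddball, base = base, noise = noise,
                              seed = as.integer(seed)),
                 plan = plan),
            class = "fpvs_recording")
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf("<fpvs_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  cat(sprintf("  markers: %s\n",
              paste(unique(x$markers$label), collapse = ", ")))
  invisible(x)
}
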