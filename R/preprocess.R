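#' Construct an epoch
#'
#' @param data channels x samples matrix (microvolts), with channel row
#'   names.
#' @param fs_hz sampling rate.
#' @param t0_s time of the first sample relative to stimulation onset.
#' @param meta named list of condition labels / bookkeeping.
#' @return an object of class `fpvs_epoch`.
#' @export
fpvs_epoch <- function(data, fs_hz, t0_s = 0, meta = list()) {
  stopifnot(is.matrix(data), ncol(data) > 0, fs_hz > 0)
  structure(list(data = data, fs_hz = fs_hz, t0_s = t0_s, meta = meta),
            class = "fpvs_epoch")
}

#' @export
print.fpvs_epoch <- function(x, ...) {
  cat(sprintf("<fpvs_epoch> %d channels x %d samples @ %g Hz, t0 = %g s\n",
              nrow(x$data), ncol(x$data), x$fs_hz, x$t0_s))
  invisible(x)
}

# zero-phase FFT filter on a channels x samples matrix
.fft_bandpass <- function(mat, fs, lo, hi, transition_hz = 0) {
  n <- ncol(mat)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  if (transition_hz <= 0) {
    mask <- as.numeric(f >= lo & f <= hi)
  } else {
    # raised-cosine transitions centred on the band edges
    ramp_up <- function(f) {
      ifelse(f <= lo - transition_hz / 2, 0,
             ifelse(f >= lo + transition_hz / 2, 1,
                    0.5 * (1 + sin(pi * (f - lo) / transition_hz))))
    }
    ramp_dn <- function(f) {
      ifelse(f <= hi - transition_hz / 2, 1,
             ifelse(f >= hi + transition_hz / 2, 0,
                    0.5 * (1 - sin(pi * (f - hi) / transition_hz))))
    }
    mask <- ramp_up(f) * ramp_dn(f)
  }
  X <- mvfft(t(mat))
  t(Re(mvfft(X * mask, inverse = TRUE))) / n
}

#' FFT band-pass filter
#'
#' Zero-phase filtering by masking Fourier coefficients outside
#' `[lo_hz, hi_hz]` (hard mask by default; an optional raised-cosine
#' transition of width `transition_hz` softens the edges) and inverse
#' transforming.  Mirrors the FFT filters of frequency-tagging toolboxes.
#'
#' @param x `fpvs_recording` or `fpvs_epoch`.
#' @param lo_hz,hi_hz band edges, `0 <= lo < hi <= fs/2`.
#' @param transition_hz raised-cosine transition width (0 = hard mask).
#' @return object of the same class, filtered.
#' @export
bandpass_fft <- function(x, lo_hz = 0.1, hi_hz = 100, transition_hz = 0) {
  stopifnot(lo_hz >= 0, lo_hz < hi_hz)
  if (hi_hz > x$fs_hz / 2) {
    stop("configuration error: band edge above Nyquist (", x$fs_hz / 2,
         " Hz)")
  }
  x$data <- .fft_bandpass(x$data, x$fs_hz, lo_hz, hi_hz, transition_hz)
  x
}

#' Segment a recording around a marker
#'
#' Cuts a window from `pre_s` before to `post_s` after the given marker
#' (default: stimulation onset, giving the -2 to 62 s segment of a 60-s
#' sequence with 2-s fades).
#'
#' @param recording a `fpvs_recording`.
#' @param onset_marker marker label to align on.
#' @param pre_s,post_s window, seconds.
#' @return a `fpvs_epoch` with `t0_s = -pre_s` and
#'   `(pre_s + post_s) * fs` samples.
#' @export
segment <- function(recording, onset_marker = "stim_onset",
                    pre_s = 2, post_s = 62) {
  m <- recording$markers
  hit <- m$sample[m$label == onset_marker]
  if (length(hit) == 0) {
    stop("segmentation error: marker '", onset_marker, "' not found")
  }
  s0 <- hit[1]
  fs <- recording$fs_hz
  from <- s0 - as.integer(round(pre_s * fs))
  n <- as.integer(round((pre_s + post_s) * fs))
  to <- from + n - 1L
  if (from < 1L || to > ncol(recording$data)) {
    stop("segmentation error: window [", from, ", ", to,
         "] outside recording (", ncol(recording$data), " samples)")
  }
  meta <- list(onset_marker = onset_marker)
  if (!is.null(recording$plan)) {
    meta$task <- recording$plan$task
    meta$control_type <- recording$plan$control_type
    meta$duration_s <- recording$plan$duration_s
  }
  fpvs_epoch(recording$data[, from:to, drop = FALSE], fs, -pre_s, meta)
}

#' Resample an epoch
#'
#' FFT-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency and inverse transformed, which preserves in-band sinusoid
#' amplitudes exactly for bin-locked components (well within 0.5% for
#' others) and the epoch duration.  Only downsampling is supported.
#'
#' @param epoch a `fpvs_epoch`.
#' @param target_fs new sampling rate; `n * target_fs / fs` must be an
#'   integer.
#' @return the resampled `fpvs_epoch`.
#' @export
resample_epoch <- function(epoch, target_fs = 512) {
  fs <- epoch$fs_hz
  if (target_fs > fs) {
    stop("configuration error: upsampling is not supported")
  }
  if (target_fs == fs) return(epoch)
  n <- ncol(epoch$data)
  n_new <- n * target_fs / fs
  if (abs(n_new - round(n_new)) > 1e-9) {
    stop("configuration error: epoch length incompatible with target_fs")
  }
  n_new <- as.integer(round(n_new))
  X <- mvfft(t(epoch$data))  # n x channels
  half <- n_new %/% 2
  Y <- matrix(0 + 0i, nrow = n_new, ncol = ncol(X))
  Y[1:(half + 1), ] <- X[1:(half + 1), ]
  if (half >= 1) {
    Y[(n_new - half + 2):n_new, ] <- X[(n - half + 2):n, ]
  }
  # keep the new Nyquist bin real so the output stays real
  if (n_new %% 2 == 0) {
    Y[half + 1, ] <- Re(X[half + 1, ])
  }
  # inverse over n_new points with amplitude-preserving scale n_new/n:
  # Re(ifft(Y))/n_new * (n_new/n) = Re(ifft(Y))/n
  data <- t(Re(mvfft(Y, inverse = TRUE))) / n
  dimnames(data) <- dimnames(epoch$data)
  epoch$data <- data
  epoch$fs_hz <- target_fs
  epoch
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of its
#' `k` nearest good neighbours on the montage sphere (linear
#' interpolation); good channels are untouched.
#'
#' @param epoch a `fpvs_epoch` with channel row names.
#' @param bad character vector of bad channels.
#' @param montage montage data.frame.
#' @param k number of neighbours.
#' @return the repaired `fpvs_epoch`.
#' @export
interpolate_channels <- function(epoch, bad, montage = fpvs_montage(),
                                 k = 4) {
  chans <- rownames(epoch$data)
  if (length(bad) == 0) return(epoch)
  if (!all(bad %in% chans)) {
    stop("unknown bad channels: ",
         paste(setdiff(bad, chans), collapse = ", "))
  }
  good <- setdiff(chans, bad)
  if (length(good) < k) {
    stop("need at least k = ", k, " good channels, have ", length(good))
  }
  pos <- .montage_positions(montage, chans)
  rownames(pos) <- chans
  for (b in bad) {
    d <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[b, ])^2))
    nn <- good[order(d)][seq_len(k)]
    w <- 1 / pmax(d[order(d)][seq_len(k)], 1e-12)
    w <- w / sum(w)
    epoch$data[b, ] <- as.numeric(w %*% epoch$data[nn, , drop = FALSE])
  }
  epoch
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean from every sample, so each column of
#' the data matrix has zero mean.
#'
#' @param epoch a `fpvs_epoch` (>= 2 channels).
#' @return the re-referenced `fpvs_epoch`.
#' @export
rereference_average <- function(epoch) {
  stopifnot(nrow(epoch$data) >= 2)
  epoch$data <- sweep(epoch$data, 2, colMeans(epoch$data))
  epoch
}

#' Crop to whole oddball cycles
#'
#' Keeps samples from stimulation onset (t = 0) through the largest whole
#' number of oddball cycles, so both the oddball frequency and the base
#' rate (and all their harmonics below Nyquist) land exactly on FFT bins.
#' For a 60-s window at 512 Hz with 0.5-s cycles this retains 120 cycles =
#' 30720 samples, the last at 59.998 s.
#'
#' @param epoch a `fpvs_epoch` covering t = 0.
#' @param cycle_s oddball cycle duration (1 / oddball frequency).
#' @param max_duration_s optional cap (e.g. the 60-s stimulation window, to
#'   exclude the fade-out from the analysed window).
#' @return the cropped `fpvs_epoch` with `t0_s = 0`.
#' @export
crop_to_cycles <- function(epoch, cycle_s = 0.5, max_duration_s = NULL) {
  fs <- epoch$fs_hz
  i0 <- as.integer(round(-epoch$t0_s * fs))  # 0-based index of t = 0
  if (i0 < 0 || i0 >= ncol(epoch$data)) {
    stop("epoch does not cover stimulation onset (t = 0)")
  }
  avail_s <- (ncol(epoch$data) - i0) / fs
  if (!is.null(max_duration_s)) avail_s <- min(avail_s, max_duration_s)
  n_cycles <- floor(avail_s / cycle_s + 1e-9)
  if (n_cycles < 1) stop("epoch shorter than one cycle")
  n_keep <- as.integer(round(n_cycles * cycle_s * fs))
  epoch$data <- epoch$data[, (i0 + 1L):(i0 + n_keep), drop = FALSE]
  epoch$t0_s <- 0
  epoch$meta$n_cycles <- n_cycles
  epoch
}

#' Average epochs in the time domain
#'
#' Sample-wise arithmetic mean of repetitions of the same condition,
#' increasing SNR before the FFT.
#'
#' @param epochs list of `fpvs_epoch`s of identical shape, rate and t0.
#' @return a `fpvs_epoch`; `meta$n_averaged` records the count.
#' @export
average_epochs <- function(epochs) {
  stopifnot(length(epochs) >= 1)
  e1 <- epochs[[1]]
  for (e in epochs[-1]) {
    if (!identical(dim(e$data), dim(e1$data)) || e$fs_hz != e1$fs_hz ||
        e$t0_s != e1$t0_s) {
      stop("epochs must share shape, sampling rate and t0")
    }
  }
  e1$data <- Reduce(`+`, lapply(epochs, `[[`, "data")) / length(epochs)
  e1$meta$n_averaged <- length(epochs)
  e1
}

#' Full preprocessing chain for one recording
#'
#' Applies, in order: FFT band-pass, segmentation around stimulation
#' onset, resampling, bad-channel interpolation, average re-referencing
#' and cycle-aligned cropping.
#'
#' @param recording a `fpvs_recording`.
#' @param lo_hz,hi_hz band-pass edges.
#' @param pre_s,post_s segmentation window.
#' @param target_fs resampling target.
#' @param bad_channels channels to interpolate.
#' @param montage montage for interpolation.
#' @param cycle_s oddball cycle length.
#' @param stim_duration_s stimulation window used to cap the crop; taken
#'   from the recording's plan when `NULL`.
#' @return a cycle-cropped `fpvs_epoch`.
#' @export
preprocess <- function(recording, lo_hz = 0.1, hi_hz = 100,
                       pre_s = 2, post_s = 62, target_fs = 512,
                       bad_channels = character(0),
                       montage = fpvs_montage(), cycle_s = 0.5,
                       stim_duration_s = NULL) {
  if (is.null(stim_duration_s)) {
    stim_duration_s <- if (!is.null(recording$plan)) {
      recording$plan$duration_s
    } else {
      post_s - 2  # conventional 60-s window of a -2..62 s segment
    }
  }
  x <- bandpass_fft(recording, lo_hz, hi_hz)
  x <- segment(x, "stim_onset", pre_s, post_s)
  x <- resample_epoch(x, target_fs)
  x <- interpolate_channels(x, bad_channels, montage)
  x <- rereference_average(x)
  crop_to_cycles(x, cycle_s, stim_duration_s)
}
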