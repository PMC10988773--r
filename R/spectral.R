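#' Amplitude spectrum of an epoch
#'
#' One-sided FFT amplitude spectrum, normalized so a real sinusoid of peak
#' amplitude A microvolts at an exact bin yields A at that bin (factor
#' 2/N; DC and Nyquist carry factor 1/N).  No windowing and no
#' zero-padding: responses are bin-locked by design, and the bin spacing
#' is exactly `1 / duration`.
#'
#' @param epoch a `fpvs_epoch`.
#' @return an object of class `fpvs_spectrum`: list with `amps`
#'   (channels x bins, microvolts), `freqs` (Hz), `df_hz`,
#'   `channel_names`, `duration_s`.
#' @examples
#' t <- (0:511) / 256
#' e <- fpvs_epoch(matrix(cos(2 * pi * 2 * t), 1), 256)
#' s <- amplitude_spectrum(e)
#' s$amps[1, bin_index(s, 2)]  # 1
#' @export
amplitude_spectrum <- function(epoch) {
  n <- ncol(epoch$data)
  stopifnot(n > 0)
  X <- mvfft(t(epoch$data))  # n x channels
  n_bins <- floor(n / 2) + 1L
  amps <- t(Mod(X[seq_len(n_bins), , drop = FALSE])) * 2 / n
  dimnames(amps) <- NULL  # channels tracked in channel_names
  amps[, 1] <- amps[, 1] / 2                      # DC
  if (n %% 2 == 0) amps[, n_bins] <- amps[, n_bins] / 2  # Nyquist
  df <- epoch$fs_hz / n
  structure(list(amps = amps,
                 freqs = (seq_len(n_bins) - 1L) * df,
                 df_hz = df,
                 channel_names = rownames(epoch$data),
                 duration_s = n / epoch$fs_hz,
                 meta = epoch$meta),
            class = "fpvs_spectrum")
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("<fpvs_spectrum> %d channels x %d bins, df = %.6f Hz (0-%.6g Hz)\n",
              nrow(x$amps), ncol(x$amps), x$df_hz, max(x$freqs)))
  invisible(x)
}

#' Frequency resolution of an epoch duration
#'
#' The FFT bin spacing of a window of the given duration: `1 / duration`.
#' The 59.998-s cycle-cropped window gives 0.01667 Hz (printed as .016 at
#' three truncated decimals), fine enough to identify responses at the
#' exact stimulation frequencies.
#'
#' @param epoch_duration_s window duration, seconds.
#' @return bin spacing in Hz.
#' @export
freq_resolution <- function(epoch_duration_s) {
  stopifnot(epoch_duration_s > 0)
  1 / epoch_duration_s
}

#' Locate the FFT bin of a target frequency
#'
#' @param spectrum a `fpvs_spectrum`.
#' @param f_hz target frequency.
#' @param tol maximum allowed |bin centre - target| (default half a bin).
#' @return 1-based bin index whose centre is nearest `f_hz`.
#' @export
bin_index <- function(spectrum, f_hz, tol = spectrum$df_hz / 2) {
  stopifnot(f_hz >= 0)
  if (f_hz > max(spectrum$freqs) + tol) {
    stop("frequency-alignment error: ", f_hz, " Hz beyond Nyquist")
  }
  i <- as.integer(round(f_hz / spectrum$df_hz)) + 1L
  i <- min(max(i, 1L), length(spectrum$freqs))
  if (abs(spectrum$freqs[i] - f_hz) >= tol + 1e-12) {
    stop("frequency-alignment error: no bin within ", tol, " Hz of ",
         f_hz, " Hz (nearest: ", spectrum$freqs[i], " Hz)")
  }
  i
}

#' Export a spectrum as long-format TSV
#'
#' Columns `channel`, `freq`, `amp`.
#'
#' @param spectrum a `fpvs_spectrum`.
#' @param path output path.
#' @param f_max optional frequency cap to keep files small.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path, f_max = NULL) {
  keep <- if (is.null(f_max)) seq_along(spectrum$freqs) else
    which(spectrum$freqs <= f_max)
  d <- data.frame(
    channel = rep(spectrum$channel_names, times = length(keep)),
    freq = rep(spectrum$freqs[keep], each = nrow(spectrum$amps)),
    amp = as.numeric(spectrum$amps[, keep]),
    stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# single-channel amplitude vector access (for noise-window statistics)
.spectrum_vector <- function(spectrum, channel = NULL) {
  if (is.numeric(spectrum)) return(spectrum)
  stopifnot(inherits(spectrum, "fpvs_spectrum"))
  if (is.null(channel)) {
    if (nrow(spectrum$amps) != 1) {
      stop("multi-channel spectrum: give a channel or ROI-average first")
    }
    spectrum$amps[1, ]
  } else {
    i <- match(channel, spectrum$channel_names)
    if (is.na(i)) stop("channel not in spectrum: ", channel)
    spectrum$amps[i, ]
  }
}
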