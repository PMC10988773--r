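# shared fixture builders; everything is generated in code at test time

make_sets <- function(n_dev = 30, n_base = 30, prefix = c("w", "n")) {
  list(
    dev = stimulus_set(sprintf("%s%03d", prefix[1], seq_len(n_dev)),
                       "word", "dev"),
    base = stimulus_set(sprintf("%s%03d", prefix[2], seq_len(n_base)),
                        "nonword", "base")
  )
}

# single-channel epoch holding a sum of exact-bin cosines
cosine_epoch <- function(freqs, amps, duration_s = 60, fs = 512,
                         phases = 0, n_channels = 1) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  phases <- rep_len(phases, length(freqs))
  x <- rowSums(mapply(function(f, a, ph) a * cos(2 * pi * f * t + ph),
                      freqs, amps, phases))
  data <- matrix(rep(x, each = n_channels), nrow = n_channels)
  rownames(data) <- paste0("ch", seq_len(n_channels))
  fpvs_epoch(data, fs)
}

# amplitude spectrum of white gaussian time noise (Rayleigh-distributed bins)
noise_amplitude_vector <- function(n = 2^14, fs = 512, seed = 1) {
  x <- with_seed(seed, rnorm(n))
  amplitude_spectrum(fpvs_epoch(matrix(x, 1, dimnames = list("ch1", NULL)),
                                fs))
}

# brute-force neighbouring-bin statistics used as the independent oracle
brute_bin_stats <- function(a, tb) {
  snr_idx <- c((tb - 10):(tb - 1), (tb + 1):(tb + 10))
  cand_idx <- c((tb - 12):(tb - 2), (tb + 2):(tb + 12))
  w <- a[cand_idx]
  ord_min <- which(w == min(w))[1]
  w2 <- w[-ord_min]
  ord_max <- which(w2 == max(w2))[1]
  zw <- w2[-ord_max]
  m <- sum(zw) / length(zw)
  s <- sqrt(sum((zw - m)^2) / (length(zw) - 1))
  list(snr = a[tb] / mean(a[snr_idx]),
       corrected = a[tb] - m,
       z = (a[tb] - m) / s)
}

# small montage-free scaled run configuration (noiseless by default)
tiny_config <- function(..., noise = list(pink_scale = 0, white_scale = 0)) {
  fpvs_config(
    n_participants = 1L,
    design = list(duration_s = 10, n_reps = 1, n_task_events = 2,
                  n_words = 10),
    acquisition = list(fs_hz = 256, pre_s = 2.5, post_s = 0.5),
    noise = noise,
    preprocess = list(hi_hz = 60, target_fs = 128, post_s = 12),
    analysis = list(f_max_oddball = 8, f_max_base = 40),
    ...
  )
}

# expected ROI amplitude after common-average re-referencing: the average
# reference subtracts the mean topography weight from every channel
rereferenced_weight <- function(topography, channels, roi_channels) {
  w <- topography[channels]
  w[is.na(w)] <- 0
  mean(w[roi_channels]) - mean(w)
}
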