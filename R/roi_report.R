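#' Region-of-interest definitions
#'
#' A named electrode set averaged together.  Defaults follow the usual
#' occipito-temporal / medial-occipital choices: LROI is five electrodes
#' around PO7, RROI its exact right-hemisphere mirror, MO the
#' medial-occipital set.  The LROI membership is configurable and is
#' echoed in every report.
#'
#' @param name ROI name.
#' @param channels electrode names.
#' @return an object of class `fpvs_roi`.
#' @export
fpvs_roi <- function(name, channels) {
  stopifnot(is.character(name), length(channels) >= 1)
  structure(list(name = name, channels = channels), class = "fpvs_roi")
}

#' @rdname fpvs_roi
#' @export
default_rois <- function() {
  list(
    LROI = fpvs_roi("LROI", c("PO7", "P7", "P9", "PO9", "O1")),
    RROI = fpvs_roi("RROI", c("PO8", "P8", "P10", "PO10", "O2")),
    MO   = fpvs_roi("MO", c("Oz", "Iz", "O1", "O2"))
  )
}

#' Average a spectrum over an ROI
#'
#' Unweighted mean across the ROI channels at every bin, returning a
#' single-channel spectrum named after the ROI.
#'
#' @param spectrum a `fpvs_spectrum`.
#' @param roi a `fpvs_roi`.
#' @return single-channel `fpvs_spectrum`.
#' @export
roi_average <- function(spectrum, roi) {
  idx <- match(roi$channels, spectrum$channel_names)
  if (anyNA(idx)) {
    stop("ROI channels missing from spectrum: ",
         paste(roi$channels[is.na(idx)], collapse = ", "))
  }
  out <- spectrum
  out$amps <- matrix(colMeans(spectrum$amps[idx, , drop = FALSE]),
                     nrow = 1)
  out$channel_names <- roi$name
  out
}

#' Grand-average spectra across participants
#'
#' Bin-wise mean across a list of spectra on identical frequency grids.
#'
#' @param spectra list of `fpvs_spectrum`s.
#' @return a `fpvs_spectrum`.
#' @export
grand_average <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  s1 <- spectra[[1]]
  for (s in spectra[-1]) {
    if (!isTRUE(all.equal(s$freqs, s1$freqs)) ||
        !identical(dim(s$amps), dim(s1$amps))) {
      stop("spectra must share the same frequency grid and shape")
    }
  }
  s1$amps <- Reduce(`+`, lapply(spectra, `[[`, "amps")) / length(spectra)
  s1$meta$n_grand_averaged <- length(spectra)
  s1
}

#' Individual-level significance table
#'
#' Marks each (participant, condition, task, control type, ROI) cell
#' significant when its Z exceeds `z_thresh` (default 1.64, one-tailed
#' p < .05) and tallies the counts usually reported: participants
#' significant in at least one cell, in all cells, and per-ROI / task /
#' discrimination breakdowns.
#'
#' @param results data.frame with at least `participant`, `z`, and any of
#'   `discrimination`, `task`, `control_type`, `roi`.
#' @param z_thresh individual-level critical Z.
#' @return list with `table` (input plus `significant`) and `summary`
#'   (named list of counts).
#' @export
individual_significance <- function(results, z_thresh = 1.64) {
  stopifnot(all(c("participant", "z") %in% names(results)))
  results$significant <- results$z > z_thresh
  by_part <- split(results$significant, results$participant)
  n_any <- sum(vapply(by_part, any, TRUE))
  n_all <- sum(vapply(by_part, all, TRUE))
  summary <- list(
    n_participants = length(by_part),
    n_significant_any_cell = n_any,
    n_significant_all_cells = n_all,
    z_thresh = z_thresh
  )
  for (fac in intersect(c("roi", "task", "discrimination", "control_type"),
                        names(results))) {
    # participants significant in >= 1 cell of each factor level
    lev <- split(results, results[[fac]])
    summary[[paste0("by_", fac)]] <- vapply(lev, function(d) {
      sum(vapply(split(d$significant, d$participant), any, TRUE))
    }, 0L)
  }
  list(table = results, summary = summary)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic t approximation, as appropriate with ties).
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with `rho`, `p`, `n`; `rho` is `NA` (with a warning) for a
#'   constant vector.
#' @examples
#' spearman_correlation(1:5, c(3, 1, 2, 5, 4))$rho  # 0.6
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Score behavioural responses to the orthogonal task
#'
#' Matches key presses to go events: a hit is the first unmatched press
#' falling within the response window after a go event; each press matches
#' at most one event; presses matched to no go event count as false
#' alarms.  The false-alarm rate is relative to the number of no-go events
#' when there are any (bars task), else to the number of events.
#'
#' @param events data.frame from [plan_task_events()] (`onset_s`, `is_go`).
#' @param presses numeric vector of key-press onsets, seconds.
#' @param window response window after a go onset, seconds
#'   (default 0.15-1.0).
#' @return list: `n_go`, `n_nogo`, `hits`, `hit_rate`, `fa_count`,
#'   `fa_rate`, `mean_rt_s` (mean hit reaction time), `rts_s`.
#' @export
score_behavior <- function(events, presses, window = c(0.15, 1.0)) {
  go <- events$onset_s[events$is_go]
  n_go <- length(go)
  n_nogo <- sum(!events$is_go)
  presses <- sort(as.numeric(unlist(presses)))
  used <- rep(FALSE, length(presses))
  rts <- numeric(0)
  for (g in sort(go)) {
    ok <- !used & presses >= g + window[1] & presses <= g + window[2]
    if (any(ok)) {
      i <- which(ok)[1]
      used[i] <- TRUE
      rts <- c(rts, presses[i] - g)
    }
  }
  fa <- sum(!used)
  denom <- if (n_nogo > 0) n_nogo else max(length(events$onset_s), 1L)
  list(n_go = n_go, n_nogo = n_nogo,
       hits = length(rts),
       hit_rate = if (n_go > 0) length(rts) / n_go else NA_real_,
       fa_count = fa, fa_rate = fa / denom,
       mean_rt_s = if (length(rts) > 0) mean(rts) else NA_real_,
       rts_s = rts)
}
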