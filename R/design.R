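#' Construct a stimulus set
#'
#' A stimulus set is a labelled collection of items of one category
#' (words, pseudowords or nonwords), optionally carrying per-item
#' psycholinguistic attributes (orthographic neighbourhood size and
#' per-million bigram frequency) used for matching validation.
#'
#' @param labels character vector of unique item labels.
#' @param category one of `"word"`, `"pseudoword"`, `"nonword"`.
#' @param set_id identifier for the set.
#' @param n_letters integer letter counts (default: `nchar(labels)`).
#' @param neighbours optional numeric orthographic-neighbour counts.
#' @param bigram_freq optional numeric bigram frequencies (per million).
#' @return a data.frame of class `fpvs_stimset` with one row per item and
#'   attribute `set_id`.
#' @examples
#' stimulus_set(c("radio", "tigre"), "word", "w-demo")
#' @export
stimulus_set <- function(labels, category = c("word", "pseudoword", "nonword"),
                         set_id = "set", n_letters = nchar(labels),
                         neighbours = NULL, bigram_freq = NULL) {
  category <- match.arg(category)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("labels must be unique within a set")
  if (length(labels) < 1L) stop("a stimulus set needs at least one item")
  n_letters <- as.integer(n_letters)
  if (any(n_letters < 1L)) stop("n_letters must be >= 1")
  out <- data.frame(
    label = labels, category = category, n_letters = n_letters,
    neighbours = if (is.null(neighbours)) NA_real_ else as.numeric(neighbours),
    bigram_freq = if (is.null(bigram_freq)) NA_real_ else as.numeric(bigram_freq),
    stringsAsFactors = FALSE
  )
  attr(out, "set_id") <- set_id
  class(out) <- c("fpvs_stimset", "data.frame")
  out
}

#' Read / write stimulus sets as TSV
#'
#' UTF-8 tab-separated files with columns `label`, `category`, `n_letters`,
#' `neighbours`, `bigram_freq`.
#'
#' @param path file path.
#' @param set a `fpvs_stimset`.
#' @param set_id set identifier used on read.
#' @return `read_stimulus_tsv()` returns a `fpvs_stimset`;
#'   `write_stimulus_tsv()` returns `path` invisibly.
#' @export
read_stimulus_tsv <- function(path, set_id = basename(path)) {
  d <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("label", "category", "n_letters")
  if (!all(need %in% names(d))) {
    stop("stimulus TSV must have columns: ", paste(need, collapse = ", "))
  }
  stimulus_set(d$label, unique(d$category), set_id = set_id,
               n_letters = d$n_letters, neighbours = d$neighbours,
               bigram_freq = d$bigram_freq)
}

#' @rdname read_stimulus_tsv
#' @export
write_stimulus_tsv <- function(set, path) {
  write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# sequential draw of a multiset honouring "no two adjacent labels equal";
# slots occupy stream positions `positions` (adjacency only where positions
# are consecutive); forbidden_prev/next carry already-placed stream
# neighbours (deviants) the drawn item must also differ from
.schedule_no_repeat <- function(labels, counts, positions, forbidden_prev,
                                forbidden_next, max_retries = 10000L) {
  n_slots <- length(positions)
  chained <- c(FALSE, diff(positions) == 1L)
  for (attempt in seq_len(max_retries)) {
    remaining <- counts
    out <- character(n_slots)
    prev <- ""
    ok <- TRUE
    for (i in seq_len(n_slots)) {
      prev_i <- if (chained[i]) prev else ""
      cand <- remaining > 0L &
        labels != prev_i &
        labels != forbidden_prev[i] &
        labels != forbidden_next[i]
      # dead-end avoidance: an item holding at least half the remaining
      # slots must be placed whenever it is allowed
      n_left <- n_slots - i + 1L
      must <- which(cand & remaining * 2L >= n_left)
      pick <- if (length(must) > 0L) {
        must[sample.int(length(must), 1L)]
      } else if (any(cand)) {
        idx <- which(cand)
        idx[sample.int(length(idx), 1L, prob = remaining[idx])]
      } else {
        ok <- FALSE
        break
      }
      out[i] <- labels[pick]
      remaining[pick] <- remaining[pick] - 1L
      prev <- labels[pick]
    }
    if (ok) return(out)
  }
  stop("scheduling error: could not satisfy no-repeat constraint after ",
       max_retries, " retries")
}

#' Plan one oddball stimulation sequence
#'
#' Builds the timed presentation stream of a single stimulation sequence:
#' base-category items at the base rate with every `oddball_every`-th
#' presentation replaced by a deviant (so deviants recur at
#' `f_base / oddball_every` Hz), no immediate repetition of the same label,
#' and an orthogonal task-event schedule.
#'
#' Two control types are supported. With `"set_size"` the base and deviant
#' sets have equal size, so base items are repeated `oddball_every - 1`
#' times more often than deviants (e.g. 30 base x 16 and 30 deviants x 4 in
#' a 60-s, 10 Hz sequence).  With `"item_repetition"` the base set has
#' `oddball_every - 1` times more items, so every item - base or deviant -
#' appears equally often (4x).
#'
#' @param deviants,base `fpvs_stimset`s of deviant and base items.
#' @param control_type `"set_size"` or `"item_repetition"`.
#' @param task `"cross"` (focused attention) or `"bars"` (deployed).
#' @param duration_s stimulation duration in seconds (fades excluded).
#' @param f_base base presentation rate, Hz.
#' @param oddball_every a deviant every this many presentations.
#' @param fade_in_s,fade_out_s fade durations, seconds.
#' @param n_task_events colour-change events per sequence.
#' @param seed integer; same seed reproduces the plan exactly.
#' @return an object of class `fpvs_plan`: list with `stream`
#'   (data.frame `onset_s`, `label`, `category`, `is_deviant`), `events`
#'   (see [plan_task_events()]), and the design parameters.
#' @examples
#' dev <- stimulus_set(sprintf("w%02d", 1:30), "word", "w")
#' nw  <- stimulus_set(sprintf("n%02d", 1:30), "nonword", "nw1")
#' p <- plan_sequence(dev, nw, "set_size", seed = 1)
#' nrow(p$stream)          # 600
#' sum(p$stream$is_deviant) # 120
#' @export
plan_sequence <- function(deviants, base,
                          control_type = c("set_size", "item_repetition"),
                          task = c("cross", "bars"),
                          duration_s = 60, f_base = 10, oddball_every = 5,
                          fade_in_s = 2, fade_out_s = 2,
                          n_task_events = 8, seed = 1L) {
  control_type <- match.arg(control_type)
  task <- match.arg(task)
  n_pres <- duration_s * f_base
  if (abs(n_pres - round(n_pres)) > 1e-9) {
    stop("configuration error: duration_s * f_base must be an integer")
  }
  n_pres <- as.integer(round(n_pres))
  if (n_pres %% oddball_every != 0L) {
    stop("configuration error: duration_s * f_base must be divisible by ",
         "oddball_every")
  }
  n_dev <- n_pres %/% oddball_every
  n_base_slots <- n_pres - n_dev
  n_d <- nrow(deviants); n_b <- nrow(base)
  if (control_type == "set_size") {
    if (n_b != n_d) {
      stop("configuration error: set_size control requires equally sized ",
           "base and deviant sets (got ", n_b, " vs ", n_d, ")")
    }
  } else {
    if (n_b != (oddball_every - 1L) * n_d) {
      stop("configuration error: item_repetition control requires ",
           "|base| = ", oddball_every - 1L, " x |deviants| (got ", n_b,
           " vs ", n_d, " deviants)")
    }
  }
  if (n_dev %% n_d != 0L || n_base_slots %% n_b != 0L) {
    stop("configuration error: presentation counts do not divide evenly ",
         "over the stimulus sets")
  }
  dev_reps <- n_dev %/% n_d
  base_reps <- n_base_slots %/% n_b

  with_seed(seed, {
    # deviant positions: every oddball_every-th presentation (5, 10, ...)
    dev_pos <- seq(oddball_every, n_pres, by = oddball_every)
    base_pos <- setdiff(seq_len(n_pres), dev_pos)
    # deviants are never stream-adjacent (separated by bases): plain shuffle
    dev_labels <- sample(rep(deviants$label, dev_reps))
    # base slots: no-repeat within runs, and never equal to the neighbouring
    # deviant label (guards against cross-set label collisions)
    stream_lab <- character(n_pres)
    stream_lab[dev_pos] <- dev_labels
    fprev <- fnext <- rep("", length(base_pos))
    fprev[base_pos > 1L] <- stream_lab[base_pos[base_pos > 1L] - 1L]
    fnext[base_pos < n_pres] <- stream_lab[base_pos[base_pos < n_pres] + 1L]
    # only deviant neighbours are known now; base-base adjacency handled by
    # the sequential scheduler itself
    base_labels <- .schedule_no_repeat(base$label,
                                       rep(base_reps, n_b), base_pos,
                                       fprev, fnext)
    stream_lab[base_pos] <- base_labels
    events <- plan_task_events(task, n_task_events, duration_s,
                               seed = sample.int(.Machine$integer.max, 1L))
    stream <- data.frame(
      position = seq_len(n_pres),
      onset_s = (seq_len(n_pres) - 1L) / f_base,
      label = stream_lab,
      category = ifelse(seq_len(n_pres) %in% dev_pos,
                        deviants$category[1], base$category[1]),
      is_deviant = seq_len(n_pres) %in% dev_pos,
      stringsAsFactors = FALSE
    )
    out <- list(
      stream = stream, events = events,
      base_rate_hz = f_base, oddball_every = oddball_every,
      oddball_hz = f_base / oddball_every,
      duration_s = duration_s, fade_in_s = fade_in_s, fade_out_s = fade_out_s,
      control_type = control_type, task = task,
      deviant_set = attr(deviants, "set_id"), base_set = attr(base, "set_id"),
      seed = as.integer(seed)
    )
    class(out) <- "fpvs_plan"
    out
  })
}

#' @export
print.fpvs_plan <- function(x, ...) {
  cat(sprintf(
    "<fpvs_plan> %gs @ %g Hz, deviant every %d (%.1f Hz), %s control, %s task\n",
    x$duration_s, x$base_rate_hz, x$oddball_every, x$oddball_hz,
    x$control_type, x$task))
  cat(sprintf("  %d presentations (%d deviants), %d task events, seed %d\n",
              nrow(x$stream), sum(x$stream$is_deviant), nrow(x$events),
              x$seed))
  invisible(x)
}

#' Plan orthogonal task events
#'
#' Schedules brief colour-change events uniformly at random within the
#' stimulation window, with a minimum inter-event gap and no events inside
#' the fade windows.  In the cross task every change is a go event; in the
#' bars task the change affects both bars (go) with probability `p_go`,
#' otherwise the left or right bar alone (no-go), equiprobably.
#'
#' @param task `"cross"` or `"bars"`.
#' @param n_events number of events.
#' @param duration_s length of the schedulable window, seconds.
#' @param min_gap_s minimum gap between event offset and next onset.
#' @param p_go probability that a bars event is a both-bars go event.
#' @param event_duration_s event duration (200 ms).
#' @param seed integer seed.
#' @return data.frame with columns `onset_s`, `duration_s`, `kind`
#'   (`cross_change`, `bars_both`, `bars_left`, `bars_right`) and `is_go`.
#' @examples
#' plan_task_events("bars", 8, 60, seed = 7)
#' @export
plan_task_events <- function(task = c("cross", "bars"), n_events, duration_s,
                             min_gap_s = 1.0, p_go = 0.5,
                             event_duration_s = 0.2, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_events >= 0)
  if (n_events == 0L) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      kind = character(0), is_go = logical(0),
                      stringsAsFactors = FALSE))
  }
  slot <- event_duration_s + min_gap_s
  slack <- duration_s - n_events * slot
  if (slack < 0) stop("scheduling error: events do not fit in the sequence")
  with_seed(seed, {
    # uniform placement subject to the minimum gap via the spacings method
    u <- sort(runif(n_events, 0, slack))
    onsets <- u + (seq_len(n_events) - 1L) * slot
    if (task == "cross") {
      kind <- rep("cross_change", n_events)
      is_go <- rep(TRUE, n_events)
    } else {
      r <- runif(n_events)
      kind <- ifelse(r < p_go, "bars_both",
                     ifelse(r < p_go + (1 - p_go) / 2, "bars_left",
                            "bars_right"))
      is_go <- kind == "bars_both"
    }
    data.frame(onset_s = onsets, duration_s = event_duration_s, kind = kind,
               is_go = is_go, stringsAsFactors = FALSE)
  })
}

#' Plan a full session
#'
#' Crosses discrimination level (words among nonwords, NWW, or among
#' pseudowords, PWW) with control type (set size / item repetition),
#' repeats each condition `n_reps` times per task, and blocks sequences by
#' task.  The default grid gives 2 tasks x 4 conditions x 3 repetitions =
#' 24 sequences.
#'
#' @param stimuli a list with elements `words` (`fpvs_stimset`) and, per
#'   discrimination level `NWW`/`PWW`, base sets for each control type:
#'   `list(NWW = list(set_size = ..., item_repetition = ...), PWW = ...)`.
#'   See [demo_stimuli()].
#' @param n_reps repetitions of each condition within each task.
#' @param task_order length-2 permutation of `c("cross", "bars")`.
#' @param seed integer seed (sequence order and per-sequence seeds derive
#'   from it).
#' @param ... passed to [plan_sequence()] (e.g. `duration_s`, `f_base`).
#' @return an object of class `fpvs_session`: list with `sequences` (list of
#'   `fpvs_plan`), `index` (data.frame of task/discrimination/control/rep),
#'   `task_order` and `seed`.
#' @examples
#' # scaled-down session: 10 words over 5-s sequences keeps counts exact
#' s <- plan_session(demo_stimuli(n_words = 10, seed = 1), n_reps = 1,
#'                   seed = 1, duration_s = 5, n_task_events = 2)
#' nrow(s$index)  # 8
#' @export
plan_session <- function(stimuli, n_reps = 3,
                         task_order = c("cross", "bars"), seed = 1L, ...) {
  stopifnot(setequal(task_order, c("cross", "bars")), length(task_order) == 2)
  grid <- expand.grid(discrimination = c("NWW", "PWW"),
                      control_type = c("set_size", "item_repetition"),
                      rep = seq_len(n_reps), stringsAsFactors = FALSE)
  with_seed(seed, {
    sequences <- list()
    index <- NULL
    for (task in task_order) {
      ord <- sample.int(nrow(grid))
      block <- grid[ord, , drop = FALSE]
      for (i in seq_len(nrow(block))) {
        row <- block[i, ]
        base <- stimuli[[row$discrimination]][[row$control_type]]
        seq_seed <- sample.int(.Machine$integer.max, 1L)
        plan <- plan_sequence(stimuli$words, base,
                              control_type = row$control_type, task = task,
                              seed = seq_seed, ...)
        sequences[[length(sequences) + 1L]] <- plan
        index <- rbind(index, data.frame(
          sequence = length(sequences), task = task,
          discrimination = row$discrimination,
          control_type = row$control_type, rep = row$rep,
          seed = seq_seed, stringsAsFactors = FALSE))
      }
    }
    out <- list(sequences = sequences, index = index,
                task_order = task_order, seed = as.integer(seed))
    class(out) <- "fpvs_session"
    out
  })
}

#' @export
print.fpvs_session <- function(x, ...) {
  cat(sprintf("<fpvs_session> %d sequences, task order %s, seed %d\n",
              length(x$sequences), paste(x$task_order, collapse = " -> "),
              x$seed))
  invisible(x)
}

#' Generate synthetic demonstration stimulus sets
#'
#' Random letter-string stand-ins for the word / pseudoword / nonword sets
#' (30 words, 4 x 30 pseudowords, 4 x 30 nonwords, all 5 letters), with
#' synthetic attributes mimicking the matching structure: pseudowords match
#' the words' orthographic-neighbour and bigram-frequency distributions,
#' nonwords do not.  Purely synthetic labels - no lexical database is used.
#'
#' @param n_words words per set.
#' @param n_letters letters per item.
#' @param seed integer seed.
#' @return list with `words`, `pw_sets` (list of 4), `nw_sets` (list of 4)
#'   and the [plan_session()]-ready `NWW`/`PWW` base-set structure.
#' @export
demo_stimuli <- function(n_words = 30, n_letters = 5, seed = 1L) {
  with_seed(seed, {
    cons <- strsplit("bcdfgjlmnprstv", "")[[1]]
    vow <- strsplit("aeiou", "")[[1]]
    mk_label <- function() {
      paste0(paste0(sample(cons, ceiling(n_letters / 2), TRUE),
                    c(sample(vow, floor(n_letters / 2), TRUE), "")),
             collapse = "")
    }
    mk_set <- function(n, category, id, neigh_mean, bigram_mean) {
      labels <- character(0)
      while (length(labels) < n) labels <- unique(c(labels, mk_label()))
      labels <- labels[seq_len(n)]
      stimulus_set(labels, category, id,
                   neighbours = pmax(0, round(rnorm(n, neigh_mean, 2))),
                   bigram_freq = pmax(0, rnorm(n, bigram_mean, 3500)))
    }
    words <- mk_set(n_words, "word", "words", 2.6, 11600)
    pw_sets <- lapply(1:4, function(i)
      mk_set(n_words, "pseudoword", paste0("PW", i), 2.6, 11600))
    nw_sets <- lapply(1:4, function(i)
      mk_set(n_words, "nonword", paste0("NW", i), 0.1, 6500))
    join4 <- function(sets, id) {
      d <- do.call(rbind, lapply(sets, as.data.frame))
      stimulus_set(d$label, unique(d$category), id,
                   n_letters = d$n_letters, neighbours = d$neighbours,
                   bigram_freq = d$bigram_freq)
    }
    list(
      words = words, pw_sets = pw_sets, nw_sets = nw_sets,
      NWW = list(set_size = nw_sets[[1]],
                 item_repetition = join4(nw_sets, "NW1-4")),
      PWW = list(set_size = pw_sets[[1]],
                 item_repetition = join4(pw_sets, "PW1-4"))
    )
  })
}

#' Validate psycholinguistic matching between two stimulus sets
#'
#' Two-sample t-tests per attribute (orthographic neighbours, bigram
#' frequency), flagging attributes on which the sets differ at `alpha`.
#' Pseudoword sets are expected to match the words; nonword sets are
#' expected to be flagged on both attributes.
#'
#' @param words,other `fpvs_stimset`s with attributes present.
#' @param attributes attribute columns to compare.
#' @param alpha significance level for flagging.
#' @param var_equal use the pooled-variance (Student) t-test; default Welch.
#' @return data.frame with columns `attribute`, `t`, `df`, `p`, `flagged`.
#' @export
validate_matching <- function(words, other,
                              attributes = c("neighbours", "bigram_freq"),
                              alpha = 0.05, var_equal = FALSE) {
  for (a in attributes) {
    if (anyNA(words[[a]]) || anyNA(other[[a]])) {
      stop("validation error: attribute '", a, "' missing for some items")
    }
  }
  rows <- lapply(attributes, function(a) {
    x <- words[[a]]; y <- other[[a]]
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      # identical constant sets: no evidence of difference
      return(data.frame(attribute = a, t = 0, df = NA_real_, p = 1,
                        flagged = FALSE, stringsAsFactors = FALSE))
    }
    tt <- t.test(x, y, var.equal = var_equal)
    data.frame(attribute = a, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               flagged = tt$p.value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a sequence plan to disk
#'
#' Writes a JSON sidecar with the full plan and a 3-column BIDS-style
#' events table (`onset`, `duration`, `trial_type`).
#'
#' @param plan a `fpvs_plan`.
#' @param stem output path stem; writes `<stem>_plan.json` and
#'   `<stem>_events.tsv`.
#' @return invisibly, the two paths written.
#' @export
write_plan <- function(plan, stem) {
  pj <- paste0(stem, "_plan.json")
  ev <- paste0(stem, "_events.tsv")
  jsonlite::write_json(unclass(plan), pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tab <- rbind(
    data.frame(onset = plan$stream$onset_s, duration = 1 / plan$base_rate_hz,
               trial_type = ifelse(plan$stream$is_deviant, "deviant", "base"),
               stringsAsFactors = FALSE),
    data.frame(onset = plan$events$onset_s, duration = plan$events$duration_s,
               trial_type = plan$events$kind, stringsAsFactors = FALSE)
  )
  tab <- tab[order(tab$onset), ]
  write.table(tab, ev, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pj, ev))
}
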