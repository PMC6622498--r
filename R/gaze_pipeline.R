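# Looking-while-listening preprocessing: AOI labelling, 50 ms binning, the
# trial-level log-gaze proportion ratio, and the comprehension / track-loss
# exclusion filters with an audit ledger.

#' Gaze sample states
#' @return The four-state alphabet used throughout the gaze pipeline.
#' @export
gaze_states <- function() {
  c("TARGET", "DISTRACTOR", "OTHER_ONSCREEN", "OFFSCREEN")
}

#' Define the screen and area-of-interest layout
#'
#' Two equal AOI rectangles (default 400 x 400 px on a 1280 x 1024 px
#' screen), one on each side, vertically centred.  Rectangle membership is
#' half-open: a point at `x0 + width` lies outside the rectangle.
#'
#' @param screen Width and height of the screen in pixels.
#' @param aoi_size Width and height of each AOI rectangle.
#' @param left_x,right_x Left edge of the left/right rectangle.
#' @param y Top edge of both rectangles.
#' @return A list of class `lg_aoi_layout`.
#' @export
aoi_layout <- function(screen = c(1280, 1024), aoi_size = c(400, 400),
                       left_x = 88, right_x = 792,
                       y = (screen[2] - aoi_size[2]) / 2) {
  rect <- function(x0) c(x0 = x0, y0 = y, x1 = x0 + aoi_size[1],
                         y1 = y + aoi_size[2])
  l <- rect(left_x); r <- rect(right_x)
  stopifnot(l[["x0"]] >= 0, r[["x1"]] <= screen[1],
            l[["y0"]] >= 0, l[["y1"]] <= screen[2])
  if (l[["x1"]] > r[["x0"]]) stop("AOI rectangles overlap", call. = FALSE)
  structure(list(screen = screen, left = l, right = r),
            class = "lg_aoi_layout")
}

in_rect <- function(x, y, r) {
  x >= r[["x0"]] & x < r[["x1"]] & y >= r[["y0"]] & y < r[["y1"]]
}

#' Label gaze points with AOI states
#'
#' @param points Data frame with columns `x`, `y` (pixels; `NA` marks a lost
#'   sample).
#' @param layout An [aoi_layout()].
#' @param target_side `"left"` or `"right"`: which rectangle holds the
#'   target image.
#' @return Character vector of states (see [gaze_states()]).
#' @export
label_samples <- function(points, layout, target_side = c("left", "right")) {
  target_side <- match.arg(target_side)
  x <- points$x; y <- points$y
  tgt <- layout[[target_side]]
  dst <- layout[[setdiff(c("left", "right"), target_side)]]
  on_screen <- !is.na(x) & !is.na(y) &
    x >= 0 & x < layout$screen[1] & y >= 0 & y < layout$screen[2]
  st <- rep("OFFSCREEN", nrow(points))
  st[on_screen] <- "OTHER_ONSCREEN"
  it <- on_screen & in_rect(x, y, tgt)
  id <- on_screen & in_rect(x, y, dst)
  st[it] <- "TARGET"
  st[id] <- "DISTRACTOR"
  st
}

#' Construct a gaze trial
#'
#' One trial's labelled 500 Hz sample stream plus metadata.  Sample times
#' are implicit: sample `i` is at `2 * (i - 1)` ms relative to label onset.
#' When explicit times are supplied they must be strictly increasing with
#' 2 ms spacing starting at 0.
#'
#' @param trial_id,child_id Identifiers.
#' @param condition `"related"` or `"unrelated"`.
#' @param target,distractor Item ids.
#' @param rating Comprehension rating in 1..4.
#' @param states Vector of states (character, factor or integer codes
#'   into [gaze_states()]).
#' @param target_side `"left"` or `"right"`.
#' @param t Optional explicit sample times (ms).
#' @return A list of class `lg_gaze_trial`; `$state` holds integer codes.
#' @export
gaze_trial <- function(trial_id, child_id, condition, target, distractor,
                       rating, states, target_side = "left", t = NULL) {
  lv <- gaze_states()
  if (is.numeric(states)) {
    state <- as.integer(states)
    if (any(state < 1L | state > 4L)) stop("invalid state codes",
                                           call. = FALSE)
  } else {
    state <- match(as.character(states), lv)
    if (anyNA(state)) {
      abort_with_listing("states outside the four-state alphabet",
                         unique(as.character(states)[is.na(state)]))
    }
  }
  if (!is.null(t)) {
    if (length(t) != length(state) || any(diff(t) != 2) || t[1] != 0) {
      stop("sample times must start at 0 and increase in 2 ms steps",
           call. = FALSE)
    }
  }
  stopifnot(condition %in% c("related", "unrelated"),
            rating %in% 1:4, target_side %in% c("left", "right"))
  structure(list(trial_id = as.character(trial_id),
                 child_id = as.character(child_id),
                 condition = condition, target = target,
                 distractor = distractor, rating = as.integer(rating),
                 target_side = target_side, state = state, hz = 500L),
            class = "lg_gaze_trial")
}

#' @export
print.lg_gaze_trial <- function(x, ...) {
  cat("<gaze trial ", x$trial_id, "> ", x$condition, " ", x$target, "/",
      x$distractor, ", ", length(x$state), " samples\n", sep = "")
  invisible(x)
}

trial_times <- function(trial) 2 * (seq_along(trial$state) - 1)

#' Bin a trial's samples into fixed-width intervals
#'
#' Bin `b` aggregates samples with `bin_ms * b <= t < bin_ms * (b + 1)`.
#' Proportions are state counts over all samples in the bin (off-screen
#' samples included in the denominator); bins holding no samples are
#' flagged and carry `NA` proportions.
#'
#' @param trial An `lg_gaze_trial`.
#' @param bin_ms Bin width in ms (default 50).
#' @return Data frame with one row per bin: `bin_start`, `n`, `p_target`,
#'   `p_distractor`, `p_other`, `p_offscreen`, `empty`.
#' @export
bin_timecourse <- function(trial, bin_ms = 50) {
  t <- trial_times(trial)
  end <- t[length(t)] + 2
  starts <- seq(0, end - 1, by = bin_ms)
  idx <- findInterval(t, starts)
  counts <- matrix(0L, length(starts), 4L)
  tab <- table(idx, factor(trial$state, levels = 1:4))
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  n <- rowSums(counts)
  p <- counts / ifelse(n == 0, NA_real_, n)
  data.frame(bin_start = starts, n = n,
             p_target = p[, 1], p_distractor = p[, 2],
             p_other = p[, 3], p_offscreen = p[, 4],
             empty = n == 0L)
}

#' Trial-level log-gaze proportion ratio
#'
#' Over the analysis window (default 300 to 2000 ms post label onset,
#' half-open at the sample level), computes
#' `log((n_target + c) / (n_distractor + c))` where `c` is an additive
#' smoothing constant.  Positive values indicate a target preference, zero
#' equivalent target/distractor looking.  With `smoothing = 0` and either
#' count zero, the ratio is undefined and the trial is marked accordingly.
#'
#' @param trial An `lg_gaze_trial`.
#' @param window Length-2 numeric, window in ms (half-open).
#' @param smoothing Additive smoothing constant `c >= 0` (default 0.5).
#' @return One-row data frame: `trial_id`, `child_id`, `condition`, `item`
#'   (the target), `distractor`, `rating`, `n_target`, `n_distractor`,
#'   `n_onscreen`, `n_window`, `onscreen_prop`, `log_gaze`, `undefined`.
#' @export
#' @examples
#' st <- rep(c("TARGET", "DISTRACTOR"), each = 500)
#' tr <- gaze_trial("t1", "c1", "related", "dog", "bird", 4, st)
#' trial_log_gaze(tr)$log_gaze  # 0: equivalent looking
trial_log_gaze <- function(trial, window = c(300, 2000), smoothing = 0.5) {
  stopifnot(length(window) == 2L, window[2] > window[1], smoothing >= 0)
  t <- trial_times(trial)
  if (window[1] < 0 || window[2] > t[length(t)] + 2) {
    stop("analysis window [", window[1], ", ", window[2],
         ") extends beyond the sampled range", call. = FALSE)
  }
  sel <- t >= window[1] & t < window[2]
  if (!any(sel)) stop("analysis window contains no samples", call. = FALSE)
  cnt <- tabulate(trial$state[sel], nbins = 4L)
  n_window <- sum(sel)
  n_onscreen <- sum(cnt[1:3])
  undefined <- smoothing == 0 && (cnt[1] == 0L || cnt[2] == 0L)
  lg <- if (undefined) NA_real_ else
    log((cnt[1] + smoothing) / (cnt[2] + smoothing))
  data.frame(trial_id = trial$trial_id, child_id = trial$child_id,
             condition = trial$condition, item = trial$target,
             distractor = trial$distractor, rating = trial$rating,
             n_target = cnt[1], n_distractor = cnt[2],
             n_onscreen = n_onscreen, n_window = n_window,
             onscreen_prop = n_onscreen / n_window,
             log_gaze = lg, undefined = undefined,
             stringsAsFactors = FALSE)
}

#' Trial accuracy table for a list of trials
#'
#' @param trials List of `lg_gaze_trial`.
#' @inheritParams trial_log_gaze
#' @return Data frame with one row per trial (see [trial_log_gaze()]).
#' @export
trial_accuracy_table <- function(trials, window = c(300, 2000),
                                 smoothing = 0.5) {
  n <- length(trials)
  cnt <- matrix(0L, n, 4L)
  n_window <- integer(n)
  meta <- matrix("", n, 5L)
  rating <- integer(n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    t <- trial_times(tr)
    if (window[1] < 0 || window[2] > t[length(t)] + 2) {
      stop("analysis window [", window[1], ", ", window[2],
           ") extends beyond the sampled range of trial ", tr$trial_id,
           call. = FALSE)
    }
    sel <- t >= window[1] & t < window[2]
    if (!any(sel)) stop("analysis window contains no samples",
                        call. = FALSE)
    cnt[i, ] <- tabulate(tr$state[sel], nbins = 4L)
    n_window[i] <- sum(sel)
    meta[i, ] <- c(tr$trial_id, tr$child_id, tr$condition, tr$target,
                   tr$distractor)
    rating[i] <- tr$rating
  }
  undefined <- smoothing == 0 & (cnt[, 1L] == 0L | cnt[, 2L] == 0L)
  lg <- ifelse(undefined, NA_real_,
               log((cnt[, 1L] + smoothing) / (cnt[, 2L] + smoothing)))
  data.frame(trial_id = meta[, 1L], child_id = meta[, 2L],
             condition = meta[, 3L], item = meta[, 4L],
             distractor = meta[, 5L], rating = rating,
             n_target = cnt[, 1L], n_distractor = cnt[, 2L],
             n_onscreen = rowSums(cnt[, 1:3, drop = FALSE]),
             n_window = n_window,
             onscreen_prop = rowSums(cnt[, 1:3, drop = FALSE]) / n_window,
             log_gaze = lg, undefined = undefined,
             stringsAsFactors = FALSE)
}

#' Apply the comprehension and track-loss filters
#'
#' Filters are applied sequentially, in the order used for the study
#' bookkeeping: first, trials whose target item was rated below
#' `min_rating` are removed (comprehension filter); then, among the
#' survivors, trials with less than `min_onscreen` of the analysis window
#' spent on screen are removed (track loss); finally any trial whose
#' log-gaze ratio is undefined (only possible with zero smoothing) is
#' removed.  "On screen" counts target, distractor and other on-screen
#' samples.
#'
#' @param acc Trial accuracy table from [trial_accuracy_table()] (columns
#'   `rating`, `onscreen_prop`, `log_gaze` required).
#' @param min_rating Minimum comprehension rating retained (default 2).
#' @param min_onscreen Minimum on-screen proportion retained (default 0.2).
#' @return List with `retained` (accuracy rows surviving all filters),
#'   `exclusions` (data frame `trial_id`, `reason`), and `ledger` (data
#'   frame `stage`, `n_in`, `n_excluded`, `n_retained`, `pct_excluded`,
#'   with percentages relative to each stage's input).
#' @export
filter_trials <- function(acc, min_rating = 2, min_onscreen = 0.2) {
  stages <- list(
    low_rating = function(d) d$rating < min_rating,
    track_loss = function(d) d$onscreen_prop < min_onscreen,
    undefined_ratio = function(d) is.na(d$log_gaze)
  )
  cur <- acc
  ledger <- list()
  excl <- list()
  for (nm in names(stages)) {
    bad <- stages[[nm]](cur)
    ledger[[nm]] <- data.frame(
      stage = nm, n_in = nrow(cur), n_excluded = sum(bad),
      n_retained = nrow(cur) - sum(bad),
      pct_excluded = if (nrow(cur)) 100 * sum(bad) / nrow(cur) else 0,
      stringsAsFactors = FALSE)
    if (any(bad)) {
      excl[[nm]] <- data.frame(trial_id = cur$trial_id[bad], reason = nm,
                               stringsAsFactors = FALSE)
    }
    cur <- cur[!bad, , drop = FALSE]
  }
  rownames(cur) <- NULL
  list(retained = cur,
       exclusions = if (length(excl))
         do.call(rbind, c(excl, list(make.row.names = FALSE))) else
           data.frame(trial_id = character(0), reason = character(0)),
       ledger = do.call(rbind, c(ledger, list(make.row.names = FALSE))))
}

#' Mean fixation timecourse by group
#'
#' Averages per-bin target and distractor fixation proportions over trials
#' within groups.  Proportions keep all-sample denominators (off-AOI and
#' off-screen looks included), matching the plotting convention in which
#' curves start near zero while the child leaves the central fixation
#' stimulus.
#'
#' @param trials List of `lg_gaze_trial`.
#' @param split Optional data frame `trial_id`, `group`; trials missing
#'   from it form no group.  `NULL` pools everything into `"all"`.
#' @param bin_ms Bin width in ms.
#' @return Long data frame: `group`, `bin_start`, `state` (TARGET or
#'   DISTRACTOR), `proportion`, `n_trials`.
#' @export
grand_timecourse <- function(trials, split = NULL, bin_ms = 50) {
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (is.null(split)) {
    split <- data.frame(trial_id = ids, group = "all",
                        stringsAsFactors = FALSE)
  }
  grp <- split$group[match(ids, split$trial_id)]
  keep <- !is.na(grp)
  if (!any(keep)) {
    warning("no trials matched any group; empty timecourse", call. = FALSE)
    return(data.frame(group = character(0), bin_start = numeric(0),
                      state = character(0), proportion = numeric(0),
                      n_trials = integer(0)))
  }
  binned <- lapply(which(keep), function(i) {
    b <- bin_timecourse(trials[[i]], bin_ms)
    data.frame(group = grp[i], bin_start = b$bin_start,
               p_target = b$p_target, p_distractor = b$p_distractor,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, binned)
  agg <- stats::aggregate(cbind(p_target, p_distractor) ~ group + bin_start,
                          data = all, FUN = mean, na.rm = TRUE,
                          na.action = NULL)
  nt <- stats::aggregate(p_target ~ group + bin_start, data = all,
                         FUN = length, na.action = NULL)
  out <- rbind(
    data.frame(group = agg$group, bin_start = agg$bin_start,
               state = "TARGET", proportion = agg$p_target,
               stringsAsFactors = FALSE),
    data.frame(group = agg$group, bin_start = agg$bin_start,
               state = "DISTRACTOR", proportion = agg$p_distractor,
               stringsAsFactors = FALSE))
  out$n_trials <- nt$p_target[match(paste(out$group, out$bin_start),
                                    paste(nt$group, nt$bin_start))]
  out[order(out$group, out$bin_start, out$state), , drop = FALSE]
}

#' Read gaze samples and trial metadata from delimited text
#'
#' Accepts either pre-labelled samples (columns `trial_id`, `t_ms`,
#' `state`) or raw coordinates (columns `trial_id`, `t_ms`, `x`, `y`) which
#' are labelled against `layout` using each trial's `target_side`.
#'
#' @param samples_path Sample file (tab-separated, header row).
#' @param meta_path Trial metadata file with columns `trial_id`,
#'   `child_id`, `condition`, `target`, `distractor`, `rating`,
#'   `target_side`.
#' @param layout An [aoi_layout()]; only used for coordinate input.
#' @return List of `lg_gaze_trial`.
#' @export
read_gaze_trials <- function(samples_path, meta_path, layout = aoi_layout()) {
  smp <- read_tsv(samples_path)
  meta <- read_tsv(meta_path)
  need <- c("trial_id", "child_id", "condition", "target", "distractor",
            "rating", "target_side")
  stopifnot(all(need %in% names(meta)))
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    s <- smp[smp$trial_id == m$trial_id, , drop = FALSE]
    if (nrow(s) == 0L) {
      stop("no samples for trial ", m$trial_id, call. = FALSE)
    }
    s <- s[order(s$t_ms), , drop = FALSE]
    states <- if ("state" %in% names(s)) s$state else
      label_samples(s, layout, m$target_side)
    gaze_trial(m$trial_id, m$child_id, m$condition, m$target, m$distractor,
               m$rating, states, m$target_side, t = s$t_ms)
  })
}
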