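#' Interaction times per cage, behavior class and time bin
#'
#' Sums qualifying (retained) frames per cage and behavior class and
#' converts to seconds at the recording frame rate. Time bins are half-open
#' intervals `[bin_s * (m-1), bin_s * m)` of *retained-frame* time: the k-th
#' retained frame (0-based) occurs at `k / fps` seconds. Per-bin and
#' cumulative per-bin totals support the per-minute running index.
#'
#' @param series A (smoothed) `label_series` from [classify_frames()].
#' @param fps Frames per second; defaults to the series attribute.
#' @param bin_s Bin width in seconds (default 60 = one minute).
#' @return Object of class `interaction_summary`: list with
#'   * `per_class` — `cage`, `label`, `seconds` totals;
#'   * `per_cage` — `cage`, `seconds_sniff`, `seconds_rear`,
#'     `seconds_other`, `seconds_total`;
#'   * `per_bin` — `bin`, `cage`, `label`, `seconds`, `cum_seconds`;
#'   * `n_bins`, `fps`, `bin_s`, `duration_retained_s`, `duration_wall_s`.
#' @export
interaction_times <- function(series, fps = attr(series, "fps"),
                              bin_s = 60) {
  stopifnot(inherits(series, "label_series"), is.numeric(fps), fps > 0,
            bin_s > 0)
  n <- nrow(series)
  cages <- c("A", "B")
  labels <- c("sniff", "rear", "other")
  grid <- expand.grid(cage = cages, label = labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  n_bins <- max(1L, ceiling(n / (fps * bin_s)))
  bin_grid <- expand.grid(bin = seq_len(n_bins), cage = cages,
                          label = labels, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)

  if (n > 0) {
    sec <- (seq_len(n) - 1L) / fps          # retained-frame time
    bin <- pmin(floor(sec / bin_s) + 1L, n_bins)
    act <- series$label != "none"
    if (any(act)) {
      tab <- aggregate(
        list(frames = rep(1L, sum(act))),
        by = list(bin = bin[act], cage = series$cage[act],
                  label = series$label[act]),
        FUN = sum
      )
    } else {
      tab <- data.frame(bin = integer(0), cage = character(0),
                        label = character(0), frames = integer(0))
    }
  } else {
    tab <- data.frame(bin = integer(0), cage = character(0),
                      label = character(0), frames = integer(0))
  }

  per_bin <- merge(bin_grid, tab, all.x = TRUE, sort = FALSE)
  per_bin$frames[is.na(per_bin$frames)] <- 0L
  per_bin <- per_bin[order(per_bin$cage, per_bin$label, per_bin$bin), ]
  per_bin$seconds <- per_bin$frames / fps
  per_bin$cum_seconds <- stats::ave(
    per_bin$seconds, per_bin$cage, per_bin$label, FUN = cumsum)
  per_bin$frames <- NULL
  rownames(per_bin) <- NULL

  per_class <- aggregate(seconds ~ cage + label, data = per_bin, FUN = sum)
  per_class <- merge(grid, per_class, all.x = TRUE, sort = FALSE)
  per_class$seconds[is.na(per_class$seconds)] <- 0

  per_cage <- data.frame(cage = cages, stringsAsFactors = FALSE)
  for (lb in labels) {
    per_cage[[paste0("seconds_", lb)]] <- vapply(cages, function(cg) {
      per_class$seconds[per_class$cage == cg & per_class$label == lb]
    }, numeric(1))
  }
  per_cage$seconds_total <- per_cage$seconds_sniff + per_cage$seconds_rear +
    per_cage$seconds_other

  structure(list(
    per_class = per_class, per_cage = per_cage, per_bin = per_bin,
    n_bins = n_bins, fps = fps, bin_s = bin_s,
    duration_retained_s = n / fps,
    duration_wall_s = if (n > 0) (max(series$frame) + 1) / fps else 0
  ), class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("Interaction summary: %.1f s retained (%d bins of %g s)\n",
              x$duration_retained_s, x$n_bins, x$bin_s))
  print(x$per_cage, row.names = FALSE)
  invisible(x)
}

#' Discrimination index
#'
#' `DI = (time_novel - time_familiar) / (time_novel + time_familiar)`,
#' the standard recognition-memory preference score: +1 means exclusive
#' exploration of the novel stimulus, 0 no preference, -1 exclusive
#' exploration of the familiar one. When both times are zero the index is
#' undefined and `NA` is returned (see [flag_di()] for the exclusion
#' bookkeeping).
#'
#' @param time_novel,time_familiar Non-negative exploration times, seconds
#'   (vectorized).
#' @return Numeric DI in `[-1, 1]`, `NA` where total exploration is zero.
#' @export
#' @examples
#' discrimination_index(30, 10)  # 0.5
discrimination_index <- function(time_novel, time_familiar) {
  if (any(time_novel < 0, na.rm = TRUE) ||
      any(time_familiar < 0, na.rm = TRUE)) {
    stop("exploration times must be non-negative")
  }
  total <- time_novel + time_familiar
  ifelse(total > 0, (time_novel - time_familiar) / total, NA_real_)
}

#' Discrimination index with saturation/zero-total flags
#'
#' Applies [discrimination_index()] and records the exclusion state used
#' for early-window analyses: subjects with DI of exactly +1 or -1 explored
#' only one stimulus, so no preference can be established and they are
#' excluded; zero total exploration leaves the DI undefined.
#'
#' @inheritParams discrimination_index
#' @return Data frame `di`, `excluded`, `reason`
#'   (`"none"`, `"saturated_plus1"`, `"saturated_minus1"`, `"zero_total"`).
#' @export
flag_di <- function(time_novel, time_familiar) {
  di <- discrimination_index(time_novel, time_familiar)
  reason <- rep("none", length(di))
  reason[!is.na(di) & di == 1] <- "saturated_plus1"
  reason[!is.na(di) & di == -1] <- "saturated_minus1"
  reason[is.na(di)] <- "zero_total"
  data.frame(di = di, excluded = reason != "none", reason = reason,
             stringsAsFactors = FALSE)
}

#' Cumulative discrimination index
#'
#' The cumulative DI after trial k is the mean of the DIs from the current
#' and all prior trials; it damps trial-to-trial noise and exposes slow
#' drift such as the build-up of proactive interference across continuous
#' recognition trials.
#'
#' @param dis Ordered per-trial DIs in `[-1, 1]`, no missing values.
#' @return Numeric vector of running means, same length as `dis`.
#' @export
#' @examples
#' cumulative_di(c(0.2, 0.4))  # 0.2 0.3
cumulative_di <- function(dis) {
  if (length(dis) == 0) stop("empty DI sequence")
  if (anyNA(dis)) stop("DI sequence contains missing values")
  if (any(dis < -1 | dis > 1)) stop("DIs must lie in [-1, 1]")
  cumsum(dis) / seq_along(dis)
}

#' Per-minute running discrimination index
#'
#' Computes the DI per time bin from exploration of each cage summed up to
#' and including that bin (cumulative totals), giving the preference
#' trajectory over the session.
#'
#' @param summary An [interaction_times()] result.
#' @param novel,familiar Cage ids carrying the novel and familiar stimulus.
#' @param measure `"total"`, `"sniff"` or `"rear"`.
#' @return Data frame `bin`, `novel_s`, `familiar_s` (cumulative seconds),
#'   `di` (`NA` where cumulative total is zero), `flagged`.
#' @export
running_di_per_minute <- function(summary, novel = "A", familiar = "B",
                                  measure = c("total", "sniff", "rear")) {
  stopifnot(inherits(summary, "interaction_summary"))
  measure <- match.arg(measure)
  cum_measure <- function(cage) {
    pb <- summary$per_bin[summary$per_bin$cage == cage, ]
    if (measure == "total") {
      tapply(pb$cum_seconds, pb$bin, sum)
    } else {
      pb <- pb[pb$label == measure, ]
      stats::setNames(pb$cum_seconds, pb$bin)[as.character(seq_len(summary$n_bins))]
    }
  }
  nv <- as.numeric(cum_measure(novel))
  fm <- as.numeric(cum_measure(familiar))
  di <- discrimination_index(nv, fm)
  data.frame(bin = seq_len(summary$n_bins), novel_s = nv, familiar_s = fm,
             di = di, flagged = is.na(di))
}

#' Early- and late-block average discrimination indices
#'
#' Means of the per-trial DIs over an early and a late trial block
#' (defaults: trials 1-4 and 8-11 of an 11-trial continuous recognition
#' session).
#'
#' @param dis Per-trial DIs, trial 1 first.
#' @param early,late Integer trial indices of the two blocks.
#' @return Named numeric vector `c(early = ..., late = ...)`.
#' @export
block_average_di <- function(dis, early = 1:4, late = 8:11) {
  need <- max(early, late)
  if (length(dis) < need) {
    stop("need at least ", need, " trials (got ", length(dis),
         "); override `early`/`late` for shorter designs")
  }
  if (anyNA(dis[early]) || anyNA(dis[late])) {
    stop("missing DI inside a trial block")
  }
  c(early = mean(dis[early]), late = mean(dis[late]))
}

#' Discrimination index over the first minutes of a session
#'
#' DI computed from cumulative exploration over the first `window_bins`
#' time bins (default: minutes 1-2), with the saturation exclusion applied:
#' subjects that explored only one cage in the window (DI exactly +1 or -1)
#' are flagged excluded because no preference can be established.
#'
#' @inheritParams running_di_per_minute
#' @param window_bins Number of leading bins in the window (default 2).
#' @return One-row data frame: `measure`, `novel_s`, `familiar_s`, `di`,
#'   `excluded`, `reason`.
#' @export
early_window_di <- function(summary, novel = "A", familiar = "B",
                            measure = c("total", "sniff", "rear"),
                            window_bins = 2) {
  stopifnot(inherits(summary, "interaction_summary"))
  measure <- match.arg(measure)
  if (summary$n_bins < window_bins) {
    stop("session has ", summary$n_bins, " bins; ", window_bins,
         " required for the early window")
  }
  run <- running_di_per_minute(summary, novel, familiar, measure)
  row <- run[run$bin == window_bins, ]
  fl <- flag_di(row$novel_s, row$familiar_s)
  cbind(data.frame(measure = measure, novel_s = row$novel_s,
                   familiar_s = row$familiar_s, stringsAsFactors = FALSE),
        fl)
}

#' Score a recognition-memory exploration table
#'
#' Computes per-trial DI, cumulative DI and exclusion flags from a manually
#' scored exploration table (one row per subject and trial with novel and
#' familiar exploration seconds). Standard and continuous recognition
#' designs differ only in the number of trials; the scoring is identical.
#'
#' @param table Data frame with columns `subject_id`, `trial`,
#'   `time_novel_s`, `time_familiar_s` (extra columns such as `group` are
#'   carried through).
#' @return The table with `di`, `cdi`, `excluded`, `reason` columns
#'   appended, ordered by subject then trial. `cdi` is computed per subject
#'   over trials with defined DI.
#' @export
score_exploration_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "trial", "time_novel_s",
                  "time_familiar_s") %in% names(table)))
  table <- table[order(table$subject_id, table$trial), , drop = FALSE]
  fl <- flag_di(table$time_novel_s, table$time_familiar_s)
  out <- cbind(table, fl)
  out$cdi <- stats::ave(out$di, out$subject_id, FUN = function(v) {
    ok <- !is.na(v)
    cdi <- rep(NA_real_, length(v))
    if (any(ok)) cdi[ok] <- cumsum(v[ok]) / seq_len(sum(ok))
    cdi
  })
  rownames(out) <- NULL
  out
}
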