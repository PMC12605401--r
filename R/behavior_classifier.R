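#' Classify sniffing and rearing per retained frame
#'
#' For each retained frame, the distance from the tracking point to the
#' nearest point of each cage footprint boundary decides the cage context:
#' the nearer cage if that distance is at most `interaction_radius_cm`
#' (inclusive), otherwise no context. Within a cage context the frame is
#' labeled
#' * `rear`  — the snout passed the confidence gate and lies over the cage
#'   footprint (inset by `rear_inset_cm`), or the snout failed the gate and
#'   the mid-body point is within `rear_fallback_cm` of the boundary
#'   (overhead projection of the animal elevated against the cage wall);
#' * `sniff` — the snout lies in the perimeter annulus of width
#'   `sniff_band_cm` just outside the footprint (close-range investigation
#'   through the cage bars);
#' * `other` — any other interaction frame.
#'
#' Frames equidistant from both cage boundaries are assigned to cage A and
#' flagged in the `tie` column.
#'
#' @param points Output of [gate_frames()] (positions in cm).
#' @param geom An [apparatus_geometry()].
#' @param dist_to Distance convention: `"boundary"` (default, distance to
#'   the nearest point of the footprint boundary) or `"center"` (distance to
#'   the cage center) for sensitivity analyses.
#' @return Data frame of class `label_series`, one row per retained frame in
#'   index order: `frame`, `cage` (`"A"`/`"B"`/`NA`), `label`
#'   (`"sniff"`/`"rear"`/`"other"`/`"none"`), `source`, `tie`;
#'   attribute `fps`.
#' @export
classify_frames <- function(points, geom, dist_to = c("boundary", "center")) {
  stopifnot(inherits(points, "tracked_points"),
            inherits(geom, "apparatus_geometry"))
  dist_to <- match.arg(dist_to)
  validate_geometry(geom)

  kept <- points[points$retained, , drop = FALSE]
  n <- nrow(kept)
  if (n == 0) {
    return(empty_label_series(attr(points, "fps")))
  }
  r <- geom$cage_radius_cm

  dc_a <- sqrt((kept$x_cm - geom$cage_a_center[1])^2 +
               (kept$y_cm - geom$cage_a_center[2])^2)
  dc_b <- sqrt((kept$x_cm - geom$cage_b_center[1])^2 +
               (kept$y_cm - geom$cage_b_center[2])^2)
  # distance from the tracking point to the footprint boundary (or center)
  d_a <- if (dist_to == "boundary") abs(dc_a - r) else dc_a
  d_b <- if (dist_to == "boundary") abs(dc_b - r) else dc_b

  tie <- d_a == d_b
  near_a <- d_a <= d_b          # ties resolved toward cage A
  d_min <- pmin(d_a, d_b)
  in_zone <- d_min <= geom$interaction_radius_cm
  cage <- ifelse(in_zone, ifelse(near_a, "A", "B"), NA_character_)

  # distance from the tracking point to the *context* cage center
  dc <- ifelse(near_a, dc_a, dc_b)
  snout_ok <- kept$source == "snout"
  over_footprint <- dc <= r - geom$rear_inset_cm
  in_band <- dc > r & (dc - r) <= geom$sniff_band_cm

  label <- rep("none", n)
  is_rear <- in_zone &
    ((snout_ok & over_footprint) |
     (!snout_ok & d_min <= geom$rear_fallback_cm))
  is_sniff <- in_zone & !is_rear & snout_ok & in_band
  label[in_zone] <- "other"
  label[is_rear] <- "rear"
  label[is_sniff] <- "sniff"
  cage[label == "none"] <- NA_character_

  out <- data.frame(frame = kept$frame, cage = cage, label = label,
                    source = kept$source, tie = tie & in_zone,
                    stringsAsFactors = FALSE)
  structure(out, fps = attr(points, "fps"),
            class = c("label_series", "data.frame"))
}

empty_label_series <- function(fps) {
  structure(
    data.frame(frame = integer(0), cage = character(0),
               label = character(0), source = character(0),
               tie = logical(0), stringsAsFactors = FALSE),
    fps = fps, class = c("label_series", "data.frame")
  )
}

joint_class <- function(series) {
  ifelse(series$label == "none", "none",
         paste(series$cage, series$label, sep = ":"))
}

split_joint <- function(cls) {
  cage <- rep(NA_character_, length(cls))
  label <- rep("none", length(cls))
  hit <- cls != "none"
  parts <- strsplit(cls[hit], ":", fixed = TRUE)
  cage[hit] <- vapply(parts, `[`, "", 1)
  label[hit] <- vapply(parts, `[`, "", 2)
  list(cage = cage, label = label)
}

#' Smooth a label series with a moving-average majority vote
#'
#' Each joint (cage, label) class is turned into a per-frame indicator and
#' averaged over a centered window of `window_frames` retained frames
#' (5 frames = 200 ms at 25 fps by default; the window shrinks at the series
#' edges). The smoothed label is the class with the highest average; ties
#' break toward the previous smoothed label, then toward the unsmoothed
#' label.
#'
#' @param series A `label_series` from [classify_frames()].
#' @param window_frames Odd positive window length, default 5.
#' @return A smoothed `label_series`.
#' @export
smooth_labels <- function(series, window_frames = 5) {
  stopifnot(inherits(series, "label_series"))
  if (window_frames < 1 || window_frames %% 2 == 0) {
    stop("window_frames must be a positive odd integer")
  }
  n <- nrow(series)
  if (n == 0 || window_frames == 1) return(series)

  cls <- joint_class(series)
  levels <- unique(cls)
  k <- length(levels)
  code <- match(cls, levels)
  half <- (window_frames - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)

  # windowed indicator counts per class via cumulative sums
  counts <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    cs <- c(0L, cumsum(code == j))
    counts[, j] <- cs[hi + 1L] - cs[lo]
  }
  best <- max.col(counts, ties.method = "first")
  maxc <- counts[cbind(seq_len(n), best)]
  n_at_max <- rowSums(counts == maxc)

  out_code <- best
  ties <- which(n_at_max > 1L)
  for (i in ties) {
    cand <- which(counts[i, ] == maxc[i])
    prev <- if (i > 1L) out_code[i - 1L] else NA_integer_
    out_code[i] <- if (!is.na(prev) && prev %in% cand) prev
                   else if (code[i] %in% cand) code[i]
                   else cand[1L]
  }

  sm <- split_joint(levels[out_code])
  out <- series
  out$cage <- sm$cage
  out$label <- sm$label
  out
}

#' Extract behavior bouts from a label series
#'
#' A bout is a maximal run of consecutive retained frames sharing one
#' (cage, label) pair with label other than `none`. When no frames were
#' dropped inside a run, `duration_s = (end_frame - start_frame + 1) / fps`;
#' with drop-outs the retained-frame count of the run is used.
#'
#' @param series A (typically smoothed) `label_series`.
#' @param fps Frames per second; defaults to the series attribute.
#' @return Data frame `cage`, `label`, `start_frame`, `end_frame`,
#'   `n_frames`, `duration_s`.
#' @export
extract_bouts <- function(series, fps = attr(series, "fps")) {
  stopifnot(inherits(series, "label_series"), is.numeric(fps), fps > 0)
  if (nrow(series) == 0) {
    return(data.frame(cage = character(0), label = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      n_frames = integer(0), duration_s = numeric(0),
                      stringsAsFactors = FALSE))
  }
  cls <- joint_class(series)
  runs <- rle(cls)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != "none"
  sj <- split_joint(runs$values[keep])
  data.frame(
    cage = sj$cage, label = sj$label,
    start_frame = series$frame[starts[keep]],
    end_frame = series$frame[ends[keep]],
    n_frames = runs$lengths[keep],
    duration_s = runs$lengths[keep] / fps,
    stringsAsFactors = FALSE
  )
}

#' Write a label series or bout table to CSV
#' @param x A `label_series` or bout data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
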