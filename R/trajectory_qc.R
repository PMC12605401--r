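#' Apply the frame-inclusion gate and snout-to-mid-body fallback
#'
#' A frame is retained if and only if the mid-body likelihood reaches the
#' confidence threshold. For retained frames the tracking point is the snout
#' when the snout itself passes the gate, otherwise the mid-body point
#' (recorded in `source`). Positions are converted from pixels to
#' centimetres using the calibrated scale. Excluded frames carry no position
#' and contribute to no downstream time: all time-based metrics run on
#' retained-frame time.
#'
#' @param track A [pose_track()] (pixel coordinates).
#' @param geom An [apparatus_geometry()] providing `px_per_cm` and
#'   `confidence_threshold`.
#' @param threshold Optional override of the confidence threshold.
#' @return Data frame of class `tracked_points`: one row per frame with
#'   `frame`, `retained`, `source` (`"snout"`/`"mid_body"`/`NA`), `x_cm`,
#'   `y_cm`, plus attribute `fps`.
#' @export
gate_frames <- function(track, geom, threshold = geom$confidence_threshold) {
  stopifnot(inherits(track, "pose_track"),
            inherits(geom, "apparatus_geometry"),
            threshold >= 0, threshold <= 1)
  sn <- landmark_series(track, "snout")
  mb <- landmark_series(track, "mid_body")
  retained <- !is.na(mb$likelihood) & mb$likelihood >= threshold &
    !is.na(mb$x)
  snout_ok <- retained & !is.na(sn$likelihood) & sn$likelihood >= threshold &
    !is.na(sn$x)
  source <- ifelse(retained, ifelse(snout_ok, "snout", "mid_body"),
                   NA_character_)
  x <- ifelse(snout_ok, sn$x, mb$x) / geom$px_per_cm
  y <- ifelse(snout_ok, sn$y, mb$y) / geom$px_per_cm
  x[!retained] <- NA_real_
  y[!retained] <- NA_real_
  out <- data.frame(frame = sn$frame, retained = retained, source = source,
                    x_cm = x, y_cm = y, stringsAsFactors = FALSE)
  structure(out, fps = track_fps(track), threshold = threshold,
            class = c("tracked_points", "data.frame"))
}

#' Fraction of frames passing the confidence gate
#'
#' @param points Output of [gate_frames()].
#' @return Proportion of retained frames in `[0, 1]`.
#' @export
retained_fraction <- function(points) {
  if (nrow(points) == 0) stop("empty tracked-point sequence")
  mean(points$retained)
}

#' Per-session tracking quality report
#'
#' @param points Output of [gate_frames()].
#' @param session_id Session identifier for the report row.
#' @return One-row data frame: `session_id`, `n_frames`, `n_retained`,
#'   `retained_fraction`, `n_snout_fallbacks`, and both duration readings
#'   (`duration_wall_s` over all frames, `duration_retained_s` over retained
#'   frames).
#' @export
qc_report <- function(points, session_id = "session") {
  fps <- attr(points, "fps")
  data.frame(
    session_id = session_id,
    n_frames = nrow(points),
    n_retained = sum(points$retained),
    retained_fraction = retained_fraction(points),
    n_snout_fallbacks = sum(points$source == "mid_body", na.rm = TRUE),
    duration_wall_s = nrow(points) / fps,
    duration_retained_s = sum(points$retained) / fps,
    stringsAsFactors = FALSE
  )
}
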