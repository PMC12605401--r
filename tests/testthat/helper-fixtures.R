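# Shared fixture builders. Everything is generated in code; no stored data.

default_geom <- function(...) apparatus_geometry(px_per_cm = 8, ...)

# build a 2-landmark pose track from per-frame snout/mid_body specs;
# each of sn / mb is a data.frame or list with x, y, likelihood vectors
tiny_track <- function(sn, mb, fps = 25, frames = NULL) {
  n <- length(sn$x)
  if (is.null(frames)) frames <- 0:(n - 1)
  df <- rbind(
    data.frame(frame = frames, landmark = "snout", x = sn$x, y = sn$y,
               likelihood = sn$likelihood),
    data.frame(frame = frames, landmark = "mid_body", x = mb$x, y = mb$y,
               likelihood = mb$likelihood)
  )
  pose_track(df, fps = fps)
}

# tracked points straight from cm coordinates (bypasses gating) so the
# classifier can be exercised on hand-placed positions
make_points <- function(x, y, source = "snout", retained = TRUE, fps = 25) {
  n <- length(x)
  structure(
    data.frame(frame = 0:(n - 1), retained = rep_len(retained, n),
               source = rep_len(source, n), x_cm = x, y_cm = y,
               stringsAsFactors = FALSE),
    fps = fps, class = c("tracked_points", "data.frame")
  )
}

# hand-built label series; cage NA where label is "none"
make_series <- function(label, cage = "A", fps = 25) {
  n <- length(label)
  cage <- rep_len(cage, n)
  cage[label == "none"] <- NA_character_
  structure(
    data.frame(frame = 0:(n - 1), cage = cage, label = label,
               source = "snout", tie = FALSE, stringsAsFactors = FALSE),
    fps = fps, class = c("label_series", "data.frame")
  )
}

# per-frame agreement between classified labels and simulator ground truth
truth_agreement <- function(labels, truth_frames) {
  m <- merge(labels, truth_frames, by = "frame",
             suffixes = c("_hat", "_true"))
  same_cage <- (is.na(m$cage_hat) & is.na(m$cage_true)) |
    (!is.na(m$cage_hat) & !is.na(m$cage_true) & m$cage_hat == m$cage_true)
  mean(m$label == m$class & same_cage)
}

# one-vs-rest F1 per class over merged classified/truth frames
class_f1 <- function(labels, truth_frames,
                     classes = c("sniff", "rear", "other", "none")) {
  m <- merge(labels, truth_frames, by = "frame")
  vapply(classes, function(cl) {
    tp <- sum(m$label == cl & m$class == cl)
    fp <- sum(m$label == cl & m$class != cl)
    fn <- sum(m$label != cl & m$class == cl)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

# session-level DI recovered from the full pipeline, novel cage = A
recovered_di <- function(seed, rho, duration_s = 600, jitter = 0,
                         dropout = 0) {
  cfg <- sim_config(seed = seed, duration_s = duration_s,
                    preference_rho = rho, jitter_sd_cm = jitter,
                    dropout_prob = dropout)
  sim <- simulate_tcsi_session(cfg)
  pc <- run_pipeline(sim$track, cfg$geometry)$summary$per_cage
  (pc$seconds_total[pc$cage == "A"] - pc$seconds_total[pc$cage == "B"]) /
    sum(pc$seconds_total)
}
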