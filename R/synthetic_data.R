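#' Configuration for the synthetic session generator
#'
#' Describes a simulated overhead-view three-chamber session: a semi-Markov
#' behavioral state sequence (roam, approach, sniff, rear, idle) with
#' geometric dwell times, a per-visit cage choice biased toward the novel
#' cage with probability `preference_rho`, landmark placement consistent
#' with the zone geometry, Gaussian landmark jitter, and per-frame
#' likelihood drop-out. The implied session-level discrimination index is
#' `2 * preference_rho - 1`.
#'
#' @param seed Integer RNG seed.
#' @param fps Frames per second, default 25.
#' @param duration_s Session length in seconds, default 600 (the 10-minute
#'   social-memory phase).
#' @param geometry An [apparatus_geometry()].
#' @param preference_rho Probability in `[0, 1]` that a cage visit targets
#'   the novel cage, default 0.5.
#' @param novel_cage `"A"` or `"B"`, default `"A"`.
#' @param state_dwell_means Named mean dwell times in seconds for the five
#'   states.
#' @param jitter_sd_cm Isotropic Gaussian measurement noise on every
#'   landmark, cm (default 0).
#' @param dropout_prob Per-frame, per-landmark probability that the
#'   estimator loses the landmark: its likelihood falls below the
#'   confidence threshold and its position is scattered (default 0).
#' @param session_id Session identifier.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, fps = 25, duration_s = 600,
                       geometry = apparatus_geometry(),
                       preference_rho = 0.5, novel_cage = "A",
                       state_dwell_means = c(roam = 3, approach = 1,
                                             sniff = 2.5, rear = 1.5,
                                             idle = 2),
                       jitter_sd_cm = 0, dropout_prob = 0,
                       session_id = "sim") {
  stopifnot(fps > 0, duration_s > 0,
            inherits(geometry, "apparatus_geometry"),
            preference_rho >= 0, preference_rho <= 1,
            novel_cage %in% c("A", "B"),
            all(c("roam", "approach", "sniff", "rear", "idle") %in%
                names(state_dwell_means)),
            all(state_dwell_means > 0),
            jitter_sd_cm >= 0, dropout_prob >= 0, dropout_prob <= 1)
  validate_geometry(geometry)
  structure(list(seed = seed, fps = fps, duration_s = duration_s,
                 geometry = geometry, preference_rho = preference_rho,
                 novel_cage = novel_cage,
                 state_dwell_means = state_dwell_means,
                 jitter_sd_cm = jitter_sd_cm, dropout_prob = dropout_prob,
                 session_id = session_id),
            class = "sim_config")
}

# landmark offsets (cm) along the body axis u (snout -> tail direction)
# and its perpendicular; snout is the origin of the template
BODY_TEMPLATE <- list(
  snout = c(0, 0), left_ear = c(0.7, 0.8), right_ear = c(0.7, -0.8),
  neck = c(1.5, 0), mid_body = c(3.5, 0), tail_base = c(6, 0),
  mid_tail = c(8.5, 0), tail_end = c(11, 0)
)

# semi-Markov transition kernel (next-state probabilities, no self loops)
SIM_TRANSITIONS <- list(
  roam = c(approach = 0.7, idle = 0.3),
  idle = c(roam = 0.6, approach = 0.4),
  approach = c(sniff = 0.7, rear = 0.3),
  sniff = c(rear = 0.3, roam = 0.5, idle = 0.2),
  rear = c(sniff = 0.4, roam = 0.4, idle = 0.2)
)

#' Simulate one three-chamber session with known ground truth
#'
#' Generates a full eight-landmark pose track (pixel coordinates) plus the
#' frame-level ground-truth ethogram. States place the snout consistently
#' with the classification geometry: sniffing in the perimeter band just
#' outside the cage footprint, rearing over the footprint, approach in the
#' interaction zone beyond the sniff band, roaming and idling well outside
#' both zones. The mid-body point sits 3.5 cm behind the snout along the
#' body axis (pointing away from the cage during visits). Each cage visit
#' (approach and the sniff/rear states that follow it) targets the novel
#' cage with probability `preference_rho`.
#'
#' @param config A [sim_config()].
#' @return List with elements
#'   * `track` — a [pose_track()] in pixels;
#'   * `truth` — list with `frames` (frame, state, cage, class),
#'     `per_class` (cage, class, true_seconds over all frames),
#'     `implied_di`, `novel_cage`.
#' @export
simulate_tcsi_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geom <- config$geometry
  set.seed(config$seed)
  fps <- config$fps
  n_frames <- round(config$duration_s * fps)
  r <- geom$cage_radius_cm
  band <- geom$sniff_band_cm
  inter <- geom$interaction_radius_cm

  # state segments until the session is filled
  states <- character(0); cages <- character(0); lens <- integer(0)
  cur <- "roam"; cur_cage <- NA_character_; total <- 0L
  other_cage <- function(cg) if (cg == "A") "B" else "A"
  while (total < n_frames) {
    if (cur == "approach" && is.na(cur_cage)) {
      cur_cage <- if (stats::runif(1) < config$preference_rho) {
        config$novel_cage
      } else {
        other_cage(config$novel_cage)
      }
    }
    mean_frames <- config$state_dwell_means[[cur]] * fps
    dwell <- 1L + stats::rgeom(1, min(1, 1 / mean_frames))
    dwell <- min(dwell, n_frames - total)
    states <- c(states, cur); cages <- c(cages, cur_cage)
    lens <- c(lens, dwell); total <- total + dwell
    p <- SIM_TRANSITIONS[[cur]]
    nxt <- sample(names(p), 1, prob = p)
    if (!nxt %in% c("approach", "sniff", "rear")) cur_cage <- NA_character_
    if (nxt == "approach") cur_cage <- NA_character_  # new visit, new choice
    cur <- nxt
  }

  n_seg <- length(states)
  snout <- matrix(NA_real_, total, 2)
  axis_u <- matrix(NA_real_, total, 2)  # unit vector snout -> tail
  pos0 <- cumsum(c(1L, lens))[seq_len(n_seg)]

  roam_box <- c(xmin = geom$cage_a_center[1] + r + inter + 2,
                xmax = geom$cage_b_center[1] - r - inter - 2,
                ymin = 4, ymax = geom$arena_h_cm - 4)
  idle_anchor <- c(geom$arena_w_cm / 2, geom$arena_h_cm - 4)

  for (s in seq_len(n_seg)) {
    idx <- pos0[s]:(pos0[s] + lens[s] - 1L)
    m <- lens[s]
    st <- states[s]
    if (st %in% c("approach", "sniff", "rear")) {
      ctr <- if (cages[s] == "A") geom$cage_a_center else geom$cage_b_center
      theta <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(m, 0, 0.02))
      rad <- switch(st,
        sniff = stats::runif(m, r + 0.15 * band, r + 0.85 * band),
        rear = stats::runif(m, max(0.5, 0.2 * r),
                            max(0.6, r - geom$rear_inset_cm - 0.3)),
        approach = stats::runif(m, r + band + 0.2 * (inter - band),
                                r + band + 0.8 * (inter - band)))
      u_out <- cbind(cos(theta), sin(theta))   # away from cage center
      snout[idx, ] <- cbind(ctr[1] + rad * u_out[, 1],
                            ctr[2] + rad * u_out[, 2])
      axis_u[idx, ] <- u_out
    } else {
      anchor <- if (st == "roam") {
        c(stats::runif(1, roam_box["xmin"] + 2, roam_box["xmax"] - 2),
          stats::runif(1, roam_box["ymin"] + 2, roam_box["ymax"] - 2))
      } else {
        idle_anchor + stats::runif(2, -1, 1)
      }
      step_sd <- if (st == "roam") 0.5 else 0.05
      wx <- anchor[1] + cumsum(stats::rnorm(m, 0, step_sd))
      wy <- anchor[2] + cumsum(stats::rnorm(m, 0, step_sd))
      wx <- pmin(pmax(wx, roam_box["xmin"]), roam_box["xmax"])
      wy <- pmin(pmax(wy, roam_box["ymin"]), roam_box["ymax"])
      snout[idx, ] <- cbind(wx, wy)
      phi <- stats::runif(1, 0, 2 * pi)
      axis_u[idx, ] <- matrix(c(cos(phi), sin(phi)), m, 2, byrow = TRUE)
    }
  }

  # full skeleton from the body template, then measurement model
  perp <- cbind(-axis_u[, 2], axis_u[, 1])
  thr <- geom$confidence_threshold
  landmark_names <- names(BODY_TEMPLATE)
  per_lm <- lapply(landmark_names, function(lm) {
    off <- BODY_TEMPLATE[[lm]]
    xy <- snout + off[1] * axis_u + off[2] * perp
    if (config$jitter_sd_cm > 0) {
      xy <- xy + matrix(stats::rnorm(2 * total, 0, config$jitter_sd_cm),
                        total, 2)
    }
    drop <- stats::runif(total) < config$dropout_prob
    lik <- stats::runif(total, thr, 1)
    if (any(drop)) {
      lik[drop] <- stats::runif(sum(drop), 0, thr * 0.999)
      xy[drop, ] <- xy[drop, , drop = FALSE] +
        matrix(stats::rnorm(2 * sum(drop), 0, 10), sum(drop), 2)
    }
    data.frame(frame = 0:(total - 1L), landmark = lm,
               x = xy[, 1] * geom$px_per_cm, y = xy[, 2] * geom$px_per_cm,
               likelihood = lik, stringsAsFactors = FALSE)
  })
  track <- pose_track(do.call(rbind, per_lm), fps = fps,
                      session_id = config$session_id)

  state_f <- rep(states, lens)
  cage_f <- rep(cages, lens)
  class_f <- c(roam = "none", idle = "none", approach = "other",
               sniff = "sniff", rear = "rear")[state_f]
  truth_frames <- data.frame(frame = 0:(total - 1L), state = state_f,
                             cage = cage_f, class = unname(class_f),
                             stringsAsFactors = FALSE)
  per_class <- aggregate(
    list(true_seconds = rep(1 / fps, total)),
    by = list(cage = ifelse(is.na(cage_f), "none", cage_f),
              class = unname(class_f)),
    FUN = sum)

  list(track = track,
       truth = list(frames = truth_frames, per_class = per_class,
                    implied_di = 2 * config$preference_rho - 1,
                    novel_cage = config$novel_cage))
}

#' Simulate continuous novel-object-recognition exploration tables
#'
#' Generates manually-scored-style exploration tables for two groups with a
#' known per-subject, per-trial target discrimination index
#' `clamp(base_di + group_effect * treated + drift * trial + N(0, noise_sd),
#' -1, 1)`, emitted as novel/familiar times with a fixed total exploration
#' per trial so that the DI of each row equals its target exactly.
#'
#' @param n_subjects Subjects per group.
#' @param n_trials Trials per subject (default 11, the continuous
#'   recognition design).
#' @param base_di Baseline DI of the control group (default 0.4, a typical
#'   healthy novelty preference).
#' @param group_effect Additive DI shift of the treated group (default 0).
#' @param drift Per-trial DI slope (default 0).
#' @param noise_sd SD of the per-row Gaussian DI noise (default 0.15).
#' @param total_exploration_s Total exploration seconds per trial
#'   (default 20).
#' @param groups Group labels, control first.
#' @param seed RNG seed.
#' @return Data frame `subject_id`, `group`, `trial`, `time_novel_s`,
#'   `time_familiar_s`, `target_di` (the ground-truth DI of the row).
#' @export
simulate_cnor_tables <- function(n_subjects = 12, n_trials = 11,
                                 base_di = 0.4, group_effect = 0,
                                 drift = 0, noise_sd = 0.15,
                                 total_exploration_s = 20,
                                 groups = c("control", "treated"),
                                 seed = 1) {
  stopifnot(n_subjects >= 1, n_trials >= 1, noise_sd >= 0,
            total_exploration_s > 0, length(groups) == 2)
  set.seed(seed)
  rows <- expand.grid(trial = seq_len(n_trials),
                      subject = seq_len(n_subjects), group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  di <- base_di + group_effect * (rows$group == groups[2]) +
    drift * rows$trial + stats::rnorm(nrow(rows), 0, noise_sd)
  di <- pmin(pmax(di, -1), 1)
  data.frame(
    subject_id = sprintf("%s_%02d", rows$group, rows$subject),
    group = rows$group, trial = rows$trial,
    time_novel_s = total_exploration_s * (1 + di) / 2,
    time_familiar_s = total_exploration_s * (1 - di) / 2,
    target_di = di, stringsAsFactors = FALSE
  )
}

#' Run the full classification pipeline on a pose track
#'
#' Convenience wrapper: gate, classify, smooth, summarize.
#'
#' @param track A [pose_track()].
#' @param geom An [apparatus_geometry()].
#' @param smooth_window Smoothing window in frames (default 5).
#' @param bin_s Time-bin width in seconds for the summary (default 60).
#' @return List `points`, `labels`, `bouts`, `summary`.
#' @export
run_pipeline <- function(track, geom, smooth_window = 5, bin_s = 60) {
  points <- gate_frames(track, geom)
  labels <- smooth_labels(classify_frames(points, geom), smooth_window)
  list(points = points, labels = labels,
       bouts = extract_bouts(labels),
       summary = interaction_times(labels, bin_s = bin_s))
}
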