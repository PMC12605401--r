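# geometry used throughout: cage A center (10,20), B (50,20), radius 5,
# interaction zone 5 cm from the footprint boundary, sniff band 3 cm
test_that("zone rules: sniff band, footprint rearing, 5 cm gate", {
  geom <- default_geom()
  # hand-placed snout positions along the x-axis through cage A's center
  pts <- make_points(
    x = c(10 + 5 + 4.0,   # 4.0 cm outside boundary: zone but past band
          10 + 5 + 1.5,   # 1.5 cm outside: sniff band
          10 + 2.0,       # over the footprint: rear
          10 + 5 + 5.0,   # exactly 5 cm: inclusive boundary of the zone
          10 + 5 + 5.1),  # 5.1 cm: outside
    y = rep(20, 5))
  lab <- classify_frames(pts, geom)
  expect_equal(lab$cage, c("A", "A", "A", "A", NA))
  expect_equal(lab$label, c("other", "sniff", "rear", "other", "none"))
})

test_that("cage context goes to the nearer boundary; ties cannot be in-zone", {
  geom <- default_geom()
  pts <- make_points(x = c(18, 42, 30), y = rep(20, 3))
  # 18: 3 cm from A boundary; 42: 3 cm from B; 30: equidistant (15 cm each)
  lab <- classify_frames(pts, geom)
  expect_equal(lab$cage, c("A", "B", NA))
  # the non-overlap invariant puts the perpendicular bisector outside both
  # interaction zones, so an equidistant frame is never an interaction
  # frame and the tie flag stays FALSE
  expect_equal(lab$label[3], "none")
  expect_false(any(lab$tie))
})

test_that("mid-body fallback infers rearing near the cage, none afar", {
  geom <- default_geom()  # rear_fallback_cm = radius + 2 = 7 > zone radius
  pts <- make_points(x = c(10 + 5 + 1, 10 + 5 + 4), y = c(20, 20),
                     source = "mid_body")
  lab <- classify_frames(pts, geom)
  # with the default fallback (7 cm) every in-zone fallback frame rears
  expect_equal(lab$label, c("rear", "rear"))
  # a tighter fallback distinguishes close (rear) from far (other)
  geom2 <- default_geom(rear_fallback_cm = 2)
  lab2 <- classify_frames(pts, geom2)
  expect_equal(lab2$label, c("rear", "other"))
  # sniffing requires a confidently tracked snout
  expect_false(any(c(lab$label, lab2$label) == "sniff"))
})

test_that("majority smoothing follows the 5-frame moving-average rule", {
  # single discordant frame is voted away (majority 4/5)
  s <- make_series(c("sniff", "sniff", "rear", "sniff", "sniff"))
  expect_equal(smooth_labels(s, 5)$label, rep("sniff", 5))

  # constant series is a fixed point
  s2 <- make_series(rep("rear", 7))
  expect_identical(smooth_labels(s2, 5)$label, rep("rear", 7))

  # hand-enumerated edge behavior with the window shrunk at the ends:
  # [rear rear sniff sniff], window 5 ->
  #   frame0 win(0:2) r2 s1 -> rear
  #   frame1 win(0:3) r2 s2 tie -> previous output = rear
  #   frame2 win(0:4->0:3) tie -> previous output = rear
  #   frame3 win(1:3) r1 s2 -> sniff
  s3 <- make_series(c("rear", "rear", "sniff", "sniff"))
  expect_equal(smooth_labels(s3, 5)$label,
               c("rear", "rear", "rear", "sniff"))

  expect_error(smooth_labels(s, 4), "odd")
  expect_error(smooth_labels(s, 0), "odd")
})

test_that("smoothing never invents a class absent from the window", {
  set.seed(202)
  classes <- c("A:sniff", "A:rear", "B:sniff", "B:other", "none")
  for (rep_i in 1:10) {
    raw <- sample(classes, 60, replace = TRUE)
    cage <- ifelse(raw == "none", NA, substr(raw, 1, 1))
    label <- ifelse(raw == "none", "none", sub("^[AB]:", "", raw))
    s <- make_series(label)
    s$cage <- cage
    sm <- smooth_labels(s, 5)
    joint_in <- ifelse(s$label == "none", "none",
                       paste(s$cage, s$label, sep = ":"))
    joint_out <- ifelse(sm$label == "none", "none",
                        paste(sm$cage, sm$label, sep = ":"))
    for (i in seq_along(joint_out)) {
      win <- joint_in[max(1, i - 2):min(length(joint_in), i + 2)]
      expect_true(joint_out[i] %in% win)
    }
  }
})

test_that("bout extraction merges runs and converts frames to seconds", {
  # 50 consecutive sniff frames at 25 fps form one 2.0 s bout
  s <- make_series(rep("sniff", 50))
  b <- extract_bouts(s, 25)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 2.0)
  expect_equal(b$start_frame, 0)
  expect_equal(b$end_frame, 49)

  # alternating sniff/none over 10 frames: 5 bouts of one frame (0.04 s)
  s2 <- make_series(rep(c("sniff", "none"), 5))
  b2 <- extract_bouts(s2, 25)
  expect_equal(nrow(b2), 5)
  expect_equal(b2$duration_s, rep(0.04, 5))

  # same label at different cages is not merged
  s3 <- make_series(rep("sniff", 6), cage = rep(c("A", "B"), each = 3))
  expect_equal(nrow(extract_bouts(s3, 25)), 2)
})

test_that("per-frame labels partition time; sniff frames are interaction frames", {
  cfg <- sim_config(seed = 9, duration_s = 120, jitter_sd_cm = 0.5,
                    dropout_prob = 0.05)
  sim <- simulate_tcsi_session(cfg)
  res <- run_pipeline(sim$track, cfg$geometry)
  lab <- res$labels
  # exactly one label per retained frame, cage set iff interacting
  expect_equal(nrow(lab), sum(res$points$retained))
  expect_true(all(lab$label %in% c("sniff", "rear", "other", "none")))
  expect_true(all(is.na(lab$cage) == (lab$label == "none")))
  # conservation: class seconds sum to total interaction seconds per cage
  pc <- res$summary$per_cage
  expect_equal(pc$seconds_sniff + pc$seconds_rear + pc$seconds_other,
               pc$seconds_total, tolerance = 1e-12)
})
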