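test_that("interaction times sum qualifying frames at 25 fps", {
  # 250 sniff@A frames -> 10 s
  s <- make_series(rep("sniff", 250))
  summ <- interaction_times(s, fps = 25)
  expect_equal(summ$per_cage$seconds_sniff[summ$per_cage$cage == "A"], 10)

  # mixed classes at one cage: totals conserve
  s2 <- make_series(c(rep("sniff", 250), rep("rear", 125), rep("other", 50)))
  pc <- interaction_times(s2, fps = 25)$per_cage
  a <- pc[pc$cage == "A", ]
  expect_equal(a$seconds_sniff, 10)
  expect_equal(a$seconds_rear, 5)
  expect_equal(a$seconds_other, 2)
  expect_equal(a$seconds_total, 17)

  # no interaction frames -> all zeros
  z <- interaction_times(make_series(rep("none", 10)), fps = 25)
  expect_true(all(z$per_cage$seconds_total == 0))
})

test_that("minute bins are half-open in retained-frame time", {
  # frames 0..1499 are minute 1 (seconds [0, 60)), frame 1500 starts minute 2
  s <- make_series(rep("sniff", 1501))
  pb <- interaction_times(s, fps = 25)$per_bin
  a_sniff <- pb[pb$cage == "A" & pb$label == "sniff", ]
  expect_equal(a_sniff$seconds[a_sniff$bin == 1], 60)
  expect_equal(a_sniff$seconds[a_sniff$bin == 2], 1 / 25)
  expect_equal(a_sniff$cum_seconds[a_sniff$bin == 2], 60 + 1 / 25)
})

test_that("discrimination index formula, bounds, flags", {
  expect_equal(discrimination_index(30, 10), 0.5)
  expect_equal(discrimination_index(7, 7), 0)
  expect_true(is.na(discrimination_index(0, 0)))
  expect_error(discrimination_index(-1, 2), "non-negative")

  # antisymmetry and bounds on random inputs
  set.seed(31)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  expect_equal(discrimination_index(a, b), -discrimination_index(b, a))
  expect_true(all(abs(discrimination_index(a, b)) <= 1))

  fl <- flag_di(c(12, 0, 0, 3), c(0, 12, 0, 1))
  expect_equal(fl$reason, c("saturated_plus1", "saturated_minus1",
                            "zero_total", "none"))
  expect_equal(fl$excluded, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fl$di[1], 1)
  expect_equal(fl$di[4], 0.5)
})

test_that("cumulative DI equals the prefix mean (brute-force oracle)", {
  expect_equal(cumulative_di(c(0.2, 0.4)), c(0.2, 0.3))
  expect_equal(cumulative_di(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(cumulative_di(c(1, -1, 0)), c(1, 0, 0))
  set.seed(99)
  for (i in 1:25) {
    x <- runif(sample(1:30, 1), -1, 1)
    oracle <- vapply(seq_along(x), function(k) mean(x[1:k]), numeric(1))
    # exact up to one ulp at unit magnitude (cumsum vs two-pass mean)
    expect_lte(max(abs(cumulative_di(x) - oracle)), .Machine$double.eps)
  }
  expect_error(cumulative_di(numeric(0)), "empty")
  expect_error(cumulative_di(c(0.2, NA)), "missing")
  expect_error(cumulative_di(c(0.2, 1.4)), "\\[-1, 1\\]")
})

test_that("running DI per minute uses cumulative exploration", {
  # minute 1: N=4 s, F=1 s; minute 2 adds N=2 s, F=3 s (cumulative 6/4)
  lab <- c(rep("sniff", 100), rep("none", 1375), rep("sniff", 25),
           rep("sniff", 50), rep("none", 1350), rep("sniff", 75), "none")
  cage <- c(rep("A", 100), rep(NA, 1375), rep("B", 25),
            rep("A", 50), rep(NA, 1350), rep("B", 75), NA)
  s <- make_series(lab); s$cage <- cage
  summ <- interaction_times(s, fps = 25)
  run <- running_di_per_minute(summ, novel = "A", familiar = "B")
  expect_equal(run$di, c(0.6, 0.2))
  expect_equal(run$novel_s, c(4, 6))
  expect_equal(run$familiar_s, c(1, 4))

  # all exploration on the novel cage saturates at +1 every minute
  s3 <- make_series(rep(c("sniff", "none"), 1500))
  run3 <- running_di_per_minute(interaction_times(s3, fps = 25))
  expect_true(all(run3$di == 1))

  # a minute before any exploration is flagged undefined
  s4 <- make_series(c(rep("none", 1500), rep("sniff", 1500)))
  run4 <- running_di_per_minute(interaction_times(s4, fps = 25))
  expect_true(run4$flagged[1] && is.na(run4$di[1]))
  expect_equal(run4$di[2], 1)
})

test_that("trial-block averages over trials 1-4 and 8-11", {
  dis <- (1:11) / 20
  expect_equal(block_average_di(dis), c(early = 0.125, late = 0.475))
  expect_equal(block_average_di(rep(0.3, 11)), c(early = 0.3, late = 0.3))
  expect_error(block_average_di(dis[1:9]), "at least 11")
  dis_na <- dis; dis_na[2] <- NA
  expect_error(block_average_di(dis_na), "missing")
  # shorter designs work with explicit blocks
  expect_equal(block_average_di(c(0.1, 0.2, 0.5, 0.7),
                                early = 1:2, late = 3:4),
               c(early = 0.15, late = 0.6))
})

test_that("early-window DI applies the saturation exclusion", {
  two_min <- function(nA, nB) {
    # nA/nB seconds of sniffing at each cage inside minutes 1-2
    lab <- c(rep("sniff", nA * 25), rep("sniff", nB * 25))
    cage <- c(rep("A", nA * 25), rep("B", nB * 25))
    pad <- 3000 - length(lab)
    s <- make_series(c(lab, rep("none", pad)))
    s$cage <- c(cage, rep(NA, pad))
    interaction_times(s, fps = 25)
  }
  ok <- early_window_di(two_min(20, 10))
  expect_equal(ok$di, 1 / 3, tolerance = 1e-12)
  expect_false(ok$excluded)

  sat <- early_window_di(two_min(8, 0))
  expect_equal(sat$di, 1)
  expect_true(sat$excluded)
  expect_equal(sat$reason, "saturated_plus1")

  none <- early_window_di(two_min(0, 0))
  expect_equal(none$reason, "zero_total")

  expect_error(early_window_di(interaction_times(make_series(rep("sniff", 100)),
                                                 fps = 25)),
               "early window")
})

test_that("exploration tables are scored per subject with cDI and flags", {
  tab <- data.frame(
    subject_id = rep(c("m1", "m2"), each = 3),
    group = rep(c("control", "treated"), each = 3),
    trial = rep(1:3, 2),
    time_novel_s = c(30, 10, 12, 5, 0, 0),
    time_familiar_s = c(10, 10, 0, 15, 10, 0))
  out <- score_exploration_table(tab)
  m1 <- out[out$subject_id == "m1", ]
  expect_equal(m1$di, c(0.5, 0, 1))
  expect_equal(m1$cdi, cumulative_di(m1$di))
  expect_equal(m1$reason, c("none", "none", "saturated_plus1"))
  m2 <- out[out$subject_id == "m2", ]
  expect_equal(m2$reason, c("none", "saturated_minus1", "zero_total"))
  # undefined DI propagates as missing: cDI over defined trials only,
  # and NA (never imputed) on the undefined trial itself
  expect_equal(m2$cdi[2], mean(c(-0.5, -1)))
  expect_true(is.na(m2$cdi[3]))
})
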