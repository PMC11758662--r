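test_that("duty factor is the propulsion share of the cycle", {
  full <- make_cycle(c(LF = 0, LH = 10, RF = 50, RH = 60),
                     c(LF = 100, LH = 30, RF = 30, RH = 30))
  expect_equal(duty_factor(full, "LF"), 100)

  cyc <- make_cycle(c(LF = 0, LH = 32.2, RF = 50, RH = 84.2),
                    c(LF = 36.9, LH = 33.5, RF = 38.2, RH = 33.0))
  expect_equal(duty_factor(cyc, "LF"), 36.9)

  # 0.875 s propulsion in a 2.5 s cycle -> 35%
  ev <- data.frame(
    limb = c("LF", "LF", "LH", "RF", "RH"),
    phase = "propulsion",
    start_s = c(0, 2.5, 0.4, 1.2, 1.7),
    end_s = c(0.875, 3.375, 1.2, 2.1, 2.4)
  )
  expect_equal(duty_factor(normalize_cycle(ev), "LF"), 35.0)
})

test_that("propulsion delay is the circular forward start-to-start distance", {
  cyc <- make_cycle(c(LF = 0, LH = 13.4, RF = 50.2, RH = 65.0),
                    c(LF = 33.6, LH = 34.3, RF = 34.6, RH = 33.2))
  expect_equal(propulsion_delay(cyc, "LF", "LF"), 0)
  expect_equal(propulsion_delay(cyc, "LF", "LH"), 13.4)
  # RH at 65 wraps around to the next LF start: 100 - 65 = 35
  expect_equal(propulsion_delay(cyc, "RH", "LF"), 35.0)
})

test_that("signed overlap is the circular propulsion intersection, sliding negated", {
  b <- make_cycle(c(LF = 0, LH = 32.2, RF = 50, RH = 84.2),
                  c(LF = 36.9, LH = 33.5, RF = 38.2, RH = 33.0))
  expect_equal(signed_overlap(b, "LF", "LH"), 4.7)
  expect_equal(sliding_phase(b, "LF", "LH"), 0)

  a <- make_cycle(c(LF = 0, LH = 13.4, RF = 50.2, RH = 65.0),
                  c(LF = 33.6, LH = 34.3, RF = 34.6, RH = 33.2))
  # RH (65, 98.2) vs LF (0, 33.6): disjoint, smaller gap 1.8 -> negative
  expect_equal(signed_overlap(a, "LF", "RH"), -1.8, tolerance = 1e-9)
  expect_equal(sliding_phase(a, "LF", "RH"), 1.8, tolerance = 1e-9)
  expect_equal(signed_overlap(a, "RH", "LF"), signed_overlap(a, "LF", "RH"))

  # nesting: one interval strictly inside the other -> shorter duration
  nest <- make_cycle(c(LF = 0, LH = 10, RF = 50, RH = 60),
                     c(LF = 40, LH = 12, RF = 20, RH = 20))
  expect_equal(signed_overlap(nest, "LF", "LH"), 12)
})

test_that("signed overlap matches an independent discretized oracle", {
  set.seed(7)
  for (i in 1:200) {
    cyc <- random_cycle()
    pairs <- list(c("LF", "LH"), c("RF", "RH"), c("LF", "RH"), c("RF", "LH"))
    pr <- pairs[[sample.int(4, 1)]]
    got <- signed_overlap(cyc, pr[1], pr[2])
    want <- oracle_signed_overlap(cyc$propulsion[pr[1], ],
                                  cyc$propulsion[pr[2], ])
    expect_lt(abs(got - want), 0.02)
  }
})

test_that("compute_params reproduces the composite ratios from mean cycles", {
  pa <- compute_params(mean_lap("CatA")$cycles[[1]])
  expect_equal(pa$df_front, 34.1)
  expect_equal(pa$mean_lat_dl, 14.1, tolerance = 1e-9)
  expect_equal(pa$alpha, 14.1 / 34.1, tolerance = 1e-9)

  pb <- compute_params(mean_lap("CatB")$cycles[[1]])
  expect_equal(pb$beta, 16.8 / 33.25, tolerance = 1e-9)

  # zero lateral delays with 50/50 diagonal delays -> alpha = 0
  sync <- make_cycle(c(LF = 0, LH = 0, RF = 50, RH = 50),
                     c(LF = 35, LH = 35, RF = 35, RH = 35))
  ps <- compute_params(sync)
  expect_equal(ps$mean_lat_dl, 0)
  expect_equal(ps$alpha, 0)
  expect_equal(ps$diag_dl_left + ps$diag_dl_right, 100)
})

test_that("delay closure and the overlap identity hold on generated cycles", {
  set.seed(11)
  cfg <- synthetic_config(cycles_per_lap = 1L)
  for (cat in CATEGORY_LEVELS) {
    for (i in 1:10) {
      p <- compute_params(generate_lap(cat, config = cfg)$cycles[[1]])
      closure <- p$lat_dl_left + p$diag_dl_right + p$lat_dl_right + p$diag_dl_left
      expect_equal(closure, 100, tolerance = 1e-9)
      # second limb starts inside the first's propulsion and outlasts it
      if (p$lat_dl_left < p$df_lf &&
          p$lat_dl_left + p$df_lh > p$df_lf) {
        expect_equal(p$lat_ol_left, p$df_lf - p$lat_dl_left, tolerance = 1e-9)
      }
    }
  }
})

test_that("parameters are invariant to uniform time scaling", {
  lap <- mean_lap("CatC")
  ev <- lap_to_events(lap)
  p1 <- compute_params(normalize_cycle(ev))
  ev2 <- ev
  ev2$start_s <- ev$start_s * 3.7
  ev2$end_s <- ev$end_s * 3.7
  p2 <- compute_params(normalize_cycle(ev2))
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-9)
})

test_that("alpha rises when both lateral delays rise at fixed duty factors", {
  alpha_at <- function(lat) {
    dl <- c(lat, 50 - lat, lat, 50 - lat)  # keep closure at 100
    starts <- c(LF = 0, LH = dl[1], RF = dl[1] + dl[2],
                RH = dl[1] + dl[2] + dl[3])
    compute_params(make_cycle(starts, c(LF = 34, LH = 33, RF = 34, RH = 33)))$alpha
  }
  lats <- seq(10, 35, by = 5)
  alphas <- vapply(lats, alpha_at, numeric(1))
  expect_true(all(diff(alphas) > 0))
})

test_that("aggregate_lap averages base parameters and recomputes ratios", {
  one <- mean_lap("CatB")
  expect_equal(unclass(aggregate_lap(one)),
               unclass(compute_params(one$cycles[[1]])), tolerance = 1e-12)

  three <- mean_lap("CatB", n_cycles = 3L)  # identical cycles
  expect_equal(unclass(aggregate_lap(three)),
               unclass(compute_params(three$cycles[[1]])), tolerance = 1e-12)

  c1 <- make_cycle(c(LF = 0, LH = 20, RF = 50, RH = 70),
                   c(LF = 30, LH = 30, RF = 30, RH = 30))
  c2 <- make_cycle(c(LF = 0, LH = 20, RF = 50, RH = 70),
                   c(LF = 40, LH = 30, RF = 30, RH = 30))
  lap <- lap_recording("H01", 1L, "L", list(c1, c2))
  agg <- aggregate_lap(lap)
  expect_equal(agg$df_lf, 35)
  # ratios recomputed from averaged components, not averaged as ratios
  expect_equal(agg$alpha, agg$mean_lat_dl / agg$df_front)

  empty <- lap_recording("H01", 1L, "L", list(), validate = FALSE)
  expect_error(aggregate_lap(empty), "no analyzable cycle")
})

test_that("lap_parameters binds metadata with stable parameter columns", {
  laps <- list(mean_lap("CatA"), mean_lap("CatD", n_cycles = 2L))
  df <- lap_parameters(laps)
  expect_equal(nrow(df), 2L)
  expect_true(all(c("horse_id", "hand", "expert_label", "alpha", "beta",
                    "df_lf", "lat_ol_right", "mean_diag_dl") %in% names(df)))
  expect_equal(df$category_true, c("CatA", "CatD"))
})
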