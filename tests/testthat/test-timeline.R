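test_that("normalize_cycle maps seconds onto percent-of-cycle with LF at 0", {
  ev <- data.frame(
    limb = c("LF", "LF", "LH", "RF", "RH"),
    phase = "propulsion",
    start_s = c(10.0, 12.5, 10.335, 11.2, 11.6),
    end_s = c(10.9, 13.4, 11.2, 12.1, 12.4)
  )
  cyc <- normalize_cycle(ev)
  expect_s3_class(cyc, "swim_cycle")
  expect_equal(cyc$duration_s, 2.5)
  expect_equal(unname(cyc$propulsion["LF", ]), c(0, 36))
  expect_equal(unname(cyc$propulsion["LH", ]), c(13.4, 48))
})

test_that("normalize_cycle handles full-cycle propulsion and wrap-around", {
  # reference propulsion spanning the entire cycle -> (0, 100)
  ev <- data.frame(
    limb = c("LF", "LF", "LH", "RF", "RH"),
    phase = "propulsion",
    start_s = c(0, 2.5, 0.2, 0.9, 1.6),
    end_s = c(2.5, 5.0, 1.0, 1.8, 2.4)
  )
  cyc <- normalize_cycle(ev)
  expect_equal(unname(cyc$propulsion["LF", ]), c(0, 100))

  # RH starting at 2.45 s of a 2.5 s cycle, ending 0.3 s into the next
  ev2 <- data.frame(
    limb = c("LF", "LF", "LH", "RF", "RH"),
    phase = "propulsion",
    start_s = c(0, 2.5, 0.4, 1.2, 2.45),
    end_s = c(0.9, 3.4, 1.2, 2.1, 2.75)
  )
  cyc2 <- normalize_cycle(ev2)
  expect_equal(unname(cyc2$propulsion["RH", ]), c(98, 110))
  # presentation reduces mod 100
  bars <- coordination_diagram(cyc2)
  rh <- bars[bars$limb == "RH", ]
  expect_equal(nrow(rh), 2L)
  expect_equal(rh$start, c(98, 0))
  expect_equal(rh$end, c(100, 10))
})

test_that("normalize_cycle rejects malformed windows with the documented errors", {
  base <- data.frame(
    limb = c("LF", "LF", "LH", "RF", "RH"),
    phase = "propulsion",
    start_s = c(0, 2.5, 0.4, 1.2, 1.7),
    end_s = c(0.9, 3.4, 1.2, 2.1, 2.4)
  )
  expect_error(normalize_cycle(base[base$limb != "RH", ]), "incomplete cycle")
  dup <- rbind(base, data.frame(limb = "LH", phase = "propulsion",
                                start_s = 2.0, end_s = 2.2))
  expect_error(normalize_cycle(dup), "ambiguous cycle")
  expect_error(normalize_cycle(base, cycle_end = 0), "invalid timing")
})

test_that("normalization is shift-invariant and idempotent", {
  ev <- data.frame(
    limb = c("LF", "LF", "LH", "RF", "RH"),
    phase = "propulsion",
    start_s = c(3.0, 5.7, 3.5, 4.3, 5.0),
    end_s = c(4.0, 6.7, 4.4, 5.3, 5.9)
  )
  ref <- normalize_cycle(ev)
  for (shift in c(-3, 0.1, 17, 1234.5)) {
    ev2 <- ev
    ev2$start_s <- ev$start_s + shift
    ev2$end_s <- ev$end_s + shift
    shifted <- normalize_cycle(ev2)
    expect_equal(shifted$propulsion, ref$propulsion)
    expect_equal(shifted$duration_s, ref$duration_s)
  }
  # feeding the percent axis back in as a timeline is the identity
  again <- normalize_cycle(
    data.frame(limb = c(LIMB_LEVELS, "LF"), phase = "propulsion",
               start_s = c(ref$propulsion[, "start"], 100),
               end_s = c(ref$propulsion[, "end"], 120)),
    cycle_end = 100
  )
  expect_equal(again$propulsion, ref$propulsion)
})

test_that("split_lap_into_cycles yields n-1 cycles from n reference starts", {
  lap0 <- mean_lap("CatC", n_cycles = 3L)
  ev <- lap_to_events(lap0)  # carries 4 LF starts (3 cycles + sentinel)
  lap <- split_lap_into_cycles(ev, horse_id = "H01", lap_index = 2L, hand = "R")
  expect_s3_class(lap, "lap_recording")
  expect_length(lap$cycles, 3L)
  # round-trip: parameters of the reassembled lap match the generated lap
  expect_equal(unclass(aggregate_lap(lap)), unclass(aggregate_lap(lap0)),
               tolerance = 1e-8)

  expect_error(
    split_lap_into_cycles(ev[ev$limb != "RF", ]),
    "incomplete cycle"
  )
  one_start <- ev[ev$phase == "propulsion" & ev$start_s < 1, ]
  expect_error(split_lap_into_cycles(one_start), "no analyzable cycle")

  # trailing events beyond the last reference start are dropped with a warning
  trailing <- rbind(ev, data.frame(
    horse_id = lap0$horse_id, lap_index = lap0$lap_index, hand = lap0$hand,
    session_context = lap0$session_context, limb = "LH", phase = "propulsion",
    start_s = max(ev$start_s) + 0.5, end_s = max(ev$start_s) + 0.9
  ))
  expect_warning(res <- split_lap_into_cycles(trailing), "incomplete")
  expect_length(res$cycles, 3L)
})

test_that("validate_lap reports violations without raising", {
  good <- mean_lap("CatA", n_cycles = 2L)
  expect_identical(validate_lap(good), character(0))

  bad <- good
  bad$cycles[[1]]$propulsion["LH", "end"] <- bad$cycles[[1]]$propulsion["LH", "start"]
  diags <- validate_lap(bad)
  expect_true(any(grepl("LH", diags)))

  # overlapping propulsion and return for one limb -> tiling diagnostic
  ev <- lap_to_events(good)
  ridx <- which(ev$limb == "RF" & ev$phase == "return")[1]
  ev$start_s[ridx] <- ev$start_s[ridx] - 0.05
  overlapping <- good
  overlapping$events <- ev
  expect_true(any(grepl("phase tiling violated", validate_lap(overlapping))))

  nolap <- structure(list(hand = "L", cycles = list()),
                     class = "lap_recording")
  expect_true("no analyzable cycle" %in% validate_lap(nolap))
})

test_that("per-limb propulsion and return phases tile the emitted timeline", {
  lap <- mean_lap("CatB", n_cycles = 2L)
  ev <- lap_to_events(lap)
  lap$events <- ev
  expect_identical(validate_lap(lap), character(0))
  for (limb in LIMB_LEVELS) {
    sub <- ev[ev$limb == limb, ]
    sub <- sub[order(sub$start_s), ]
    # consecutive intervals abut exactly and alternate phases
    expect_equal(sub$start_s[-1], sub$end_s[-nrow(sub)], tolerance = 1e-9)
    expect_true(all(sub$phase[-1] != sub$phase[-nrow(sub)]))
    # so propulsion + return durations sum to the covered timeline
    covered <- max(sub$end_s) - min(sub$start_s)
    expect_equal(sum(sub$end_s - sub$start_s), covered, tolerance = 1e-9)
  }
})
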