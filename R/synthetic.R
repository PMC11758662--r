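# Synthetic lap generator. Delays and duty factors are the generative
# primitives: the four propulsion starts are placed cumulatively around the
# cycle (LF at 0, then LH, RF, RH via the lateral/diagonal delays) and bar
# lengths are the duty factors. Overlaps are consequences, never drawn, which
# reproduces the overlap identities observed in the reference profiles.

#' Configuration for the synthetic lap generator
#'
#' @param laps_per_horse Laps per simulated session (default 12: two warm-up
#'   laps followed by five left-hand and five right-hand laps, mirroring a
#'   standard session template).
#' @param cycles_per_lap Candidate numbers of complete cycles per lap; one is
#'   drawn per lap (default 2 or 3).
#' @param cycle_duration_s Range (seconds) from which each lap's cycle
#'   duration is drawn uniformly. Cycle duration cancels in every percent
#'   parameter, so this only shapes the raw timelines.
#' @param jitter_sd Cycle-to-cycle standard deviation (percent of cycle)
#'   added independently to every drawn parameter in each cycle. Real
#'   within-lap variability is not well characterized; the default 1.5 is a
#'   deliberately mild guess.
#' @param label_noise_rate Probability that an emitted expert label disagrees
#'   with the generating category's strategy.
#' @param trunc_bounds Truncation bounds (percent) for all parameter draws;
#'   prevents degenerate propulsion phases.
#' @param seed Integer seed used by [generate_cohort()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(laps_per_horse = 12L, cycles_per_lap = c(2L, 3L),
                             cycle_duration_s = c(2.0, 3.5), jitter_sd = 1.5,
                             label_noise_rate = 0, trunc_bounds = c(5, 95),
                             seed = 1L) {
  stopifnot(laps_per_horse >= 1L,
            all(cycles_per_lap >= 1L),
            length(cycle_duration_s) == 2L, all(cycle_duration_s > 0),
            cycle_duration_s[1L] <= cycle_duration_s[2L],
            jitter_sd >= 0,
            label_noise_rate >= 0, label_noise_rate <= 1,
            length(trunc_bounds) == 2L, trunc_bounds[1L] < trunc_bounds[2L])
  structure(
    list(laps_per_horse = as.integer(laps_per_horse),
         cycles_per_lap = as.integer(cycles_per_lap),
         cycle_duration_s = cycle_duration_s,
         jitter_sd = jitter_sd,
         label_noise_rate = label_noise_rate,
         trunc_bounds = trunc_bounds,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Truncated-normal draw via inverse CDF; exact, no rejection loop. sd = 0
# returns the mean (which must lie inside the bounds).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) {
    if (any(mean <= lo | mean >= hi)) {
      stop("infeasible profile: mean outside truncation bounds with sd = 0")
    }
    return(rep(mean, length.out = n))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (any(phi - plo < 1e-12)) {
    stop("infeasible profile: truncation bounds leave no probability mass")
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Resolve a profile argument: a category code or a two-row (left/right)
# data frame in the category_profiles() layout.
resolve_profile <- function(profile) {
  if (is.character(profile) && length(profile) == 1L) {
    profile <- category_profiles(match.arg(profile, CATEGORY_LEVELS))
  }
  stopifnot(is.data.frame(profile), nrow(profile) == 2L,
            all(c("left", "right") %in% profile$side))
  profile[match(c("left", "right"), profile$side), , drop = FALSE]
}

# Draw the eight generative parameters once: four duty factors and four
# delays, with the delays renormalized to close the cycle exactly. The
# delay order follows the propulsion sequence LF -> LH -> RF -> RH -> LF:
# lat_left, diag_right, lat_right, diag_left.
draw_base_params <- function(prof, bounds) {
  left <- prof[prof$side == "left", ]
  right <- prof[prof$side == "right", ]
  df <- c(
    LF = rtrunc_norm(1, left$df_fore_mean, left$df_fore_sd, bounds[1], bounds[2]),
    LH = rtrunc_norm(1, left$df_hind_mean, left$df_hind_sd, bounds[1], bounds[2]),
    RF = rtrunc_norm(1, right$df_fore_mean, right$df_fore_sd, bounds[1], bounds[2]),
    RH = rtrunc_norm(1, right$df_hind_mean, right$df_hind_sd, bounds[1], bounds[2])
  )
  dl <- c(
    lat_left = rtrunc_norm(1, left$lat_dl_mean, left$lat_dl_sd, bounds[1], bounds[2]),
    diag_right = rtrunc_norm(1, right$diag_dl_mean, right$diag_dl_sd, bounds[1], bounds[2]),
    lat_right = rtrunc_norm(1, right$lat_dl_mean, right$lat_dl_sd, bounds[1], bounds[2]),
    diag_left = rtrunc_norm(1, left$diag_dl_mean, left$diag_dl_sd, bounds[1], bounds[2])
  )
  dl <- dl / sum(dl) * 100  # close the cycle exactly
  list(df = df, delays = dl)
}

# Build a swim_cycle from duty factors and sequence-ordered delays.
cycle_from_params <- function(df, delays, duration_s) {
  starts <- c(LF = 0,
              LH = delays[["lat_left"]],
              RF = delays[["lat_left"]] + delays[["diag_right"]],
              RH = delays[["lat_left"]] + delays[["diag_right"]] +
                delays[["lat_right"]])
  mat <- cbind(start = starts[LIMB_LEVELS],
               end = starts[LIMB_LEVELS] + df[LIMB_LEVELS])
  rownames(mat) <- LIMB_LEVELS
  swim_cycle(duration_s, mat)
}

#' Generate one synthetic lap
#'
#' Draws the four duty factors and the four sequence delays from truncated
#' normal distributions around a category profile, renormalizes the delays to
#' close the cycle exactly, and emits `cycles_per_lap` cycles with
#' independent cycle-to-cycle jitter. The lap carries its generating category
#' in `$category_true` and an expert label equal to the category's strategy,
#' flipped with probability `label_noise_rate`.
#'
#' @param profile A category code (`"CatA"`--`"CatD"`, resolved via
#'   [category_profiles()]) or a two-row left/right profile data frame in the
#'   same layout.
#' @param hand Swimming direction of the lap, `"L"` or `"R"`.
#' @param config A [synthetic_config()].
#' @param horse_id,lap_index,session_context Lap metadata.
#' @param seed Optional seed; if given, the draw is reproducible on its own.
#'   Leave `NULL` when calling from [generate_cohort()], which manages the
#'   random stream.
#' @return A [lap_recording()] with extra fields `category_true` and
#'   `drawn_params` (the pre-jitter duty factors and delays).
#' @export
generate_lap <- function(profile, hand = "L", config = synthetic_config(),
                         horse_id = "SIM01", lap_index = 1L,
                         session_context = "regular", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prof <- resolve_profile(profile)
  category <- prof$category[1L]
  bounds <- config$trunc_bounds
  base <- draw_base_params(prof, bounds)
  n_cycles <- if (length(config$cycles_per_lap) > 1L) {
    sample(config$cycles_per_lap, 1L)
  } else {
    config$cycles_per_lap
  }
  duration_s <- stats::runif(1, config$cycle_duration_s[1L],
                             config$cycle_duration_s[2L])
  cycles <- lapply(seq_len(n_cycles), function(i) {
    if (config$jitter_sd > 0) {
      df_i <- pmin(pmax(base$df + stats::rnorm(4, 0, config$jitter_sd),
                        bounds[1L]), bounds[2L])
      dl_i <- pmin(pmax(base$delays + stats::rnorm(4, 0, config$jitter_sd),
                        bounds[1L]), bounds[2L])
      dl_i <- dl_i / sum(dl_i) * 100
      names(df_i) <- names(base$df)
      names(dl_i) <- names(base$delays)
    } else {
      df_i <- base$df
      dl_i <- base$delays
    }
    cycle_from_params(df_i, dl_i, duration_s)
  })
  strategy <- as.character(category_to_strategy(category))
  if (config$label_noise_rate > 0 &&
      stats::runif(1) < config$label_noise_rate) {
    strategy <- sample(setdiff(STRATEGY_LEVELS, strategy), 1L)
  }
  lap <- lap_recording(horse_id, lap_index, hand, cycles,
                       session_context = session_context,
                       expert_label = strategy)
  lap$category_true <- category
  lap$drawn_params <- base
  lap
}

#' Generate a synthetic cohort of laps
#'
#' Simulates one session per horse following the standard template: two
#' warm-up laps (one per hand), then the remaining laps split into a
#' left-hand block and a right-hand block, each starting with an
#' `"after_break"` lap (the pool blocks are separated by treadmill breaks).
#' Each lap's generating category is drawn from the horse's category mixture.
#'
#' @param mixtures Data frame with columns `horse_id`, `CatA`, `CatB`,
#'   `CatC`, `CatD`; each row's proportions must sum to 1. Optionally a
#'   `hand` column ("L"/"R") for hand-dependent mixtures (two rows per
#'   horse).
#' @param config A [synthetic_config()]; `config$seed` seeds the whole
#'   cohort.
#' @param profiles Profile table in the [category_profiles()] layout.
#' @return List of [lap_recording()] objects.
#' @export
generate_cohort <- function(mixtures, config = synthetic_config(),
                            profiles = category_profiles()) {
  stopifnot(is.data.frame(mixtures),
            all(c("horse_id", CATEGORY_LEVELS) %in% names(mixtures)))
  prop_mat <- as.matrix(mixtures[, CATEGORY_LEVELS])
  if (any(prop_mat < 0) || any(abs(rowSums(prop_mat) - 1) > 1e-6)) {
    stop("invalid mixture: category proportions must be >= 0 and sum to 1")
  }
  by_hand <- "hand" %in% names(mixtures)
  set.seed(config$seed)
  laps <- list()
  horse_ids <- unique(mixtures$horse_id)
  for (h in horse_ids) {
    n_laps <- config$laps_per_horse
    plan <- session_plan(n_laps)
    for (i in seq_len(n_laps)) {
      row <- if (by_hand) {
        which(mixtures$horse_id == h & mixtures$hand == plan$hand[i])
      } else {
        which(mixtures$horse_id == h)
      }
      if (length(row) != 1L) {
        stop("invalid mixture: expected exactly one mixture row for horse ",
             h, if (by_hand) paste0(" and hand ", plan$hand[i]))
      }
      category <- sample(CATEGORY_LEVELS, 1L, prob = prop_mat[row, ])
      prof <- profiles[profiles$category == category, , drop = FALSE]
      laps[[length(laps) + 1L]] <- generate_lap(
        prof, hand = plan$hand[i], config = config, horse_id = h,
        lap_index = i, session_context = plan$context[i]
      )
    }
  }
  laps
}

# Session template: two warm-up laps (L then R), then a left block and a
# right block, each opening with an after_break lap.
session_plan <- function(n_laps) {
  if (n_laps == 1L) {
    return(list(hand = "L", context = "regular"))
  }
  n_rest <- n_laps - 2L
  n_left <- ceiling(n_rest / 2)
  hand <- c("L", "R", rep("L", n_left), rep("R", n_rest - n_left))
  context <- c("warmup", "warmup", rep("regular", n_rest))
  if (n_left >= 1L) context[3L] <- "after_break"
  if (n_rest - n_left >= 1L) context[3L + n_left] <- "after_break"
  list(hand = hand, context = context)
}

#' Convert a lap recording back to an event table in seconds
#'
#' Lays the lap's cycles out consecutively on a seconds timeline and emits
#' one row per phase interval: every propulsion interval, the return
#' intervals that are fully determined (i.e. whose closing propulsion start
#' is within the lap), and a final sentinel propulsion start of the reference
#' limb that closes the last cycle, so that
#' [split_lap_into_cycles()] round-trips the lap.
#'
#' @param lap A [lap_recording()].
#' @return Data frame with columns `horse_id`, `lap_index`, `hand`,
#'   `session_context`, `limb`, `phase`, `start_s`, `end_s`.
#' @export
lap_to_events <- function(lap) {
  stopifnot(inherits(lap, "lap_recording"))
  n <- length(lap$cycles)
  durs <- vapply(lap$cycles, function(cy) cy$duration_s, numeric(1))
  offsets <- cumsum(c(0, durs))[seq_len(n)]
  prop <- do.call(rbind, lapply(seq_len(n), function(k) {
    cy <- lap$cycles[[k]]
    data.frame(
      limb = LIMB_LEVELS,
      start_s = offsets[k] + cy$propulsion[LIMB_LEVELS, 1L] / 100 * durs[k],
      end_s = offsets[k] + cy$propulsion[LIMB_LEVELS, 2L] / 100 * durs[k],
      stringsAsFactors = FALSE
    )
  }))
  # sentinel: reference-limb propulsion start opening the (n+1)-th cycle
  ref <- lap$cycles[[n]]$reference_limb %||% "LF"
  last_end <- offsets[n] + durs[n]
  ref_dur <- (lap$cycles[[n]]$propulsion[ref, 2L] -
                lap$cycles[[n]]$propulsion[ref, 1L]) / 100 * durs[n]
  prop <- rbind(prop, data.frame(limb = ref, start_s = last_end,
                                 end_s = last_end + ref_dur))
  prop$phase <- "propulsion"

  # return intervals: from each propulsion end to the same limb's next start
  prop_sorted <- prop[order(prop$limb, prop$start_s), , drop = FALSE]
  ret <- do.call(rbind, lapply(split(prop_sorted, prop_sorted$limb), function(s) {
    if (nrow(s) < 2L) return(NULL)
    starts <- s$end_s[-nrow(s)]
    ends <- s$start_s[-1L]
    keep <- ends > starts + 1e-9
    if (!any(keep)) return(NULL)
    data.frame(limb = s$limb[1L], start_s = starts[keep], end_s = ends[keep],
               phase = "return", stringsAsFactors = FALSE)
  }))
  ev <- rbind(prop, ret)
  ev <- ev[order(ev$start_s, ev$limb), , drop = FALSE]
  out <- data.frame(
    horse_id = lap$horse_id, lap_index = lap$lap_index, hand = lap$hand,
    session_context = lap$session_context, limb = ev$limb, phase = ev$phase,
    start_s = ev$start_s, end_s = ev$end_s, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Equal-mixture helper
#'
#' Convenience constructor for [generate_cohort()] mixtures: every horse gets
#' the same category proportions (uniform by default).
#'
#' @param horse_ids Character vector of horse identifiers.
#' @param proportions Named numeric vector of category proportions summing
#'   to 1.
#' @export
equal_mixtures <- function(horse_ids,
                           proportions = c(CatA = 0.25, CatB = 0.25,
                                           CatC = 0.25, CatD = 0.25)) {
  stopifnot(all(CATEGORY_LEVELS %in% names(proportions)))
  out <- data.frame(horse_id = horse_ids, stringsAsFactors = FALSE)
  for (cat in CATEGORY_LEVELS) out[[cat]] <- unname(proportions[cat])
  out
}
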