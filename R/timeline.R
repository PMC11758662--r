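# Domain objects for the timeline model: phase intervals in seconds,
# swimming cycles on a circular percent-of-cycle axis, and lap recordings.
#
# Conventions: the cycle axis is [0, 100) percent with the reference limb's
# (default LF) propulsion start at exactly 0. Propulsion intervals are stored
# as (start, end) with start in [0, 100) and end = start + duration; an
# interval crossing the cycle boundary keeps end > 100 internally and is
# reduced mod 100 only for presentation.

VIDEO_FPS <- 120  # source videos run at 120 frames per second

#' Construct a swimming cycle
#'
#' A swimming cycle holds each limb's single propulsion interval on the
#' circular percent-of-cycle axis, with the reference limb's propulsion start
#' at 0\%. The return phase is the complement of the propulsion phase, so it
#' is not stored.
#'
#' @param duration_s Cycle duration in seconds (time between consecutive
#'   reference-limb propulsion starts).
#' @param propulsion A 4 x 2 numeric matrix with rownames `LF`, `LH`, `RF`,
#'   `RH` and columns `start`, `end` in percent of cycle. `end` may exceed
#'   100 for intervals wrapping the cycle boundary.
#' @param reference_limb Limb anchored at 0\%.
#' @param validate If `FALSE`, skip invariant checks (used when assembling
#'   deliberately malformed objects for diagnostics).
#' @return An object of class `swim_cycle`.
#' @export
swim_cycle <- function(duration_s, propulsion, reference_limb = "LF",
                       validate = TRUE) {
  x <- structure(
    list(duration_s = duration_s, propulsion = propulsion,
         reference_limb = reference_limb),
    class = "swim_cycle"
  )
  if (validate) {
    bad <- validate_cycle(x)
    if (length(bad)) stop("invalid swim_cycle: ", paste(bad, collapse = "; "))
  }
  x
}

# Invariant checks shared by the constructor and validate_lap(); returns a
# character vector of diagnostics, empty when the cycle is well formed.
validate_cycle <- function(cycle) {
  out <- character()
  p <- cycle$propulsion
  if (!is.matrix(p) || !is.numeric(p) ||
      !identical(sort(rownames(p)), sort(LIMB_LEVELS)) || ncol(p) != 2L) {
    return("propulsion must be a numeric 4 x 2 matrix with limb rownames")
  }
  if (!is.numeric(cycle$duration_s) || length(cycle$duration_s) != 1L ||
      !is.finite(cycle$duration_s) || cycle$duration_s <= 0) {
    out <- c(out, "invalid timing: cycle duration must be a positive number")
  }
  for (limb in LIMB_LEVELS) {
    s <- p[limb, 1L]; e <- p[limb, 2L]
    if (!is.finite(s) || !is.finite(e)) {
      out <- c(out, paste0(limb, ": non-finite propulsion interval"))
      next
    }
    dur <- e - s
    if (dur <= 0) out <- c(out, paste0(limb, ": propulsion duration must be positive"))
    if (dur > 100) out <- c(out, paste0(limb, ": propulsion duration exceeds the cycle"))
    if (s < 0 || s >= 100) out <- c(out, paste0(limb, ": propulsion start outside [0,100)"))
  }
  ref <- cycle$reference_limb
  if (ref %in% rownames(p) && is.finite(p[ref, 1L]) && p[ref, 1L] != 0) {
    out <- c(out, paste0("reference limb ", ref, " propulsion start must be 0"))
  }
  out
}

#' @export
print.swim_cycle <- function(x, ...) {
  cat("<swim_cycle>  Tcycle =", format(x$duration_s, digits = 4), "s\n")
  p <- x$propulsion[LIMB_LEVELS, , drop = FALSE]
  disp <- cbind(start = round(p[, 1L], 1),
                end = round(p[, 2L] %% 100, 1),
                duty = round(p[, 2L] - p[, 1L], 1))
  print(disp)
  invisible(x)
}

#' Normalize raw phase intervals into a percent-of-cycle swimming cycle
#'
#' Maps one cycle's propulsion events (in seconds) onto the circular
#' percent-of-cycle axis. The cycle runs from the reference limb's first
#' propulsion start to its next propulsion start; every limb must begin
#' exactly one propulsion inside that window. Intervals running past the
#' cycle boundary wrap (end percent > 100).
#'
#' @param events Data frame of phase intervals with columns `limb`, `phase`,
#'   `start_s`, `end_s`. Rows with `phase != "propulsion"` are ignored.
#' @param reference_limb Limb whose propulsion start defines 0\% (default
#'   `"LF"`).
#' @param cycle_end Optional explicit cycle end time in seconds. If missing,
#'   the reference limb's second propulsion start in `events` is used.
#' @return A [swim_cycle()].
#' @export
#' @examples
#' ev <- data.frame(
#'   limb = c("LF", "LF", "LH", "RF", "RH"),
#'   phase = "propulsion",
#'   start_s = c(10, 12.5, 10.335, 11.2, 11.6),
#'   end_s = c(10.9, 13.4, 11.2, 12.1, 12.4)
#' )
#' normalize_cycle(ev)
normalize_cycle <- function(events, reference_limb = "LF", cycle_end = NULL) {
  stopifnot(is.data.frame(events),
            all(c("limb", "phase", "start_s", "end_s") %in% names(events)))
  prop <- events[events$phase == "propulsion", , drop = FALSE]
  ref_starts <- sort(prop$start_s[prop$limb == reference_limb])
  if (length(ref_starts) == 0L) {
    stop("incomplete cycle: no propulsion event for reference limb ",
         reference_limb)
  }
  t0 <- ref_starts[1L]
  t_end <- if (!is.null(cycle_end)) {
    cycle_end
  } else if (length(ref_starts) >= 2L) {
    ref_starts[2L]
  } else {
    stop("invalid timing: cycle end undetermined (need a second ",
         reference_limb, " propulsion start or an explicit cycle_end)")
  }
  tcycle <- t_end - t0
  if (!is.finite(tcycle) || tcycle <= 0) {
    stop("invalid timing: non-positive cycle duration")
  }

  mat <- matrix(NA_real_, nrow = 4L, ncol = 2L,
                dimnames = list(LIMB_LEVELS, c("start", "end")))
  for (limb in LIMB_LEVELS) {
    sel <- prop$limb == limb & prop$start_s >= t0 & prop$start_s < t_end
    if (sum(sel) == 0L) stop("incomplete cycle: missing limb ", limb)
    if (sum(sel) > 1L) {
      stop("ambiguous cycle: multiple ", limb, " propulsion starts in window")
    }
    s_pct <- (prop$start_s[sel] - t0) / tcycle * 100
    dur_pct <- (prop$end_s[sel] - prop$start_s[sel]) / tcycle * 100
    mat[limb, ] <- c(s_pct, s_pct + dur_pct)
  }
  # anchor the reference start at exactly 0 (kill float residue)
  if (abs(mat[reference_limb, 1L]) < 1e-9) {
    mat[reference_limb, 2L] <- mat[reference_limb, 2L] - mat[reference_limb, 1L]
    mat[reference_limb, 1L] <- 0
  }
  swim_cycle(tcycle, mat, reference_limb = reference_limb)
}

#' Construct a lap recording
#'
#' A lap is one traversal of the pool, holding the ordered complete swimming
#' cycles observed in it (typically two or three) plus metadata and an
#' optional expert strategy label.
#'
#' @param horse_id Horse identifier.
#' @param lap_index Lap number within the session (>= 1).
#' @param hand Swimming direction, `"L"` or `"R"`.
#' @param cycles List of [swim_cycle()] objects.
#' @param session_context Optional `"warmup"`, `"regular"` or `"after_break"`.
#' @param expert_label Optional expert strategy label (`"S1"`, `"S2"`, `"S3"`).
#' @param validate If `FALSE`, skip invariant checks.
#' @return An object of class `lap_recording`.
#' @export
lap_recording <- function(horse_id, lap_index, hand, cycles,
                          session_context = NA_character_,
                          expert_label = NA_character_, validate = TRUE) {
  x <- structure(
    list(horse_id = as.character(horse_id),
         lap_index = as.integer(lap_index),
         hand = as.character(hand),
         session_context = session_context,
         cycles = cycles,
         expert_label = expert_label),
    class = "lap_recording"
  )
  if (validate) {
    if (length(cycles) < 1L) stop("no analyzable cycle: lap has no cycles")
    if (!x$hand %in% c("L", "R")) stop("hand must be 'L' or 'R'")
    if (!is.na(expert_label) && !expert_label %in% STRATEGY_LEVELS) {
      stop("expert_label must be one of ", paste(STRATEGY_LEVELS, collapse = ", "))
    }
  }
  x
}

#' @export
print.lap_recording <- function(x, ...) {
  cat(sprintf("<lap_recording> horse %s, lap %d, hand %s, %d cycle(s)%s\n",
              x$horse_id, x$lap_index, x$hand, length(x$cycles),
              if (!is.na(x$expert_label)) paste0(", expert ", x$expert_label) else ""))
  invisible(x)
}

#' Split a lap's event stream into complete swimming cycles
#'
#' Segments a sorted per-limb event stream (seconds) at the reference limb's
#' successive propulsion starts: n starts yield n - 1 complete cycles. Any
#' trailing events after the last reference start form an incomplete cycle
#' and are dropped with a warning.
#'
#' @inheritParams normalize_cycle
#' @param horse_id,lap_index,hand,session_context,expert_label Lap metadata,
#'   see [lap_recording()].
#' @return A [lap_recording()].
#' @export
split_lap_into_cycles <- function(events, horse_id = "H?", lap_index = 1L,
                                  hand = "L", session_context = NA_character_,
                                  expert_label = NA_character_,
                                  reference_limb = "LF") {
  stopifnot(is.data.frame(events),
            all(c("limb", "phase", "start_s", "end_s") %in% names(events)))
  prop <- events[events$phase == "propulsion", , drop = FALSE]
  ref_starts <- sort(prop$start_s[prop$limb == reference_limb])
  if (length(ref_starts) < 2L) {
    stop("no analyzable cycle: need at least two ", reference_limb,
         " propulsion starts")
  }
  n_cycles <- length(ref_starts) - 1L
  cycles <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    win <- prop[prop$start_s >= ref_starts[k] - 1e-9, , drop = FALSE]
    cycles[[k]] <- normalize_cycle(win, reference_limb = reference_limb,
                                   cycle_end = ref_starts[k + 1L])
  }
  trailing <- prop$limb != reference_limb & prop$start_s >= ref_starts[n_cycles + 1L]
  if (any(trailing)) {
    warning("dropping trailing incomplete cycle (",
            sum(trailing), " propulsion event(s) after the last ",
            reference_limb, " start)")
  }
  lap <- lap_recording(horse_id, lap_index, hand, cycles,
                       session_context = session_context,
                       expert_label = expert_label)
  lap$events <- events
  lap
}

#' Validate a lap recording
#'
#' Checks the type invariants of a lap and its cycles and returns one
#' diagnostic message per violation. Unlike the constructors this never
#' raises, so it can triage arbitrarily malformed objects.
#'
#' @param lap A [lap_recording()] (possibly built with `validate = FALSE`).
#' @return Character vector of diagnostics; empty if the lap is well formed.
#' @export
validate_lap <- function(lap) {
  out <- character()
  if (!inherits(lap, "lap_recording")) {
    return("not a lap_recording object")
  }
  if (is.null(lap$cycles) || length(lap$cycles) < 1L) {
    out <- c(out, "no analyzable cycle")
  }
  if (!isTRUE(lap$hand %in% c("L", "R"))) {
    out <- c(out, "hand must be 'L' or 'R'")
  }
  for (k in seq_along(lap$cycles)) {
    cyc <- lap$cycles[[k]]
    if (!inherits(cyc, "swim_cycle")) {
      out <- c(out, paste0("cycle ", k, ": not a swim_cycle"))
      next
    }
    bad <- validate_cycle(cyc)
    if (length(bad)) out <- c(out, paste0("cycle ", k, ": ", bad))
  }
  # phase tiling: when raw events are attached, each limb's propulsion and
  # return intervals must alternate and tile the timeline without overlap
  if (!is.null(lap$events)) {
    ev <- lap$events
    for (limb in intersect(unique(ev$limb), LIMB_LEVELS)) {
      sub <- ev[ev$limb == limb, , drop = FALSE]
      sub <- sub[order(sub$start_s), , drop = FALSE]
      if (nrow(sub) < 2L) next
      gaps <- sub$start_s[-1L] - sub$end_s[-nrow(sub)]
      if (any(abs(gaps) > 1e-6)) {
        out <- c(out, paste0("phase tiling violated for limb ", limb))
      }
      if (any(sub$phase[-1L] == sub$phase[-nrow(sub)])) {
        out <- c(out, paste0("phases do not alternate for limb ", limb))
      }
    }
  }
  out
}

#' Coordination diagram of a swimming cycle
#'
#' Returns the rendering-ready propulsion bars of a cycle: one row per limb in
#' canonical order, with wrap-around bars split at the cycle boundary.
#'
#' @param cycle A [swim_cycle()].
#' @return Data frame with columns `limb`, `segment`, `start`, `end` (percent
#'   of cycle, all within [0, 100]).
#' @seealso [plot_coordination()]
#' @export
coordination_diagram <- function(cycle) {
  stopifnot(inherits(cycle, "swim_cycle"))
  rows <- lapply(LIMB_LEVELS, function(limb) {
    s <- cycle$propulsion[limb, 1L]
    e <- cycle$propulsion[limb, 2L]
    if (e <= 100) {
      data.frame(limb = limb, segment = 1L, start = s, end = e)
    } else {
      data.frame(limb = c(limb, limb), segment = c(1L, 2L),
                 start = c(s, 0), end = c(100, e - 100))
    }
  })
  out <- do.call(rbind, rows)
  out$limb <- factor(out$limb, levels = LIMB_LEVELS)
  out
}

# Convert a frame count at the source video rate into seconds.
frames_to_seconds <- function(frames, fps = VIDEO_FPS) frames / fps
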