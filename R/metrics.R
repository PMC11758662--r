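# Quantitative coordination parameters computed on the circular cycle axis:
# duty factors, propulsion-start delays, signed overlaps (sliding coded as
# negative overlap), and the composite lateral/diagonal ratios alpha and beta.

#' Duty factor of a limb
#'
#' Propulsion duration as a percentage of the cycle duration.
#'
#' @param cycle A [swim_cycle()].
#' @param limb One of `"LF"`, `"LH"`, `"RF"`, `"RH"`.
#' @return Duty factor in percent of cycle, in (0, 100].
#' @export
duty_factor <- function(cycle, limb) {
  stopifnot(inherits(cycle, "swim_cycle"))
  limb <- match.arg(limb, LIMB_LEVELS)
  unname(cycle$propulsion[limb, 2L] - cycle$propulsion[limb, 1L])
}

#' Delay between two limbs' propulsion starts
#'
#' Circular forward distance (percent of cycle) from `from_limb`'s propulsion
#' start to `to_limb`'s propulsion start, in [0, 100).
#'
#' @inheritParams duty_factor
#' @param from_limb,to_limb Limb codes.
#' @export
propulsion_delay <- function(cycle, from_limb, to_limb) {
  stopifnot(inherits(cycle, "swim_cycle"))
  from_limb <- match.arg(from_limb, LIMB_LEVELS)
  to_limb <- match.arg(to_limb, LIMB_LEVELS)
  unname((cycle$propulsion[to_limb, 1L] - cycle$propulsion[from_limb, 1L]) %% 100)
}

#' Signed overlap between two limbs' propulsion phases
#'
#' Percentage of the cycle during which both limbs are simultaneously in
#' propulsion. When the two propulsion intervals are disjoint on the circle,
#' the limbs are in a sliding phase instead and the value returned is minus
#' the smaller of the two circular gaps separating the intervals, so sliding
#' is encoded as negative overlap.
#'
#' @inheritParams duty_factor
#' @param limb_a,limb_b Limb codes.
#' @return Signed overlap in percent of cycle.
#' @seealso [sliding_phase()]
#' @export
signed_overlap <- function(cycle, limb_a, limb_b) {
  stopifnot(inherits(cycle, "swim_cycle"))
  limb_a <- match.arg(limb_a, LIMB_LEVELS)
  limb_b <- match.arg(limb_b, LIMB_LEVELS)
  a <- cycle$propulsion[limb_a, ]
  b <- cycle$propulsion[limb_b, ]
  circular_signed_overlap(a[1L], a[2L], b[1L], b[2L])
}

# Exact signed overlap of two arcs (s, e) on a circle of circumference 100,
# with s in [0, 100) and e - s in (0, 100]. Arc lengths <= 100, so the linear
# intersection at shifts -100/0/+100 covers every circular intersection.
circular_signed_overlap <- function(a1, a2, b1, b2) {
  seg <- function(x1, x2, y1, y2) max(0, min(x2, y2) - max(x1, y1))
  ov <- seg(a1, a2, b1, b2) +
    seg(a1, a2, b1 - 100, b2 - 100) +
    seg(a1, a2, b1 + 100, b2 + 100)
  ov <- min(ov, a2 - a1, b2 - b1)
  if (ov > 0) return(ov)
  g1 <- (b1 - a2) %% 100  # gap from end of A forward to start of B
  g2 <- (a1 - b2) %% 100  # gap from end of B forward to start of A
  -min(g1, g2)
}

#' Sliding phase between two limbs
#'
#' Presentation helper: the positive sliding duration, i.e. `max(0,
#' -signed_overlap(...))`.
#'
#' @inheritParams signed_overlap
#' @export
sliding_phase <- function(cycle, limb_a, limb_b) {
  max(0, -signed_overlap(cycle, limb_a, limb_b))
}

# Canonical pairings used throughout: lateral delay runs fore -> ipsilateral
# hind, diagonal delay runs hind -> diagonal fore (wrapping across the cycle
# boundary for RH -> LF), contralateral delays run left -> right. These are
# the unique directions under which the reference tables satisfy both the
# delay-closure identity and the overlap identity.

#' Compute the full coordination parameter vector of a cycle
#'
#' Calculates all per-cycle quantitative parameters: the four duty factors
#' and their fore/hind means, the six propulsion-start delays (lateral,
#' diagonal, contralateral), the four signed overlaps, the mean lateral and
#' diagonal delays, and the composite ratios
#' \deqn{\alpha = MeanLatDL / DF_{front}, \qquad \beta = MeanDiagDL / DF_{hind}.}
#' Small alpha means ipsilateral fore-hind synchronization (lateral two-beat
#' swimming); small beta means diagonal synchronization.
#'
#' @param cycle A [swim_cycle()].
#' @return An object of class `coordination_params`: a named list of percent
#'   parameters plus the dimensionless `alpha` and `beta`.
#' @export
compute_params <- function(cycle) {
  stopifnot(inherits(cycle, "swim_cycle"))
  df <- vapply(LIMB_LEVELS, function(l) duty_factor(cycle, l), numeric(1))
  p <- list(
    df_lf = df[["LF"]], df_rf = df[["RF"]],
    df_lh = df[["LH"]], df_rh = df[["RH"]],
    lat_dl_left   = propulsion_delay(cycle, "LF", "LH"),
    lat_dl_right  = propulsion_delay(cycle, "RF", "RH"),
    diag_dl_left  = propulsion_delay(cycle, "RH", "LF"),
    diag_dl_right = propulsion_delay(cycle, "LH", "RF"),
    colat_dl_fore = propulsion_delay(cycle, "LF", "RF"),
    colat_dl_hind = propulsion_delay(cycle, "LH", "RH"),
    lat_ol_left   = signed_overlap(cycle, "LF", "LH"),
    lat_ol_right  = signed_overlap(cycle, "RF", "RH"),
    diag_ol_left  = signed_overlap(cycle, "LF", "RH"),
    diag_ol_right = signed_overlap(cycle, "RF", "LH")
  )
  finalize_params(p)
}

# Fill in the derived fields (pair means and ratios) from the base fields.
finalize_params <- function(p) {
  p$df_front <- (p$df_lf + p$df_rf) / 2
  p$df_hind <- (p$df_lh + p$df_rh) / 2
  p$mean_lat_dl <- (p$lat_dl_left + p$lat_dl_right) / 2
  p$mean_diag_dl <- (p$diag_dl_left + p$diag_dl_right) / 2
  p$alpha <- p$mean_lat_dl / p$df_front
  p$beta <- p$mean_diag_dl / p$df_hind
  structure(p[param_field_order()], class = "coordination_params")
}

param_field_order <- function() {
  c("df_lf", "df_rf", "df_lh", "df_rh", "df_front", "df_hind",
    "lat_dl_left", "lat_dl_right", "diag_dl_left", "diag_dl_right",
    "colat_dl_fore", "colat_dl_hind",
    "lat_ol_left", "lat_ol_right", "diag_ol_left", "diag_ol_right",
    "mean_lat_dl", "mean_diag_dl", "alpha", "beta")
}

# Base (non-derived) fields averaged by aggregate_lap().
param_base_fields <- function() {
  c("df_lf", "df_rf", "df_lh", "df_rh",
    "lat_dl_left", "lat_dl_right", "diag_dl_left", "diag_dl_right",
    "colat_dl_fore", "colat_dl_hind",
    "lat_ol_left", "lat_ol_right", "diag_ol_left", "diag_ol_right")
}

#' @export
print.coordination_params <- function(x, ...) {
  cat("<coordination_params>\n")
  v <- unlist(x)
  print(round(v, 3))
  invisible(x)
}

#' @export
as.data.frame.coordination_params <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Aggregate a lap's cycles into one parameter vector
#'
#' Averages every base parameter (duty factors, delays, overlaps)
#' arithmetically over the lap's cycles, then recomputes the pair means and
#' the ratios alpha and beta from the averaged components — ratios are never
#' averaged as ratios, avoiding the mean-of-ratios ambiguity.
#'
#' @param lap A [lap_recording()].
#' @return A `coordination_params` object for the lap.
#' @export
aggregate_lap <- function(lap) {
  stopifnot(inherits(lap, "lap_recording"))
  if (length(lap$cycles) < 1L) stop("no analyzable cycle")
  per_cycle <- lapply(lap$cycles, compute_params)
  base <- param_base_fields()
  avg <- lapply(base, function(f) {
    mean(vapply(per_cycle, function(p) p[[f]], numeric(1)))
  })
  names(avg) <- base
  finalize_params(avg)
}

#' Per-lap parameter table for a cohort
#'
#' Applies [aggregate_lap()] to every lap and binds the results with lap
#' metadata into one data frame (one row per lap), the interchange format
#' consumed by the classifier and the evaluation functions. Column names are
#' stable: the metadata columns `horse_id`, `lap_index`, `hand`,
#' `session_context`, `expert_label` followed by the parameter fields in the
#' order of [compute_params()].
#'
#' @param laps List of [lap_recording()] objects.
#' @return Data frame with one row per lap.
#' @export
lap_parameters <- function(laps) {
  stopifnot(length(laps) >= 1L)
  rows <- lapply(laps, function(lap) {
    p <- as.data.frame(aggregate_lap(lap))
    meta <- data.frame(
      horse_id = lap$horse_id,
      lap_index = lap$lap_index,
      hand = lap$hand,
      session_context = lap$session_context %||% NA_character_,
      expert_label = lap$expert_label %||% NA_character_,
      stringsAsFactors = FALSE
    )
    meta$category_true <- lap$category_true %||% NA_character_
    cbind(meta, p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
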