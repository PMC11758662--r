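# Readers and writers for the documented CSV/JSON interchange formats, plus
# cohort summary tables.

EVENT_COLUMNS <- c("horse_id", "lap_index", "hand", "limb", "phase")

#' Read a lap events CSV into lap recordings
#'
#' The events file has one row per phase interval with columns `horse_id`,
#' `lap_index`, `hand` (L/R), optional `session_context`, `limb`
#' (LF/LH/RF/RH), `phase` (propulsion/return) and either `start_s`/`end_s`
#' in seconds or `start_frame`/`end_frame` at the source video frame rate
#' (120 fps by default), which are converted to seconds. Laps are assembled
#' with [split_lap_into_cycles()]; an optional labels CSV (`horse_id`,
#' `lap_index`, `expert_label`) attaches expert strategy labels.
#'
#' @param path Path to the events CSV.
#' @param labels_path Optional path to the labels CSV.
#' @param fps Frame rate used to convert `start_frame`/`end_frame` columns.
#' @return List of [lap_recording()] objects.
#' @export
read_lap_events <- function(path, labels_path = NULL, fps = VIDEO_FPS) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_seconds <- all(c("start_s", "end_s") %in% names(df))
  has_frames <- all(c("start_frame", "end_frame") %in% names(df))
  if (!has_seconds && !has_frames) {
    stop("schema error: need start_s/end_s or start_frame/end_frame columns")
  }
  if (!has_seconds) {
    df$start_s <- frames_to_seconds(as_time(df$start_frame, "start_frame"), fps)
    df$end_s <- frames_to_seconds(as_time(df$end_frame, "end_frame"), fps)
  } else {
    df$start_s <- as_time(df$start_s, "start_s")
    df$end_s <- as_time(df$end_s, "end_s")
  }
  bad_limb <- !df$limb %in% LIMB_LEVELS
  if (any(bad_limb)) {
    stop("value error at line ", which(bad_limb)[1L] + 1L,
         ": unknown limb '", df$limb[bad_limb][1L], "'")
  }
  bad_hand <- !df$hand %in% c("L", "R")
  if (any(bad_hand)) {
    stop("value error at line ", which(bad_hand)[1L] + 1L,
         ": hand must be L or R")
  }
  if (!"session_context" %in% names(df)) df$session_context <- NA_character_

  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    need <- c("horse_id", "lap_index", "expert_label")
    if (!all(need %in% names(labels))) {
      stop("schema error: labels file needs columns ",
           paste(need, collapse = ", "))
    }
  }

  key <- paste(df$horse_id, df$lap_index, sep = "\r")
  laps <- lapply(split(df, factor(key, levels = unique(key))), function(sub) {
    lbl <- NA_character_
    if (!is.null(labels)) {
      hit <- labels$horse_id == sub$horse_id[1L] &
        labels$lap_index == sub$lap_index[1L]
      if (any(hit)) lbl <- labels$expert_label[hit][1L]
    }
    split_lap_into_cycles(
      sub, horse_id = sub$horse_id[1L], lap_index = sub$lap_index[1L],
      hand = sub$hand[1L], session_context = sub$session_context[1L],
      expert_label = lbl
    )
  })
  names(laps) <- NULL
  laps
}

as_time <- function(x, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.finite(v)
  if (any(bad)) {
    stop("value error at line ", which(bad)[1L] + 1L,
         ": unparseable ", col, " '", x[bad][1L], "'")
  }
  v
}

#' Write lap recordings to an events CSV
#'
#' Inverse of [read_lap_events()]: serializes each lap via [lap_to_events()]
#' and writes one deterministic CSV (no timestamps).
#'
#' @param laps List of [lap_recording()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lap_events <- function(laps, path) {
  ev <- do.call(rbind, lapply(laps, lap_to_events))
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write expert labels of a lap list to CSV
#'
#' @inheritParams write_lap_events
#' @export
write_labels <- function(laps, path) {
  df <- do.call(rbind, lapply(laps, function(lap) {
    data.frame(horse_id = lap$horse_id, lap_index = lap$lap_index,
               expert_label = lap$expert_label, stringsAsFactors = FALSE)
  }))
  df <- df[!is.na(df$expert_label), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read the per-lap parameters table
#'
#' One row per lap with the metadata and parameter columns of
#' [lap_parameters()]; column names are stable.
#'
#' @param params Data frame from [lap_parameters()].
#' @param path CSV path.
#' @export
write_parameters <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save or load a fitted classifier as JSON
#'
#' The model JSON records the thresholds, per-step cluster centers, seed and
#' fit metadata.
#'
#' @param model A [fit_two_step()] model.
#' @param path JSON path.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "swim_classifier"))
  obj <- list(
    alpha1 = model$alpha1, beta1 = model$beta1, beta2 = model$beta2,
    centers = model$centers, seed = model$seed,
    n_laps = model$fit_metadata$n_laps,
    counts = as.list(as.integer(model$fit_metadata$counts)) |>
      stats::setNames(names(model$fit_metadata$counts))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(alpha1 = obj$alpha1, beta1 = obj$beta1, beta2 = obj$beta2,
         centers = obj$centers, seed = obj$seed,
         fit_metadata = list(n_laps = obj$n_laps, counts = unlist(obj$counts))),
    class = "swim_classifier"
  )
}

#' Summarize a classified cohort
#'
#' Cohort-level summary tables in the style of the study reports: per-horse
#' and per-hand category counts and percentages, pooled category shares, the
#' two-beat/four-beat split, hand shares, and each horse's dominant category
#' (modal; ties reported joined by "/").
#'
#' @param df Data frame with columns `horse_id` (optional), `hand`,
#'   `category`, and optionally `n` (pre-tabulated counts; defaults to one
#'   lap per row).
#' @return An object of class `cohort_summary` with elements `pooled`,
#'   `by_hand`, `hand_share`, `beat_split`, `by_horse`, `dominant`,
#'   `n_laps`.
#' @export
#' @examples
#' summarize_cohort(reference_cohort_counts())
summarize_cohort <- function(df) {
  stopifnot(is.data.frame(df), all(c("hand", "category") %in% names(df)))
  if (nrow(df) == 0L) {
    return(structure(list(pooled = data.frame(), by_hand = data.frame(),
                          hand_share = data.frame(), beat_split = data.frame(),
                          by_horse = data.frame(), dominant = data.frame(),
                          n_laps = 0L),
                     class = "cohort_summary"))
  }
  if (!"n" %in% names(df)) df$n <- 1L
  if (!"horse_id" %in% names(df)) df$horse_id <- "(all)"
  df$horse_id[is.na(df$horse_id)] <- "(all)"
  total <- sum(df$n)
  cat_f <- factor(df$category, levels = CATEGORY_LEVELS)
  pooled_n <- tapply(df$n, cat_f, sum, default = 0L)
  pooled <- data.frame(category = CATEGORY_LEVELS,
                       n = as.integer(pooled_n),
                       pct = 100 * as.numeric(pooled_n) / total)
  by_hand <- stats::aggregate(n ~ hand + category, data = df, sum)
  by_hand$pct <- 100 * by_hand$n / total
  hand_n <- tapply(df$n, df$hand, sum)
  hand_share <- data.frame(hand = names(hand_n), n = as.integer(hand_n),
                           pct = 100 * as.numeric(hand_n) / total)
  two_beat <- sum(pooled$n[pooled$category %in% c("CatA", "CatB")])
  four_beat <- sum(pooled$n[pooled$category %in% c("CatC", "CatD")])
  beat_split <- data.frame(
    pattern = c("two_beat", "four_beat"),
    n = c(two_beat, four_beat),
    pct = 100 * c(two_beat, four_beat) / total
  )
  by_horse <- stats::aggregate(n ~ horse_id + hand + category, data = df, sum)
  horse_tot <- tapply(df$n, list(df$horse_id, cat_f), sum, default = 0L)
  dominant <- data.frame(
    horse_id = rownames(horse_tot),
    dominant = apply(horse_tot, 1L, function(r) {
      paste(colnames(horse_tot)[r == max(r)], collapse = "/")
    }),
    stringsAsFactors = FALSE
  )
  structure(
    list(pooled = pooled, by_hand = by_hand, hand_share = hand_share,
         beat_split = beat_split, by_horse = by_horse, dominant = dominant,
         n_laps = as.integer(total)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_laps, "laps\n\nCategory shares:\n")
  p <- x$pooled
  p$pct <- round(p$pct, 1)  # reports use one decimal
  print(p, row.names = FALSE)
  b <- x$beat_split
  b$pct <- round(b$pct, 1)
  cat("\nBeat split:\n")
  print(b, row.names = FALSE)
  h <- x$hand_share
  h$pct <- round(h$pct, 1)
  cat("\nHand share:\n")
  print(h, row.names = FALSE)
  if (nrow(x$dominant) && !all(is.na(x$dominant$horse_id))) {
    cat("\nDominant category per horse:\n")
    print(x$dominant, row.names = FALSE)
  }
  invisible(x)
}
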