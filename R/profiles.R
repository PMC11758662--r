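# Bundled reference values from the motivating study of horses swimming in a
# U-shaped pool: per-category coordination statistics, classifier thresholds,
# cohort composition and category-wise classifier metrics. These are the
# package defaults for simulation and fixed-threshold classification.

#' Reference coordination profiles for the four categories
#'
#' Per-category, per-side means and standard deviations (percent of cycle) of
#' the generative coordination parameters: forelimb and hindlimb duty factors,
#' lateral delays (fore to ipsilateral hind) and diagonal delays (hind to
#' diagonal fore). These eight quantities fully determine a coordination
#' diagram: propulsion starts are placed cumulatively around the cycle
#' (LF at 0, then LH, RF, RH via the delays) and bar lengths are the duty
#' factors. The four delays of every column set close the cycle (sum to 100
#' within rounding), so overlaps are consequences, never free parameters.
#'
#' The categories are: CatA lateral two-beat (large lateral overlap), CatB
#' diagonal two-beat (large diagonal overlap), CatC four-beat with medium
#' overlap, CatD four-beat with low overlap and reduced duty factors.
#'
#' @param category Optional category code(s) to subset to.
#' @return A data frame with one row per category and side, columns
#'   `category`, `side`, and `<param>_mean` / `<param>_sd` for `df_fore`,
#'   `df_hind`, `lat_dl`, `diag_dl`.
#' @seealso [generate_lap()], [reference_overlaps()], [reference_thresholds()]
#' @export
#' @examples
#' category_profiles("CatA")
category_profiles <- function(category = NULL) {
  prof <- data.frame(
    category     = rep(CATEGORY_LEVELS, each = 2L),
    side         = rep(c("left", "right"), 4L),
    df_fore_mean = c(33.6, 34.6, 36.9, 38.2, 34.6, 33.9, 28.2, 28.0),
    df_fore_sd   = c(3.3, 3.2, 2.2, 2.3, 2.9, 4.5, 2.8, 2.7),
    df_hind_mean = c(34.3, 33.2, 33.5, 33.0, 32.6, 31.9, 27.4, 27.1),
    df_hind_sd   = c(3.9, 4.5, 3.7, 3.5, 5.2, 4.2, 2.7, 2.3),
    lat_dl_mean  = c(13.4, 14.8, 32.2, 34.2, 24.8, 25.4, 20.6, 21.1),
    lat_dl_sd    = c(4.0, 6.5, 3.2, 2.4, 5.2, 3.3, 2.9, 2.6),
    diag_dl_mean = c(35.0, 36.8, 15.8, 17.8, 24.6, 25.3, 27.9, 30.4),
    diag_dl_sd   = c(4.5, 3.7, 3.4, 3.3, 4.4, 4.4, 3.3, 3.2),
    stringsAsFactors = FALSE
  )
  if (!is.null(category)) {
    bad <- setdiff(category, CATEGORY_LEVELS)
    if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
    prof <- prof[prof$category %in% category, , drop = FALSE]
    rownames(prof) <- NULL
  }
  prof
}

#' Reference overlap statistics for the four categories
#'
#' Per-category, per-side means and standard deviations (percent of cycle) of
#' the lateral and diagonal signed overlaps reported alongside the duty
#' factors and delays of [category_profiles()]. Overlaps are derived
#' quantities (they satisfy `lat_ol = df_fore - lat_dl` and
#' `diag_ol = df_hind(opposite side) - diag_dl` up to rounding), so they are
#' shipped separately for validation rather than as generator inputs.
#'
#' @param category Optional category code(s) to subset to.
#' @return A data frame with columns `category`, `side`, `lat_ol_mean`,
#'   `lat_ol_sd`, `diag_ol_mean`, `diag_ol_sd`.
#' @export
reference_overlaps <- function(category = NULL) {
  ov <- data.frame(
    category     = rep(CATEGORY_LEVELS, each = 2L),
    side         = rep(c("left", "right"), 4L),
    lat_ol_mean  = c(20.2, 19.9, 4.7, 4.0, 9.8, 8.6, 7.6, 7.0),
    lat_ol_sd    = c(4.6, 6.1, 3.1, 2.6, 6.9, 3.3, 3.5, 3.0),
    diag_ol_mean = c(-1.8, -2.4, 17.2, 15.7, 7.3, 7.3, -0.8, -3.0),
    diag_ol_sd   = c(5.4, 6.0, 3.5, 5.3, 4.2, 6.4, 4.1, 4.5),
    stringsAsFactors = FALSE
  )
  if (!is.null(category)) {
    ov <- ov[ov$category %in% category, , drop = FALSE]
    rownames(ov) <- NULL
  }
  ov
}

#' Reference classification thresholds
#'
#' The fitted thresholds of the two-step classifier on the original study
#' cohort: `alpha1` separates the lateral two-beat category CatA (alpha <=
#' alpha1) from the rest; `beta1` and `beta2` split the remainder into CatB
#' (beta < beta1), CatC (beta1 <= beta < beta2) and CatD (beta >= beta2).
#' Shipped as constants for fixed-threshold classification of new laps.
#'
#' @return Named numeric vector with elements `alpha1`, `beta1`, `beta2`.
#' @seealso [classify_fixed()]
#' @export
reference_thresholds <- function() {
  c(alpha1 = 0.58, beta1 = 0.63, beta2 = 0.91)
}

#' Reference cohort composition (hand x category lap counts)
#'
#' Lap counts of the original 125-lap study cohort by swimming direction
#' (hand) and classified category, as published in the study's summary row.
#' Note: summing that study's per-horse rows ([reference_horse_counts()])
#' gives 19 right-hand CatC laps and 7 right-hand CatD laps, one lap shifted
#' relative to this summary (20 and 6); the published cohort-level
#' percentages are consistent with this summary row, which is therefore the
#' one used for proportion checks.
#'
#' @return A data frame with columns `hand` ("L"/"R"), `category`, `n`.
#' @seealso [summarize_cohort()]
#' @export
reference_cohort_counts <- function() {
  data.frame(
    hand     = rep(c("L", "R"), each = 4L),
    category = rep(CATEGORY_LEVELS, 2L),
    n        = c(19L, 7L, 23L, 13L, 22L, 15L, 20L, 6L),
    stringsAsFactors = FALSE
  )
}

#' Reference per-horse category counts
#'
#' Per-horse, per-hand classified lap counts of the original study cohort
#' (11 horses, 125 laps). See [reference_cohort_counts()] for a one-lap
#' bookkeeping discrepancy between these rows and the published totals.
#'
#' @return A data frame with columns `horse_id`, `hand`, `category`, `n`
#'   (zero-count combinations omitted).
#' @export
reference_horse_counts <- function() {
  df <- rbind(
    data.frame(horse_id = "#01", hand = c("L", "R"), category = "CatB", n = c(4L, 6L)),
    data.frame(horse_id = "#02", hand = c("L", "R", "L", "R"),
               category = rep(c("CatC", "CatD"), each = 2L), n = c(2L, 4L, 2L, 3L)),
    data.frame(horse_id = "#03", hand = c("R", "L", "L", "R"),
               category = c("CatA", "CatC", "CatD", "CatD"), n = c(5L, 5L, 1L, 1L)),
    data.frame(horse_id = "#06", hand = c("L", "R", "L", "R"),
               category = rep(c("CatC", "CatD"), each = 2L), n = c(1L, 4L, 5L, 2L)),
    data.frame(horse_id = "#08", hand = c("L", "R"), category = "CatA", n = c(7L, 5L)),
    data.frame(horse_id = "#09", hand = c("L", "R", "R", "L", "R"),
               category = c("CatA", "CatA", "CatB", "CatC", "CatC"),
               n = c(2L, 1L, 3L, 3L, 2L)),
    data.frame(horse_id = "#11", hand = c("L", "R"), category = "CatA", n = c(6L, 6L)),
    data.frame(horse_id = "#12", hand = c("R", "L", "R"),
               category = c("CatA", "CatC", "CatC"), n = c(1L, 6L, 5L)),
    data.frame(horse_id = "#13", hand = c("L", "R", "L", "R"),
               category = rep(c("CatA", "CatC"), each = 2L), n = c(2L, 2L, 4L, 4L)),
    data.frame(horse_id = "#14", hand = c("L", "R", "L", "R"),
               category = rep(c("CatA", "CatD"), each = 2L), n = c(1L, 2L, 5L, 1L)),
    data.frame(horse_id = "#15", hand = c("L", "L", "R", "L"),
               category = c("CatA", "CatB", "CatB", "CatC"), n = c(1L, 3L, 6L, 2L))
  )
  rownames(df) <- NULL
  df
}

#' Reference category-wise classifier metrics
#'
#' Published precision, recall, F1 and support of the two-step classifier on
#' the original cohort, with CatC and CatD pooled ("C+D") as in the source
#' summary. Used in tests to verify that F1 is the harmonic mean of precision
#' and recall.
#'
#' @return A data frame with columns `group`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
reference_category_metrics <- function() {
  data.frame(
    group     = c("A", "B", "C+D"),
    precision = c(0.97, 0.91, 0.98),
    recall    = c(0.97, 1.00, 0.96),
    f1        = c(0.97, 0.95, 0.97),
    support   = c(37L, 21L, 67L),
    stringsAsFactors = FALSE
  )
}
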