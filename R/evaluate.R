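# Evaluation of predicted coordination categories against expert strategy
# labels, and permutation tests of parameter differences between categories.

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall; defined as 0 when both are 0.
#'
#' @param precision,recall Numeric vectors in [0, 1].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Confusion-matrix evaluation of categories against expert strategies
#'
#' Cross-tabulates expert strategy labels (ground truth) against predicted
#' categories and computes overall accuracy plus category-wise precision,
#' recall, F1 and support. A predicted category counts as correct when its
#' mapped strategy ([category_to_strategy()]) equals the expert label. With
#' `merge_cd = TRUE` the two four-beat subcategories CatC and CatD are pooled
#' into one group "C+D", since both map to strategy S3.
#'
#' @param expert Vector of expert strategy labels (`S1`/`S2`/`S3`).
#' @param predicted Vector of predicted categories (`CatA`--`CatD`).
#' @param merge_cd Pool CatC and CatD into one group for the category-wise
#'   metrics and the confusion matrix columns.
#' @return An object of class `confusion_summary`: `matrix` (expert strategy
#'   x predicted group counts), `overall_accuracy`, and `per_category` (data
#'   frame with `group`, `strategy`, `precision`, `recall`, `f1`, `support`).
#'   Support is the number of laps carrying the group's strategy label.
#' @export
confusion_evaluate <- function(expert, predicted, merge_cd = TRUE) {
  expert <- as.character(expert)
  predicted <- as.character(predicted)
  if (length(expert) == 0L || length(expert) != length(predicted)) {
    stop("invalid label sets: need equal-length, non-empty label vectors")
  }
  if (!all(expert %in% STRATEGY_LEVELS)) {
    stop("invalid label sets: unknown expert strategy label")
  }
  if (!all(predicted %in% CATEGORY_LEVELS)) {
    stop("invalid label sets: unknown predicted category label")
  }
  mapped <- as.character(category_to_strategy(predicted))
  accuracy <- mean(mapped == expert)

  if (merge_cd) {
    groups <- list("A" = "CatA", "B" = "CatB", "C+D" = c("CatC", "CatD"))
  } else {
    groups <- list("A" = "CatA", "B" = "CatB", "C" = "CatC", "D" = "CatD")
  }
  pred_group <- predicted
  if (merge_cd) pred_group[pred_group %in% c("CatC", "CatD")] <- "C+D"
  pred_group <- sub("^Cat", "", pred_group)
  mat <- table(expert = factor(expert, levels = STRATEGY_LEVELS),
               predicted = factor(pred_group, levels = names(groups)))

  per <- lapply(names(groups), function(g) {
    cats <- groups[[g]]
    strat <- as.character(category_to_strategy(cats[1L]))
    in_group <- predicted %in% cats
    is_strat <- expert == strat
    tp <- sum(in_group & is_strat)
    precision <- if (sum(in_group) == 0L) 0 else tp / sum(in_group)
    recall <- if (sum(is_strat) == 0L) 0 else tp / sum(is_strat)
    data.frame(group = g, strategy = strat,
               precision = precision, recall = recall,
               f1 = f1_score(precision, recall),
               support = sum(is_strat), stringsAsFactors = FALSE)
  })
  structure(
    list(matrix = mat, overall_accuracy = accuracy,
         per_category = do.call(rbind, per), merge_cd = merge_cd),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>  overall accuracy:",
      sprintf("%.1f%%", 100 * x$overall_accuracy), "\n\n")
  print(x$matrix)
  cat("\n")
  pc <- x$per_category
  pc[c("precision", "recall", "f1")] <- round(pc[c("precision", "recall", "f1")], 2)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Cohen's kappa between expert strategies and mapped categories
#'
#' Chance-corrected agreement between the expert labels and the predicted
#' categories mapped onto strategies. Provided as a symmetric complement to
#' [confusion_evaluate()], which treats the expert labels as ground truth.
#'
#' @inheritParams confusion_evaluate
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(expert, predicted) {
  expert <- factor(as.character(expert), levels = STRATEGY_LEVELS)
  mapped <- category_to_strategy(predicted)
  if (length(expert) == 0L || length(expert) != length(mapped)) {
    stop("invalid label sets: need equal-length, non-empty label vectors")
  }
  tab <- table(expert, mapped)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Two-sample permutation test on the absolute mean difference
#'
#' Tests the difference between two samples with the statistic
#' |mean(a) - mean(b)|. The null distribution is built by randomly
#' reassigning the pooled values to two groups of the original sizes
#' `n_perm` times; the p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), which is never zero.
#'
#' @param a,b Numeric samples.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @param level Significance level used for the `significant` flag
#'   (default 0.001, flagged when p < level).
#' @param parameter_name,group_pair Optional labels carried into the result.
#' @return An object of class `permutation_result` with fields
#'   `parameter_name`, `group_pair`, `observed_stat`, `p_value`,
#'   `n_permutations`, `seed`, `level`, `significant`.
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = 1L, level = 0.001,
                             parameter_name = NA_character_,
                             group_pair = NA_character_) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("insufficient data: empty sample")
  }
  stopifnot(n_perm >= 1L)
  obs <- abs(mean(a) - mean(b))
  # canonicalize: sort the pooled values and permute indices for the smaller
  # group; the partition statistic is unchanged and the test becomes exactly
  # symmetric in (a, b)
  pooled <- sort(c(a, b))
  n <- length(pooled)
  k <- min(length(a), length(b))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, k)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  }, numeric(1))
  tol <- 1e-9 * max(1, obs)  # guard float ties in >=
  p <- (1 + sum(null_stats >= obs - tol)) / (1 + n_perm)
  structure(
    list(parameter_name = parameter_name, group_pair = group_pair,
         observed_stat = obs, p_value = p, n_permutations = n_perm,
         seed = seed, level = level, significant = p < level),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s %s: |diff of means| = %.4g, p = %.4g (%d perms)%s\n",
              ifelse(is.na(x$parameter_name), "", x$parameter_name),
              ifelse(is.na(x$group_pair), "", paste0("[", x$group_pair, "]")),
              x$observed_stat, x$p_value, x$n_permutations,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise permutation tests of parameters across categories
#'
#' Runs [permutation_test()] for every (parameter, category pair)
#' combination, flagging significance at the stated level (default p <
#' 0.001). No multiple-testing correction is applied by default; set
#' `adjust = "bonferroni"` to correct across all tests.
#'
#' @param params Data frame with a `category` column and numeric parameter
#'   columns (e.g. [lap_parameters()] plus a `category` column).
#' @param parameter_names Parameters to test; defaults to the twelve
#'   per-side duty factor, delay and overlap columns present in `params`.
#' @param n_perm,seed,level As in [permutation_test()]; each test uses a
#'   distinct seed derived from `seed`.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Data frame with one row per (parameter, category pair):
#'   `parameter`, `pair`, `observed_stat`, `p_value`, `significant`.
#' @export
pairwise_parameter_tests <- function(params, parameter_names = NULL,
                                     n_perm = 10000L, seed = 1L,
                                     level = 0.001,
                                     adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(params), "category" %in% names(params))
  default_params <- c("df_lf", "df_rf", "df_lh", "df_rh",
                      "lat_dl_left", "lat_dl_right",
                      "diag_dl_left", "diag_dl_right",
                      "lat_ol_left", "lat_ol_right",
                      "diag_ol_left", "diag_ol_right")
  if (is.null(parameter_names)) {
    parameter_names <- intersect(default_params, names(params))
  }
  stopifnot(all(parameter_names %in% names(params)))
  cats <- sort(unique(as.character(params$category)))
  sizes <- table(params$category)
  cats <- cats[sizes[cats] >= 2L]
  if (length(cats) < 2L) {
    stop("insufficient data: need >= 2 categories with >= 2 laps each")
  }
  pairs <- utils::combn(cats, 2L, simplify = FALSE)
  rows <- list()
  counter <- 0L
  for (pn in parameter_names) {
    for (pr in pairs) {
      counter <- counter + 1L
      res <- permutation_test(
        params[params$category == pr[1L], pn],
        params[params$category == pr[2L], pn],
        n_perm = n_perm, seed = seed + counter, level = level,
        parameter_name = pn, group_pair = paste(pr, collapse = " vs ")
      )
      rows[[counter]] <- data.frame(
        parameter = pn, pair = res$group_pair,
        observed_stat = res$observed_stat, p_value = res$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") {
    out$p_value <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  out$significant <- out$p_value < level
  out
}
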