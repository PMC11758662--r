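# Two-step k-means threshold classifier in the (alpha, beta) plane.
#
# Step 1 clusters alpha (k = 2); the lower cluster is the lateral two-beat
# category CatA and the boundary alpha1 is the midpoint between the two
# clusters' nearest members. Step 2 clusters beta of the remaining laps
# (k = 3); the clusters ordered by centroid give CatB < CatC < CatD with
# boundaries beta1 and beta2 again taken between nearest members. Boundary
# ties follow the printed inequalities: alpha <= alpha1 -> CatA;
# beta < beta1 -> CatB; beta1 <= beta < beta2 -> CatC; beta >= beta2 -> CatD.

# Coerce classifier input (a lap_parameters() data frame, a list of
# coordination_params, or a single coordination_params) to a data frame with
# alpha and beta columns.
as_alpha_beta <- function(params) {
  if (inherits(params, "coordination_params")) {
    return(data.frame(alpha = params$alpha, beta = params$beta))
  }
  if (is.data.frame(params)) {
    stopifnot(all(c("alpha", "beta") %in% names(params)))
    return(params[, c("alpha", "beta"), drop = FALSE])
  }
  if (is.list(params)) {
    return(data.frame(
      alpha = vapply(params, function(p) p$alpha, numeric(1)),
      beta = vapply(params, function(p) p$beta, numeric(1))
    ))
  }
  stop("cannot interpret classifier input")
}

# 1-D k-means with multiple random restarts; returns cluster ids ordered so
# that cluster 1 has the lowest centroid.
kmeans_1d <- function(x, k, nstart = 10L) {
  km <- stats::kmeans(matrix(x, ncol = 1L), centers = k, nstart = nstart)
  ord <- order(km$centers[, 1L])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  list(cluster = relabel[km$cluster], centers = sort(km$centers[, 1L]))
}

# Separating boundary between two adjacent 1-D clusters: the midpoint of the
# nearest members, which classifies the training points identically to the
# cluster assignment.
cluster_boundary <- function(x, cluster, lo, hi) {
  (max(x[cluster == lo]) + min(x[cluster == hi])) / 2
}

#' Fit the two-step coordination classifier
#'
#' Runs 1-D k-means with k = 2 on the lateral ratio alpha; the lower cluster
#' defines CatA and the threshold `alpha1`. Then runs 1-D k-means with k = 3
#' on the diagonal ratio beta of the remaining laps, defining CatB, CatC and
#' CatD and the thresholds `beta1 < beta2`. Thresholds are midpoints between
#' adjacent clusters' nearest members, so classifying the training laps with
#' the fitted thresholds reproduces the cluster assignment exactly.
#'
#' @param params A [lap_parameters()] data frame (or list of
#'   `coordination_params`) with at least 5 laps, finite alpha and beta,
#'   at least 2 distinct alpha values and 3 distinct beta values outside the
#'   low-alpha cluster.
#' @param seed Integer seed controlling the k-means restarts.
#' @param nstart Number of random restarts per k-means run.
#' @return An object of class `swim_classifier`: thresholds `alpha1`,
#'   `beta1`, `beta2`, per-step cluster `centers`, the `seed`, and
#'   `fit_metadata` (lap count and per-category counts).
#' @seealso [classify_fixed()], [predict.swim_classifier()]
#' @export
fit_two_step <- function(params, seed = 1L, nstart = 10L) {
  ab <- as_alpha_beta(params)
  alpha <- ab$alpha
  beta <- ab$beta
  if (nrow(ab) < 5L || any(!is.finite(alpha)) || any(!is.finite(beta))) {
    stop("degenerate clustering input: need >= 5 laps with finite alpha and beta")
  }
  if (length(unique(alpha)) < 2L) {
    stop("degenerate clustering input: all alpha values identical")
  }
  set.seed(seed)
  km_a <- kmeans_1d(alpha, 2L, nstart = nstart)
  is_a <- km_a$cluster == 1L
  alpha1 <- cluster_boundary(alpha, km_a$cluster, 1L, 2L)

  beta_rest <- beta[!is_a]
  if (length(unique(beta_rest)) < 3L) {
    stop("degenerate clustering input: need >= 3 distinct beta values ",
         "outside the low-alpha cluster")
  }
  km_b <- kmeans_1d(beta_rest, 3L, nstart = nstart)
  beta1 <- cluster_boundary(beta_rest, km_b$cluster, 1L, 2L)
  beta2 <- cluster_boundary(beta_rest, km_b$cluster, 2L, 3L)

  model <- structure(
    list(alpha1 = alpha1, beta1 = beta1, beta2 = beta2,
         centers = list(alpha = km_a$centers, beta = km_b$centers),
         seed = seed),
    class = "swim_classifier"
  )
  labels <- classify_fixed(ab, thresholds = model)
  model$fit_metadata <- list(
    n_laps = nrow(ab),
    counts = table(factor(labels, levels = CATEGORY_LEVELS))
  )
  model
}

#' @export
print.swim_classifier <- function(x, ...) {
  cat("<swim_classifier>  two-step k-means threshold classifier\n")
  cat(sprintf("  alpha1 = %.4f   beta1 = %.4f   beta2 = %.4f\n",
              x$alpha1, x$beta1, x$beta2))
  if (!is.null(x$fit_metadata)) {
    cat("  fitted on", x$fit_metadata$n_laps, "laps:",
        paste(names(x$fit_metadata$counts), as.integer(x$fit_metadata$counts),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Extract (alpha1, beta1, beta2) from a model, named vector or list.
as_thresholds <- function(thresholds) {
  th <- c(alpha1 = unname(thresholds[["alpha1"]]),
          beta1 = unname(thresholds[["beta1"]]),
          beta2 = unname(thresholds[["beta2"]]))
  if (any(!is.finite(th)) || th["beta1"] >= th["beta2"]) {
    stop("invalid thresholds: need finite values with beta1 < beta2")
  }
  th
}

#' Classify laps with fixed thresholds
#'
#' Deterministic category rule on the (alpha, beta) plane:
#' CatA when `alpha <= alpha1`; otherwise CatB when `beta < beta1`, CatC when
#' `beta1 <= beta < beta2`, CatD when `beta >= beta2`. Defaults to the
#' bundled [reference_thresholds()].
#'
#' @param params A `coordination_params`, a list of them, or a
#'   [lap_parameters()] data frame.
#' @param thresholds A fitted [fit_two_step()] model, or any named
#'   vector/list with `alpha1`, `beta1`, `beta2`.
#' @return Factor of category labels with levels `CatA`--`CatD`.
#' @export
#' @examples
#' classify_fixed(data.frame(alpha = 0.41, beta = 1.06))
classify_fixed <- function(params, thresholds = reference_thresholds()) {
  th <- as_thresholds(thresholds)
  ab <- as_alpha_beta(params)
  if (any(!is.finite(ab$alpha)) || any(!is.finite(ab$beta))) {
    stop("unclassifiable lap: non-finite alpha or beta")
  }
  lab <- ifelse(ab$alpha <= th["alpha1"], "CatA",
                ifelse(ab$beta < th["beta1"], "CatB",
                       ifelse(ab$beta < th["beta2"], "CatC", "CatD")))
  factor(lab, levels = CATEGORY_LEVELS)
}

#' @param object A fitted `swim_classifier`.
#' @param newdata Parameters to classify, as in [classify_fixed()].
#' @param ... Unused.
#' @rdname fit_two_step
#' @export
predict.swim_classifier <- function(object, newdata, ...) {
  classify_fixed(newdata, thresholds = object)
}

#' Map coordination categories onto swimming strategies
#'
#' CatA is the lateral two-beat strategy S1, CatB the diagonal two-beat
#' strategy S2, and CatC and CatD are the medium- and low-overlap variations
#' of the four-beat strategy S3. The mapping is not invertible for S3.
#'
#' @param category Vector of category labels.
#' @return Factor of strategy labels with levels `S1`, `S2`, `S3`.
#' @export
category_to_strategy <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category[!is.na(category)]), CATEGORY_LEVELS)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  map <- c(CatA = "S1", CatB = "S2", CatC = "S3", CatD = "S3")
  factor(unname(map[category]), levels = STRATEGY_LEVELS)
}

#' Alternative clustering schemes for benchmarking
#'
#' Two simpler clusterings of the same laps, for comparison with the
#' two-step classifier: `"single_k3_on_plane"` runs one k-means with k = 3 on
#' the (alpha, beta) plane; `"two_successive_k2"` runs k = 2 on alpha and
#' then k = 2 on beta of the remaining laps. Both return three groups mapped
#' onto strategies (they cannot resolve the two four-beat subcategories).
#'
#' @inheritParams fit_two_step
#' @param scheme Clustering scheme.
#' @return List with `labels` (factor of `S1`/`S2`/`S3`), `scheme`, `seed`
#'   and `centers`.
#' @export
fit_alternative <- function(params,
                            scheme = c("single_k3_on_plane", "two_successive_k2"),
                            seed = 1L, nstart = 10L) {
  scheme <- match.arg(scheme)
  ab <- as_alpha_beta(params)
  if (nrow(ab) < 5L || any(!is.finite(ab$alpha)) || any(!is.finite(ab$beta))) {
    stop("degenerate clustering input: need >= 5 laps with finite alpha and beta")
  }
  set.seed(seed)
  if (scheme == "single_k3_on_plane") {
    km <- stats::kmeans(as.matrix(ab), centers = 3L, nstart = nstart)
    centers <- km$centers
    # lowest-alpha centroid -> S1; of the rest, lowest-beta centroid -> S2
    s1 <- which.min(centers[, "alpha"])
    rest <- setdiff(seq_len(3L), s1)
    s2 <- rest[which.min(centers[rest, "beta"])]
    map <- rep("S3", 3L)
    map[s1] <- "S1"
    map[s2] <- "S2"
    labels <- factor(map[km$cluster], levels = STRATEGY_LEVELS)
  } else {
    if (length(unique(ab$alpha)) < 2L) {
      stop("degenerate clustering input: all alpha values identical")
    }
    km_a <- kmeans_1d(ab$alpha, 2L, nstart = nstart)
    labels <- rep("S1", nrow(ab))
    rest <- km_a$cluster == 2L
    if (length(unique(ab$beta[rest])) < 2L) {
      stop("degenerate clustering input: beta values outside the low-alpha ",
           "cluster are identical")
    }
    km_b <- kmeans_1d(ab$beta[rest], 2L, nstart = nstart)
    labels[rest] <- c("S2", "S3")[km_b$cluster]
    labels <- factor(labels, levels = STRATEGY_LEVELS)
    centers <- list(alpha = km_a$centers, beta = km_b$centers)
  }
  list(labels = labels, scheme = scheme, seed = seed, centers = centers)
}
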