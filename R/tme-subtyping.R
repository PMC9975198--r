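TME_ARCHETYPES <- c("IE", "IE/F", "F", "D")

# Farthest-point (kmeans++-like, deterministic given RNG state) initial centers.
farthest_point_centers <- function(x, k) {
  n <- nrow(x)
  centers <- sample.int(n, 1)
  while (length(centers) < k) {
    d <- apply(x, 1, function(r) min(colSums((t(x[centers, , drop = FALSE]) - r)^2)))
    centers <- c(centers, which.max(d))
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of samples on signature-score profiles
#'
#' Lloyd's algorithm with Euclidean distance, up to `n_iter` iterations, best
#' of `n_restarts` random initializations by within-cluster sum of squares
#' (inertia). Scores are z-scored per signature by default before clustering.
#' Runs that produce an empty cluster are retried with farthest-point seeding.
#' Deterministic for a fixed seed and invariant to sample order.
#'
#' @param scores samples-by-signatures numeric matrix (no missing values).
#' @param k number of clusters (default 4).
#' @param n_iter maximum Lloyd iterations (default 1000).
#' @param n_restarts random restarts (default 25).
#' @param seed RNG seed.
#' @param z_score z-score each signature column first (default TRUE).
#' @return list with `labels` (tibble `sample_id`, `cluster`,
#'   `distance_to_centroid`), `centroids` (k x signatures), `inertia`.
#' @export
tme_cluster <- function(scores, k = 4, n_iter = 1000, n_restarts = 25,
                        seed = 1, z_score = TRUE) {
  x <- as.matrix(scores)
  if (anyNA(x)) stop("scores contain missing values", call. = FALSE)
  if (k < 2 || k > nrow(x)) stop("require 2 <= k <= number of samples", call. = FALSE)
  if (z_score) x <- scale(x)
  ord <- order(rownames(x) %||% as.character(seq_len(nrow(x))))
  x_ord <- x[ord, , drop = FALSE]
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      kmeans(x_ord, centers = k, iter.max = n_iter, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        suppressWarnings(kmeans(x_ord, centers = farthest_point_centers(x_ord, k),
                                iter.max = n_iter, algorithm = "Lloyd")),
        error = function(e) NULL)
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
  labels <- integer(nrow(x))
  labels[ord] <- best$cluster
  d <- sqrt(rowSums((x - best$centers[labels, , drop = FALSE])^2))
  list(
    labels = tibble(sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    cluster = labels, distance_to_centroid = d),
    centroids = best$centers,
    inertia = best$tot.withinss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map clusters to tumor-microenvironment archetypes
#'
#' Each centroid is summarized by its mean score over immune-axis signatures
#' (I) and over fibrotic-axis signatures (S). Using the cross-centroid medians
#' as high/low cuts, the quadrants map to archetypes: high I / low S = IE
#' (immune-enriched non-fibrotic), high/high = IE/F, low/high = F, low/low =
#' D (depleted). If two centroids land in one quadrant, the one farther from
#' the cut keeps it and the other takes the nearest unassigned quadrant, with
#' a warning. The mapping is a bijection.
#'
#' @param centroids k-by-signatures matrix (from [tme_cluster()]).
#' @param immune_sets,fibrotic_sets character vectors naming the signature
#'   columns on each axis.
#' @return tibble `cluster`, `archetype`, `immune_mean`, `fibrotic_mean`.
#' @export
label_archetypes <- function(centroids, immune_sets, fibrotic_sets) {
  sig <- colnames(centroids)
  tagged <- sum(sig %in% c(immune_sets, fibrotic_sets))
  if (tagged < length(sig) / 2)
    stop("axis tag missing for more than half of the signatures", call. = FALSE)
  I <- rowMeans(centroids[, intersect(sig, immune_sets), drop = FALSE])
  S <- rowMeans(centroids[, intersect(sig, fibrotic_sets), drop = FALSE])
  hi_i <- I > median(I)
  hi_s <- S > median(S)
  quadrant <- ifelse(hi_i & !hi_s, "IE",
              ifelse(hi_i & hi_s, "IE/F",
              ifelse(!hi_i & hi_s, "F", "D")))
  k <- nrow(centroids)
  archetype <- rep(NA_character_, k)
  # distance from the cuts: stronger claims resolved first
  strength <- abs(I - median(I)) + abs(S - median(S))
  for (i in order(-strength)) {
    if (!(quadrant[i] %in% archetype)) {
      archetype[i] <- quadrant[i]
    }
  }
  unassigned <- which(is.na(archetype))
  if (length(unassigned) > 0) {
    warning("centroid quadrant collision; nearest unassigned archetype used",
            call. = FALSE)
    quad_coords <- matrix(c(1, -1, 1, 1, -1, 1, -1, -1), ncol = 2, byrow = TRUE,
                          dimnames = list(c("IE", "IE/F", "F", "D"), NULL))
    for (i in unassigned) {
      free <- setdiff(TME_ARCHETYPES, archetype)
      pos <- c(sign(I[i] - median(I) + 1e-12), sign(S[i] - median(S) + 1e-12))
      d <- apply(quad_coords[free, , drop = FALSE], 1, function(qc) sum((qc - pos)^2))
      archetype[i] <- free[which.min(d)]
    }
  }
  tibble(cluster = seq_len(k), archetype = archetype,
         immune_mean = I, fibrotic_mean = S)
}

#' Assign TME subtypes to samples
#'
#' Convenience wrapper: clusters the score matrix with [tme_cluster()] and
#' labels the clusters with [label_archetypes()].
#'
#' @inheritParams tme_cluster
#' @inheritParams label_archetypes
#' @return `ppgl_tme`: list with `assignments` (tibble `sample_id`, `cluster`,
#'   `archetype`, `distance_to_centroid`), `centroids`, `archetype_map`,
#'   `inertia`.
#' @export
tme_assign <- function(scores, immune_sets, fibrotic_sets, k = 4,
                       n_iter = 1000, n_restarts = 25, seed = 1,
                       z_score = TRUE) {
  cl <- tme_cluster(scores, k = k, n_iter = n_iter, n_restarts = n_restarts,
                    seed = seed, z_score = z_score)
  map <- label_archetypes(cl$centroids, immune_sets, fibrotic_sets)
  assignments <- cl$labels |>
    left_join(map[, c("cluster", "archetype")], by = "cluster")
  structure(list(assignments = assignments, centroids = cl$centroids,
                 archetype_map = map, inertia = cl$inertia),
            class = "ppgl_tme")
}
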