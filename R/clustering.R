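#' K-means clustering of SOM node weights
#'
#' Partitions the node-weight vectors into `k` homogeneous subgroups with
#' multi-restart K-means ([stats::kmeans()]). Cluster labels are reordered
#' so cluster 1 has the highest centroid grand mean (descending), which
#' makes labels deterministic and comparable across runs: cluster 1 is the
#' high-performing profile, cluster `k` the lowest.
#'
#' @param model a [batch_train()] model.
#' @param k number of clusters (default 4).
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @return an object of class `cluster_solution`: `k`, `node_labels`,
#'   `centroids` (k x n_tasks), `inertia` (total within-cluster SS),
#'   `seed`.
#' @export
kmeans_nodes <- function(model, k = 4L, n_restarts = 100L, seed = 1L) {
  stopifnot(inherits(model, "som_model"))
  W <- model$weights
  if (k > nrow(W)) stop("`k` exceeds the number of nodes", call. = FALSE)
  if (k < 1L) stop("`k` must be positive", call. = FALSE)
  if (k == nrow(W)) {
    # every node its own cluster; stats::kmeans rejects k = n
    ord <- order(rowMeans(W), decreasing = TRUE)
    return(structure(
      list(k = as.integer(k), node_labels = match(seq_len(k), ord),
           centroids = W[ord, , drop = FALSE], inertia = 0, seed = seed),
      class = "cluster_solution"))
  }
  km <- NULL
  for (attempt in 1:5) { # rare empty-cluster failures get a fresh seed stream
    km <- try(with_seed(derive_seed(seed, "kmeans", attempt),
                        stats::kmeans(W, centers = k, nstart = n_restarts,
                                      iter.max = 100L)),
              silent = TRUE)
    if (!inherits(km, "try-error")) break
  }
  if (inherits(km, "try-error")) stop("k-means failed to converge", call. = FALSE)
  ord <- order(rowMeans(km$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  structure(
    list(k = as.integer(k), node_labels = relabel[km$cluster],
         centroids = km$centers[ord, , drop = FALSE], inertia = km$tot.withinss,
         seed = seed),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, inertia %.2f, sizes: %s\n",
              x$k, x$inertia,
              paste(tabulate(x$node_labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Allocate participants to node clusters through their BMUs
#'
#' Each participant inherits the cluster of their best matching unit.
#'
#' @param model a [batch_train()] model.
#' @param solution a [kmeans_nodes()] solution for that model.
#' @param scores a [score_table()] over the same tasks.
#' @return a data.frame with `participant_id`, `bmu`, `cluster`.
#' @export
allocate_to_clusters <- function(model, solution, scores) {
  stopifnot(inherits(solution, "cluster_solution"))
  bmu <- map_to_bmus(model, scores)
  data.frame(participant_id = scores$participant_id, bmu = bmu,
             cluster = solution$node_labels[bmu], row.names = NULL)
}

#' Mean silhouette width across candidate cluster counts
#'
#' Clusters the node weights for each `k` and reports the mean silhouette
#' width over nodes as a clustering-quality measure ([cluster::silhouette()];
#' singleton clusters score 0 by convention, so the all-singleton solution
#' scores 0). Values of `k < 2` are excluded with a warning (silhouette is
#' undefined).
#'
#' @param model a [batch_train()] model.
#' @param k_range candidate cluster counts.
#' @param n_restarts,seed passed to [kmeans_nodes()].
#' @return a data.frame with `k` and `mean_silhouette`.
#' @export
silhouette_scan <- function(model, k_range = 2:8, n_restarts = 50L, seed = 1L) {
  stopifnot(inherits(model, "som_model"))
  if (any(k_range < 2)) {
    warning("k < 2 excluded: silhouette undefined", call. = FALSE)
    k_range <- k_range[k_range >= 2]
  }
  if (any(k_range > nrow(model$weights))) {
    stop("k in range exceeds the number of nodes", call. = FALSE)
  }
  d <- stats::dist(model$weights)
  n <- nrow(model$weights)
  res <- vapply(k_range, function(k) {
    labels <- kmeans_nodes(model, k, n_restarts, derive_seed(seed, "sil", k))$node_labels
    if (k == n) return(0) # all singletons: 0 by convention
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  }, 0)
  data.frame(k = as.integer(k_range), mean_silhouette = res)
}

#' Cluster stability under map retraining
#'
#' Retrains the map `n_reps` times on seeded bootstrap resamples of the
#' cohort, reclusters the node weights, reallocates every participant, and
#' measures pairwise agreement between the resulting participant partitions
#' with the adjusted Rand index (label-permutation invariant; 1 = identical
#' partitions, about 0 = chance). Batch SOM training is deterministic given
#' the data, so participant resampling is what makes each retrain an
#' independent probe of robustness.
#'
#' @param data a [score_table()].
#' @param som_config a [som_config()].
#' @param k number of clusters.
#' @param n_reps retrains (>= 2).
#' @param seed integer seed.
#' @param max_pairs cap on the number of rep pairs scored (pairs are
#'   sampled beyond this).
#' @return an object of class `stability_report`: `n_reps`,
#'   `pairwise_agreement`, `mean`, `min`.
#' @export
stability_analysis <- function(data, som_config = cogsom::som_config(), k = 4L,
                               n_reps = 1000L, seed = 1L, max_pairs = 500L) {
  stopifnot(inherits(data, "score_table"))
  if (n_reps < 2L) stop("need at least 2 retrains", call. = FALSE)
  n <- nrow(data$scores)
  if (nrow(unique(data$scores)) < 2L) {
    stop("degenerate data: all participants identical", call. = FALSE)
  }
  partitions <- matrix(NA_integer_, n, n_reps)
  for (r in seq_len(n_reps)) {
    idx <- with_seed(derive_seed(seed, "stab-boot", r),
                     sample.int(n, n, replace = TRUE))
    boot <- score_table(data$scores[idx, , drop = FALSE],
                        sprintf("B%05d", seq_len(n)), data$task_names)
    model <- batch_train(boot, som_config)
    sol <- kmeans_nodes(model, k, seed = derive_seed(seed, "stab-km", r))
    bmu <- bmu_rows(data$scores, model$weights)
    partitions[, r] <- sol$node_labels[bmu]
  }
  pairs <- utils::combn(n_reps, 2L)
  if (ncol(pairs) > max_pairs) {
    keep <- with_seed(derive_seed(seed, "stab-pairs"),
                      sample.int(ncol(pairs), max_pairs))
    pairs <- pairs[, keep, drop = FALSE]
  }
  ari <- vapply(seq_len(ncol(pairs)), function(i) {
    mclust::adjustedRandIndex(partitions[, pairs[1, i]], partitions[, pairs[2, i]])
  }, 0)
  structure(
    list(n_reps = n_reps, pairwise_agreement = ari,
         mean = mean(ari), min = min(ari), seed = seed),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d retrains, mean ARI %.3f (min %.3f)\n",
              x$n_reps, x$mean, x$min))
  invisible(x)
}

#' Per-cluster per-task profile summary
#'
#' Means, standard errors and normal 95% confidence intervals of the task
#' scores within each allocated cluster; the numbers behind subgroup
#' profile plots.
#'
#' @param allocations output of [allocate_to_clusters()].
#' @param scores the matching [score_table()].
#' @return a data.frame with `cluster`, `task`, `n`, `mean`, `se`,
#'   `ci_lower`, `ci_upper`. Empty clusters are reported with `NA`
#'   statistics and a warning.
#' @export
profile_summary <- function(allocations, scores) {
  stopifnot(inherits(scores, "score_table"))
  if (!all(scores$participant_id %in% allocations$participant_id)) {
    stop("every participant must be allocated", call. = FALSE)
  }
  idx <- match(scores$participant_id, allocations$participant_id)
  cl <- allocations$cluster[idx]
  ks <- sort(unique(allocations$cluster))
  ks <- seq_len(max(ks)) # report empty clusters too
  out <- do.call(rbind, lapply(ks, function(g) {
    rows <- which(cl == g)
    if (!length(rows)) {
      warning(sprintf("cluster %d is empty", g), call. = FALSE)
      return(data.frame(cluster = g, task = scores$task_names, n = 0L,
                        mean = NA_real_, se = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_))
    }
    m <- colMeans(scores$scores[rows, , drop = FALSE])
    se <- apply(scores$scores[rows, , drop = FALSE], 2L, stats::sd) /
      sqrt(length(rows))
    data.frame(cluster = g, task = scores$task_names, n = length(rows),
               mean = unname(m), se = unname(se),
               ci_lower = unname(m - 1.96 * se), ci_upper = unname(m + 1.96 * se))
  }))
  rownames(out) <- NULL
  out
}
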