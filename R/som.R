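#' SOM training configuration
#'
#' Defaults mirror the map used for the published baseline analysis: a
#' 64-node (8 x 8) lattice, initial neighbourhood size 2, ten ordering-phase
#' batch cycles and two fine-tuning cycles (neighbourhood restricted to the
#' BMU). The lattice is rectangular with Chebyshev grid distance by
#' default, which makes the boxcar neighbourhood set exactly reproducible;
#' hexagonal and link (Manhattan/hex-axial) metrics are available.
#'
#' @param grid_rows,grid_cols lattice dimensions (product >= 4).
#' @param initial_neighbourhood initial neighbourhood size (INS), positive.
#' @param ordering_steps number of ordering-phase cycles `n`; 0 skips the
#'   ordering phase entirely (fine-tuning only).
#' @param fine_tune_steps number of BMU-only refinement cycles, >= 0.
#' @param topology `"rectangular"` or `"hexagonal"`.
#' @param grid_metric `"chebyshev"` (default) or `"link"` (lattice link
#'   distance: Manhattan on a rectangular grid, axial hex distance on a
#'   hexagonal one).
#' @param seed integer seed; only consumed by the degenerate-rank jitter
#'   fallback of the PCA initialization.
#' @return an object of class `som_config`.
#' @export
som_config <- function(grid_rows = 8L, grid_cols = 8L,
                       initial_neighbourhood = 2, ordering_steps = 10L,
                       fine_tune_steps = 2L,
                       topology = c("rectangular", "hexagonal"),
                       grid_metric = c("chebyshev", "link"), seed = 1L) {
  topology <- match.arg(topology)
  grid_metric <- match.arg(grid_metric)
  assert_scalar_number(grid_rows, "grid_rows", lower = 1)
  assert_scalar_number(grid_cols, "grid_cols", lower = 1)
  if (grid_rows * grid_cols < 4) stop("need at least 4 nodes", call. = FALSE)
  assert_scalar_number(initial_neighbourhood, "initial_neighbourhood")
  if (initial_neighbourhood <= 0) stop("`initial_neighbourhood` must be positive", call. = FALSE)
  assert_scalar_number(ordering_steps, "ordering_steps", lower = 0)
  assert_scalar_number(fine_tune_steps, "fine_tune_steps", lower = 0)
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         initial_neighbourhood = as.numeric(initial_neighbourhood),
         ordering_steps = as.integer(ordering_steps),
         fine_tune_steps = as.integer(fine_tune_steps),
         topology = topology, grid_metric = grid_metric,
         seed = as.integer(seed)),
    class = "som_config"
  )
}

#' Neighbourhood size schedule
#'
#' The ordering-phase neighbourhood radius shrinks linearly with the cycle
#' index: `ND(t) = 1 + INS * (1 - t / n)`, reaching exactly 1 at `t = n`.
#'
#' @param t cycle index, `0 <= t <= n`.
#' @param ins initial neighbourhood size.
#' @param n total number of ordering steps.
#' @return the neighbourhood radius at step `t`.
#' @export
neighbourhood_size <- function(t, ins, n) {
  if (any(t < 0) || any(t > n)) {
    stop("`t` must lie in [0, n]", call. = FALSE)
  }
  1 + ins * (1 - t / n)
}

# Row-major lattice coordinates; node i = (row - 1) * grid_cols + col.
grid_coords <- function(config) {
  expand.grid(col = seq_len(config$grid_cols),
              row = seq_len(config$grid_rows))[, c("row", "col")]
}

# Pairwise node-to-node grid distances under the configured topology/metric.
grid_distance_matrix <- function(config) {
  gc <- grid_coords(config)
  r <- gc$row; c <- gc$col
  dr <- abs(outer(r, r, `-`))
  dc <- abs(outer(c, c, `-`))
  if (config$topology == "rectangular") {
    if (config$grid_metric == "chebyshev") pmax(dr, dc) else dr + dc
  } else {
    # offset rows -> axial coordinates; hex link distance
    q <- c - floor(r / 2)
    dq <- outer(q, q, `-`)
    drr <- outer(r, r, `-`)
    (abs(dq) + abs(drr) + abs(dq + drr)) / 2
  }
}

#' Initialize node weights from the leading principal components
#'
#' Linear (Kohonen-style) initialization: node `(r, c)` starts at the data
#' mean plus `a_r * sqrt(lambda1) * u1 + b_c * sqrt(lambda2) * u2`, with
#' `a_r`, `b_c` linearly spaced over `[-2, 2]` along the lattice rows and
#' columns and `(lambda_i, u_i)` the two leading eigenpairs of the data
#' covariance. If the data have rank below 2 the initialization falls back
#' to the mean plus a small seeded jitter (magnitude `1e-3` of the score
#' SD) with a warning.
#'
#' @param data a [score_table()] with at least 3 rows and 2 tasks.
#' @param config a [som_config()].
#' @return an `n_nodes x n_tasks` weight matrix (row-major node order).
#' @export
initialize_weights <- function(data, config) {
  stopifnot(inherits(data, "score_table"), inherits(config, "som_config"))
  X <- data$scores
  if (nrow(X) < 3L) stop("need at least 3 participants to initialize", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 tasks", call. = FALSE)
  n_nodes <- config$grid_rows * config$grid_cols
  mu <- colMeans(X)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  tol <- max(eg$values[1], 0) * 1e-10
  if (eg$values[1] <= 0 || eg$values[2] <= tol) {
    warning("data rank < 2; initializing at the mean with seeded jitter",
            call. = FALSE)
    sd_scale <- sqrt(max(mean(diag(stats::cov(X))), .Machine$double.eps))
    jitter <- with_seed(config$seed,
                        matrix(stats::rnorm(n_nodes * ncol(X)), n_nodes)) *
      1e-3 * sd_scale
    W <- matrix(mu, n_nodes, ncol(X), byrow = TRUE) + jitter
    colnames(W) <- data$task_names
    return(W)
  }
  span <- function(k) if (k == 1L) 0 else seq(-2, 2, length.out = k)
  # fix eigenvector signs for determinism
  fix_sign <- function(u) if (u[which.max(abs(u))] < 0) -u else u
  u1 <- fix_sign(eg$vectors[, 1]) * sqrt(eg$values[1])
  u2 <- fix_sign(eg$vectors[, 2]) * sqrt(eg$values[2])
  gc <- grid_coords(config)
  a <- span(config$grid_rows)[gc$row]
  b <- span(config$grid_cols)[gc$col]
  W <- matrix(mu, n_nodes, ncol(X), byrow = TRUE) +
    outer(a, u1) + outer(b, u2)
  colnames(W) <- data$task_names
  W
}

# Squared Euclidean distances between rows of X (n x k) and rows of W (m x k).
cross_dist2 <- function(X, W) {
  d2 <- outer(rowSums(X^2), rowSums(W^2), `+`) - 2 * X %*% t(W)
  pmax(d2, 0)
}

# BMU index per row of X; ties broken by lowest row-major node index.
bmu_rows <- function(X, W) {
  max.col(-cross_dist2(X, W), ties.method = "first")
}

#' Best matching unit
#'
#' The node whose weight vector has the least Euclidean distance to `x`;
#' ties are broken by the lowest row-major node index, keeping training
#' deterministic.
#'
#' @param x a numeric score vector.
#' @param weights node-weight matrix (`n_nodes x n_tasks`).
#' @return the winning node index.
#' @export
best_matching_unit <- function(x, weights) {
  weights <- as.matrix(weights)
  if (length(x) != ncol(weights)) {
    stop("dimension mismatch between `x` and `weights`", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  bmu_rows(matrix(x, 1L), weights)[1L]
}

# One batch cycle: every node's weight becomes the mean of the inputs whose
# BMU lies within `radius` of it on the lattice; nodes with an empty buffer
# keep their weights. All updates are concurrent.
batch_cycle <- function(X, W, gdist, radius) {
  bmu <- bmu_rows(X, W)
  counts <- tabulate(bmu, nbins = nrow(W))
  sums <- matrix(0, nrow(W), ncol(W))
  nz <- which(counts > 0)
  if (length(nz)) {
    sums[nz, ] <- rowsum(X, bmu, reorder = TRUE)
  }
  member <- gdist <= radius            # node i's buffer pools BMU-nodes j
  num <- member %*% sums
  den <- as.vector(member %*% counts)
  upd <- den > 0
  W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  W
}

#' Train a batch self-organizing map
#'
#' Runs `ordering_steps` batch cycles with the boxcar neighbourhood shrinking
#' per [neighbourhood_size()] (cycle `t` uses radius `ND(t)`), followed by
#' `fine_tune_steps` cycles in which each node is updated only from the
#' inputs for which it is the BMU. Nodes whose buffer is empty keep their
#' weights; buffers are cleared every cycle. Training is fully deterministic
#' given the data and configuration.
#'
#' @param data a [score_table()].
#' @param config a [som_config()].
#' @return an object of class `som_model`: `weights` (n_nodes x n_tasks),
#'   `grid` (per-node lattice coordinates), `config`, `task_names` and
#'   `quantization_error` on the training data.
#' @export
batch_train <- function(data, config = som_config()) {
  stopifnot(inherits(data, "score_table"), inherits(config, "som_config"))
  X <- data$scores
  if (nrow(X) == 0L) stop("empty training data", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite scores", call. = FALSE)
  W <- initialize_weights(data, config)
  gdist <- grid_distance_matrix(config)
  for (t in seq_len(config$ordering_steps)) {
    r <- neighbourhood_size(t, config$initial_neighbourhood, config$ordering_steps)
    W <- batch_cycle(X, W, gdist, r)
  }
  for (t in seq_len(config$fine_tune_steps)) {
    W <- batch_cycle(X, W, gdist, 0) # radius 0: BMU-only neighbourhood
  }
  model <- structure(
    list(weights = W, grid = grid_coords(config), config = config,
         task_names = data$task_names, quantization_error = NA_real_),
    class = "som_model"
  )
  model$quantization_error <- quantization_error(model, data)
  model
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %dx%d %s lattice, %d tasks, quantization error %.3f\n",
              x$config$grid_rows, x$config$grid_cols, x$config$topology,
              length(x$task_names), x$quantization_error))
  invisible(x)
}

#' Quantization error
#'
#' Mean Euclidean distance between the input vectors and their best matching
#' units; the fit measure reported for a trained map.
#'
#' @param model a [batch_train()] model.
#' @param data a [score_table()] with matching tasks.
#' @return the mean input-to-BMU distance.
#' @export
quantization_error <- function(model, data) {
  stopifnot(inherits(model, "som_model"), inherits(data, "score_table"))
  check_same_tasks(model$task_names, data$task_names)
  X <- data$scores
  if (nrow(X) == 0L) stop("empty data", call. = FALSE)
  d2 <- cross_dist2(X, model$weights)
  bmu <- max.col(-d2, ties.method = "first")
  mean(sqrt(d2[cbind(seq_len(nrow(X)), bmu)]))
}

#' Extract component planes
#'
#' One plane per task: plane `k` is column `k` of the node-weight matrix,
#' i.e. the map's representation of that task over the lattice.
#'
#' @param model a [batch_train()] model.
#' @return a named list of numeric vectors of length `n_nodes`.
#' @export
component_planes <- function(model) {
  stopifnot(inherits(model, "som_model"))
  planes <- lapply(seq_along(model$task_names),
                   function(k) unname(model$weights[, k]))
  names(planes) <- model$task_names
  planes
}

#' Map participants to their BMUs
#'
#' @param model a [batch_train()] model.
#' @param data a [score_table()] with matching tasks.
#' @return an integer vector of node indices, one per participant.
#' @export
map_to_bmus <- function(model, data) {
  stopifnot(inherits(model, "som_model"), inherits(data, "score_table"))
  check_same_tasks(model$task_names, data$task_names)
  bmu_rows(data$scores, model$weights)
}

#' Serialize a SOM model to JSON
#'
#' Writes the configuration, task names, grid shape and row-major weight
#' matrix at full floating-point precision, so [read_som()] restores a
#' bit-identical model.
#'
#' @param model a [batch_train()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_som <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  payload <- list(
    format = "cogsom/som-model/1",
    config = unclass(model$config),
    task_names = model$task_names,
    grid_rows = model$config$grid_rows,
    grid_cols = model$config$grid_cols,
    weights = asplit(unname(model$weights), 1L),
    quantization_error = model$quantization_error
  )
  json_write(payload, path)
}

#' Restore a SOM model written by [write_som()]
#'
#' @param path path to the JSON document.
#' @return a `som_model`.
#' @export
read_som <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cogsom/som-model/1")) {
    stop("not a serialized SOM model: ", path, call. = FALSE)
  }
  config <- do.call(som_config, p$config[c("grid_rows", "grid_cols",
                                           "initial_neighbourhood",
                                           "ordering_steps", "fine_tune_steps",
                                           "topology", "grid_metric", "seed")])
  W <- matrix(as.numeric(p$weights), nrow = config$grid_rows * config$grid_cols)
  colnames(W) <- p$task_names
  structure(
    list(weights = W, grid = grid_coords(config), config = config,
         task_names = p$task_names,
         quantization_error = p$quantization_error),
    class = "som_model"
  )
}
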