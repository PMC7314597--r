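# Brute-force reference implementations and small fixture builders. These
# stay deliberately naive (explicit loops, exhaustive enumeration) so they
# are independent of the package's vectorized code paths.

random_table <- function(n, k = 4L, seed = 1L, mean = 100, sd = 15,
                         tasks = paste0("task", seq_len(k))) {
  set.seed(seed)
  score_table(matrix(rnorm(n * k, mean, sd), n, k),
              sprintf("S%03d", seq_len(n)), tasks)
}

# Wrap a raw weight matrix as a trained model on a matching lattice.
model_from_weights <- function(W, grid_rows = NULL, grid_cols = NULL,
                               tasks = colnames(W)) {
  n_nodes <- nrow(W)
  if (is.null(grid_rows)) {
    grid_rows <- max(1L, floor(sqrt(n_nodes)))
    while (n_nodes %% grid_rows != 0L) grid_rows <- grid_rows - 1L
    grid_cols <- n_nodes %/% grid_rows
  }
  if (is.null(tasks)) tasks <- paste0("task", seq_len(ncol(W)))
  colnames(W) <- tasks
  cfg <- som_config(grid_rows = grid_rows, grid_cols = grid_cols)
  structure(list(weights = W, grid = cogsom:::grid_coords(cfg), config = cfg,
                 task_names = tasks, quantization_error = NA_real_),
            class = "som_model")
}

# Exhaustive argmin BMU.
bmu_brute <- function(x, W) {
  d <- apply(W, 1L, function(w) sqrt(sum((x - w)^2)))
  which.min(d) # returns the first (lowest index) minimum
}

# One batch cycle by explicit loops over nodes and inputs.
batch_cycle_brute <- function(X, W, gdist, radius) {
  bmu <- apply(X, 1L, bmu_brute, W = W)
  W_new <- W
  for (i in seq_len(nrow(W))) {
    members <- which(gdist[i, bmu] <= radius)
    if (length(members)) {
      W_new[i, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  W_new
}

quantization_error_brute <- function(W, X) {
  mean(apply(X, 1L, function(x) {
    min(apply(W, 1L, function(w) sqrt(sum((x - w)^2))))
  }))
}

knn_predict_brute <- function(W, observed, target_col, obs_cols, k) {
  d <- apply(W[, obs_cols, drop = FALSE], 1L,
             function(w) sqrt(sum((observed - w)^2)))
  nn <- order(d)[seq_len(k)]
  dk <- d[nn]; tk <- W[nn, target_col]
  if (any(dk == 0)) return(mean(tk[dk == 0]))
  sum((1 / dk) * tk) / sum(1 / dk)
}

# All permutations of 1..n (n <= 7 keeps this enumerable).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- matrix(seq_len(n)[-first][sub], nrow(sub))
    cbind(first, rest, deparse.level = 0)
  }))
}

# Exhaustive shuffled-prediction p (no add-one: exact over the full group).
exhaustive_perm_p <- function(predicted, true_scores) {
  perms <- permutations(length(predicted))
  observed <- mean(abs(predicted - true_scores))
  nulls <- apply(perms, 1L, function(p) mean(abs(predicted[p] - true_scores)))
  mean(nulls <= observed)
}

# Exhaustive two-sided label-permutation p for a mean difference.
exhaustive_label_p <- function(a, b) {
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  observed <- abs(mean(a) - mean(b))
  nulls <- apply(idx, 2L, function(i) abs(mean(pooled[i]) - mean(pooled[-i])))
  mean(nulls >= observed - 1e-12)
}

# Minimum within-cluster SS over every assignment of n points to k
# non-empty clusters.
kmeans_brute <- function(X, k) {
  n <- nrow(X)
  best <- list(ss = Inf, labels = NULL)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    if (length(unique(lab)) != k) next
    ss <- 0
    for (g in seq_len(k)) {
      pts <- X[lab == g, , drop = FALSE]
      ss <- ss + sum(sweep(pts, 2L, colMeans(pts))^2)
    }
    if (ss < best$ss) best <- list(ss = ss, labels = lab)
  }
  best
}

# Mutually orthogonal planes around a mean of 100: sample correlation of
# every plane pair is exactly zero.
orthogonal_planes <- function(n_nodes, n_tasks, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n_nodes * n_tasks), n_nodes))))[, -1]
  Q * 10 + 100
}
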