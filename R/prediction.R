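#' Predict a held-out task score from the K nearest map nodes
#'
#' Finds the `k` nodes closest (Euclidean) to the participant's scores on
#' the observed tasks, then returns a distance-weighted mean of those nodes'
#' values on the target task. The default weighting is inverse distance
#' (`w_i = (1/d_i) / sum_j (1/d_j)`), the simplest scheme under which the
#' closest node has the highest weight; if any node matches the observed
#' sub-vector exactly, the unweighted mean of the zero-distance nodes is
#' returned.
#'
#' @param model a [batch_train()] model.
#' @param observed named numeric vector covering every task except
#'   `target_task`.
#' @param target_task the task to predict.
#' @param k number of nearest nodes (default 3).
#' @param weighting `"inverse"` (default), `"inverse_squared"` or
#'   `"uniform"`.
#' @return the predicted score.
#' @export
knn_predict <- function(model, observed, target_task, k = 3L,
                        weighting = c("inverse", "inverse_squared", "uniform")) {
  stopifnot(inherits(model, "som_model"))
  weighting <- match.arg(weighting)
  if (!target_task %in% model$task_names) {
    stop("unknown target task: ", target_task, call. = FALSE)
  }
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (k > nrow(model$weights)) stop("`k` exceeds the number of nodes", call. = FALSE)
  obs_tasks <- setdiff(model$task_names, target_task)
  if (is.null(names(observed))) {
    if (length(observed) != length(obs_tasks)) {
      stop("`observed` must cover all tasks except the target", call. = FALSE)
    }
    names(observed) <- obs_tasks
  }
  if (!all(obs_tasks %in% names(observed))) {
    stop("`observed` is missing task(s): ",
         paste(setdiff(obs_tasks, names(observed)), collapse = ", "), call. = FALSE)
  }
  x <- observed[obs_tasks]
  sub <- model$weights[, obs_tasks, drop = FALSE]
  # direct differences (not the expanded-square form): an exact sub-vector
  # match must yield a distance of exactly zero
  d <- sqrt(rowSums(sweep(sub, 2L, x)^2))
  nn <- order(d)[seq_len(k)] # order() is stable: ties at lower node index first
  dk <- d[nn]
  tk <- model$weights[nn, target_task]
  if (any(dk == 0)) return(mean(tk[dk == 0]))
  w <- switch(weighting,
              inverse = 1 / dk,
              inverse_squared = 1 / dk^2,
              uniform = rep(1, k))
  sum(w * tk) / sum(w)
}

new_permutation_result <- function(observed, null_values, p, seed) {
  structure(
    list(observed_statistic = observed, null_values = null_values,
         n_resamples = length(null_values), p_value = p, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4f, p = %.4g (%d resamples)\n",
              x$observed_statistic, x$p_value, x$n_resamples))
  invisible(x)
}

#' Shuffled-prediction permutation p-value
#'
#' Observed statistic: mean absolute difference between predicted and true
#' scores. Each null value re-pairs the predictions with the true scores by
#' a random shuffle. By default small p means the intact pairing predicts
#' better than chance: `p = (1 + #\{null <= observed\}) / (1 + n_shuffles)`
#' (add-one convention, so p is never exactly 0). `direction = "paper"`
#' gives the complementary proportion of null values greater than the
#' observed error.
#'
#' @param predicted,true_scores numeric vectors of equal length >= 2.
#' @param n_shuffles number of random shuffles.
#' @param seed integer seed.
#' @param direction `"better_than_chance"` (default) or `"paper"`.
#' @return a `permutation_result`.
#' @export
permutation_p <- function(predicted, true_scores, n_shuffles = 1000L, seed = 1L,
                          direction = c("better_than_chance", "paper")) {
  direction <- match.arg(direction)
  if (length(predicted) != length(true_scores)) {
    stop("`predicted` and `true_scores` must have equal length", call. = FALSE)
  }
  n <- length(predicted)
  if (n < 2L) stop("need at least 2 paired scores", call. = FALSE)
  observed <- mean(abs(predicted - true_scores))
  null_values <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    mean(abs(predicted[sample.int(n)] - true_scores))
  }, 0))
  p <- switch(direction,
              better_than_chance = (1 + sum(null_values <= observed)) / (1 + n_shuffles),
              paper = (1 + sum(null_values > observed)) / (1 + n_shuffles))
  new_permutation_result(observed, null_values, p, seed)
}

# Predict every task of every row of `table` from the other tasks; returns
# an n x n_tasks matrix of predictions.
predict_all_tasks <- function(model, table, k) {
  tasks <- model$task_names
  preds <- matrix(NA_real_, nrow(table$scores), length(tasks),
                  dimnames = list(NULL, tasks))
  for (tk in tasks) {
    obs_tasks <- setdiff(tasks, tk)
    for (i in seq_len(nrow(table$scores))) {
      preds[i, tk] <- knn_predict(model, table$scores[i, obs_tasks], tk, k)
    }
  }
  preds
}

#' Leave-N-out cross-validation of map representativeness
#'
#' Per repetition: hold out `floor(holdout_fraction * N)` participants,
#' train a SOM on the remainder, predict each held-out participant's score
#' on every task from their other three (K-nearest-node prediction), and
#' record per-task mean absolute errors; `shuffles_per_rep` random
#' re-pairings of the predictions give the chance-level errors.
#'
#' The observed statistic per task is the mean MAE over repetitions. With
#' `null_pooling = "cohort"` (default) chance level is represented by
#' `shuffles_per_rep` cohort-level re-pairings: null replicate `s` draws one
#' permutation of the whole cohort and, in every repetition, compares each
#' held-out participant's prediction against the target score of the
#' participant that permutation assigns to them. Each null value is
#' therefore a mean over the same repetitions as the observed statistic and
#' shares its cross-repetition dependence (repetitions reuse one cohort),
#' which keeps the test calibrated under the null even for large `n_reps`.
#' `"flat"` is the naive alternative: fresh within-holdout shuffles per
#' repetition, all individual shuffle MAEs pooled into one flat null set.
#' That compares a low-variance average against single draws and is not
#' calibrated; it is kept for comparability with analyses that used it.
#'
#' @param data a [score_table()].
#' @param som_config a [som_config()].
#' @param n_reps number of CV repetitions.
#' @param holdout_fraction fraction held out per repetition (in (0, 1)).
#' @param k nearest nodes used for prediction.
#' @param shuffles_per_rep shuffles per repetition for the null.
#' @param seed integer master seed.
#' @param null_pooling `"cohort"` or `"flat"`.
#' @return an object of class `cv_report`: `per_task_mae`, `per_task_p`,
#'   `rep_errors` (reps x tasks MAE matrix), `null_mae` (null values per
#'   task), plus the settings.
#' @export
cross_validate <- function(data, som_config = cogsom::som_config(),
                           n_reps = 1000L, holdout_fraction = 0.2, k = 3L,
                           shuffles_per_rep = 100L, seed = 1L,
                           null_pooling = c("cohort", "flat")) {
  stopifnot(inherits(data, "score_table"))
  null_pooling <- match.arg(null_pooling)
  n <- nrow(data$scores)
  n_hold <- floor(holdout_fraction * n)
  if (n_hold < 1L || n - n_hold < 3L) {
    stop(sprintf("degenerate split: %d held out of %d", n_hold, n), call. = FALSE)
  }
  tasks <- data$task_names
  rep_errors <- matrix(NA_real_, n_reps, length(tasks),
                       dimnames = list(NULL, tasks))
  null_arr <- array(NA_real_, c(n_reps, shuffles_per_rep, length(tasks)))
  # cohort-level null pairings, one permutation per null replicate, shared
  # by every repetition
  sigma <- if (null_pooling == "cohort") {
    vapply(seq_len(shuffles_per_rep), function(s) {
      with_seed(derive_seed(seed, "cv-null", s), sample.int(n))
    }, integer(n))
  }
  for (r in seq_len(n_reps)) {
    hold <- with_seed(derive_seed(seed, "cv-split", r), sample.int(n, n_hold))
    train <- score_table(data$scores[-hold, , drop = FALSE],
                         data$participant_id[-hold], tasks)
    test <- score_table(data$scores[hold, , drop = FALSE],
                        data$participant_id[hold], tasks)
    model <- batch_train(train, som_config)
    preds <- predict_all_tasks(model, test, k)
    errs <- abs(preds - test$scores)
    rep_errors[r, ] <- colMeans(errs)
    if (null_pooling == "cohort") {
      for (s in seq_len(shuffles_per_rep)) {
        null_arr[r, s, ] <- colMeans(abs(preds - data$scores[sigma[hold, s], ,
                                                             drop = FALSE]))
      }
    } else {
      null_arr[r, , ] <- with_seed(derive_seed(seed, "cv-shuffle", r), {
        vapply(seq_len(shuffles_per_rep), function(s) {
          perm <- sample.int(n_hold)
          colMeans(abs(preds[perm, , drop = FALSE] - test$scores))
        }, numeric(length(tasks)))
      }) |> t()
    }
  }
  per_task_mae <- colMeans(rep_errors)
  null_mae <- if (null_pooling == "cohort") {
    apply(null_arr, c(2, 3), mean) # null replicate s averaged over reps
  } else {
    matrix(null_arr, ncol = length(tasks))
  }
  colnames(null_mae) <- tasks
  per_task_p <- vapply(seq_along(tasks), function(j) {
    (1 + sum(null_mae[, j] <= per_task_mae[j])) / (1 + nrow(null_mae))
  }, 0)
  names(per_task_p) <- tasks
  structure(
    list(per_task_mae = per_task_mae, per_task_p = per_task_p,
         rep_errors = rep_errors, null_mae = null_mae, n_reps = n_reps,
         holdout_fraction = holdout_fraction, k_neighbours = k,
         shuffles_per_rep = shuffles_per_rep, null_pooling = null_pooling,
         seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d reps, holdout %.0f%%, k = %d\n",
              x$n_reps, 100 * x$holdout_fraction, x$k_neighbours))
  print(data.frame(task = names(x$per_task_mae),
                   mae = round(x$per_task_mae, 2),
                   p = signif(x$per_task_p, 3), row.names = NULL))
  invisible(x)
}

#' Generalization of a trained map to an external sample
#'
#' Leave-one-task-out prediction of every score in an external table using a
#' map trained elsewhere, with shuffled-prediction permutation nulls per
#' task.
#'
#' @param model a [batch_train()] model.
#' @param external a [score_table()] over the same tasks.
#' @param k nearest nodes used for prediction.
#' @param n_shuffles shuffles for the null distribution.
#' @param seed integer seed.
#' @return a list with `per_task_mae`, `per_task_p`, `tests` (a
#'   `permutation_result` per task) and `predictions`.
#' @export
generalization_errors <- function(model, external, k = 3L,
                                  n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(model, "som_model"), inherits(external, "score_table"))
  check_same_tasks(model$task_names, external$task_names)
  preds <- predict_all_tasks(model, external, k)
  tasks <- model$task_names
  tests <- lapply(seq_along(tasks), function(j) {
    permutation_p(preds[, j], external$scores[, j], n_shuffles,
                  derive_seed(seed, "generalization", tasks[j]))
  })
  names(tests) <- tasks
  list(per_task_mae = vapply(tests, `[[`, 0, "observed_statistic"),
       per_task_p = vapply(tests, `[[`, 0, "p_value"),
       tests = tests, predictions = preds)
}

#' Permutation comparison of two prediction-error sets
#'
#' Observed statistic: absolute difference of the two group means. The null
#' reassigns the pooled errors to the two groups at random; the two-sided
#' add-one p-value is the proportion of null differences at least as large.
#'
#' @param errors_a,errors_b numeric vectors of per-observation errors.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return a `permutation_result`.
#' @export
compare_error_sets <- function(errors_a, errors_b, n_perm = 10000L, seed = 1L) {
  if (!length(errors_a) || !length(errors_b)) {
    stop("both error sets must be nonempty", call. = FALSE)
  }
  observed <- abs(mean(errors_a) - mean(errors_b))
  pooled <- c(errors_a, errors_b)
  na <- length(errors_a)
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), na)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  }, 0))
  p <- (1 + sum(null_values >= observed)) / (1 + n_perm)
  new_permutation_result(observed, null_values, p, seed)
}
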