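#' Component-plane similarity matrix
#'
#' Pairwise Pearson correlations between the component planes of a trained
#' map: entry (i, j) correlates task i's and task j's node-weight elements
#' over all nodes. High correlation means the map represents the two tasks
#' with overlapping topology.
#'
#' @param model a [batch_train()] model.
#' @return a symmetric `n_tasks x n_tasks` matrix with unit diagonal,
#'   class `similarity_matrix`.
#' @export
similarity_matrix <- function(model) {
  stopifnot(inherits(model, "som_model"))
  W <- model$weights
  sds <- apply(W, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant component plane for task(s): ",
         paste(model$task_names[sds == 0], collapse = ", "), call. = FALSE)
  }
  m <- stats::cor(W)
  diag(m) <- 1
  dimnames(m) <- list(model$task_names, model$task_names)
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' @export
print.similarity_matrix <- function(x, ...) {
  print(round(unclass(x), 3))
  invisible(x)
}

resample_pair_r <- function(W, a, b, idx) {
  x <- W[idx, a]; y <- W[idx, b]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Bootstrap test for a training-induced change in one task-pair similarity
#'
#' Resamples node indices with replacement, independently within the pre-
#' and the post-training map (node identities do not correspond across
#' separately trained maps) but jointly for the two tasks within a map,
#' recomputes the two plane correlations, and stores the difference
#' `r_post - r_pre`. With the default two-sided rule the null of no change
#' is rejected when 0 falls outside the central `1 - alpha` nearest-rank
#' percentile interval of the `B` differences; `tail_rule = "paper"`
#' rejects when 0 falls in the bottom or top `alpha` tail (a 2-alpha total
#' rule, kept for comparability).
#'
#' @param model_pre,model_post trained maps over the same task set.
#' @param task_a,task_b the task pair.
#' @param B bootstrap resamples (default 10000).
#' @param alpha significance level.
#' @param seed integer seed.
#' @param tail_rule `"two_sided"` (default) or `"paper"`.
#' @return an object of class `plane_difference_test`: `pair`, `r_pre`,
#'   `r_post`, `boot_differences`, `ci`, `alpha`, `reject`, `direction`.
#' @export
bootstrap_pair_difference <- function(model_pre, model_post, task_a, task_b,
                                      B = 10000L, alpha = 0.05, seed = 1L,
                                      tail_rule = c("two_sided", "paper")) {
  stopifnot(inherits(model_pre, "som_model"), inherits(model_post, "som_model"))
  tail_rule <- match.arg(tail_rule)
  check_same_tasks(model_pre$task_names, model_post$task_names)
  for (tk in c(task_a, task_b)) {
    if (!tk %in% model_pre$task_names) stop("unknown task: ", tk, call. = FALSE)
  }
  for (m in list(pre = model_pre, post = model_post)) {
    if (stats::sd(m$weights[, task_a]) == 0 || stats::sd(m$weights[, task_b]) == 0) {
      stop("constant source component plane; correlation undefined", call. = FALSE)
    }
  }
  r_pre <- stats::cor(model_pre$weights[, task_a], model_pre$weights[, task_b])
  r_post <- stats::cor(model_post$weights[, task_a], model_post$weights[, task_b])
  n_pre <- nrow(model_pre$weights)
  n_post <- nrow(model_post$weights)
  boot <- with_seed(seed, vapply(seq_len(B), function(b) {
    rp <- rq <- NA_real_
    for (try in 1:100) { # redraw when a resampled plane is constant
      rp <- resample_pair_r(model_pre$weights, task_a, task_b,
                            sample.int(n_pre, replace = TRUE))
      if (!is.na(rp)) break
    }
    for (try in 1:100) {
      rq <- resample_pair_r(model_post$weights, task_a, task_b,
                            sample.int(n_post, replace = TRUE))
      if (!is.na(rq)) break
    }
    if (is.na(rp) || is.na(rq)) {
      stop("persistent constant resampled plane", call. = FALSE)
    }
    rq - rp
  }, 0))
  ci <- if (tail_rule == "two_sided") {
    c(nearest_rank(boot, alpha / 2), nearest_rank(boot, 1 - alpha / 2))
  } else {
    c(nearest_rank(boot, alpha), nearest_rank(boot, 1 - alpha))
  }
  structure(
    list(pair = c(task_a, task_b), r_pre = r_pre, r_post = r_post,
         boot_differences = boot, ci = ci, alpha = alpha,
         tail_rule = tail_rule, reject = (0 < ci[1]) || (0 > ci[2]),
         direction = sign(stats::median(boot)), seed = seed),
    class = "plane_difference_test"
  )
}

#' @export
print.plane_difference_test <- function(x, ...) {
  cat(sprintf("<plane_difference_test> %s-%s: r_pre %.3f, r_post %.3f, CI [%.3f, %.3f], %s\n",
              x$pair[1], x$pair[2], x$r_pre, x$r_post, x$ci[1], x$ci[2],
              if (x$reject) "CHANGED" else "no change"))
  invisible(x)
}

#' Bootstrap difference tests for all task pairs
#'
#' Runs [bootstrap_pair_difference()] for every unordered task pair
#' (6 pairs for four tasks) with per-pair seeds derived deterministically
#' from `seed`.
#'
#' @inheritParams bootstrap_pair_difference
#' @return a list of `plane_difference_test`, named `"taskA|taskB"`.
#' @export
compare_all_pairs <- function(model_pre, model_post, B = 10000L, alpha = 0.05,
                              seed = 1L, tail_rule = c("two_sided", "paper")) {
  tail_rule <- match.arg(tail_rule)
  tasks <- model_pre$task_names
  out <- list()
  for (i in seq_len(length(tasks) - 1L)) {
    for (j in seq((i + 1L), length(tasks))) {
      key <- paste(tasks[i], tasks[j], sep = "|")
      out[[key]] <- bootstrap_pair_difference(
        model_pre, model_post, tasks[i], tasks[j], B = B, alpha = alpha,
        seed = derive_seed(seed, "pair", tasks[i], tasks[j]),
        tail_rule = tail_rule)
    }
  }
  out
}
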