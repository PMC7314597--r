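#' Allocate a paired pre/post cohort to baseline clusters
#'
#' Maps every participant to a baseline cluster at both timepoints (via
#' their BMU on the baseline map, which is never retrained on the training
#' cohort) and computes per-task gain scores (post minus pre).
#'
#' @param model the baseline [batch_train()] model.
#' @param solution the baseline [kmeans_nodes()] solution.
#' @param pre,post [score_table()]s with identical participant sets in
#'   identical order.
#' @return a data.frame of class `transition_table`: `participant_id`,
#'   `cluster_pre`, `cluster_post`, one `gain_<task>` column per task, and
#'   any covariates carried by `pre`.
#' @export
allocate_timepoints <- function(model, solution, pre, post) {
  stopifnot(inherits(pre, "score_table"), inherits(post, "score_table"))
  if (!identical(pre$participant_id, post$participant_id)) {
    off <- union(setdiff(pre$participant_id, post$participant_id),
                 setdiff(post$participant_id, pre$participant_id))
    stop("pre/post participant sets differ",
         if (length(off)) paste0(": ", paste(off, collapse = ", "))
         else " (ordering mismatch)", call. = FALSE)
  }
  check_same_tasks(model$task_names, pre$task_names)
  check_same_tasks(model$task_names, post$task_names)
  a_pre <- allocate_to_clusters(model, solution, pre)
  a_post <- allocate_to_clusters(model, solution, post)
  gains <- post$scores - pre$scores
  colnames(gains) <- paste0("gain_", pre$task_names)
  out <- data.frame(participant_id = pre$participant_id,
                    cluster_pre = a_pre$cluster, cluster_post = a_post$cluster,
                    gains, row.names = NULL, check.names = FALSE)
  if (!is.null(pre$covariates)) out <- cbind(out, pre$covariates)
  attr(out, "task_names") <- pre$task_names
  class(out) <- c("transition_table", class(out))
  out
}

#' Classify transition interest groups
#'
#' Participants are assigned to exactly one of five mutually exclusive
#' categories based on their pre-to-post cluster transition: movers into
#' cluster 1, 2 or 3 (only from outside that cluster), stayers in cluster 4
#' (there at both timepoints), and `other` for every remaining transition
#' (including participants already in clusters 1-3 at pre-training).
#'
#' @param transitions an [allocate_timepoints()] table with cluster labels
#'   in 1..4.
#' @return a factor of length `nrow(transitions)` with levels
#'   `mover_to_1`, `mover_to_2`, `mover_to_3`, `stayer_in_4`, `other`.
#' @export
interest_groups <- function(transitions) {
  pre <- transitions$cluster_pre
  post <- transitions$cluster_post
  if (!all(pre %in% 1:4) || !all(post %in% 1:4)) {
    stop("cluster labels must lie in 1..4", call. = FALSE)
  }
  g <- rep("other", length(pre))
  for (c in 1:3) g[pre != c & post == c] <- paste0("mover_to_", c)
  g[pre == 4 & post == 4] <- "stayer_in_4"
  factor(g, levels = c("mover_to_1", "mover_to_2", "mover_to_3",
                       "stayer_in_4", "other"))
}

#' Gain-score and covariate comparison of interest groups
#'
#' Per task: one-way ANOVA of gain scores across the interest groups (the
#' `other` remainder is excluded, as are groups with fewer than 2 members,
#' with a warning) plus Tukey HSD pairwise comparisons. The same ANOVA +
#' Tukey is run on a baseline covariate (e.g. a fluid-intelligence score
#' assessed prior to training). Also reports per-group per-task gain means
#' and SDs and the 4 x 4 pre/post transition count matrix.
#'
#' @param transitions an [allocate_timepoints()] table.
#' @param grouping the matching [interest_groups()] factor.
#' @param covariate_name optional name of a covariate column in
#'   `transitions`.
#' @param alpha significance level for the Tukey decisions.
#' @return a list with `gain_anova` (per task), `gain_tukey` (per task),
#'   `covariate_anova`, `covariate_tukey`, `group_summary`,
#'   `transition_counts`, `groups_used`.
#' @export
trajectory_report <- function(transitions, grouping = interest_groups(transitions),
                              covariate_name = NULL, alpha = 0.05) {
  tasks <- attr(transitions, "task_names")
  stopifnot(!is.null(tasks), length(grouping) == nrow(transitions))
  keep_levels <- setdiff(levels(grouping), "other")
  sizes <- table(factor(grouping, levels = keep_levels))
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(keep_levels)) {
    warning("interest group(s) with n < 2 excluded: ",
            paste(setdiff(keep_levels, usable), collapse = ", "), call. = FALSE)
  }
  if (length(usable) < 2L) stop("need at least 2 non-empty interest groups", call. = FALSE)
  split_by_group <- function(values) {
    out <- lapply(usable, function(g) values[grouping == g])
    names(out) <- usable
    out
  }
  gain_anova <- list(); gain_tukey <- list()
  for (tk in tasks) {
    groups <- split_by_group(transitions[[paste0("gain_", tk)]])
    gain_anova[[tk]] <- oneway_anova(groups)
    gain_tukey[[tk]] <- tukey_hsd(groups, alpha)
  }
  covariate_anova <- covariate_tukey <- NULL
  if (!is.null(covariate_name)) {
    if (!covariate_name %in% names(transitions)) {
      stop("covariate not found: ", covariate_name, call. = FALSE)
    }
    cov_groups <- split_by_group(transitions[[covariate_name]])
    covariate_anova <- oneway_anova(cov_groups)
    covariate_tukey <- tukey_hsd(cov_groups, alpha)
  }
  group_summary <- do.call(rbind, lapply(usable, function(g) {
    rows <- grouping == g
    do.call(rbind, lapply(tasks, function(tk) {
      v <- transitions[[paste0("gain_", tk)]][rows]
      data.frame(group = g, task = tk, n = sum(rows),
                 mean_gain = mean(v), sd_gain = stats::sd(v))
    }))
  }))
  rownames(group_summary) <- NULL
  transition_counts <- table(
    pre = factor(transitions$cluster_pre, levels = 1:4),
    post = factor(transitions$cluster_post, levels = 1:4))
  list(gain_anova = gain_anova, gain_tukey = gain_tukey,
       covariate_anova = covariate_anova, covariate_tukey = covariate_tukey,
       group_summary = group_summary,
       transition_counts = unclass(transition_counts), groups_used = usable)
}

#' Treatment-by-time interaction (two-way mixed ANOVA)
#'
#' Per task: classical mixed ANOVA with a between-subjects treatment factor
#' and a two-level within-subjects time factor (pre/post), returning the
#' interaction term. With only two time levels no sphericity correction is
#' needed.
#'
#' @param group_labels treatment group per participant (e.g. adaptive vs
#'   non-adaptive).
#' @param pre_scores,post_scores paired [score_table()]s.
#' @return a data.frame with `task`, `F`, `df1`, `df2`, `p` for the
#'   group-by-time interaction.
#' @export
treatment_time_interaction <- function(group_labels, pre_scores, post_scores) {
  stopifnot(inherits(pre_scores, "score_table"), inherits(post_scores, "score_table"))
  if (!identical(pre_scores$participant_id, post_scores$participant_id)) {
    stop("pre/post rows must be paired by participant", call. = FALSE)
  }
  if (length(group_labels) != nrow(pre_scores$scores)) {
    stop("one group label per participant required", call. = FALSE)
  }
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop("need at least two treatment groups", call. = FALSE)
  n <- length(g)
  out <- lapply(pre_scores$task_names, function(tk) {
    df <- data.frame(
      id = factor(rep(pre_scores$participant_id, 2L)),
      group = rep(g, 2L),
      time = factor(rep(c("pre", "post"), each = n), levels = c("pre", "post")),
      score = c(pre_scores$scores[, tk], post_scores$scores[, tk])
    )
    fit <- stats::aov(score ~ group * time + Error(id), data = df)
    within <- summary(fit)[["Error: Within"]][[1]]
    row <- which(trimws(rownames(within)) == "group:time")
    F_stat <- within[row, "F value"]
    p <- within[row, "Pr(>F)"]
    ss_int <- within[row, "Sum Sq"]
    ss_err <- within["Residuals", "Sum Sq"]
    scale <- sum((df$score - mean(df$score))^2)
    if (is.nan(F_stat) || ss_int + ss_err <= 1e-10 * max(scale, 1)) {
      # parallel trajectories: the within stratum carries (numerically) no
      # variance beyond the time main effect, so the ratio is meaningless
      F_stat <- if (ss_int <= 1e-10 * max(scale, 1)) 0 else Inf
      p <- if (F_stat == 0) 1 else 0
    }
    data.frame(task = tk, F = F_stat,
               df1 = within[row, "Df"],
               df2 = within["Residuals", "Df"],
               p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
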