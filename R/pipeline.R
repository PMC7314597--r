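#' Pipeline configuration
#'
#' Bundles every setting of the five-step analysis: data sources (paths to
#' baseline/pre/post score tables, or simulation specs), SOM parameters,
#' cross-validation, similarity-bootstrap and clustering settings, the
#' covariate used for trajectory prediction, and a master seed from which
#' all stage seeds are derived. Defaults equal the published analysis
#' settings (8 x 8 map, INS = 2, 10 + 2 steps, 20% holdout, 1000 CV reps,
#' 100 shuffles/rep, k = 3 prediction neighbours, B = 10000, K = 4
#' clusters).
#'
#' @param baseline_path,pre_path,post_path optional CSV paths; when omitted
#'   the cohorts are simulated from `baseline_spec` / `training_spec`.
#' @param baseline_spec,training_spec [cohort_spec()]s used when no paths
#'   are given.
#' @param som a [som_config()].
#' @param cv_reps,holdout,k_neighbours,cv_shuffles cross-validation settings.
#' @param rsa_B,rsa_alpha,rsa_tail_rule similarity bootstrap settings.
#' @param k_clusters,kmeans_restarts,stability_reps clustering settings.
#' @param covariate covariate column used in the trajectory report.
#' @param seed master seed.
#' @param out_dir output directory for stage artifacts.
#' @return a validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(baseline_path = NULL, pre_path = NULL,
                            post_path = NULL, baseline_spec = NULL,
                            training_spec = NULL, som = som_config(),
                            cv_reps = 1000L, holdout = 0.2, k_neighbours = 3L,
                            cv_shuffles = 100L, rsa_B = 10000L,
                            rsa_alpha = 0.05,
                            rsa_tail_rule = c("two_sided", "paper"),
                            k_clusters = 4L, kmeans_restarts = 100L,
                            stability_reps = 25L, covariate = "gf_score",
                            seed = 1L, out_dir = "cogsom-output") {
  rsa_tail_rule <- match.arg(rsa_tail_rule)
  have_paths <- !is.null(baseline_path) && !is.null(pre_path) && !is.null(post_path)
  if (!have_paths) {
    if (is.null(baseline_spec)) baseline_spec <- default_baseline_spec(seed = derive_seed(seed, "baseline-cohort"))
    if (is.null(training_spec)) training_spec <- default_training_spec(seed = derive_seed(seed, "training-cohort"))
  }
  if (holdout <= 0 || holdout >= 1) {
    stop("`holdout` must lie strictly between 0 and 1", call. = FALSE)
  }
  assert_scalar_number(cv_reps, "cv_reps", lower = 1)
  assert_scalar_number(cv_shuffles, "cv_shuffles", lower = 1)
  assert_scalar_number(rsa_B, "rsa_B", lower = 1)
  assert_scalar_number(k_clusters, "k_clusters", lower = 2)
  assert_scalar_number(stability_reps, "stability_reps", lower = 2)
  stopifnot(inherits(som, "som_config"))
  structure(
    list(baseline_path = baseline_path, pre_path = pre_path,
         post_path = post_path, baseline_spec = baseline_spec,
         training_spec = training_spec, som = som, cv_reps = as.integer(cv_reps),
         holdout = holdout, k_neighbours = as.integer(k_neighbours),
         cv_shuffles = as.integer(cv_shuffles), rsa_B = as.integer(rsa_B),
         rsa_alpha = rsa_alpha, rsa_tail_rule = rsa_tail_rule,
         k_clusters = as.integer(k_clusters),
         kmeans_restarts = as.integer(kmeans_restarts),
         stability_reps = as.integer(stability_reps), covariate = covariate,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

config_fingerprint <- function(config) {
  skim <- unclass(config)
  skim$baseline_spec <- NULL; skim$training_spec <- NULL
  skim$out_dir <- NULL # where artifacts land does not change what is computed
  skim$som <- unclass(skim$som)
  fnv1a32(paste(
    jsonlite::toJSON(skim, auto_unbox = TRUE, digits = I(17), null = "null"),
    collapse = ""))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

sim_df <- function(sim) {
  data.frame(task = names(sim), value = unname(sim))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: baseline cohort load/simulation, baseline SOM
#' training, leave-N-out cross-validation, generalization to the pre- and
#' post-training samples, pre/post SOM training, component-plane similarity
#' difference tests, node clustering with silhouette and retrain-stability
#' diagnostics, timepoint allocation, and the trajectory (interest-group)
#' report. Every artifact is written under `config$out_dir` and listed in
#' `manifest.json` with the config fingerprint and seeds, and the whole run
#' is reproducible from the master seed.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  fingerprint <- config_fingerprint(config)
  artifacts <- list()
  emit <- function(stage, file) {
    artifacts[[stage]] <<- c(artifacts[[stage]] %||% character(), file)
  }

  # -- stage 1: cohorts ------------------------------------------------
  stage_log("cohorts", "seed %d, fingerprint %s", config$seed, fingerprint)
  if (!is.null(config$baseline_path)) {
    baseline <- read_score_table(config$baseline_path)
    pre <- read_score_table(config$pre_path)
    post <- read_score_table(config$post_path)
  } else {
    baseline <- simulate_baseline_cohort(config$baseline_spec)
    paired <- simulate_training_cohort(config$training_spec)
    pre <- paired$pre; post <- paired$post
  }
  write_score_table(baseline, file.path(config$out_dir, "baseline_scores.csv"))
  write_score_table(pre, file.path(config$out_dir, "pre_scores.csv"))
  write_score_table(post, file.path(config$out_dir, "post_scores.csv"))
  emit("cohorts", c("baseline_scores.csv", "pre_scores.csv", "post_scores.csv"))

  # -- stage 2: baseline SOM -------------------------------------------
  som_base <- batch_train(baseline, config$som)
  stage_log("som_baseline", "quantization error %.3f", som_base$quantization_error)
  write_som(som_base, file.path(config$out_dir, "som_baseline.json"))
  emit("som_baseline", "som_baseline.json")

  # -- stage 3: cross-validation ---------------------------------------
  cv <- cross_validate(baseline, config$som, n_reps = config$cv_reps,
                       holdout_fraction = config$holdout,
                       k = config$k_neighbours,
                       shuffles_per_rep = config$cv_shuffles,
                       seed = derive_seed(config$seed, "cv"))
  stage_log("cross_validation", "MAE %s",
            paste(sprintf("%.2f", cv$per_task_mae), collapse = "/"))
  json_write(list(per_task_mae = as.list(cv$per_task_mae),
                  per_task_p = as.list(cv$per_task_p),
                  n_reps = cv$n_reps, holdout_fraction = cv$holdout_fraction,
                  k_neighbours = cv$k_neighbours,
                  shuffles_per_rep = cv$shuffles_per_rep, seed = cv$seed),
             file.path(config$out_dir, "cv_report.json"))
  long <- data.frame(rep = rep(seq_len(nrow(cv$rep_errors)), ncol(cv$rep_errors)),
                     task = rep(colnames(cv$rep_errors), each = nrow(cv$rep_errors)),
                     mae = as.vector(cv$rep_errors))
  utils::write.csv(long, file.path(config$out_dir, "cv_errors.csv"), row.names = FALSE)
  emit("cross_validation", c("cv_report.json", "cv_errors.csv"))

  # -- stage 4: generalization -----------------------------------------
  gen <- list(
    pre = generalization_errors(som_base, pre, k = config$k_neighbours,
                                n_shuffles = config$cv_shuffles * 10L,
                                seed = derive_seed(config$seed, "gen-pre")),
    post = generalization_errors(som_base, post, k = config$k_neighbours,
                                 n_shuffles = config$cv_shuffles * 10L,
                                 seed = derive_seed(config$seed, "gen-post")))
  json_write(lapply(gen, function(g) list(per_task_mae = as.list(g$per_task_mae),
                                          per_task_p = as.list(g$per_task_p))),
             file.path(config$out_dir, "generalization.json"))
  emit("generalization", "generalization.json")

  # -- stage 5: pre/post SOMs ------------------------------------------
  som_pre <- batch_train(pre, config$som)
  som_post <- batch_train(post, config$som)
  write_som(som_pre, file.path(config$out_dir, "som_pre.json"))
  write_som(som_post, file.path(config$out_dir, "som_post.json"))
  emit("som_prepost", c("som_pre.json", "som_post.json"))

  # -- stage 6: similarity / RSA ---------------------------------------
  sim_pre <- similarity_matrix(som_pre)
  sim_post <- similarity_matrix(som_post)
  utils::write.csv(unclass(sim_pre), file.path(config$out_dir, "similarity_pre.csv"))
  utils::write.csv(unclass(sim_post), file.path(config$out_dir, "similarity_post.csv"))
  rsa <- compare_all_pairs(som_pre, som_post, B = config$rsa_B,
                           alpha = config$rsa_alpha,
                           seed = derive_seed(config$seed, "rsa"),
                           tail_rule = config$rsa_tail_rule)
  stage_log("rsa", "%d of %d pairs changed",
            sum(vapply(rsa, `[[`, TRUE, "reject")), length(rsa))
  json_write(lapply(rsa, function(t) list(
    pair = t$pair, r_pre = t$r_pre, r_post = t$r_post,
    ci = t$ci, alpha = t$alpha, reject = t$reject, direction = t$direction)),
    file.path(config$out_dir, "rsa_tests.json"))
  emit("rsa", c("similarity_pre.csv", "similarity_post.csv", "rsa_tests.json"))

  # -- stage 7: clustering ---------------------------------------------
  solution <- kmeans_nodes(som_base, config$k_clusters, config$kmeans_restarts,
                           seed = derive_seed(config$seed, "kmeans"))
  alloc <- allocate_to_clusters(som_base, solution, baseline)
  sil <- silhouette_scan(som_base, k_range = 2:min(8, nrow(som_base$weights)),
                         seed = derive_seed(config$seed, "silhouette"))
  stab <- stability_analysis(baseline, config$som, config$k_clusters,
                             n_reps = config$stability_reps,
                             seed = derive_seed(config$seed, "stability"))
  stage_log("clustering", "k = %d, stability mean ARI %.3f",
            config$k_clusters, stab$mean)
  json_write(list(k = solution$k, node_labels = solution$node_labels,
                  centroids = asplit(unname(solution$centroids), 1L),
                  inertia = solution$inertia, seed = solution$seed),
             file.path(config$out_dir, "cluster_solution.json"))
  utils::write.csv(alloc, file.path(config$out_dir, "allocations_baseline.csv"),
                   row.names = FALSE)
  json_write(list(silhouette = sil,
                  stability = list(n_reps = stab$n_reps, mean = stab$mean,
                                   min = stab$min)),
             file.path(config$out_dir, "cluster_diagnostics.json"))
  utils::write.csv(profile_summary(alloc, baseline),
                   file.path(config$out_dir, "cluster_profiles.csv"),
                   row.names = FALSE)
  emit("clustering", c("cluster_solution.json", "allocations_baseline.csv",
                       "cluster_diagnostics.json", "cluster_profiles.csv"))

  # -- stage 8: trajectories -------------------------------------------
  transitions <- allocate_timepoints(som_base, solution, pre, post)
  grouping <- interest_groups(transitions)
  cov_name <- if (!is.null(config$covariate) &&
                  config$covariate %in% names(transitions)) config$covariate
  report <- trajectory_report(transitions, grouping, cov_name)
  utils::write.csv(cbind(transitions, interest_group = as.character(grouping)),
                   file.path(config$out_dir, "transitions.csv"), row.names = FALSE)
  json_write(list(
    gain_anova = report$gain_anova,
    covariate = cov_name,
    covariate_anova = report$covariate_anova,
    group_summary = report$group_summary,
    transition_counts = asplit(unname(report$transition_counts), 1L),
    groups_used = report$groups_used),
    file.path(config$out_dir, "trajectory_report.json"))
  emit("trajectories", c("transitions.csv", "trajectory_report.json"))

  manifest <- list(package = "cogsom",
                   config_fingerprint = fingerprint,
                   master_seed = config$seed,
                   stages = artifacts)
  json_write(manifest, file.path(config$out_dir, "manifest.json"))
  stage_log("done", "8 stages in %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}
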