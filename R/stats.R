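#' Pearson correlation with validation
#'
#' Thin validated wrapper around [stats::cor()]: both inputs must have equal
#' length at least 3 and be non-constant, otherwise the correlation is
#' undefined and an error is raised (rather than returning `NA`).
#'
#' @param x,y numeric vectors of equal length.
#' @return the sample Pearson correlation coefficient, in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Cohen's d from pre/post summary statistics
#'
#' Standardized mean difference using the pooled SD of the two timepoints,
#' `d = (m_post - m_pre) / sqrt((sd_pre^2 + sd_post^2) / 2)`. This is the
#' formulation that reproduces published transfer effect sizes from
#' age-standardized working memory assessments when applied to their printed
#' pre/post means and SDs.
#'
#' @param m_pre,sd_pre pre-training mean and SD.
#' @param m_post,sd_post post-training mean and SD.
#' @param n optional sample size, carried through for reporting.
#' @return an object of class `cogsom_effect_size` with elements `d`,
#'   `m_pre`, `sd_pre`, `m_post`, `sd_post`, `n`.
#' @examples
#' cohens_d_from_summary(93.95, 15.58, 100.54, 17.64)$d
#' @export
cohens_d_from_summary <- function(m_pre, sd_pre, m_post, sd_post, n = NULL) {
  assert_scalar_number(m_pre, "m_pre")
  assert_scalar_number(m_post, "m_post")
  if (!is.numeric(sd_pre) || sd_pre <= 0 || !is.numeric(sd_post) || sd_post <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  d <- (m_post - m_pre) / sqrt((sd_pre^2 + sd_post^2) / 2)
  structure(
    list(d = d, m_pre = m_pre, sd_pre = sd_pre, m_post = m_post,
         sd_post = sd_post, n = n),
    class = "cogsom_effect_size"
  )
}

#' @export
print.cogsom_effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (pre %.2f±%.2f, post %.2f±%.2f)\n",
              x$d, x$m_pre, x$sd_pre, x$m_post, x$sd_post))
  invisible(x)
}

#' One-way between-groups ANOVA
#'
#' Classical fixed-effects decomposition with a pooled error term
#' (equal-variance assumption), as used for comparing subgroup score and
#' gain-score profiles.
#'
#' @param groups a list of numeric vectors, one per group (each `n >= 2`).
#' @return a list with `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  F_stat <- unname(fit$statistic)
  p <- unname(fit$p.value)
  if (is.nan(F_stat)) {
    # zero within-group variance: decide by the between-group spread alone
    ss_b <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(y))^2, 0))
    F_stat <- if (ss_b <= 1e-12) 0 else Inf
    p <- if (F_stat == 0) 1 else 0
  }
  list(F = F_stat,
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]),
       p = p)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range post-hoc comparisons of all group-mean pairs with the
#' pooled within-group variance, via [stats::TukeyHSD()].
#'
#' @param groups a list of numeric vectors, one per group. Names, if present,
#'   label the comparisons.
#' @param alpha familywise significance level used for the `reject` column.
#' @return a data.frame with columns `group_a`, `group_b`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `reject`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  nms <- names(groups) %||% as.character(seq_along(groups))
  nms[nms == ""] <- as.character(which(nms == ""))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nms, vapply(groups, length, 1L)), levels = nms)
  tk <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = 1 - alpha)$g
  # zero pooled variance makes p NaN; a zero mean difference is then "no
  # difference" (p = 1), a nonzero one is unambiguous (p = 0)
  bad <- is.nan(tk[, "p adj"])
  tk[bad, "p adj"] <- ifelse(abs(tk[bad, "diff"]) <= 1e-12, 1, 0)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group_a = vapply(pairs, `[`, "", 1L),
    group_b = vapply(pairs, `[`, "", 2L),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    reject = unname(tk[, "p adj"]) < alpha,
    row.names = NULL
  )
}
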