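#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way fixed-effects ANOVA from per-group sample sizes,
#' means and standard deviations alone:
#' \deqn{MS_{between} = \sum_i n_i (m_i - \bar m)^2 / (g - 1), \quad
#'       MS_{within} = \sum_i (n_i - 1) s_i^2 / \sum_i (n_i - 1),}
#' with \eqn{\bar m} the n-weighted grand mean, \eqn{F} their ratio on
#' \eqn{(g - 1, \sum n_i - g)} degrees of freedom. This is the route by
#' which published group tables (mean +/- SD, n) can be re-analysed without
#' raw data.
#'
#' @param summaries A data frame with columns `group` (or `label`), `n`,
#'   `mean`, `sd`; one row per group.
#' @return An `ecs_anova` object: list with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `ms_between`, `ms_within`, `grand_mean`,
#'   `summaries`. Methods: [tidy()], [glance()].
#' @examples
#' s <- tibble::tibble(group = c("A", "B"), n = c(9, 9),
#'                     mean = c(1, 2), sd = c(0.5, 0.6))
#' glance(anova_from_summary(s))
#' @export
anova_from_summary <- function(summaries) {
  s <- as_tibble(summaries)
  if ("label" %in% names(s) && !"group" %in% names(s)) {
    s <- dplyr::rename(s, group = "label")
  }
  need <- c("group", "n", "mean", "sd")
  missing <- setdiff(need, names(s))
  if (length(missing) > 0L) {
    stop_validation("summaries are missing column(s): %s",
                    paste(missing, collapse = ", "))
  }
  if (nrow(s) < 2L) stop_validation("need at least 2 groups")
  if (any(s$n < 2)) stop_validation("every group needs n >= 2")
  if (any(s$sd < 0)) stop_validation("standard deviations must be >= 0")
  g <- nrow(s)
  N <- sum(s$n)
  grand <- sum(s$n * s$mean) / N
  ss_between <- sum(s$n * (s$mean - grand)^2)
  df_between <- g - 1
  df_within <- N - g
  ss_within <- sum((s$n - 1) * s$sd^2)
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f_stat <- if (ms_within > 0) ms_between / ms_within else {
    if (ms_between == 0) NaN else Inf
  }
  p_value <- if (is.finite(f_stat)) {
    pf(f_stat, df_between, df_within, lower.tail = FALSE)
  } else if (is.nan(f_stat)) NA_real_ else 0
  structure(
    list(f_stat = f_stat, df_between = df_between, df_within = df_within,
         p_value = p_value, ms_between = ms_between, ms_within = ms_within,
         grand_mean = grand, summaries = s),
    class = "ecs_anova"
  )
}

#' One-way ANOVA from raw per-group values
#'
#' Computes the between/within sums of squares directly from the raw
#' observations. Algebraically identical to [anova_from_summary()] applied
#' to the groups' exact means, SDs and sizes -- an identity exercised in the
#' test suite.
#'
#' @param data A data frame of raw observations.
#' @param value,group Column names (unquoted) holding the response and the
#'   group label.
#' @return An `ecs_anova` (see [anova_from_summary()]).
#' @export
anova_oneway <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  df <- tibble(v = rlang::eval_tidy(value, data),
               g = as.character(rlang::eval_tidy(group, data)))
  if (any(!is.finite(df$v))) stop_validation("values must be finite")
  counts <- table(df$g)
  if (length(counts) < 2L) stop_validation("need at least 2 groups")
  if (any(counts < 2)) stop_validation("every group needs n >= 2")
  grand <- mean(df$v)
  by_g <- dplyr::summarise(dplyr::group_by(df, .data$g),
                           n = dplyr::n(), m = mean(.data$v),
                           ss = sum((.data$v - mean(.data$v))^2))
  ss_between <- sum(by_g$n * (by_g$m - grand)^2)
  ss_within <- sum(by_g$ss)
  g_n <- nrow(by_g)
  df_between <- g_n - 1
  df_within <- nrow(df) - g_n
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f_stat <- if (ms_within > 0) ms_between / ms_within else {
    if (ss_between == 0) NaN else Inf
  }
  p_value <- if (is.finite(f_stat)) {
    pf(f_stat, df_between, df_within, lower.tail = FALSE)
  } else if (is.nan(f_stat)) NA_real_ else 0
  structure(
    list(f_stat = f_stat, df_between = df_between, df_within = df_within,
         p_value = p_value, ms_between = ms_between, ms_within = ms_within,
         grand_mean = grand,
         summaries = tibble(group = by_g$g, n = by_g$n, mean = by_g$m,
                            sd = sqrt(by_g$ss / (by_g$n - 1)))),
    class = "ecs_anova"
  )
}

#' @export
print.ecs_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Fisher's LSD post-hoc comparisons
#'
#' Unadjusted pairwise t tests using the pooled ANOVA error term:
#' \eqn{t = (m_i - m_j) / \sqrt{MS_{within}(1/n_i + 1/n_j)}}, two-sided p on
#' the within-group degrees of freedom. No multiplicity adjustment -- that
#' is the least-significant-difference procedure.
#'
#' @param summaries Group summary table as in [anova_from_summary()].
#' @param ms_within,df_within Pooled error mean square and its df, usually
#'   from the fitted `ecs_anova`.
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `mean_diff`, `t_stat`, `p_value`.
#' @export
lsd_posthoc <- function(summaries, ms_within, df_within) {
  s <- as_tibble(summaries)
  if ("label" %in% names(s) && !"group" %in% names(s)) {
    s <- dplyr::rename(s, group = "label")
  }
  if (df_within < 1) stop_validation("`df_within` must be >= 1")
  if (ms_within < 0) stop_validation("`ms_within` must be >= 0")
  pairs <- utils::combn(nrow(s), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- s$mean[i] - s$mean[j]
    se <- sqrt(ms_within * (1 / s$n[i] + 1 / s$n[j]))
    t_stat <- if (se > 0) diff / se else if (diff == 0) 0 else Inf * sign(diff)
    p <- if (is.finite(t_stat)) 2 * pt(-abs(t_stat), df_within) else 0
    tibble(group1 = s$group[i], group2 = s$group[j], mean_diff = diff,
           t_stat = t_stat, p_value = p)
  })
}

#' Pearson correlation with t-based inference
#'
#' Product-moment correlation with the exact-null t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} and a two-sided p on \eqn{n - 2}
#' degrees of freedom. `pearson_p_from_r()` applies the same transform to a
#' published correlation coefficient and sample size, allowing printed
#' (r, p) pairs to be checked without raw data.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-degenerate).
#' @return A tibble row: `r`, `n`, `t_stat`, `p_value`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop_validation("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop_validation("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_validation("zero variance in `x` or `y`")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tibble(r = r, n = n, t_stat = r_to_t(r, n), p_value = pearson_p_from_r(r, n))
}

r_to_t <- function(r, n) {
  if (abs(r) >= 1) return(Inf * sign(r))
  r * sqrt((n - 2) / (1 - r^2))
}

#' @rdname pearson_test
#' @param r Correlation coefficient in [-1, 1].
#' @param n Sample size (>= 3).
#' @export
pearson_p_from_r <- function(r, n) {
  if (abs(r) > 1) stop_validation("`r` must lie in [-1, 1]")
  if (n < 3) stop_validation("`n` must be >= 3")
  t <- r_to_t(r, n)
  if (!is.finite(t)) return(0)
  2 * pt(-abs(t), n - 2)
}

#' Published F statistics of the four ECS observables
#'
#' The omnibus one-way ANOVA F values reported for \eqn{D^*}, \eqn{k'},
#' Vd-max% and t1/2 across the four study groups. Used together with
#' [study_groups()] by the sample-size auditor and the acceptance checks.
#'
#' @return A tibble: `parameter`, `f_value`.
#' @export
study_f_values <- function() {
  tibble(parameter = c("d_eff", "k_clear", "vd_max_pct", "t_half"),
         f_value = c(5.774, 20.00, 12.81, 23.35))
}

## Group summary table for one parameter, pulled from a study_groups()-style
## spec tibble.
summaries_for <- function(specs, parameter, n = NULL) {
  m <- specs[[paste0(parameter, "_mean")]]
  s <- specs[[paste0(parameter, "_sd")]]
  if (is.null(m) || is.null(s)) {
    stop_validation("no mean/sd columns for parameter `%s`", parameter)
  }
  tibble(group = specs$label, n = n %||% specs$n, mean = m, sd = s)
}

#' Audit candidate equal sample sizes against published F statistics
#'
#' Published group tables often omit the final per-group n (attrition after
#' behavioural exclusion). Because the summary-statistics F is proportional
#' to n at fixed means/SDs (equal groups), the printed F values pin n down.
#' This auditor recomputes each parameter's F from the printed means/SDs for
#' every candidate n and reports which n reproduces all printed F values
#' simultaneously.
#'
#' @param specs Group specification tibble ([study_groups()] layout).
#' @param f_values Tibble of printed F values (`parameter`, `f_value`),
#'   default [study_f_values()].
#' @param n_candidates Candidate equal per-group sizes. Default 5:10.
#' @param tol Maximum relative deviation from every printed F for a
#'   candidate to count as consistent. Default 0.02, comfortably above
#'   printed-summary rounding and far below the ~11% jump between adjacent
#'   n.
#' @return A tibble: `n`, per-parameter recomputed `f_<parameter>` columns,
#'   `max_rel_dev`, `consistent`; with attribute `n_consistent` (the
#'   consistent n values).
#' @export
audit_group_n <- function(specs = study_groups(), f_values = study_f_values(),
                          n_candidates = 5:10, tol = 0.02) {
  validate_group_specs(specs)
  rows <- purrr::map_dfr(n_candidates, function(n) {
    devs <- purrr::pmap_dbl(f_values, function(parameter, f_value) {
      f <- anova_from_summary(summaries_for(specs, parameter, n = n))$f_stat
      abs(f / f_value - 1)
    })
    fs <- purrr::pmap_dbl(f_values, function(parameter, f_value) {
      anova_from_summary(summaries_for(specs, parameter, n = n))$f_stat
    })
    out <- tibble(n = n)
    out[paste0("f_", f_values$parameter)] <- as.list(fs)
    out$max_rel_dev <- max(devs)
    out$consistent <- max(devs) <= tol
    out
  })
  structure(rows, n_consistent = rows$n[rows$consistent])
}
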