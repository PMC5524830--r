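#' Tidiers for fitted objects
#'
#' Broom-style methods: `tidy()` returns one row per term/quantity,
#' `glance()` a one-row model summary, `augment()` observation-level
#' results.
#'
#' @param x A fitted object (`point_source_fit`, `ecs_anova`, `vd_curve`).
#' @param ... Unused.
#' @name ecstrace-tidiers
NULL

#' @rdname ecstrace-tidiers
#' @export
tidy.point_source_fit <- function(x, ...) {
  tibble(term = c("d_eff", "k_clear", "dose_eff"),
         estimate = c(x$d_eff, x$k_clear, x$dose_eff),
         unit = c("mm^2/s", "1/s", "mol"))
}

#' @rdname ecstrace-tidiers
#' @export
glance.point_source_fit <- function(x, ...) {
  tibble(d_eff = x$d_eff, k_clear = x$k_clear, dose_eff = x$dose_eff,
         converged = x$converged, resid_norm = x$resid_norm,
         n_iter = x$n_iter, n_obs = x$n_obs, loss = x$loss)
}

#' @rdname ecstrace-tidiers
#' @export
augment.point_source_fit <- function(x, ...) {
  dplyr::mutate(x$data, .resid = .data$conc - .data$fitted)
}

#' @rdname ecstrace-tidiers
#' @export
tidy.ecs_anova <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    meansq = c(x$ms_between, x$ms_within),
    statistic = c(x$f_stat, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @rdname ecstrace-tidiers
#' @export
glance.ecs_anova <- function(x, ...) {
  tibble(statistic = x$f_stat, df = x$df_between, df.residual = x$df_within,
         p.value = x$p_value, ms.between = x$ms_between,
         ms.within = x$ms_within)
}

#' @rdname ecstrace-tidiers
#' @export
tidy.vd_curve <- function(x, ...) {
  as_tibble(unclass(x)[c("time_s", "vd_mm3", "vd_pct")])
}

#' @rdname ecstrace-tidiers
#' @export
glance.vd_curve <- function(x, ...) {
  tibble(vd_max_mm3 = attr(x, "vd_max_mm3"),
         vd_max_pct = attr(x, "vd_max_pct"),
         t_max_s = attr(x, "t_max_s"),
         t_half_s = attr(x, "t_half_s"),
         t_half_defined = attr(x, "t_half_defined"),
         brain_volume_mm3 = attr(x, "brain_volume"))
}
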