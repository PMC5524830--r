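#' Convert signal enhancement to tracer concentration
#'
#' Inverts the linear enhancement model used by the renderer:
#' `concentration = (signal - baseline) / beta`, clipped at zero (negative
#' excursions are pure noise). Grid, times and mask are preserved.
#'
#' @param series An `image_series`.
#' @param baseline Pre-contrast signal level; defaults to the value stored
#'   in the series.
#' @param beta Signal per unit concentration (> 0); defaults to the stored
#'   value.
#' @return A `conc_series`: same layout as the input with `volumes` holding
#'   concentration in mol/mm^3.
#' @export
signal_to_concentration <- function(series, baseline = series$baseline,
                                    beta = series$beta) {
  stopifnot(inherits(series, "image_series"))
  if (!is.numeric(beta) || beta <= 0) {
    stop_validation("`beta` must be a positive number")
  }
  structure(
    list(volumes = pmax((series$volumes - baseline) / beta, 0),
         times = series$times, voxel_size = series$voxel_size,
         origin = series$origin, brain_mask = series$brain_mask,
         noise_sd = series$noise_sd / beta, center = series$center),
    class = "conc_series"
  )
}

## Separable 3-point boxcar smoother (zero-padded edges). Used only to
## define the fit/Vd masks under noise: averaging 27 voxels cuts the noise
## SD about five-fold, so threshold crossings by pure noise become
## negligible while the smooth tracer field is barely biased. Fitted values
## are always the raw ones.
smooth3 <- function(a) {
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    p <- aperm(a, perm)
    m <- dim(p)[1]
    q <- p
    q[2:m, , ] <- q[2:m, , ] + p[1:(m - 1), , ]
    q[1:(m - 1), , ] <- q[1:(m - 1), , ] + p[2:m, , ]
    a <- aperm(q / 3, order(perm))
  }
  a
}

## Smoothed copy of a 4-D concentration array (per time point).
smooth_series <- function(vols) {
  out <- vols
  for (i in seq_len(dim(vols)[4])) out[, , , i] <- smooth3(vols[, , , i])
  out
}

#' Fit the point-source diffusion-clearance model to a concentration series
#'
#' Estimates \eqn{(D^*, k')} and the effective dose from all suprathreshold
#' voxel observations by bounded nonlinear least squares. Observations are
#' the raw concentrations of voxels whose locally smoothed value exceeds
#' `mask_threshold` times the smoothed series peak. Starting values come
#' from the log-linear structure of the model: regressing
#' \eqn{\log C + (3/2)\log t} on \eqn{r^2/t} and \eqn{t} gives
#' \eqn{-1/(4D^*)} and \eqn{-k'} as slopes.
#'
#' Two loss functions are available. The default `"linear"` minimises
#' squared residuals in concentration, the maximum-likelihood fit under
#' additive Gaussian image noise. `"log"` minimises squared residuals of
#' log-concentration, which weights faint voxels heavily and is biased at
#' low signal-to-noise; it is retained for noise-free work and comparison.
#'
#' @param conc A `conc_series` (see [signal_to_concentration()]).
#' @param center Injection-site world coordinates, mm; defaults to the
#'   centre stored in the series.
#' @param mask_threshold Mask cut as a fraction of the (smoothed) series
#'   peak. Default 0.05.
#' @param loss `"linear"` (default) or `"log"`.
#' @param alpha ECS volume fraction used to convert the fitted amplitude
#'   \eqn{Q/\alpha} into an effective dose.
#' @param lower,upper Bounds on `c(d_eff, k_clear)`; the defaults are a
#'   generous physical envelope (`d_eff` in [1e-5, 1e-2] mm^2/s, `k_clear`
#'   in [0, 1e-2] 1/s).
#' @param ftol Convergence tolerance on the objective.
#' @param maxiter Iteration cap.
#' @return A `point_source_fit` with elements `d_eff`, `k_clear`,
#'   `dose_eff`, `converged`, `resid_norm`, `n_iter`, `n_obs`, `loss` and
#'   the observation table `data` (columns `r_mm`, `time_s`, `conc`,
#'   `fitted`). Non-convergence is flagged, not thrown.
#' @export
fit_point_source <- function(conc, center = conc$center,
                             mask_threshold = 0.05,
                             loss = c("linear", "log"), alpha = 0.2,
                             lower = c(1e-5, 0), upper = c(1e-2, 1e-2),
                             ftol = 1e-10, maxiter = 200L) {
  stopifnot(inherits(conc, "conc_series"))
  loss <- match.arg(loss)
  nt <- length(conc$times)
  if (nt < 3L) stop_validation("need at least 3 time points to fit")
  d <- dim(conc$volumes)
  grid <- list(n = d[1], voxel_size = conc$voxel_size, origin = conc$origin)
  r <- grid_distances(grid, center)

  sm <- smooth_series(conc$volumes)
  peak <- max(sm)
  if (peak <= 0) {
    abort("no tracer signal above zero in the series",
          class = "ecstrace_fit_error")
  }
  keep <- sm >= mask_threshold * peak & conc$volumes > 0
  n_obs <- sum(keep)
  if (n_obs < 20L) {
    abort(sprintf("only %d suprathreshold voxel observations (need >= 20)", n_obs),
          class = "ecstrace_fit_error")
  }
  rr <- rep(as.vector(r), nt)[as.vector(keep)]
  tt <- rep(conc$times, each = prod(d[1:3]))[as.vector(keep)]
  cv <- conc$volumes[keep]

  ## log-linear initialisation
  y <- log(cv)
  x1 <- rr^2 / tt
  init <- coef(lm(y + 1.5 * log(tt) ~ x1 + tt))
  d0 <- min(max(-1 / (4 * init[[2]]), lower[1] * 2), upper[1] / 2)
  k0 <- min(max(-init[[3]], lower[2] + 1e-7), upper[2] / 2)
  a0 <- init[[1]] + 1.5 * log(4 * pi * d0)

  model_log <- function(p) {
    p[1] - 1.5 * log(4 * pi * p[2] * tt) - rr^2 / (4 * p[2] * tt) - p[3] * tt
  }
  scale <- max(cv)
  resfn <- if (loss == "linear") {
    function(p) (cv - exp(model_log(p))) / scale
  } else {
    function(p) y - model_log(p)
  }
  fit <- minpack.lm::nls.lm(
    par = c(a0, d0, k0),
    lower = c(-60, lower[1], lower[2]), upper = c(10, upper[1], upper[2]),
    fn = resfn,
    control = minpack.lm::nls.lm.control(ftol = ftol, maxiter = maxiter))
  converged <- fit$info %in% 1:4
  p <- fit$par
  structure(
    list(d_eff = p[2], k_clear = p[3], dose_eff = exp(p[1]) * alpha,
         log_amp = p[1], alpha = alpha, converged = converged,
         resid_norm = sqrt(sum(fit$fvec^2)), n_iter = fit$niter,
         n_obs = n_obs, loss = loss, info = fit$info,
         data = tibble(r_mm = rr, time_s = tt, conc = cv,
                       fitted = exp(model_log(p)))),
    class = "point_source_fit"
  )
}

#' @export
print.point_source_fit <- function(x, ...) {
  cat("<point_source_fit>\n")
  cat(sprintf("  D*  = %.4g mm^2/s\n  k'  = %.4g 1/s\n  dose_eff = %.4g mol\n",
              x$d_eff, x$k_clear, x$dose_eff))
  cat(sprintf("  %d obs, %d iterations, %sconverged (loss = %s)\n",
              x$n_obs, x$n_iter, if (x$converged) "" else "NOT ", x$loss))
  invisible(x)
}

#' Distribution-volume curve from a measured concentration series
#'
#' Counts in-mask voxels whose (locally smoothed) concentration meets the
#' detection threshold at each time and multiplies by the voxel volume; the
#' percentage denominator is the brain-mask volume. Metrics come from
#' [curve_metrics()].
#'
#' @inheritParams fit_point_source
#' @param theta Concentration threshold, mol/mm^3 (> 0).
#' @param brain_mask Boolean volume; defaults to the mask stored in the
#'   series.
#' @param smooth Smooth the field before thresholding (default `TRUE`; the
#'   raw field is used when the series is noise-free).
#' @return A `vd_curve` (see [vd_curve()]).
#' @export
vd_from_series <- function(conc, theta, brain_mask = conc$brain_mask,
                           smooth = TRUE) {
  stopifnot(inherits(conc, "conc_series"))
  if (!is.numeric(theta) || theta <= 0) {
    stop_domain("`theta` must be strictly positive")
  }
  if (is.null(brain_mask) || sum(brain_mask) == 0) {
    stop_validation("brain mask is empty")
  }
  vols <- conc$volumes
  if (smooth && !is.null(conc$noise_sd) && conc$noise_sd > 0) {
    vols <- smooth_series(vols)
  }
  nt <- length(conc$times)
  vox_vol <- conc$voxel_size^3
  vd <- vapply(seq_len(nt), function(i) {
    sum(vols[, , , i][brain_mask] >= theta) * vox_vol
  }, numeric(1))
  new_vd_curve(conc$times, vd, sum(brain_mask) * vox_vol)
}

#' Analyse one animal's image series end to end
#'
#' Chains the estimation stages: signal-to-concentration inversion, the
#' point-source fit for \eqn{(D^*, k')}, the voxel-count distribution-volume
#' curve, and its peak/half-life metrics. Stage failures are rethrown with
#' the stage identified; a non-converged fit is recorded, not thrown.
#'
#' @param series An `image_series`.
#' @param theta Detection threshold for the Vd curve, mol/mm^3. Default
#'   `NULL` uses 3 times the image noise SD (in concentration units); a
#'   noise-free series then requires an explicit `theta`.
#' @param animal_id,group Identifiers copied into the output row.
#' @inheritParams fit_point_source
#' @return A one-row tibble: `animal_id`, `group`, `est_d_eff`,
#'   `est_k_clear`, `est_dose_eff`, `vd_max_pct`, `t_max_s`, `t_half_s`,
#'   `t_half_defined`, `converged`, `resid_norm`, `n_iter`, `n_obs`.
#' @export
analyze_animal <- function(series, theta = NULL, animal_id = "animal",
                           group = NA_character_, mask_threshold = 0.05,
                           loss = "linear", alpha = 0.2) {
  stopifnot(inherits(series, "image_series"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed for %s: %s", stage, animal_id,
                    conditionMessage(e)),
            class = "ecstrace_stage_error", parent = e)
    })
  }
  conc <- run_stage("signal_to_concentration", signal_to_concentration(series))
  if (is.null(theta)) {
    if (is.null(series$noise_sd) || series$noise_sd <= 0) {
      stop_validation(
        "`theta` must be supplied explicitly for a noise-free series")
    }
    theta <- 3 * series$noise_sd / series$beta
  }
  fit <- run_stage("fit_point_source",
                   fit_point_source(conc, mask_threshold = mask_threshold,
                                    loss = loss, alpha = alpha))
  curve <- run_stage("vd_from_series", vd_from_series(conc, theta))
  tibble(
    animal_id = animal_id, group = group,
    est_d_eff = fit$d_eff, est_k_clear = fit$k_clear,
    est_dose_eff = fit$dose_eff,
    vd_max_pct = attr(curve, "vd_max_pct"),
    t_max_s = attr(curve, "t_max_s"),
    t_half_s = attr(curve, "t_half_s"),
    t_half_defined = attr(curve, "t_half_defined"),
    converged = fit$converged, resid_norm = fit$resid_norm,
    n_iter = fit$n_iter, n_obs = fit$n_obs
  )
}

#' Render and analyse a mechanistic cohort
#'
#' For each animal of a mechanistic cohort (see [draw_cohort()]), renders a
#' seeded synthetic image series from its true parameters and runs
#' [analyze_animal()]. Animals whose analysis fails are kept in the output
#' with `NA` estimates and the failure message in `error`.
#'
#' @param cohort Mechanistic cohort tibble.
#' @param grid Voxel grid (default [image_grid()]).
#' @param times Acquisition times, s.
#' @param noise_sd Noise SD in signal units (`NULL` = 2% of each animal's
#'   peak enhancement; 0 = noise-free).
#' @param theta Vd threshold (`NULL` = 3 x noise SD in concentration units).
#' @inheritParams render_image_series
#' @inheritParams analyze_animal
#' @return A tibble with one row per animal (columns of [analyze_animal()]
#'   plus `true_d_eff`, `true_k_clear`, `error`).
#' @export
analyze_cohort <- function(cohort, grid = NULL, times = default_times(),
                           beta = 1e9, baseline = 100, noise_sd = NULL,
                           theta = NULL, mask_threshold = 0.05,
                           loss = "linear", alpha = 0.2) {
  stopifnot(all(c("animal_id", "group", "true_d_eff", "true_k_clear",
                  "sub_seed") %in% names(cohort)))
  rows <- purrr::pmap(
    cohort[, c("animal_id", "group", "true_d_eff", "true_k_clear", "sub_seed")],
    function(animal_id, group, true_d_eff, true_k_clear, sub_seed) {
      params <- tracer_params(d_eff = true_d_eff, k_clear = true_k_clear,
                              alpha = alpha)
      g <- grid %||% image_grid(center = params$center)
      out <- tryCatch({
        series <- render_image_series(params, grid = g, times = times,
                                      beta = beta, baseline = baseline,
                                      noise_sd = noise_sd, seed = sub_seed)
        analyze_animal(series, theta = theta, animal_id = animal_id,
                       group = group, mask_threshold = mask_threshold,
                       loss = loss, alpha = alpha)
      }, error = function(e) {
        tibble(animal_id = animal_id, group = group,
               est_d_eff = NA_real_, est_k_clear = NA_real_,
               est_dose_eff = NA_real_, vd_max_pct = NA_real_,
               t_max_s = NA_real_, t_half_s = NA_real_,
               t_half_defined = NA, converged = FALSE,
               resid_norm = NA_real_, n_iter = NA_integer_,
               n_obs = NA_integer_, error = conditionMessage(e))
      })
      if (!"error" %in% names(out)) out$error <- NA_character_
      out$true_d_eff <- true_d_eff
      out$true_k_clear <- true_k_clear
      out
    })
  dplyr::bind_rows(rows)
}
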