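#' Default study-group specifications
#'
#' The four treatment groups of the study design this package emulates --
#' a 6-OHDA Parkinson's-disease model group (PD), a Madopar-treated PD
#' group, a sham-operated group and an untreated control group -- with the
#' published per-group means and standard deviations of the four ECS
#' observables. \eqn{D^*} and \eqn{k'} serve as mechanistic ground truth for
#' the synthetic generator; Vd-max% and t1/2 are additionally used in
#' empirical mode, where all four observables are drawn directly.
#'
#' Sample size defaults to 9 per group, the unique equal-n value jointly
#' consistent with all four published F statistics (see [audit_group_n()]).
#'
#' @param n Animals per group.
#' @return A tibble with one row per group: `label`, `n`, and
#'   `<param>_mean` / `<param>_sd` columns for `d_eff` (mm^2/s), `k_clear`
#'   (1/s), `vd_max_pct` (%) and `t_half` (s).
#' @export
study_groups <- function(n = 9L) {
  tibble(
    label = c("PD", "Madopar", "sham", "control"),
    n = as.integer(n),
    d_eff_mean = c(2.744, 2.340, 2.078, 2.023) * 1e-4,
    d_eff_sd = c(0.341, 0.448, 0.326, 0.501) * 1e-4,
    k_clear_mean = c(2.153, 1.109, 0.879, 0.854) * 1e-4,
    k_clear_sd = c(0.610, 0.333, 0.262, 0.355) * 1e-4,
    vd_max_pct_mean = c(2.392, 2.153, 2.091, 2.054),
    vd_max_pct_sd = c(0.185, 0.102, 0.110, 0.090),
    t_half_mean = c(97.839, 84.084, 67.374, 69.649) * 60,
    t_half_sd = c(11.874, 8.157, 7.222, 7.017) * 60
  )
}

validate_group_specs <- function(specs) {
  need <- c("label", "n", "d_eff_mean", "d_eff_sd", "k_clear_mean", "k_clear_sd")
  missing <- setdiff(need, names(specs))
  if (length(missing) > 0L) {
    stop_validation("group specs are missing column(s): %s",
                    paste(missing, collapse = ", "))
  }
  if (anyDuplicated(specs$label)) {
    stop_validation("group labels must be unique within a cohort")
  }
  if (any(specs$n < 2)) stop_validation("each group needs n >= 2")
  sd_cols <- grep("_sd$", names(specs), value = TRUE)
  for (col in sd_cols) {
    if (any(specs[[col]] < 0, na.rm = TRUE)) {
      stop_validation("negative SD in column `%s`", col)
    }
  }
  invisible(specs)
}

## Normal draw truncated at zero (rejection); group means sit several SDs
## above zero so rejections are rare.
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Draw a synthetic cohort of animals
#'
#' Draws per-animal parameters for each group, independently from normal
#' distributions with the group's means/SDs, truncated at zero. In
#' `"mechanistic"` mode only the mechanistic pair \eqn{(D^*, k')} is drawn;
#' Vd-max% and t1/2 are left to be measured by the estimation pipeline from
#' rendered images. In `"empirical"` mode all four observables are drawn
#' directly, which exercises the group-statistics stage in isolation.
#'
#' Each animal receives a sub-seed derived deterministically from the master
#' seed, its group label and its index, so cohorts are reproducible and
#' stable under reordering of groups in a configuration.
#'
#' @param specs Group specification tibble, as from [study_groups()].
#' @param seed Master seed (integer).
#' @param mode `"mechanistic"` or `"empirical"`.
#' @return A tibble with one row per animal: `animal_id`, `group`, `mode`,
#'   `sub_seed`, and parameter columns (`true_d_eff`, `true_k_clear` in
#'   mechanistic mode; `d_eff`, `k_clear`, `vd_max_pct`, `t_half_s` in
#'   empirical mode).
#' @export
draw_cohort <- function(specs = study_groups(), seed = 1L,
                        mode = c("mechanistic", "empirical")) {
  mode <- match.arg(mode)
  validate_group_specs(specs)
  if (mode == "empirical") {
    need <- c("vd_max_pct_mean", "vd_max_pct_sd", "t_half_mean", "t_half_sd")
    if (!all(need %in% names(specs))) {
      stop_validation("empirical mode needs vd_max_pct and t_half mean/sd columns")
    }
  }
  rows <- purrr::pmap(specs, function(label, n, ...) {
    spec <- list(...)
    purrr::map(seq_len(n), function(i) {
      sub_seed <- spawn_seed(seed, label, i)
      set.seed(sub_seed)
      row <- tibble(
        animal_id = sprintf("%s_%02d", label, i),
        group = label, mode = mode, sub_seed = sub_seed
      )
      if (mode == "mechanistic") {
        row$true_d_eff <- rnorm_trunc0(1, spec$d_eff_mean, spec$d_eff_sd)
        row$true_k_clear <- rnorm_trunc0(1, spec$k_clear_mean, spec$k_clear_sd)
      } else {
        row$d_eff <- rnorm_trunc0(1, spec$d_eff_mean, spec$d_eff_sd)
        row$k_clear <- rnorm_trunc0(1, spec$k_clear_mean, spec$k_clear_sd)
        row$vd_max_pct <- rnorm_trunc0(1, spec$vd_max_pct_mean, spec$vd_max_pct_sd)
        row$t_half_s <- rnorm_trunc0(1, spec$t_half_mean, spec$t_half_sd)
      }
      row
    })
  })
  dplyr::bind_rows(rows)
}

#' Acquisition time grid of the emulated protocol
#'
#' Twelve volumes 15 min apart, the first 10 min post-injection -- a span
#' that covers both the rise and the decay of the distribution volume for
#' the parameter ranges of the study groups (published half-lives of
#' 67--98 min).
#'
#' @return Times in seconds.
#' @export
default_times <- function() 600 + 0:11 * 900

#' Voxel grid centred on the injection site
#'
#' @param n Voxels per axis.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param center World coordinates (mm) the grid is centred on; the default
#'   is the substantia nigra injection site.
#' @return A list with `n`, `voxel_size` and `origin` (world coordinates of
#'   the centre of voxel index (0,0,0); voxel centres are
#'   `origin + index * voxel_size`).
#' @export
image_grid <- function(n = 64L, voxel_size = 0.2, center = c(-4.8, 1.9, -7.8)) {
  check_scalar_number(voxel_size, "voxel_size", lower = 0, strict_lower = TRUE)
  if (n < 8) stop_validation("grid needs at least 8 voxels per axis")
  list(n = as.integer(n), voxel_size = voxel_size,
       origin = as.numeric(center) - (n / 2) * voxel_size)
}

## Voxel-centre distances (mm) from a world-space point, as an n^3 array.
grid_distances <- function(grid, center) {
  ax <- function(j) grid$origin[j] + (0:(grid$n - 1)) * grid$voxel_size
  sqrt(outer(outer((ax(1) - center[1])^2, (ax(2) - center[2])^2, "+"),
             (ax(3) - center[3])^2, "+"))
}

## Ellipsoidal brain mask around the grid centre; semi-axes are a fixed
## fraction of the half-extent so the reference volume scales with the grid.
brain_mask_ellipsoid <- function(grid, fraction = 0.9) {
  half <- (grid$n * grid$voxel_size) / 2
  semi <- fraction * half
  gc <- grid$origin + (grid$n / 2) * grid$voxel_size
  ax <- function(j) grid$origin[j] + (0:(grid$n - 1)) * grid$voxel_size
  q <- outer(outer(((ax(1) - gc[1]) / semi)^2, ((ax(2) - gc[2]) / semi)^2, "+"),
             ((ax(3) - gc[3]) / semi)^2, "+")
  q <= 1
}

#' Render a synthetic dynamic image series
#'
#' Forward-renders the analytic point-source concentration field onto a
#' voxel grid at each acquisition time and converts it to signal by a linear
#' enhancement model: `signal = baseline + beta * concentration + noise`,
#' with i.i.d. additive Gaussian noise per voxel and time point. A fixed
#' ellipsoidal brain mask around the grid centre provides the reference
#' volume for Vd percentages.
#'
#' @inheritParams tracer_concentration
#' @param grid Voxel grid from [image_grid()].
#' @param times Acquisition times, s (> 0, strictly increasing).
#' @param beta Signal per unit concentration (signal units per mol/mm^3).
#' @param baseline Pre-contrast signal level.
#' @param noise_sd Noise standard deviation in signal units; `NULL` (the
#'   default) uses 2% of the peak noise-free enhancement, 0 renders
#'   noise-free.
#' @param seed Seed for the noise draw (`NULL` leaves the RNG state alone).
#' @return An `image_series`: list with `volumes` (4-D array, x-y-z-time),
#'   `times`, `voxel_size`, `origin`, `brain_mask`, `noise_sd`, plus the
#'   rendering constants `beta`, `baseline` and `center`.
#' @export
render_image_series <- function(params, grid = image_grid(center = params$center),
                                times = default_times(), beta = 1e9,
                                baseline = 100, noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(params, "tracer_params"))
  check_scalar_number(beta, "beta", lower = 0, strict_lower = TRUE)
  if (length(times) == 0L || any(times <= 0) || any(diff(times) <= 0)) {
    stop_validation("`times` must be strictly increasing and positive")
  }
  lo <- grid$origin
  hi <- grid$origin + (grid$n - 1) * grid$voxel_size
  if (any(params$center < lo) || any(params$center > hi)) {
    stop_validation("injection center (%.2f, %.2f, %.2f) lies outside the grid",
                    params$center[1], params$center[2], params$center[3])
  }
  r <- grid_distances(grid, params$center)
  nt <- length(times)
  conc <- vapply(times, function(t) tracer_concentration(params, r, t), r)
  dim(conc) <- c(grid$n, grid$n, grid$n, nt)
  if (is.null(noise_sd)) noise_sd <- 0.02 * beta * max(conc)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  vols <- baseline + beta * conc
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vols <- vols + rnorm(length(vols), 0, noise_sd)
  }
  structure(
    list(volumes = vols, times = as.numeric(times),
         voxel_size = grid$voxel_size, origin = grid$origin,
         brain_mask = brain_mask_ellipsoid(grid),
         noise_sd = noise_sd, beta = beta, baseline = baseline,
         center = params$center),
    class = "image_series"
  )
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<image_series> %dx%dx%d voxels (%.3g mm) x %d times (%g-%g s); noise SD %.3g\n",
              d[1], d[2], d[3], x$voxel_size, d[4],
              min(x$times), max(x$times), x$noise_sd))
  invisible(x)
}

#' Volume of an image-series brain mask
#'
#' @param series An `image_series`.
#' @return Mask volume in mm^3.
#' @export
mask_volume <- function(series) {
  stopifnot(inherits(series, "image_series"))
  sum(series$brain_mask) * series$voxel_size^3
}
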