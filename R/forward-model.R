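#' Kinetic parameters of a point-source tracer experiment
#'
#' Bundles the mechanistic state of one injection experiment: the effective
#' diffusion coefficient \eqn{D^*} of the tracer in the extracellular space
#' (ECS), the first-order clearance rate \eqn{k'}, the injected dose, the ECS
#' volume fraction \eqn{\alpha}, and the stereotactic injection site.
#'
#' Note on units: \eqn{k'} is a rate and is carried internally in 1/s.
#' Published tables in this field sometimes print \eqn{k'} with the same
#' 1e-4 scale (and even the same unit string) as \eqn{D^*}; magnitudes on
#' that scale are interpreted here as multiples of 1e-4 per second.
#'
#' @param d_eff Effective diffusion coefficient, mm^2/s. Must be positive.
#' @param k_clear Clearance rate coefficient, 1/s. Must be non-negative.
#' @param dose Injected tracer amount, mol. Default 2e-8 mol
#'   (a 2 uL bolus of 10 mmol/L Gd-DTPA).
#' @param alpha ECS volume fraction, in (0, 1). Default 0.2, the classical
#'   rodent-brain value. Rescales concentration amplitude only; it cancels
#'   out of \eqn{D^*}, \eqn{k'} and half-life estimation.
#' @param center Injection-site coordinates, mm (3-vector). Default is the
#'   substantia nigra stereotactic site (AP -4.8, ML 1.9, DV -7.8 relative
#'   to bregma).
#' @return An object of class `tracer_params`.
#' @examples
#' p <- tracer_params(d_eff = 2.023e-4, k_clear = 0.854e-4)
#' tracer_concentration(p, r = 0.5, t = 1800)
#' @export
tracer_params <- function(d_eff, k_clear, dose = 2e-8, alpha = 0.2,
                          center = c(-4.8, 1.9, -7.8)) {
  check_scalar_number(d_eff, "d_eff", lower = 0, strict_lower = TRUE)
  check_scalar_number(k_clear, "k_clear", lower = 0)
  check_scalar_number(dose, "dose", lower = 0)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) stop_validation("`alpha` must lie strictly in (0, 1)")
  if (!is.numeric(center) || length(center) != 3L || any(!is.finite(center))) {
    stop_validation("`center` must be a finite numeric 3-vector (mm)")
  }
  structure(
    list(d_eff = d_eff, k_clear = k_clear, dose = dose, alpha = alpha,
         center = as.numeric(center)),
    class = "tracer_params"
  )
}

#' @export
print.tracer_params <- function(x, ...) {
  cat("<tracer_params>\n")
  cat(sprintf("  D*     : %.4g mm^2/s\n", x$d_eff))
  cat(sprintf("  k'     : %.4g 1/s\n", x$k_clear))
  cat(sprintf("  dose   : %.4g mol\n", x$dose))
  cat(sprintf("  alpha  : %.3g\n", x$alpha))
  cat(sprintf("  center : (%.2f, %.2f, %.2f) mm\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Point-source tracer concentration in the ECS
#'
#' Closed-form solution of the diffusion-clearance equation
#' \deqn{\partial C/\partial t = D^* \nabla^2 C - k' C}
#' for an instantaneous release of dose \eqn{Q} into ECS fraction
#' \eqn{\alpha} at the origin at \eqn{t = 0}:
#' \deqn{C(r,t) = (Q/\alpha) (4 \pi D^* t)^{-3/2}
#'   \exp\{-r^2/(4 D^* t) - k' t\}.}
#'
#' @param params A [tracer_params()] object.
#' @param r Distance from the injection center, mm (vectorised, >= 0).
#' @param t Time since injection, s (vectorised, > 0).
#' @return Concentration in mol/mm^3, recycled over `r` and `t`.
#' @export
tracer_concentration <- function(params, r, t) {
  stopifnot(inherits(params, "tracer_params"))
  if (any(t <= 0)) stop_domain("`t` must be strictly positive (got t <= 0)")
  if (any(r < 0)) stop_domain("`r` must be non-negative")
  (params$dose / params$alpha) * (4 * pi * params$d_eff * t)^(-1.5) *
    exp(-r^2 / (4 * params$d_eff * t) - params$k_clear * t)
}

#' Radius of the suprathreshold tracer region
#'
#' Radius \eqn{r^*(t)} at which the point-source concentration equals a
#' detection threshold \eqn{\theta}:
#' \deqn{r^{*2} = 4 D^* t [\ln\{Q / (\alpha (4\pi D^* t)^{3/2} \theta)\} - k' t]}
#' when the bracket is positive, else 0 (no suprathreshold region).
#'
#' @inheritParams tracer_concentration
#' @param theta Concentration threshold, mol/mm^3 (> 0).
#' @return Radius in mm, vectorised over `t`.
#' @export
vd_radius <- function(params, theta, t) {
  stopifnot(inherits(params, "tracer_params"))
  if (any(theta <= 0)) stop_domain("`theta` must be strictly positive")
  if (any(t <= 0)) stop_domain("`t` must be strictly positive")
  bracket <- log(params$dose / (params$alpha *
                                  (4 * pi * params$d_eff * t)^1.5 * theta)) -
    params$k_clear * t
  r2 <- 4 * params$d_eff * t * pmax(bracket, 0)
  sqrt(r2)
}

#' Time at which the suprathreshold volume peaks
#'
#' Solves the stationarity condition of \eqn{r^{*2}(t)},
#' \eqn{(3/2)\ln t + 2 k' t = A - 3/2} with
#' \eqn{A = \ln\{Q/(\alpha (4\pi D^*)^{3/2}\theta)\}}, for the time at which
#' the distribution volume \eqn{V_d(t) = (4/3)\pi r^{*3}} is maximal.
#'
#' @inheritParams vd_radius
#' @return Peak time in s, or `NA` if the threshold exceeds the attainable
#'   peak concentration everywhere.
#' @export
vd_peak_time <- function(params, theta) {
  stopifnot(inherits(params, "tracer_params"))
  check_scalar_number(theta, "theta", lower = 0, strict_lower = TRUE)
  A <- log(params$dose / (params$alpha * (4 * pi * params$d_eff)^1.5 * theta))
  rhs <- A - 1.5
  k <- params$k_clear
  if (k == 0) return(exp(2 * rhs / 3))
  f <- function(t) 1.5 * log(t) + 2 * k * t - rhs
  ## f is increasing; bracket the root
  lo <- 1e-6
  hi <- 1
  while (f(hi) < 0 && hi < 1e12) hi <- hi * 10
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Distribution-volume curve of the analytic forward model
#'
#' Evaluates the tracer distribution volume
#' \eqn{V_d(t) = (4/3)\pi r^{*}(t)^3} on a time grid, expresses it as a
#' percentage of a reference brain volume, and attaches the derived summary
#' metrics (Vd-max%, the peak time, and the half-life of the decline from
#' the peak) computed by [curve_metrics()].
#'
#' @inheritParams vd_radius
#' @param times Acquisition times, s; strictly increasing, all > 0.
#' @param brain_volume Reference brain volume for the percentage
#'   denominator, mm^3 (> 0).
#' @return A `vd_curve`: a tibble with columns `time_s`, `vd_mm3`, `vd_pct`
#'   and metric attributes; see [curve_metrics()].
#' @export
vd_curve <- function(params, theta, times, brain_volume) {
  stopifnot(inherits(params, "tracer_params"))
  if (length(times) == 0L) stop_validation("`times` must be non-empty")
  if (any(diff(times) <= 0)) stop_validation("`times` must be strictly increasing")
  check_scalar_number(brain_volume, "brain_volume", lower = 0, strict_lower = TRUE)
  r <- vd_radius(params, theta, times)
  vd <- (4 / 3) * pi * r^3
  new_vd_curve(times, vd, brain_volume)
}

new_vd_curve <- function(times, vd, brain_volume) {
  m <- curve_metrics(times, vd)
  out <- tibble(time_s = as.numeric(times), vd_mm3 = as.numeric(vd),
                vd_pct = 100 * as.numeric(vd) / brain_volume)
  structure(out,
            class = c("vd_curve", class(out)),
            brain_volume = brain_volume,
            vd_max_mm3 = m$vd_max,
            vd_max_pct = 100 * m$vd_max / brain_volume,
            t_max_s = m$t_max,
            t_half_s = m$t_half,
            t_half_defined = m$t_half_defined)
}

#' Peak and half-life metrics of a distribution-volume curve
#'
#' Summarises a sampled curve of distribution volume versus time:
#' the maximum `vd_max`, its time `t_max` (earliest time on ties), and the
#' half-life `t_half` -- the time elapsed after `t_max` at which the curve
#' first falls to half its maximum, located by linear interpolation between
#' the bracketing samples. When the sampled span never reaches half-maximum
#' the half-life is flagged undefined (`NA`), not an error: the observation
#' window simply ended too early, and extrapolating beyond it is not done.
#'
#' @param times Sample times, s; strictly increasing, length >= 3.
#' @param vd Distribution volume at each time (any volume unit).
#' @return A list with `vd_max`, `t_max`, `t_half` (duration since `t_max`,
#'   `NA` when undefined) and `t_half_defined`.
#' @examples
#' curve_metrics(c(0, 600, 1200, 1800, 2400), c(0, 10, 8, 6, 4))
#' @export
curve_metrics <- function(times, vd) {
  if (length(times) != length(vd)) {
    stop_validation("`times` and `vd` must have equal length")
  }
  if (length(times) < 3L) stop_validation("need at least 3 samples")
  if (any(diff(times) <= 0)) stop_validation("`times` must be strictly increasing")
  if (any(!is.finite(vd)) || any(vd < 0)) {
    stop_validation("`vd` must be finite and non-negative")
  }
  i_max <- which.max(vd)  # earliest index on ties
  vd_max <- vd[i_max]
  t_max <- times[i_max]
  half <- vd_max / 2
  t_half <- NA_real_
  if (vd_max > 0 && i_max < length(vd)) {
    after <- seq(i_max, length(vd))
    below <- after[vd[after] <= half]
    if (length(below) > 0L) {
      j <- below[1]
      if (vd[j] == half) {
        t_half <- times[j] - t_max
      } else {
        ## interpolate between samples j-1 (above half) and j (below half)
        t_cross <- times[j - 1] + (half - vd[j - 1]) *
          (times[j] - times[j - 1]) / (vd[j] - vd[j - 1])
        t_half <- t_cross - t_max
      }
    }
  }
  list(vd_max = vd_max, t_max = t_max, t_half = t_half,
       t_half_defined = is.finite(t_half))
}

#' @export
print.vd_curve <- function(x, ...) {
  cat(sprintf("<vd_curve> %d time points; Vd-max %.3g mm^3 (%.3g%%) at t = %g s; ",
              nrow(x), attr(x, "vd_max_mm3"), attr(x, "vd_max_pct"),
              attr(x, "t_max_s")))
  if (isTRUE(attr(x, "t_half_defined"))) {
    cat(sprintf("t1/2 = %g s\n", attr(x, "t_half_s")))
  } else {
    cat("t1/2 undefined within span\n")
  }
  NextMethod()
}

#' Alternative half-life definitions
#'
#' The default half-life in this package is defined on the distribution
#' volume curve (time from its peak until it falls to half the peak; see
#' [curve_metrics()]). Two clearly named alternatives are provided for
#' comparison, neither of which is used by the estimation pipeline:
#'
#' * `content_half_life()` -- half-life of the total tracer content
#'   \eqn{\alpha \int C \, dV = Q e^{-k' t}}, i.e. \eqn{\ln 2 / k'}.
#' * `local_half_life()` -- half-life of the concentration time-course at a
#'   fixed distance `r` from the source: time from the local peak of
#'   \eqn{C(r, t)} until it first falls to half that peak, found
#'   numerically.
#'
#' @inheritParams tracer_concentration
#' @return Half-life in seconds (`Inf` for `content_half_life()` when
#'   `k_clear` is 0; `NA` for `local_half_life()` if no crossing is found).
#' @export
content_half_life <- function(params) {
  stopifnot(inherits(params, "tracer_params"))
  if (params$k_clear == 0) return(Inf)
  log(2) / params$k_clear
}

#' @rdname content_half_life
#' @export
local_half_life <- function(params, r) {
  stopifnot(inherits(params, "tracer_params"))
  check_scalar_number(r, "r", lower = 0)
  f <- function(t) tracer_concentration(params, r, t)
  if (r == 0) return(NA_real_)  # C(0, t) has no interior max (diverges at 0+)
  ## stationarity of t^{-3/2} exp(-r^2/4Dt - kt): k t^2 + (3/2) t = r^2/(4D)
  k <- params$k_clear
  t_pk <- if (k == 0) {
    r^2 / (6 * params$d_eff)
  } else {
    (-1.5 + sqrt(2.25 + k * r^2 / params$d_eff)) / (2 * k)
  }
  half <- f(t_pk) / 2
  g <- function(t) f(t) - half
  hi <- t_pk * 2
  while (g(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (g(hi) > 0) return(NA_real_)
  uniroot(g, c(t_pk, hi), tol = 1e-6)$root - t_pk
}
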