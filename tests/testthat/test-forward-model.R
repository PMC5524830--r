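test_that("parameter validation enforces the physical envelope", {
  expect_error(tracer_params(d_eff = 0, k_clear = 1e-4), class = "ecstrace_validation_error")
  expect_error(tracer_params(d_eff = 2e-4, k_clear = -1), class = "ecstrace_validation_error")
  expect_error(tracer_params(d_eff = 2e-4, k_clear = 0, alpha = 1.2),
               class = "ecstrace_validation_error")
  expect_error(tracer_params(d_eff = 2e-4, k_clear = 0, center = c(1, 2)),
               class = "ecstrace_validation_error")
  expect_s3_class(tracer_params(2e-4, 0), "tracer_params")
})

test_that("concentration solves the point-source diffusion-clearance model", {
  p <- pd_params()
  ## zero source
  p0 <- tracer_params(d_eff = p$d_eff, k_clear = p$k_clear, dose = 0)
  expect_equal(tracer_concentration(p0, c(0, 0.5, 2), 1800), c(0, 0, 0))
  ## clearance factorizes: C(k0)/C(k=0) = exp(-k0 t) for any r
  pk <- tracer_params(d_eff = p$d_eff, k_clear = 3e-4)
  pnk <- tracer_params(d_eff = p$d_eff, k_clear = 0)
  for (r in c(0, 0.3, 1.5)) {
    expect_equal(tracer_concentration(pk, r, 2400) / tracer_concentration(pnk, r, 2400),
                 exp(-3e-4 * 2400), tolerance = 1e-12)
  }
  ## strictly decreasing in r at fixed t
  r <- seq(0, 3, by = 0.05)
  expect_true(all(diff(tracer_concentration(p, r, 1800)) < 0))
  ## domain errors
  expect_error(tracer_concentration(p, 0.5, 0), class = "ecstrace_domain_error")
  expect_error(tracer_concentration(p, -0.1, 100), class = "ecstrace_domain_error")
})

test_that("mass balance holds by quadrature: alpha * int C dV = Q exp(-k t)", {
  p <- pd_params()  # k' = 2.153e-4 1/s, Q = 2e-8 mol
  for (t in c(600, 3600, 7200)) {
    expect_equal(analytic_content(p, t), p$dose * exp(-p$k_clear * t),
                 tolerance = 1e-3)
  }
  ## the t = 3600 s value equals Q exp(-k' 3600) = 9.21e-9 mol
  expect_equal(analytic_content(p, 3600), 9.213339e-09, tolerance = 1e-3)
})

test_that("vd_radius returns the threshold-crossing radius", {
  p <- control_params()
  t <- 1800
  c_peak <- tracer_concentration(p, 0, t)
  ## threshold above peak: empty suprathreshold region
  expect_equal(vd_radius(p, c_peak * 2, t), 0)
  ## defining identity C(r*, t) = theta to 1e-9 relative
  theta <- c_peak / 50
  r_star <- vd_radius(p, theta, t)
  expect_gt(r_star, 0)
  expect_lt(abs(tracer_concentration(p, r_star, t) - theta) / theta, 1e-9)
  expect_error(vd_radius(p, -1, t), class = "ecstrace_domain_error")
})

test_that("analytic suprathreshold volume agrees with voxel counting", {
  p <- control_params()
  t <- 2700
  theta <- tracer_concentration(p, 0, t) / 30
  r_star <- vd_radius(p, theta, t)
  v_analytic <- (4 / 3) * pi * r_star^3
  ## brute-force voxel count on a 0.1 mm grid
  dx <- 0.1
  ax <- seq(-3, 3, by = dx)
  cgrid <- tracer_concentration(
    p, sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+")), t)
  v_voxel <- sum(cgrid >= theta) * dx^3
  expect_equal(v_voxel, v_analytic, tolerance = 0.02)
})

test_that("vd_curve is unimodal for k' > 0 and non-decreasing for k' = 0", {
  p <- pd_params()
  theta <- 1e-9
  dense <- seq(60, 14400, by = 30)
  curve <- vd_curve(p, theta, dense, brain_volume = 900)
  ## unimodal: sign changes of successive differences at most once
  d <- diff(curve$vd_mm3)
  d <- d[d != 0]
  expect_lte(sum(diff(sign(d)) != 0), 1)
  ## no clearance, threshold low enough that the analytic peak falls beyond
  ## the observation window: Vd non-decreasing, t_half undefined
  p0 <- tracer_params(d_eff = p$d_eff, k_clear = 0)
  curve0 <- vd_curve(p0, 1e-10, default_times(), brain_volume = 900)
  expect_true(all(diff(curve0$vd_mm3) >= 0))
  expect_false(attr(curve0, "t_half_defined"))
  expect_true(is.na(attr(curve0, "t_half_s")))
  expect_error(vd_curve(p, theta, numeric(0), 900), class = "ecstrace_validation_error")
})

test_that("closed-form peak time matches the dense-grid arg-max", {
  p <- pd_params()
  theta <- 1e-9
  t_closed <- vd_peak_time(p, theta)
  grid1s <- seq(1, 14400, by = 1)
  vd <- (4 / 3) * pi * vd_radius(p, theta, grid1s)^3
  expect_lt(abs(t_closed - grid1s[which.max(vd)]), 2)
})

test_that("curve_metrics locates peak and interpolated half-life", {
  ## exact exponential decay from the peak: t1/2 = 3600 s
  t_max <- 600
  times <- seq(0, 14400, by = 300)
  lambda <- log(2) / 3600
  vd <- ifelse(times < t_max, times / t_max * 5,
               5 * exp(-lambda * (times - t_max)))
  m <- curve_metrics(times, vd)
  expect_equal(m$t_max, t_max)
  expect_equal(m$t_half, 3600, tolerance = 0.02)  # linear interp of exponential
  ## all-constant: no decay, flag set
  m2 <- curve_metrics(c(0, 600, 1200), c(3, 3, 3))
  expect_false(m2$t_half_defined)
  ## hand-computed piecewise-linear crossing: between 6 and 4, crosses 5 at 2100
  m3 <- curve_metrics(c(0, 600, 1200, 1800, 2400), c(0, 10, 8, 6, 4))
  expect_equal(m3$vd_max, 10)
  expect_equal(m3$t_max, 600)
  expect_equal(m3$t_half, 1500)
  ## contract violations
  expect_error(curve_metrics(c(0, 600), c(1, 2)), class = "ecstrace_validation_error")
  expect_error(curve_metrics(c(0, 600, 500), c(1, 2, 3)), class = "ecstrace_validation_error")
})

test_that("model ordering: larger k' shrinks both t_half and Vd-max", {
  theta <- 1e-9
  ks <- c(0.5, 1, 1.5, 2, 3) * 1e-4
  metrics <- lapply(ks, function(k) {
    p <- tracer_params(d_eff = 2.4e-4, k_clear = k)
    curve <- vd_curve(p, theta, seq(60, 21600, by = 60), brain_volume = 900)
    c(vd_max = attr(curve, "vd_max_pct"), t_half = attr(curve, "t_half_s"))
  })
  vd_max <- vapply(metrics, `[[`, numeric(1), "vd_max")
  t_half <- vapply(metrics, `[[`, numeric(1), "t_half")
  expect_true(all(diff(vd_max) < 0))
  expect_true(all(diff(t_half) < 0))
})

test_that("concentration decreases monotonically in k' and vd_radius in theta", {
  ks <- seq(0, 5e-4, by = 1e-4)
  cc <- vapply(ks, function(k) {
    tracer_concentration(tracer_params(2.4e-4, k), 0.8, 1800)
  }, numeric(1))
  expect_true(all(diff(cc) < 0))
  p <- pd_params()
  thetas <- 10^seq(-10, -8.5, by = 0.25)
  expect_true(all(diff(vd_radius(p, thetas, 1800)) < 0))
})

test_that("alternative half-life definitions behave as documented", {
  p <- pd_params()
  expect_equal(content_half_life(p), log(2) / p$k_clear)
  expect_equal(content_half_life(tracer_params(2e-4, 0)), Inf)
  ## local half-life at a fixed distance is positive and finite for k' > 0
  lh <- local_half_life(p, 1)
  expect_gt(lh, 0)
  expect_true(is.finite(lh))
})

test_that("vd_curve tidiers expose values and metrics", {
  curve <- vd_curve(pd_params(), 1e-9, default_times(), brain_volume = 900)
  td <- tidy(curve)
  expect_named(td, c("time_s", "vd_mm3", "vd_pct"))
  g <- glance(curve)
  expect_equal(g$vd_max_pct, max(td$vd_pct))
  expect_true(g$t_max_s %in% td$time_s)
})
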