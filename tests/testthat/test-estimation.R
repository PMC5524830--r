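test_that("signal inversion recovers the analytic field and clips noise floor", {
  p <- control_params()
  grid <- small_grid(n = 20, voxel_size = 0.35)
  times <- c(600, 2400)
  s <- render_image_series(p, grid = grid, times = times, beta = 3e9,
                           baseline = 80, noise_sd = 0)
  conc <- signal_to_concentration(s)
  ax <- function(j) grid$origin[j] + (0:(grid$n - 1)) * grid$voxel_size
  r <- sqrt(outer(outer((ax(1) - p$center[1])^2, (ax(2) - p$center[2])^2, "+"),
                  (ax(3) - p$center[3])^2, "+"))
  expect_equal(conc$volumes[, , , 2], tracer_concentration(p, r, 2400),
               tolerance = 1e-12)
  ## all-baseline series -> all-zero concentration
  s0 <- s; s0$volumes[] <- 80
  expect_true(all(signal_to_concentration(s0)$volumes == 0))
  ## negative noise excursions are clipped at zero
  sn <- render_image_series(p, grid = grid, times = times, beta = 3e9,
                            baseline = 80, noise_sd = 5, seed = 2)
  expect_gte(min(signal_to_concentration(sn)$volumes), 0)
  expect_error(signal_to_concentration(s, beta = 0),
               class = "ecstrace_validation_error")
})

test_that("noise-free fit recovers generator parameters to < 0.5%", {
  p <- control_params()  # group-mean D* and k' of the untreated group
  conc <- analytic_conc_series(p, small_grid(n = 32, voxel_size = 0.3),
                               default_times())
  fit <- fit_point_source(conc)
  expect_true(fit$converged)
  expect_lt(abs(fit$d_eff / p$d_eff - 1), 0.005)
  expect_lt(abs(fit$k_clear / p$k_clear - 1), 0.005)
  expect_equal(fit$dose_eff, p$dose, tolerance = 0.005)
})

test_that("amplitude and shape separate: beta only rescales dose_eff", {
  p <- control_params()
  grid <- small_grid(n = 24, voxel_size = 0.3)
  s <- render_image_series(p, grid = grid, times = default_times(),
                           beta = 1e9, baseline = 0, noise_sd = 0)
  conc1 <- signal_to_concentration(s, baseline = 0, beta = 1e9)
  conc2 <- signal_to_concentration(s, baseline = 0, beta = 0.5e9)  # doubles conc
  f1 <- fit_point_source(conc1)
  f2 <- fit_point_source(conc2)
  expect_lt(abs(f2$d_eff / f1$d_eff - 1), 1e-6)
  expect_lt(abs(f2$k_clear - f1$k_clear), 1e-6 * max(f1$k_clear, 1e-12))
  expect_equal(f2$dose_eff / f1$dose_eff, 2, tolerance = 1e-6)
})

test_that("alpha rescaling is absorbed into dose_eff only", {
  grid <- small_grid(n = 24, voxel_size = 0.3)
  p1 <- tracer_params(2.4e-4, 1.2e-4, alpha = 0.2)
  p2 <- tracer_params(2.4e-4, 1.2e-4, alpha = 0.4)
  f1 <- fit_point_source(analytic_conc_series(p1, grid, default_times()))
  f2 <- fit_point_source(analytic_conc_series(p2, grid, default_times()))
  expect_equal(f1$d_eff, f2$d_eff, tolerance = 1e-6)
  expect_equal(f1$k_clear, f2$k_clear, tolerance = 1e-6)
  ## halved amplitude Q/alpha -> halved fitted amplitude
  expect_equal(f2$dose_eff / f1$dose_eff, 0.5, tolerance = 1e-5)
})

test_that("noisy fits stay within the Monte-Carlo recovery contract", {
  ## 2% noise, small replicate set on a reduced grid; the full-size
  ## experiment runs in the acceptance suite
  p <- pd_params()
  grid <- small_grid(n = 48, voxel_size = 0.2)
  errs <- vapply(1:5, function(i) {
    s <- render_image_series(p, grid = grid, times = default_times(),
                             seed = 1000 + i)
    fit <- fit_point_source(signal_to_concentration(s))
    c(abs(fit$d_eff / p$d_eff - 1), abs(fit$k_clear / p$k_clear - 1))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("fit contract errors surface with the right classes", {
  p <- control_params()
  conc <- analytic_conc_series(p, small_grid(n = 24, voxel_size = 0.3),
                               c(600, 1500))
  expect_error(fit_point_source(conc), class = "ecstrace_validation_error")
  ## a zero series has no suprathreshold voxels
  conc3 <- analytic_conc_series(p, small_grid(n = 24, voxel_size = 0.3),
                                c(600, 1500, 2400))
  conc3$volumes[] <- 0
  expect_error(fit_point_source(conc3), class = "ecstrace_fit_error")
})

test_that("voxel-count Vd matches the analytic volume and refines with the mesh", {
  p <- control_params()
  times <- c(1200, 2400, 3600)
  theta <- tracer_concentration(p, 0, 2400) / 20
  r_star <- vd_radius(p, theta, times)
  v_true <- (4 / 3) * pi * r_star^3
  ## mean absolute error over the sampled times, per mesh
  errs <- vapply(c(0.4, 0.2, 0.1), function(dx) {
    n <- as.integer(round(9.6 / dx))
    conc <- analytic_conc_series(p, small_grid(n = n, voxel_size = dx), times)
    curve <- vd_from_series(conc, theta)
    shell <- 4 * pi * r_star^2 * dx  # one voxel-shell volume per time
    expect_true(all(abs(curve$vd_mm3 - v_true) < shell))
    mean(abs(curve$vd_mm3 - v_true))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("threshold above the global peak yields an all-zero Vd curve", {
  p <- control_params()
  conc <- analytic_conc_series(p, small_grid(n = 16, voxel_size = 0.4),
                               c(600, 1500, 2400))
  curve <- vd_from_series(conc, theta = max(conc$volumes) * 2)
  expect_true(all(curve$vd_mm3 == 0))
  expect_equal(attr(curve, "vd_max_pct"), 0)
  expect_error(vd_from_series(conc, theta = 0), class = "ecstrace_domain_error")
  conc$brain_mask[] <- FALSE
  expect_error(vd_from_series(conc, theta = 1e-9),
               class = "ecstrace_validation_error")
})

test_that("end-to-end single-animal analysis closes the loop noise-free", {
  p <- control_params()
  s <- render_image_series(p, grid = small_grid(n = 32, voxel_size = 0.3),
                           times = default_times(), noise_sd = 0)
  rec <- analyze_animal(s, theta = 1e-9, animal_id = "a1", group = "control")
  expect_true(rec$converged)
  expect_lt(abs(rec$est_d_eff / p$d_eff - 1), 0.005)
  expect_lt(abs(rec$est_k_clear / p$k_clear - 1), 0.005)
  expect_true(rec$vd_max_pct >= 0 && rec$vd_max_pct <= 100)
  expect_true(rec$t_half_defined)
  expect_gt(rec$t_half_s, 0)
  ## noise-free series demands an explicit theta
  expect_error(analyze_animal(s), class = "ecstrace_validation_error")
})

test_that("higher clearance yields smaller Vd-max and shorter half-life", {
  grid <- small_grid(n = 32, voxel_size = 0.3)
  theta <- 1e-9
  recs <- lapply(c(1e-4, 2.5e-4), function(k) {
    p <- tracer_params(2.4e-4, k)
    s <- render_image_series(p, grid = grid, times = default_times(),
                             noise_sd = 0)
    analyze_animal(s, theta = theta)
  })
  expect_lt(recs[[2]]$vd_max_pct, recs[[1]]$vd_max_pct)
  expect_lt(recs[[2]]$t_half_s, recs[[1]]$t_half_s)
})

test_that("missing time column in a series CSV is a named validation error", {
  p <- control_params()
  s <- render_image_series(p, grid = small_grid(n = 10, voxel_size = 0.5),
                           times = c(600, 1500, 2400), noise_sd = 0)
  dir <- withr::local_tempdir()
  write_image_series(s, dir, "r1")
  tt <- readr::read_csv(file.path(dir, "r1_times.csv"), show_col_types = FALSE)
  readr::write_csv(tt[, c("animal_id", "t_index")],
                   file.path(dir, "r1_times.csv"))
  expect_error(read_image_series(dir, "r1"), regexp = "time_s",
               class = "ecstrace_validation_error")
  expect_error(read_image_series(dir, "nope"),
               class = "ecstrace_validation_error")
})

test_that("fit tidiers report estimates and diagnostics", {
  p <- control_params()
  fit <- fit_point_source(analytic_conc_series(
    p, small_grid(n = 24, voxel_size = 0.3), default_times()))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "d_eff"], fit$d_eff)
  g <- glance(fit)
  expect_true(g$converged)
  au <- augment(fit)
  expect_equal(au$.resid, au$conc - au$fitted)
})
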