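test_that("afferent integration is a padded windowed mean", {
  expect_equal(integrate_afferent(rep(95, 250)), 95)
  expect_equal(integrate_afferent(rep(c(90, 100), 125)), 95)
  expect_equal(integrate_afferent(0:249), 124.5)
  # warm-up padding with the first sample
  expect_equal(integrate_afferent(c(10, 20), window_n = 4), (10 + 10 + 10 + 20) / 4)
  expect_error(integrate_afferent(numeric(0)), class = "zf_controller_error")
})

test_that("error signals subtract the set point", {
  expect_equal(error_signal(95, 95), 0)
  expect_equal(error_signal(3, 3), 0)
  expect_equal(error_signal(110, 95), 15)
})

test_that("arctangent saturation has unit slope, odd symmetry and a hard bound", {
  expect_equal(saturate(0, 18), 0)
  expect_equal(saturate(5, 5), (10 / pi) * atan(pi / 2))
  expect_equal(saturate(1e12, 18), 18, tolerance = 1e-6)
  # unit slope at zero
  expect_equal(saturate(1e-6, 18) / 1e-6, 1, tolerance = 1e-6)
  # property: |phi(e)| < L for a large random sample, both limits
  x <- with_seed(42, stats::rcauchy(1e6, scale = 50))
  expect_true(all(abs(saturate(x, 18)) < 18))
  expect_true(all(abs(saturate(x, 5)) < 5))
  expect_equal(saturate(-x, 18), -saturate(x, 18))
})

test_that("kernels are unit-area after discretization", {
  for (k in list(triangular_kernel(0.1, 0.5, 1, 200),
                 triangular_kernel(2, 5, 30, 20),
                 triangular_kernel(300, 480, 620, 10))) {
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_true(all(k >= 0))
  }
  expect_error(triangular_kernel(0.4, 0.5, 0.6, 1), class = "zf_config_error")
})

test_that("arc convolution has unit steady-state gain and exact step response", {
  k <- triangular_kernel(0.1, 0.5, 2, 10)
  n <- length(k)
  # constant input -> that constant from the first sample (warm start)
  expect_equal(convolve_arc(rep(2, n + 5), k), rep(2, n + 5))
  # impulse after a zero warm-up reproduces the kernel
  x <- c(rep(0, n), 1, rep(0, n))
  y <- convolve_arc(x, k)
  expect_equal(y[(n + 1):(2 * n)], k, tolerance = 1e-12)
  # step response equals the cumulative kernel (analytic closed form)
  xs <- c(rep(0, n), rep(1, n))
  ys <- convolve_arc(xs, k)
  expect_lt(max(abs(ys[(n + 1):(2 * n)] - cumsum(k))), 1e-9)
  # non-unit-area kernel is a config error
  expect_error(convolve_arc(rep(1, 5), c(0.5, 0.2)), class = "zf_config_error")
})

test_that("gains map efferents to effectors with the documented conventions", {
  cfg <- test_reflex_config()
  base <- list(HR = 72)
  eff0 <- apply_gains(rep(0, nrow(cfg$arcs)), cfg$arcs, base)
  expect_equal(eff0, list(HR = 72, contract_scale = 1, resist_scale = 1, dVu = 0))
  # hypotension (negative arterial efferents) -> vasoconstriction and
  # recruitment of stressed volume (negative unstressed-volume shift)
  hypo <- c(-10, -10, 0)
  eff <- apply_gains(hypo, cfg$arcs, base)
  expect_gt(eff$resist_scale, 1)
  expect_lt(eff$dVu, 0)
  expect_gt(eff$HR, 72)
  # doubling one gain doubles that effector correction
  arcs2 <- cfg$arcs
  arcs2$g_resist[2] <- 2 * arcs2$g_resist[2]
  d1 <- apply_gains(hypo, cfg$arcs, base)$resist_scale - 1
  d2 <- apply_gains(hypo, arcs2, base)$resist_scale - 1
  expect_equal(d2, 2 * d1)
  # physiological floors
  ex <- apply_gains(c(1e6, 1e6, 1e6), cfg$arcs, base)
  expect_gte(ex$HR, 0)
  expect_gte(ex$resist_scale, 0.1)
})

test_that("controller at the set points is a fixed point; a pressure drop recruits", {
  cfg <- test_reflex_config()
  ctrl <- reflex_controller(cfg, base_hr = 72)
  at_set <- list(abp = 95, pp = 35, cvp = 3)
  for (i in 1:30) {
    out <- controller_step(ctrl, at_set)
    ctrl <- out$ctrl
  }
  expect_equal(out$effectors, list(HR = 72, contract_scale = 1,
                                   resist_scale = 1, dVu = 0))
  # sudden arterial drop: HR correction positive, resistance rises over the
  # kernel timescale
  for (i in 1:60) {
    out <- controller_step(ctrl, list(abp = 60, pp = 35, cvp = 3))
    ctrl <- out$ctrl
  }
  expect_gt(out$effectors$HR, 72)
  expect_gt(out$effectors$resist_scale, 1)
  expect_lt(out$effectors$dVu, 0)
  # disabled flag pins effectors at base
  out_off <- controller_step(ctrl, list(abp = 60, pp = 35, cvp = 3),
                             disabled = TRUE)
  expect_equal(out_off$effectors$HR, 72)
  expect_equal(out_off$effectors$resist_scale, 1)
})

test_that("zero-gain controller run is bit-identical to a controller-free run", {
  cfg <- read_model_config()
  for (i in seq_along(cfg$reflex$arcs)) {
    cfg$reflex$arcs[[i]]$g_hr <- 0
    cfg$reflex$arcs[[i]]$g_contract <- 0
    cfg$reflex$arcs[[i]]$g_resist <- 0
    cfg$reflex$arcs[[i]]$g_vu <- 0
  }
  mod <- build_default_model(cfg)
  tr_on <- simulate(mod, short_scenario("on"))
  tr_off <- simulate(mod, short_scenario("off"))
  expect_identical(tr_on$abp_mmhg, tr_off$abp_mmhg)
  expect_identical(tr_on$cvp_mmhg, tr_off$cvp_mmhg)
  expect_identical(tr_on$co_l_min, tr_off$co_l_min)
})

test_that("closed loop with the controller regulates near the arterial set point", {
  mod <- human_model()
  tr <- simulate(mod, scenario_config(reflexes = "on", arrest_time = 1e6,
                                      horizon_post_arrest = 0,
                                      baseline_duration = 60,
                                      check_steady = FALSE))
  arch_setpoint <- 95
  base <- dplyr::filter(tr, time_s >= -20)
  expect_lt(abs(mean(base$abp_mmhg) - arch_setpoint), 10)
})
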