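test_that("volume status scales volumes proportionally and only once", {
  mod <- human_model()
  st <- model_state(mod)
  st_eu <- apply_volume_status(st, "euvolemia")
  expect_equal(sum(st_eu$V), sum(st$V))
  st_hypo <- apply_volume_status(st, "hypovolemia_20pct")
  expect_equal(sum(st_hypo$V), 0.8 * sum(st$V))
  expect_equal(st_hypo$V, 0.8 * st$V)
  expect_error(apply_volume_status(st_hypo, "euvolemia"),
               class = "zf_scenario_error")
})

test_that("hypovolemia strictly lowers the zero-flow equilibrium", {
  mod <- human_model()
  expect_lt(mcfp(mod, 0.8 * 5000), mcfp(mod))
  sc <- scenario_config("hypovolemia_20pct", "off",
                        valve_mode_post_arrest = "open",
                        horizon_post_arrest = 1500, check_steady = FALSE)
  tr <- cached("human_open_long_hypo", simulate(mod, sc))
  late <- dplyr::filter(tr, time_s >= 1490)
  expect_equal(mean(late$abp_mmhg), mcfp(mod, 4000), tolerance = 0.05)
  eu <- cached("human_open_long",
               simulate(mod, scenario_config(reflexes = "off",
                                             valve_mode_post_arrest = "open",
                                             horizon_post_arrest = 1500,
                                             check_steady = FALSE)))
  expect_lt(mean(late$abp_mmhg),
            mean(dplyr::filter(eu, time_s >= 1490)$abp_mmhg))
})

test_that("induce_arrest zeroes the drives and flags the state", {
  mod <- human_model()
  st <- model_state(mod)
  st2 <- induce_arrest(st, "inactive")
  expect_equal(st2$HR, 0)
  expect_equal(st2$RR, 0)
  expect_true(st2$arrest)
  expect_equal(st2$controller_mode, "inactive")
})

test_that("cardiac output ceases within seconds of arrest", {
  mod <- human_model()
  tr <- cached("human_short_off", simulate(mod, short_scenario("off")))
  after <- dplyr::filter(lowpass_mean(tr), time_s > 10)
  expect_true(all(abs(after$co_l_min) < 0.01))
})

test_that("the four study scenarios run and summarize", {
  mod <- human_model()
  res <- cached("study_short",
                run_study(mod, study_scenarios(horizon_post_arrest = 615) |>
                            purrr::map(function(s) {
                              s$baseline_duration <- 30
                              s$check_steady <- FALSE
                              s
                            })))
  expect_equal(dplyr::n_distinct(res$traces$label), 4L)
  spans <- res$traces |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(hi = max(.data$time_s))
  expect_true(all(spans$hi >= 600))
  expect_equal(nrow(res$summary), 4 * 3 * 4)  # scenarios x channels x times
  # reflex-on trace is non-monotone after arrest (rise then fall)
  von <- res$traces |> dplyr::filter(.data$label == "vf_eu")
  attr(von, "fs") <- 200
  f <- lowpass_mean(von)
  mid <- dplyr::filter(f, time_s > 60, time_s < 600)
  ipk <- which.max(mid$cvp_mmhg)
  expect_gt(ipk, 1)
  expect_lt(ipk, nrow(mid))
})

test_that("identical scenario and seed give bit-identical study traces", {
  mod <- toy_ring_model()
  tr1 <- simulate(mod, toy_ring_scenario(horizon = 5))
  tr2 <- simulate(mod, toy_ring_scenario(horizon = 5))
  expect_identical(tr1, tr2)
})
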