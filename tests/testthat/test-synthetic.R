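test_that("anchor curves pass exactly through the anchor points", {
  anchors <- anchor_table()
  for (g in unique(anchors$group)) {
    for (ch in unique(anchors$channel)) {
      a <- dplyr::filter(anchors, group == g, channel == ch)
      f <- group_mean_curve(g, ch, anchors)
      expect_equal(f(a$time_s), a$mean, tolerance = 1e-12,
                   label = paste(g, ch))
    }
  }
  # stated values from the packaged table
  expect_equal(group_mean_curve("pento_eu", "map")(30), 16)
  expect_equal(group_mean_curve("vf_eu", "cvp")(300), 22.9)
})

test_that("anchor curves respect the described post-arrest course", {
  tt <- seq(300, 600, by = 1)
  # VF curves fall monotonically from peak to plateau
  expect_true(all(diff(group_mean_curve("vf_eu", "cvp")(tt)) <= 1e-9))
  expect_true(all(diff(group_mean_curve("vf_eu", "map")(tt)) <= 1e-9))
  # flat before arrest; constant after 600
  f <- group_mean_curve("vf_eu", "map")
  expect_equal(f(c(-60, -20, 0)), rep(53, 3))
  expect_equal(f(c(601, 615)), rep(11, 2))
})

test_that("animal synthesis is deterministic with per-animal substreams", {
  spec <- cohort_spec(seed = 7)
  a1 <- synthesize_animal("vf_eu", 1, spec)
  a1b <- synthesize_animal("vf_eu", 1, spec)
  a2 <- synthesize_animal("vf_eu", 2, spec)
  expect_identical(a1, a1b)
  expect_false(identical(a1$abp_mmhg, a2$abp_mmhg))
  # different groups draw independent streams
  b1 <- synthesize_animal("pento_eu", 1, spec)
  expect_false(identical(a1$cvp_mmhg, b1$cvp_mmhg))
})

test_that("post-arrest cardiac output is zero up to small noise", {
  tr <- synthesize_animal("vf_eu", 1, cohort_spec(seed = 3))
  post <- dplyr::filter(tr, time_s > 0)
  expect_true(all(abs(post$co_l_min) < 0.05))
})

test_that("noiseless synthesis reproduces the anchors through the pipeline", {
  spec <- noiseless_cohort_spec()
  tr <- synthesize_animal("pento_eu", 1, spec)
  tp <- extract_timepoints(lowpass_mean(tr))
  a <- anchor_table() |> dplyr::filter(group == "pento_eu")
  for (ch_pair in list(c("map", "map"), c("cvp", "cvp"), c("co", "co"))) {
    got <- dplyr::filter(tp, channel == ch_pair[1]) |> dplyr::arrange(time_s)
    want <- dplyr::filter(a, channel == ch_pair[2]) |> dplyr::arrange(time_s)
    expect_equal(got$value, want$mean, tolerance = 0.1 / max(want$mean, 1),
                 label = ch_pair[1])
  }
})

test_that("cohort synthesis writes traces and a checksummed manifest", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n = c(pento_eu = 2, vf_eu = 2, vf_hypo = 2), seed = 5,
                      t_start = -30, t_end = 40)
  out <- synthesize_cohort(spec, dir = dir)
  expect_equal(dplyr::n_distinct(out$traces$animal), 6L)
  expect_length(out$manifest$files, 6L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$seed, 5L)
  expect_equal(mf$anchor_checksum, out$manifest$anchor_checksum)
  # default cohort counts mirror the study: 7 + 4 + 3 = 14 animals
  expect_equal(sum(cohort_spec()$n), 14)
})

test_that("group means over many synthetic animals track the anchors", {
  # law-of-large-numbers check on the fast time-point path
  tp <- synthesize_timepoints("vf_eu", n = 200, cohort_spec(seed = 11))
  got <- tp |>
    dplyr::group_by(channel, time_s) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  a <- anchor_table() |>
    dplyr::filter(group == "vf_eu") |>
    dplyr::mutate(channel = dplyr::recode(channel, map = "map")) |>
    dplyr::left_join(got, by = c("channel", "time_s"))
  expect_true(all(abs(a$m - a$mean) <= pmax(a$sd, 0.05)))
})

test_that("cohort pipeline round trip reproduces anchors within 1 mmHg", {
  spec <- cohort_spec(n = c(vf_eu = 50), fs = 100, seed = 21)
  traces <- purrr::map_dfr(1:50, ~ synthesize_animal("vf_eu", .x, spec))
  mean_tr <- traces |>
    dplyr::group_by(time_s) |>
    dplyr::summarise(abp_mmhg = mean(abp_mmhg), cvp_mmhg = mean(cvp_mmhg),
                     co_l_min = mean(co_l_min), .groups = "drop")
  tp <- extract_timepoints(lowpass_mean(mean_tr))
  a <- anchor_table() |> dplyr::filter(group == "vf_eu")
  cmp <- dplyr::left_join(tp, a, by = c("channel", "time_s"))
  expect_true(all(abs(cmp$value - cmp$mean) < 1))
})
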