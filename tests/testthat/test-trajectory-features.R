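test_that("triangle pulse features match their closed-form geometry", {
  tri <- make_toy_trajectory("triangle", amplitude = 2, t_peak = 60,
                             width = 120)
  ft <- extract_features(tri)
  expect_equal(ft$p38_max_amplitude, 2)
  expect_equal(ft$p38_time_to_max, 60)
  expect_equal(ft$p38_time_to_half_max, 30)
  expect_equal(ft$p38_total_activity, 120)
  expect_equal(ft$p38_n_peaks, 1)
  # both channels carry the same series
  expect_equal(ft$nfkb_total_activity, 120)
})

test_that("total activity equals the sum of the 16 interval integrals", {
  osc <- make_toy_trajectory("damped_oscillation", amplitude = 1.3,
                             period = 120, noise_sd = 0.05, seed = 21)
  ft <- extract_features(osc)
  ints <- as.numeric(ft[grep("^p38_integral_", names(ft))])
  expect_length(ints, 16)
  expect_equal(sum(ints), ft$p38_total_activity, tolerance = 1e-9)
})

test_that("amplitude scaling scales amplitude features and fixes time features", {
  base <- make_toy_trajectory("damped_oscillation", amplitude = 1, period = 100,
                              noise_sd = 0.02, seed = 8)
  scaled <- dplyr::mutate(base, p38_activity = 3 * p38_activity,
                          nfkb_activity = 3 * nfkb_activity)
  fb <- extract_features(base)
  fs <- extract_features(scaled)
  for (nm in c("max_amplitude", "max_derivative", "min_derivative",
               "total_activity", "integral_000_030")) {
    expect_equal(fs[[paste0("p38_", nm)]], 3 * fb[[paste0("p38_", nm)]],
                 tolerance = 1e-9)
  }
  for (nm in c("time_to_half_max", "time_to_max", "time_to_half_total",
               "total_duration", "n_peaks", "dominant_frequency",
               "early_late_ratio")) {
    expect_equal(fs[[paste0("p38_", nm)]], fb[[paste0("p38_", nm)]],
                 tolerance = 1e-9)
  }
})

test_that("dominant frequency lands within one spectral bin of the truth", {
  osc <- make_toy_trajectory("damped_oscillation", amplitude = 1, period = 90,
                             decay_tau = 1e6)
  ft <- extract_features(osc)
  bin <- 1 / (49 * 5)  # 0-4 h segment: 49 frames at 5 min
  expect_lt(abs(ft$p38_dominant_frequency - 1 / 90), bin)
})

test_that("baseline deduction removes constant offsets", {
  tri <- make_toy_trajectory("triangle", amplitude = 1, t_peak = 60,
                             width = 120)
  shifted <- dplyr::mutate(tri, p38_activity = p38_activity + 5,
                           nfkb_activity = nfkb_activity + 5)
  corr <- preprocess(shifted)
  expect_equal(corr$p38_activity, tri$p38_activity, tolerance = 1e-12)
  flat <- dplyr::mutate(tri, p38_activity = 3, nfkb_activity = 3)
  expect_true(all(abs(preprocess(flat)$p38_activity) < 1e-12))
})

test_that("drift correction recovers the signal from mock trajectories", {
  grid <- default_time_grid()
  drift <- 0.3 * sin(2 * pi * pmax(grid, 0) / 480)
  signal <- make_toy_trajectory("triangle", amplitude = 1, t_peak = 60,
                                width = 120)
  noisy <- dplyr::mutate(signal,
                         p38_activity = p38_activity + drift[match(time_min, grid)],
                         nfkb_activity = nfkb_activity + drift[match(time_min, grid)])
  mocks <- purrr::map(1:8, function(i) {
    make_toy_trajectory("flat", amplitude = 0, cell_id = 100 + i,
                        stimulus = "mock") |>
      dplyr::mutate(p38_activity = drift[match(time_min, grid)],
                    nfkb_activity = drift[match(time_min, grid)])
  }) |> purrr::list_rbind()
  corr <- preprocess(noisy, mock = mocks)
  # smoothing tolerance: the drift is slow, so recovery is close
  expect_lt(max(abs(corr$p38_activity - signal$p38_activity)), 0.02)
})

test_that("fewer than eight mocks falls back to baseline-only with a warning", {
  tri <- make_toy_trajectory("triangle", amplitude = 1, t_peak = 60, width = 120)
  mocks <- make_toy_population(3, "flat", amplitude = 0, noise_sd = 0.01)
  expect_warning(out <- preprocess(tri, mock = mocks), "mock")
  expect_equal(out$p38_activity, preprocess(tri)$p38_activity)
})

test_that("preprocess requires baseline frames", {
  tri <- make_toy_trajectory("triangle", amplitude = 1, t_peak = 60, width = 120)
  expect_error(preprocess(dplyr::filter(tri, time_min >= 0)), "baseline")
})

test_that("quality filtering removes incomplete and extreme cells, idempotently", {
  good <- make_toy_population(5, "triangle", amplitude = 1, noise_sd = 0.01,
                              t_peak = 60, width = 120)
  gappy <- make_toy_trajectory("triangle", amplitude = 1, t_peak = 60,
                               width = 120, cell_id = 50) |>
    dplyr::filter(!dplyr::between(time_min, 100, 150))
  extreme <- make_toy_trajectory("step", amplitude = 100, t_peak = 30,
                                 width = 60, cell_id = 60)
  all_cells <- dplyr::bind_rows(good, gappy, extreme)
  out <- quality_filter(all_cells)
  rep <- quality_report(out)
  expect_setequal(unique(out$cell_id), 1:5)
  expect_equal(rep$n_input, 7)
  expect_equal(rep$n_retained, 5)
  expect_equal(rep$n_retained + sum(rep$per_rule$removed) >= rep$n_input, TRUE)
  # idempotent (same rows; the second report sees an already-clean set)
  out2 <- quality_filter(out)
  expect_equal(out2, out, ignore_attr = TRUE)
  expect_equal(quality_report(out2)$retained_fraction, 1)
})

test_that("an all-passing set is fully retained and an all-failing set errors", {
  good <- make_toy_population(4, "triangle", amplitude = 1, noise_sd = 0.01,
                              t_peak = 60, width = 120)
  expect_equal(quality_report(quality_filter(good))$retained_fraction, 1)
  bad <- dplyr::mutate(good, p38_activity = p38_activity + 100)
  expect_error(quality_filter(bad), "thresholds")
})

test_that("responder calls follow the 3-SD / 3-frame / 1-h rule", {
  flat <- make_toy_trajectory("flat", amplitude = 0, noise_sd = 0.01, seed = 2)
  expect_false(call_responders(flat)$responder)
  stp <- make_toy_trajectory("step", amplitude = 1, t_peak = 15, width = 30,
                             noise_sd = 0.01, seed = 3)
  expect_true(call_responders(stp)$responder)
  # a supra-threshold excursion outside the 1-h window does not count
  late <- make_toy_trajectory("step", amplitude = 1, t_peak = 120, width = 60,
                              noise_sd = 0.01, seed = 4)
  expect_false(call_responders(late)$responder)
  # fewer than 3 consecutive frames does not count
  short <- make_toy_trajectory("step", amplitude = 1, t_peak = 15, width = 10,
                               noise_sd = 0.01, seed = 5)
  expect_false(call_responders(short)$responder)
})

test_that("responder fraction counts a constructed 50/50 mix exactly", {
  resp <- make_toy_population(10, "step", amplitude = 1, noise_sd = 0.01,
                              t_peak = 15, width = 60, seed0 = 100)
  nonresp <- make_toy_population(10, "flat", amplitude = 0, noise_sd = 0.01,
                                 seed0 = 200) |>
    dplyr::mutate(cell_id = cell_id + 10)
  mix <- dplyr::bind_rows(resp, nonresp)
  expect_equal(responder_fraction(mix, "p38"), 0.5)
})

test_that("responder call is monotone under pointwise amplitude increase", {
  base <- make_toy_trajectory("step", amplitude = 0.5, t_peak = 15, width = 60,
                              noise_sd = 0.01, seed = 11)
  for (mult in c(1, 2, 5)) {
    up <- dplyr::mutate(base,
                        p38_activity = p38_activity +
                          (mult - 1) * pmax(p38_activity, 0) * (time_min >= 0))
    if (call_responders(base)$responder) {
      expect_true(call_responders(up)$responder)
    }
  }
})

test_that("zero baseline SD falls back to the absolute floor with a warning", {
  stp <- make_toy_trajectory("step", amplitude = 1, t_peak = 15, width = 30)
  expect_warning(out <- call_responders(stp), "floor")
  expect_true(out$responder)
  expect_equal(out$threshold, 1e-3)
})
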