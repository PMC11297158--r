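hill_fractions <- function(doses, maxA, halfA, hillC, intersect) {
  maxA * doses^hillC / (halfA^hillC + doses^hillC) + intersect
}

test_that("responder fractions are counted exactly for constructed mixes", {
  doses <- c(0.1, 1, 10, 100)
  mixes <- c(0, 0.25, 0.5, 0.75)
  traj <- purrr::map2(doses, mixes, function(d, frac) {
    n_resp <- round(20 * frac)
    resp <- if (n_resp > 0) {
      make_toy_population(n_resp, "step", amplitude = 1, noise_sd = 0.01,
                          t_peak = 15, width = 60, seed0 = d * 100,
                          stimulus = "mix") |>
        dplyr::mutate(dose = d)
    }
    non <- make_toy_population(20 - n_resp, "flat", amplitude = 0,
                               noise_sd = 0.01, seed0 = d * 100 + 50,
                               stimulus = "mix") |>
      dplyr::mutate(cell_id = cell_id + n_resp, dose = d)
    dplyr::bind_rows(resp, non)
  }) |> purrr::list_rbind()
  dr <- build_dose_response(traj, pathways = "p38", k_sd = 6)
  expect_equal(dr$fraction, mixes)
  expect_s3_class(dr, "dose_response")
})

test_that("mock is encoded 100x below the lowest dose", {
  traj <- dplyr::bind_rows(
    make_toy_population(5, "flat", noise_sd = 0.01, stimulus = "mix") |>
      dplyr::mutate(dose = 0),
    make_toy_population(5, "step", amplitude = 1, noise_sd = 0.01,
                        t_peak = 15, width = 60, stimulus = "mix") |>
      dplyr::mutate(dose = 10)
  )
  dr <- build_dose_response(traj, pathways = "p38")
  expect_equal(min(dr$dose), 10 / 100)
})

test_that("noiseless Hill parameters are recovered within 1 percent", {
  doses <- c(0.01, 0.1, 0.5, 1, 5, 20)
  truth <- list(maxA = 0.9, halfA = 1.0, hillC = 2, intersect = 0.05)
  d <- tibble::tibble(dose = doses,
                      fraction = hill_fractions(doses, truth$maxA, truth$halfA,
                                                truth$hillC, truth$intersect))
  fit <- fit_hill(d)
  expect_lt(abs(fit$maxA / truth$maxA - 1), 0.01)
  expect_lt(abs(fit$halfA_conc / truth$halfA - 1), 0.01)
  expect_lt(abs(fit$HillC / truth$hillC - 1), 0.01)
  expect_lt(abs(fit$intersect / truth$intersect - 1), 0.01)
  # model identity: A(halfA) = intersect + maxA / 2
  expect_equal(predict(fit, fit$halfA_conc), fit$intersect + fit$maxA / 2,
               tolerance = 1e-9)
})

test_that("fitted parameters respect the declared box bounds", {
  withr::with_seed(14, {
    doses <- 10^seq(-2, 2, length.out = 8)
    d <- tibble::tibble(
      dose = doses,
      fraction = pmin(pmax(hill_fractions(doses, 0.8, 3, 1.5, 0.1) +
                             rnorm(8, 0, 0.05), 0), 1))
    fit <- fit_hill(d)
    expect_gte(fit$HillC, 0.1); expect_lte(fit$HillC, 10)
    expect_gte(fit$halfA_conc, min(doses)); expect_lte(fit$halfA_conc, max(doses))
    expect_gte(fit$maxA, 0); expect_lte(fit$maxA, 1)
    expect_gte(fit$intersect, 0); expect_lte(fit$intersect, 0.9)
  })
})

test_that("flat responses are flagged unidentifiable", {
  d <- tibble::tibble(dose = c(0.1, 1, 10, 100), fraction = 0.4)
  fit <- fit_hill(d)
  expect_false(fit$identifiable)
  expect_lt(abs(fit$intersect + fit$maxA *
                  mean(d$dose^fit$HillC /
                         (fit$halfA_conc^fit$HillC + d$dose^fit$HillC)) - 0.4),
            0.02)
  expect_error(half_max_fold_difference(fit, fit), "unidentifiable")
})

test_that("fit residual does not increase as synthetic noise shrinks", {
  doses <- 10^seq(-2, 2, length.out = 8)
  clean <- hill_fractions(doses, 0.9, 1, 2, 0.05)
  resids <- purrr::map_dbl(c(0.1, 0.03, 0.0), function(s) {
    noisy <- withr::with_seed(5, pmin(pmax(clean + rnorm(8, 0, s), 0), 1))
    fit_hill(tibble::tibble(dose = doses, fraction = noisy))$residual
  })
  expect_true(all(diff(resids) <= 1e-9))
})

test_that("half-max fold difference is a ratio, invariant to dose rescaling", {
  doses <- c(0.05, 0.2, 1, 5, 20, 100)
  f_p38 <- fit_hill(tibble::tibble(
    dose = doses, fraction = hill_fractions(doses, 0.9, 6.7, 2, 0.02)))
  f_nf <- fit_hill(tibble::tibble(
    dose = doses, fraction = hill_fractions(doses, 0.9, 1.0, 2, 0.02)))
  expect_equal(half_max_fold_difference(f_p38, f_nf), 6.7, tolerance = 0.01)
  expect_equal(half_max_fold_difference(f_nf, f_nf), 1.0, tolerance = 1e-6)
  # common rescaling of the dose axis leaves the ratio unchanged
  k <- 37
  f_p38_s <- fit_hill(tibble::tibble(
    dose = doses * k, fraction = hill_fractions(doses, 0.9, 6.7, 2, 0.02)))
  f_nf_s <- fit_hill(tibble::tibble(
    dose = doses * k, fraction = hill_fractions(doses, 0.9, 1.0, 2, 0.02)))
  expect_equal(half_max_fold_difference(f_p38_s, f_nf_s), 6.7,
               tolerance = 0.01)
})

test_that("hill fits need at least four strictly increasing doses", {
  expect_error(fit_hill(tibble::tibble(dose = c(1, 2, 3), fraction = 0.5)),
               "at least 4")
  expect_error(fit_hill(tibble::tibble(dose = c(1, 1, 2, 3),
                                       fraction = c(0.1, 0.2, 0.3, 0.4))),
               "strictly increasing")
})
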