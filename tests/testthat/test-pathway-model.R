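test_that("mock stimulation leaves both activities at baseline", {
  traj <- simulate_cell(pathway_parameters(), default_stimulus_program("mock"))
  expect_lt(max(abs(traj$p38_activity)), 1e-6)
  expect_lt(max(abs(traj$nfkb_activity)), 1e-6)
})

test_that("zero dose is treated as mock", {
  traj <- simulate_cell(pathway_parameters(),
                        default_stimulus_program("LPS", dose = 0))
  expect_lt(max(abs(traj$p38_activity)), 1e-6)
})

test_that("kinase-family mass and total NF-kB are conserved along the trace", {
  p <- pathway_parameters()
  traj <- simulate_cell(p, default_stimulus_program("P3C4"), full_state = TRUE)
  s <- attr(traj, "states")
  for (fam in list(c("p38_u", "p38_p", "p38_pp", "p38_tot"),
                   c("mkk4_u", "mkk4_p", "mkk4_pp", "mkk4_tot"),
                   c("mkk6_u", "mkk6_p", "mkk6_pp", "mkk6_tot"))) {
    total <- rowSums(s[fam[1:3]])
    expect_lt(max(abs(total - p[[fam[4]]])) / p[[fam[4]]], 1e-6)
  }
  nf <- s$complex + s$nfkb_n + s$nfkb_c
  expect_lt(max(abs(nf - p[["nfkb_tot"]])) / p[["nfkb_tot"]], 1e-6)
  expect_true(all(s[setdiff(names(s), "time_min")] > -1e-9))
})

test_that("LPS response is biphasic: MKK6-pp peaks before MKK4-pp", {
  traj <- simulate_cell(pathway_parameters(), default_stimulus_program("LPS"),
                        full_state = TRUE)
  s <- attr(traj, "states")
  t_mkk6 <- s$time_min[which.max(s$mkk6_pp)]
  t_mkk4 <- s$time_min[which.max(s$mkk4_pp)]
  expect_lt(t_mkk6, t_mkk4)
  expect_gt(t_mkk4 - t_mkk6, 30)
})

test_that("doubling total p38 doubles the response without changing its speed", {
  prog <- default_stimulus_program("LPS")
  base <- simulate_cell(pathway_parameters(), prog)
  doubled <- simulate_cell(pathway_parameters(p38_tot = 0.8), prog)
  post_b <- base[base$time_min >= 0, ]
  post_d <- doubled[doubled$time_min >= 0, ]
  expect_gt(max(post_d$p38_activity), max(post_b$p38_activity))
  expect_gt(sum(post_d$p38_activity), sum(post_b$p38_activity))
  t50 <- function(df) {
    y <- df$p38_activity
    df$time_min[which(y >= max(y) / 2)[1]]
  }
  expect_lte(abs(t50(post_d) - t50(post_b)), 5)
})

test_that("the four stimulus programs reproduce their canonical p38 phenotypes", {
  stats <- purrr::map(c("TNF", "LPS", "CpG", "P3C4"), function(st) {
    traj <- simulate_cell(pathway_parameters(), default_stimulus_program(st))
    post <- traj[traj$time_min >= 0, ]
    y <- post$p38_activity
    tibble::tibble(stimulus = st, max_amp = max(y),
                   t50 = post$time_min[which(y >= max(y) / 2)[1]])
  }) |> purrr::list_rbind()
  tnf <- stats[stats$stimulus == "TNF", ]
  others <- stats[stats$stimulus != "TNF", ]
  expect_lt(tnf$max_amp, min(others$max_amp))
  expect_lt(tnf$t50, min(others$t50))
})

test_that("invalid parameters are rejected with informative errors", {
  expect_error(pathway_parameters(bogus = 1), "Unknown pathway parameter")
  expect_error(pathway_parameters(p38_tot = -1), "positive")
  expect_error(pathway_parameters(n_mkk6 = 20), "Hill coefficients")
})

test_that("lognormal sampling has the right median, spread, and determinism", {
  rep_par <- pathway_parameters()
  spec <- population_spec(n_cells = 20000, seed = 42)
  tab <- sample_parameters(spec, rep_par)
  med <- median(tab$p38_tot)
  expect_lt(abs(med / rep_par[["p38_tot"]] - 1), 0.02)
  frac <- mean(tab$p38_tot >= 0.5 * rep_par[["p38_tot"]] &
                 tab$p38_tot <= 2 * rep_par[["p38_tot"]])
  expect_lt(abs(frac - 0.99), 0.005)
  # determinism
  tab2 <- sample_parameters(spec, rep_par)
  expect_identical(tab, tab2)
})

test_that("sigma_log = 0 and denoise flags collapse heterogeneity", {
  rep_par <- pathway_parameters()
  tab0 <- sample_parameters(population_spec(n_cells = 10, sigma_log = 0,
                                            seed = 1), rep_par)
  for (nm in distributed_parameter_names()) {
    expect_true(all(tab0[[nm]] == rep_par[[nm]]))
  }
  tabd <- sample_parameters(
    population_spec(n_cells = 10, seed = 1,
                    denoise = c("p38_module", "nfkb_module", "receptor")),
    rep_par)
  expect_true(all(purrr::map_lgl(distributed_parameter_names(),
                                 function(nm) sd(tabd[[nm]]) == 0)))
  # denoising one module only zeroes that module's columns
  tabn <- sample_parameters(population_spec(n_cells = 10, seed = 1,
                                            denoise = "nfkb_module"), rep_par)
  expect_equal(sd(tabn$nfkb_tot), 0)
  expect_gt(sd(tabn$p38_tot), 0)
})

test_that("unknown distributed parameter names fail with the valid list", {
  expect_error(
    sample_parameters(population_spec(n_cells = 2,
                                      distributed_params = "not_a_param"),
                      pathway_parameters()),
    "Valid names")
})

test_that("population simulation is paired, heterogeneous, and seeded", {
  spec <- population_spec(n_cells = 8, seed = 3)
  prog <- default_stimulus_program("LPS")
  pop <- simulate_population(spec, prog)
  expect_equal(dplyr::n_distinct(pop$cell_id), 8)
  amps <- pop |>
    dplyr::filter(time_min >= 0) |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(amp = max(p38_activity))
  expect_gt(sd(amps$amp) / mean(amps$amp), 0)
  pop2 <- simulate_population(spec, prog)
  expect_equal(pop, pop2)
})

test_that("fully denoised populations are identical across cells", {
  spec <- population_spec(n_cells = 4, seed = 5,
                          denoise = c("p38_module", "nfkb_module", "receptor"))
  pop <- simulate_population(spec, default_stimulus_program("TNF"))
  ref <- pop[pop$cell_id == 1, c("p38_activity", "nfkb_activity")]
  for (i in 2:4) {
    cur <- pop[pop$cell_id == i, c("p38_activity", "nfkb_activity")]
    expect_equal(cur, ref, ignore_attr = TRUE)
  }
})

test_that("unit rescaling applies the printed factors and round-trips", {
  expect_equal(round(0.08 / 0.73, 4), rescale_factors()$p38)
  traj <- make_toy_trajectory("triangle", amplitude = 0.73, t_peak = 60,
                              width = 120)
  scaled <- rescale_units(traj, "AU_to_model")
  expect_equal(max(scaled$p38_activity), 0.0800, tolerance = 1e-4 / 0.08)
  expect_equal(max(scaled$nfkb_activity), 0.73 * 0.0383, tolerance = 1e-10)
  expect_true(all(scaled$units == "model_uM"))
  back <- rescale_units(scaled, "model_to_AU")
  expect_equal(back$p38_activity, traj$p38_activity, tolerance = 1e-12)
  expect_error(rescale_units(traj, "model_to_AU"), "units")
  expect_error(rescale_units(traj, factors = list(p38 = -1, nfkb = 1)),
               "positive")
})

test_that("toy trajectories respect grid bounds and determinism", {
  expect_error(make_toy_trajectory("triangle", t_peak = 460, width = 200),
               "grid")
  expect_error(make_toy_trajectory("damped_oscillation", period = 1000),
               "period")
  a <- make_toy_trajectory("step", noise_sd = 0.1, seed = 7)
  b <- make_toy_trajectory("step", noise_sd = 0.1, seed = 7)
  expect_identical(a, b)
})
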