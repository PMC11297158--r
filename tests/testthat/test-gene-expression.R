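constant_traj <- function(p38, nfkb, t_end = 3000) {
  tibble::tibble(cell_id = 1L, stimulus = "const", dose = 1, replicate = 1,
                 time_min = seq(0, t_end, by = 5),
                 p38_activity = p38, nfkb_activity = nfkb,
                 units = "model_uM")
}

test_that("constant half-saturating inputs reach the closed-form steady state", {
  p <- gene_model_parameters()
  m <- simulate_mrna(p, constant_traj(p$K_d_p38, p$K_d_NFkB))
  expect_equal(tail(m$mrna, 1), p$k_syn_max / p$k_deg_max,
               tolerance = 1e-6)
})

test_that("arbitrary constant inputs converge to k_syn f / (k_deg g)", {
  p <- gene_model_parameters(k_deg_max = 0.05)
  for (vals in list(c(0.02, 0.3), c(0.1, 0.05), c(0.25, 0.2))) {
    f <- vals[2]^p$n_nfkb / (p$K_d_NFkB^p$n_nfkb + vals[2]^p$n_nfkb)
    g <- p$K_d_p38^p$n_p38 / (p$K_d_p38^p$n_p38 + vals[1]^p$n_p38)
    # horizon long enough for the slowest effective degradation rate
    t_end <- 50 / (p$k_deg_max * g)
    m <- simulate_mrna(p, constant_traj(vals[1], vals[2], t_end = t_end))
    expect_equal(tail(m$mrna, 1), p$k_syn_max * f / (p$k_deg_max * g),
                 tolerance = 1e-6)
  }
})

test_that("no NF-kB means no transcript at any time", {
  m <- simulate_mrna(gene_model_parameters(), constant_traj(0.1, 0))
  expect_true(all(m$mrna == 0))
})

test_that("with p38 absent the AND gate collapses onto the NF-kB-only model", {
  traj <- simulate_cell(pathway_parameters(), default_stimulus_program("LPS")) |>
    dplyr::mutate(p38_activity = 0)
  m_and <- simulate_mrna(gene_model_parameters(mode = "AND"), traj)
  m_nf <- simulate_mrna(gene_model_parameters(mode = "NFkB_only"), traj)
  expect_identical(m_and$mrna, m_nf$mrna)
})

test_that("the transcript trace is linear in the synthesis rate", {
  traj <- simulate_cell(pathway_parameters(), default_stimulus_program("P3C4"))
  m1 <- simulate_mrna(gene_model_parameters(k_syn_max = 1), traj)
  m2 <- simulate_mrna(gene_model_parameters(k_syn_max = 2), traj)
  expect_equal(m2$mrna, 2 * m1$mrna, tolerance = 1e-6)
})

test_that("identical denoised cells give zero across-cell expression variance", {
  pop <- simulate_population(
    population_spec(n_cells = 3, seed = 2,
                    denoise = c("p38_module", "nfkb_module", "receptor")),
    default_stimulus_program("LPS"))
  ed <- population_expression(pop)
  expect_true(all(ed$summary$var_mrna < 1e-20))
})

test_that("negative activity excursions are clamped before the Hill terms", {
  p <- gene_model_parameters()
  neg <- constant_traj(-0.05, -0.3)
  m <- simulate_mrna(p, neg)
  expect_true(all(m$mrna == 0))
})

test_that("Fano factor matches Poisson and hand-computed references", {
  expect_equal(fano_factor(c(0, 0, 4, 4)), 8 / 3)
  expect_equal(fano_factor(rep(2, 10)), 0)
  withr::with_seed(2, {
    x <- rpois(1e5, 5)
    expect_equal(fano_factor(x), 1, tolerance = 0.02)
  })
  expect_error(fano_factor(c(0, 0)), "mean")
  # scale covariance: fano(c x) = c fano(x)
  withr::with_seed(3, {
    x <- rpois(1000, 4)
    expect_equal(fano_factor(5 * x), 5 * fano_factor(x), tolerance = 1e-12)
  })
})

test_that("bimodality coefficient hits its distributional references", {
  withr::with_seed(4, {
    expect_equal(bimodality_coefficient(rnorm(30000)), 1 / 3, tolerance = 0.06)
    expect_equal(bimodality_coefficient(runif(30000)), 5 / 9, tolerance = 0.036)
    expect_equal(bimodality_coefficient(rep(c(1, 2), 5000)), 1,
                 tolerance = 0.02)
  })
  # affine invariance
  withr::with_seed(5, {
    x <- rnorm(500)
    expect_equal(bimodality_coefficient(3 * x - 7),
                 bimodality_coefficient(x), tolerance = 1e-12)
  })
  # zeros dropped under nonzero_only
  x <- c(rep(0, 50), rep(c(1, 2), 25))
  expect_equal(bimodality_coefficient(x, nonzero_only = TRUE),
               bimodality_coefficient(rep(c(1, 2), 25)))
  expect_error(bimodality_coefficient(c(1, 2, 3)), "at least 4")
})

test_that("permutation test separates clear effects and is exact under the null", {
  expect_equal(permutation_test_mean_diff(1:20, 1:20, n_perm = 500, seed = 1), 1)
  withr::with_seed(6, {
    a <- rnorm(50, 0)
    b <- rnorm(50, 5)
    expect_lte(permutation_test_mean_diff(a, b, n_perm = 5000, seed = 2), 0.001)
  })
  expect_error(permutation_test_mean_diff(1:5, 1:5, n_perm = 50), "100")
  expect_error(permutation_test_mean_diff(numeric(), 1:5), "non-empty")
})
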