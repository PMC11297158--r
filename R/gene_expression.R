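#' AND-gate gene-expression model parameters
#'
#' Parameters of the kinetic mRNA model in which NF-kB drives transcription
#' and p38 suppresses degradation (stabilises the transcript):
#' \deqn{\frac{d[mRNA]}{dt} = k_{syn,max}
#'   \frac{N^{n_{nfkb}}}{K_{d,NFkB}^{n_{nfkb}} + N^{n_{nfkb}}}
#'   - k_{deg,max} \frac{K_{d,p38}^{n_{p38}}}{K_{d,p38}^{n_{p38}} +
#'   P^{n_{p38}}} \, [mRNA]}
#' with \eqn{N(t)} nuclear NF-kB and \eqn{P(t)} pp-p38 (uM). In
#' `"NFkB_only"` mode the p38 Hill factor is replaced by 1, so degradation
#' runs at the full \eqn{k_{deg,max}}. Defaults place the two \eqn{K_d}
#' values mid-range of simulated activities; they are package choices, not
#' published values, and are fully configurable.
#'
#' @param k_syn_max Maximal synthesis rate (mRNA/min).
#' @param k_deg_max Maximal degradation rate (1/min).
#' @param K_d_NFkB,K_d_p38 Hill half-saturation constants (uM).
#' @param n_nfkb,n_p38 Hill coefficients.
#' @param mode `"AND"` or `"NFkB_only"`.
#' @return A list of class `gene_model_parameters`.
#' @export
gene_model_parameters <- function(k_syn_max = 1, k_deg_max = 0.02,
                                  K_d_NFkB = 0.15, K_d_p38 = 0.04,
                                  n_nfkb = 2, n_p38 = 2,
                                  mode = c("AND", "NFkB_only")) {
  mode <- match.arg(mode)
  vals <- c(k_syn_max, k_deg_max, K_d_NFkB, K_d_p38, n_nfkb, n_p38)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All gene-model parameters must be positive and finite.")
  }
  structure(list(k_syn_max = k_syn_max, k_deg_max = k_deg_max,
                 K_d_NFkB = K_d_NFkB, K_d_p38 = K_d_p38,
                 n_nfkb = n_nfkb, n_p38 = n_p38, mode = mode),
            class = "gene_model_parameters")
}

#' Simulate mRNA dynamics for one cell
#'
#' Integrates the AND-gate mRNA equation driven by a cell's paired activity
#' trajectory (model units, uM). Inputs are linearly interpolated between
#' frames; negative activity excursions (baseline noise) are clamped to 0
#' before entering the Hill terms; initial mRNA is 0 at stimulation.
#'
#' @param params A [gene_model_parameters()].
#' @param traj A single cell's long trajectory tibble in model units.
#' @return A tibble `time_min`, `mrna` on the post-stimulus grid.
#' @examples
#' tr <- simulate_cell(pathway_parameters(), default_stimulus_program("LPS"))
#' m <- simulate_mrna(gene_model_parameters(), tr)
#' tail(m, 1)
#' @export
simulate_mrna <- function(params, traj) {
  stopifnot(inherits(params, "gene_model_parameters"))
  if ("units" %in% names(traj) && !all(traj$units == "model_uM")) {
    abort("`traj` must be in model units (uM); apply rescale_units() first.")
  }
  if ("cell_id" %in% names(traj) && dplyr::n_distinct(traj$cell_id) > 1) {
    abort("`traj` must contain a single cell; use population_expression().")
  }
  post <- traj |> filter(.data$time_min >= 0) |> arrange(.data$time_min)
  t <- post$time_min
  nf <- approxfun(t, pmax(post$nfkb_activity, 0), rule = 2)
  pp <- approxfun(t, pmax(post$p38_activity, 0), rule = 2)
  syn_hill <- function(x) {
    xn <- x^params$n_nfkb
    xn / (params$K_d_NFkB^params$n_nfkb + xn)
  }
  deg_hill <- if (params$mode == "AND") {
    function(x) {
      kn <- params$K_d_p38^params$n_p38
      kn / (kn + x^params$n_p38)
    }
  } else {
    function(x) 1
  }
  rhs <- function(tt, y, parms) {
    list(params$k_syn_max * syn_hill(nf(tt)) -
           params$k_deg_max * deg_hill(pp(tt)) * y[1])
  }
  out <- deSolve::lsoda(c(mrna = 0), t, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (nrow(out) < length(t)) {
    abort(paste0("mRNA integration broke down at t = ",
                 signif(out[nrow(out), 1], 4), " min."))
  }
  tibble(time_min = out[, 1], mrna = out[, 2])
}

#' Population-level AND-gate gene expression
#'
#' Runs [simulate_mrna()] for every cell of a paired trajectory set, under
#' one or both regulatory modes, and samples the predicted single-cell mRNA
#' abundances at 0.25, 1, 3 and 8 h.
#'
#' @param traj Long trajectory tibble (model units), many cells.
#' @param params A [gene_model_parameters()] (its `mode` is overridden per
#'   requested mode).
#' @param modes Character vector of modes to run.
#' @param sample_times_h Sampling times in hours.
#' @return An object of class `expression_distribution`: `cells` (tibble
#'   cell_id x mode x time_h x mrna) and `summary` (per mode x time: mean,
#'   variance, Fano factor, bimodality coefficient of non-zero values when
#'   enough cells).
#' @export
population_expression <- function(traj, params = gene_model_parameters(),
                                  modes = c("AND", "NFkB_only"),
                                  sample_times_h = c(0.25, 1, 3, 8)) {
  keys <- intersect(cell_key_vars(), names(traj))
  cells <- traj |> group_by(across(all_of(keys))) |> group_split()
  out <- map(cells, function(df) {
    res <- map(modes, function(md) {
      pm <- params
      pm$mode <- md
      m <- simulate_mrna(pm, df)
      idx <- vapply(sample_times_h * 60,
                    function(tt) which.min(abs(m$time_min - tt)), integer(1))
      tibble(cell_id = df$cell_id[1], mode = md,
             time_h = sample_times_h, mrna = m$mrna[idx])
    })
    list_rbind(res)
  }) |> list_rbind()

  summ <- out |>
    group_by(.data$mode, .data$time_h) |>
    summarise(
      n = dplyr::n(),
      mean_mrna = mean(.data$mrna),
      var_mrna = var(.data$mrna),
      fano = if (mean(.data$mrna) > 0) var(.data$mrna) / mean(.data$mrna) else NA_real_,
      bimodality = tryCatch(
        bimodality_coefficient(.data$mrna, nonzero_only = TRUE),
        error = function(e) NA_real_
      ),
      .groups = "drop"
    )
  structure(list(cells = out, summary = summ, params = params),
            class = "expression_distribution")
}

#' @export
print.expression_distribution <- function(x, ...) {
  cat("AND-gate expression distributions\n")
  print(x$summary)
  invisible(x)
}

#' Fano factor
#'
#' Sample variance divided by the mean: 1 for a Poisson distribution,
#' larger for overdispersed expression. Note the Fano factor is not
#' scale-free: `fano(c * x) = c * fano(x)`.
#'
#' @param values Numeric vector with positive mean.
#' @return A single number.
#' @examples
#' fano_factor(c(0, 0, 4, 4))  # 8/3
#' @export
fano_factor <- function(values) {
  m <- mean(values)
  if (m <= 0) abort("Fano factor undefined: mean is not positive.")
  var(values) / m
}

#' Bimodality coefficient
#'
#' \deqn{BC = \frac{g_1^2 + 1}{g_2 + \frac{3 (n-1)^2}{(n-2)(n-3)}}}
#' with \eqn{g_1} the (bias-corrected) sample skewness and \eqn{g_2} the
#' sample excess kurtosis. A normal distribution gives 1/3, a uniform 5/9;
#' values above ~0.555 suggest bimodality. Expression analyses conventionally
#' drop zeros first (`nonzero_only = TRUE`).
#'
#' @param values Numeric vector.
#' @param nonzero_only Drop exact zeros before computing.
#' @return A single number.
#' @examples
#' bimodality_coefficient(rep(c(0, 1), 500))  # two-point: -> 1
#' @export
bimodality_coefficient <- function(values, nonzero_only = FALSE) {
  if (nonzero_only) values <- values[values != 0]
  n <- length(values)
  if (n < 4) abort("Bimodality coefficient needs at least 4 values.")
  g1 <- e1071::skewness(values, type = 2)
  g2 <- e1071::kurtosis(values, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Permutation test for a difference in means
#'
#' Two-sided test of the difference in group means, with p-value
#' \eqn{(1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\}) / (n_{perm} + 1)}.
#'
#' @param group_a,group_b Numeric vectors.
#' @param n_perm Number of permutations (default 10,000; at least 100).
#' @param seed Integer seed.
#' @return The p-value.
#' @export
permutation_test_mean_diff <- function(group_a, group_b, n_perm = 10000,
                                       seed = 1L) {
  if (!length(group_a) || !length(group_b)) {
    abort("Both groups must be non-empty.")
  }
  if (n_perm < 100) abort("Use at least 100 permutations.")
  obs <- abs(mean(group_a) - mean(group_b))
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  n <- length(pooled)
  tot <- sum(pooled)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(n, na)
      sa <- sum(pooled[ia])
      abs(sa / na - (tot - sa) / (n - na)) >= obs
    }, logical(1)))
  })
  (1 + exceed) / (n_perm + 1)
}
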