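#' Build a responder-fraction dose-response table
#'
#' Computes the fraction of responding cells (see [call_responders()]) at
#' each dose of a stimulus, for one or both pathways. Mock stimulation
#' (dose 0) is re-encoded on the dose axis as 100x below the lowest
#' non-zero dose, so it can sit on a logarithmic axis.
#'
#' @param traj Long trajectory tibble covering several doses of one
#'   stimulus (mock rows may carry dose 0).
#' @param pathways Character vector, subset of `c("p38", "nfkb")`.
#' @param ... Passed to [call_responders()] (`k_sd`, `n_consecutive`,
#'   `window`, `sd_floor`).
#' @return A tibble of class `dose_response`: `stimulus`, `dose` (mock
#'   re-encoded), `pathway`, `fraction`, `n_cells`.
#' @export
build_dose_response <- function(traj, pathways = c("p38", "nfkb"), ...) {
  pathways <- match.arg(pathways, several.ok = TRUE)
  doses <- sort(unique(traj$dose))
  nonzero <- doses[doses > 0]
  if (!length(nonzero)) abort("No non-zero doses in `traj`.")
  mock_dose <- min(nonzero) / 100
  rows <- map(pathways, function(pw) {
    traj |>
      group_by(.data$stimulus, .data$dose) |>
      group_split() |>
      map(function(df) {
        if (!nrow(df)) abort("Dose with zero cells.")
        tibble(
          stimulus = df$stimulus[1],
          dose = if (df$dose[1] == 0) mock_dose else df$dose[1],
          pathway = pw,
          fraction = responder_fraction(df, pw, ...),
          n_cells = dplyr::n_distinct(df$cell_id)
        )
      }) |>
      list_rbind()
  })
  out <- list_rbind(rows) |> arrange(.data$pathway, .data$dose)
  class(out) <- c("dose_response", class(out))
  out
}

#' Fit the four-parameter Hill dose-response model
#'
#' Fits \deqn{A = \mathrm{maxA} \cdot
#'   \frac{c^{\mathrm{HillC}}}{\mathrm{halfA\_conc}^{\mathrm{HillC}} +
#'   c^{\mathrm{HillC}}} + \mathrm{intersect}}
#' to responder fractions over dose by bounded nonlinear least squares,
#' with box bounds HillC in \eqn{[0.1, 10]}, halfA_conc in
#' \eqn{[\min(dose), \max(dose)]}, maxA in \eqn{[0, 1]} and intersect in
#' \eqn{[0, 0.9]}. Five deterministic multi-starts span the halfA bounds
#' log-uniformly; the best residual wins (ties by first index).
#'
#' @param dr A [build_dose_response()] table, or any tibble with `dose` and
#'   `fraction` columns.
#' @param pathway If `dr` covers both pathways, which one to fit.
#' @return An object of class `hill_fit`: `maxA`, `halfA_conc`, `HillC`,
#'   `intersect`, `residual` (sum of squares), `identifiable` (FALSE when
#'   the response is flat and halfA_conc is meaningless), `data`.
#' @examples
#' doses <- c(0.01, 0.1, 1, 10, 100, 1000)
#' d <- tibble::tibble(
#'   dose = doses,
#'   fraction = 0.05 + 0.9 * doses^2 / (1 + doses^2)
#' )
#' fit_hill(d)
#' @export
fit_hill <- function(dr, pathway = NULL) {
  if (!is.null(pathway) && "pathway" %in% names(dr)) {
    pw <- pathway
    dr <- filter(dr, .data$pathway == pw)
  }
  dr <- arrange(as_tibble(dr), .data$dose)
  if (nrow(dr) < 4) abort("Hill fitting needs at least 4 dose points.")
  if (any(diff(dr$dose) <= 0)) abort("Doses must be strictly increasing.")
  conc <- dr$dose
  a <- dr$fraction

  if (max(a) - min(a) < 1e-8) {
    # flat response: the dose term carries no signal and halfA_conc is
    # meaningless; report the offset directly instead of fitting
    return(structure(
      list(maxA = 0, halfA_conc = exp(mean(log(conc))), HillC = 1,
           intersect = min(mean(a), 0.9), residual = sum((a - mean(a))^2),
           identifiable = FALSE, data = dr, fit = NULL),
      class = "hill_fit"
    ))
  }

  lower <- c(maxA = 0, halfA_conc = min(conc), HillC = 0.1, intersect = 0)
  upper <- c(maxA = 1, halfA_conc = max(conc), HillC = 10, intersect = 0.9)
  halfa_starts <- exp(seq(log(min(conc)), log(max(conc)), length.out = 5))

  best <- NULL
  for (h0 in halfa_starts) {
    start <- list(maxA = min(max(max(a) - min(a), 0.05), 1),
                  halfA_conc = h0, HillC = 1,
                  intersect = min(max(min(a), 0), 0.9))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fraction ~ maxA * dose^HillC / (halfA_conc^HillC + dose^HillC) + intersect,
        data = dr, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    abort("Hill fit failed to converge from any of the 5 starting points.")
  }
  cf <- coef(best$fit)
  # a flat response leaves halfA_conc unidentifiable
  identifiable <- (max(a) - min(a)) > 1e-6 && cf[["maxA"]] > 1e-3
  structure(
    list(maxA = cf[["maxA"]], halfA_conc = cf[["halfA_conc"]],
         HillC = cf[["HillC"]], intersect = cf[["intersect"]],
         residual = best$rss, identifiable = identifiable,
         data = dr, fit = best$fit),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill dose-response fit\n")
  cat(sprintf("  maxA = %.4f, halfA_conc = %.4g, HillC = %.3f, intersect = %.4f\n",
              x$maxA, x$halfA_conc, x$HillC, x$intersect))
  cat("  residual SS:", signif(x$residual, 4),
      if (!x$identifiable) " (halfA_conc unidentifiable: flat response)" else "",
      "\n")
  invisible(x)
}

#' Predict from a Hill fit
#' @param object A `hill_fit`.
#' @param conc Doses at which to predict.
#' @param ... Unused.
#' @export
predict.hill_fit <- function(object, conc, ...) {
  object$maxA * conc^object$HillC /
    (object$halfA_conc^object$HillC + conc^object$HillC) + object$intersect
}

#' Fold difference between p38 and NF-kB half-max concentrations
#'
#' The ratio of the half-maximal dose for p38 activation to that for NF-kB
#' activation: values above 1 mean p38 requires more ligand than NF-kB.
#'
#' @param fit_p38,fit_nfkb `hill_fit` objects for the two pathways.
#' @return A single number, `halfA_conc(p38) / halfA_conc(nfkb)`.
#' @export
half_max_fold_difference <- function(fit_p38, fit_nfkb) {
  stopifnot(inherits(fit_p38, "hill_fit"), inherits(fit_nfkb, "hill_fit"))
  if (!fit_p38$identifiable || !fit_nfkb$identifiable) {
    abort("halfA_conc is unidentifiable for at least one pathway (flat response).")
  }
  fit_p38$halfA_conc / fit_nfkb$halfA_conc
}
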