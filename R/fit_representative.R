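#' Fit representative-cell p38 parameters to target trajectories
#'
#' Calibrates a subset of pathway parameters by least squares against
#' stimulus-labeled target p38 trajectories (typically one representative
#' experimental cell per stimulus, rescaled to model units with
#' [rescale_units()]). The objective is the summed squared error between
#' simulated and target baseline-deducted pp-p38 series across all targets.
#' Optimisation runs on log-transformed parameters (all rates and totals are
#' positive) with `stats::nlminb`.
#'
#' @param initial A [pathway_parameters()] starting point.
#' @param targets A long trajectory tibble with columns `stimulus`, `dose`,
#'   `time_min`, `p38_activity` (model units): one target trajectory per
#'   stimulus, e.g. the four canonical high-dose stimuli.
#' @param fit_params Names of the parameters to optimise; defaults to the
#'   three kinase totals.
#' @param programs Optional named list of [stimulus_program()]s keyed by
#'   stimulus; defaults to [default_stimulus_program()] at each target's dose.
#' @param control Passed to [stats::optim()] (Nelder-Mead).
#' @return A list of class `representative_fit`: `parameters` (the fitted
#'   [pathway_parameters()]), `objective` (final SSE), `convergence`
#'   (0 = success), `message`, and `initial_objective`.
#' @examples
#' \donttest{
#' rep_par <- pathway_parameters()
#' targ <- simulate_cell(rep_par, default_stimulus_program("TNF")) |>
#'   dplyr::select(stimulus, dose, time_min, p38_activity)
#' fit <- fit_representative(pathway_parameters(p38_tot = 0.45), targ)
#' fit$objective
#' }
#' @export
fit_representative <- function(initial, targets,
                               fit_params = c("p38_tot", "mkk4_tot", "mkk6_tot"),
                               programs = NULL,
                               control = list(maxit = 1000,
                                              reltol = 1e-12)) {
  validate_pathway_parameters(initial)
  req <- c("stimulus", "dose", "time_min", "p38_activity")
  miss <- setdiff(req, names(targets))
  if (length(miss)) {
    abort(paste0("`targets` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (all(abs(targets$p38_activity) < 1e-12)) {
    abort("Degenerate targets: all p38 activities are zero; nothing to fit.")
  }
  bad <- setdiff(fit_params, names(initial))
  if (length(bad)) {
    abort(paste0("Unknown fit parameter(s): ", paste(bad, collapse = ", ")))
  }

  split_targets <- targets |>
    group_by(.data$stimulus, .data$dose) |>
    group_split()
  if (is.null(programs)) {
    programs <- map(split_targets, function(tt) {
      default_stimulus_program(as.character(tt$stimulus[1]), dose = tt$dose[1])
    })
  } else {
    programs <- map(split_targets, function(tt) programs[[as.character(tt$stimulus[1])]])
  }

  objective <- function(logx) {
    pars <- initial
    pars[fit_params] <- exp(logx)
    ok <- tryCatch({
      validate_pathway_parameters(pars)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) return(1e6)
    sse <- 0
    for (j in seq_along(split_targets)) {
      tt <- split_targets[[j]]
      sim <- tryCatch(
        simulate_cell(pars, programs[[j]], grid = tt$time_min),
        error = function(e) NULL
      )
      if (is.null(sim)) return(1e6)
      sse <- sse + sum((sim$p38_activity - tt$p38_activity)^2)
    }
    sse
  }

  x0 <- log(unclass(initial)[fit_params])
  f0 <- objective(x0)
  # Nelder-Mead: derivative-free, robust to the integrator-tolerance noise
  # that finite-difference gradients would amplify
  opt <- stats::optim(x0, objective, method = "Nelder-Mead",
                      control = control)
  opt$objective <- opt$value
  fitted <- initial
  fitted[fit_params] <- exp(opt$par)
  if (opt$convergence != 0 && opt$objective > f0) {
    abort(paste0("Optimizer failed to improve on the initial parameters ",
                 "(objective ", signif(opt$objective, 4), "); best-so-far ",
                 "parameters are in the error condition."),
          class = "p38nfkb_fit_error")
  }
  structure(
    list(parameters = fitted, objective = opt$objective,
         convergence = opt$convergence, message = opt$message,
         initial_objective = f0, fit_params = fit_params),
    class = "representative_fit"
  )
}

#' @export
print.representative_fit <- function(x, ...) {
  cat("Representative-cell fit\n")
  cat("  parameters fit:", paste(x$fit_params, collapse = ", "), "\n")
  cat("  SSE:", signif(x$objective, 6),
      "(initial", paste0(signif(x$initial_objective, 6), ")"), "\n")
  invisible(x)
}
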