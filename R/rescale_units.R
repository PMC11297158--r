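#' Rescale trajectories between arbitrary units and model concentrations
#'
#' Converts kinase-translocation-reporter and nuclear-fluorescence readouts
#' (A.U.) to model concentrations (uM) and back, by a per-channel
#' multiplicative factor. The default p38 factor maps the maximal
#' baseline-corrected KTR C/N ratio observed experimentally (0.73 A.U.) onto
#' an assumed maximal pp-p38 concentration of 0.08 uM, i.e.
#' 0.08 / 0.73 = 0.1096. The default NF-kB factor is 0.0383, mapping the
#' 90th-percentile LPS response (7.62 A.U.) onto 0.30 uM nuclear NF-kB.
#' (0.30 / 7.62 rounds to 0.0394; the conventional published factor 0.0383
#' is kept as the default — see the methods vignette.)
#'
#' @param traj A long trajectory tibble with `p38_activity`, `nfkb_activity`
#'   and a `units` column (`"AU"` or `"model_uM"`).
#' @param direction `"AU_to_model"` or `"model_to_AU"`.
#' @param factors Named list with elements `p38` and `nfkb`: the
#'   multiplicative A.U. -> uM factors.
#' @return The trajectory tibble with rescaled activities and updated
#'   `units`.
#' @examples
#' rescale_factors()
#' @export
rescale_units <- function(traj,
                          direction = c("AU_to_model", "model_to_AU"),
                          factors = rescale_factors()) {
  direction <- match.arg(direction)
  if (factors$p38 <= 0 || factors$nfkb <= 0) {
    abort("Rescaling factors must be positive.")
  }
  from <- if (direction == "AU_to_model") "AU" else "model_uM"
  to <- if (direction == "AU_to_model") "model_uM" else "AU"
  if ("units" %in% names(traj) && !all(traj$units == from)) {
    abort(paste0("`traj` units are not uniformly '", from,
                 "'; refusing to rescale."))
  }
  fp <- if (direction == "AU_to_model") factors$p38 else 1 / factors$p38
  fn <- if (direction == "AU_to_model") factors$nfkb else 1 / factors$nfkb
  traj |>
    mutate(p38_activity = .data$p38_activity * fp,
           nfkb_activity = .data$nfkb_activity * fn,
           units = to)
}

#' @rdname rescale_units
#' @export
rescale_factors <- function() list(p38 = 0.1096, nfkb = 0.0383)
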