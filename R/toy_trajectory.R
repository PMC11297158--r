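#' Parametric toy trajectories with analytically known features
#'
#' Generates single-channel test pulses on the standard grid whose dynamic
#' features are known in closed form: a `flat` line, a `step`, a symmetric
#' `triangle` pulse, or a `damped_oscillation`
#' \eqn{A e^{-t/\tau} \sin(2\pi t / T)} (rectified at 0). The same series is
#' written to both activity channels so the fixture can stand in for either
#' pathway. Baseline frames are pure noise.
#'
#' @param shape `"flat"`, `"step"`, `"triangle"` or `"damped_oscillation"`.
#' @param amplitude Peak amplitude (A.U.).
#' @param t_peak Peak time for `triangle` / step-onset time for `step` (min).
#' @param width Full width of the triangle at its base, or step duration (min).
#' @param period Oscillation period (min).
#' @param decay_tau Envelope time constant for the oscillation (min).
#' @param noise_sd Gaussian noise SD added to every frame.
#' @param seed Integer seed (the fixture is deterministic given the seed).
#' @param grid Time grid, see [default_time_grid()].
#' @param cell_id,stimulus,dose,replicate Metadata for the output rows.
#' @return A long trajectory tibble (`units = "AU"`).
#' @examples
#' tri <- make_toy_trajectory("triangle", amplitude = 2, t_peak = 60,
#'                            width = 120)
#' max(tri$p38_activity)
#' @export
make_toy_trajectory <- function(shape = c("flat", "step", "triangle",
                                          "damped_oscillation"),
                                amplitude = 1, t_peak = 60, width = 120,
                                period = 90, decay_tau = 120,
                                noise_sd = 0, seed = 1L,
                                grid = default_time_grid(),
                                cell_id = 1L, stimulus = "toy", dose = 0,
                                replicate = 1L) {
  shape <- match.arg(shape)
  check_uniform_grid(grid)
  span <- max(grid)
  if (shape == "triangle" && (t_peak + width / 2) > span) {
    abort("Triangle pulse extends past the end of the time grid.")
  }
  if (shape == "step" && (t_peak + width) > span) {
    abort("Step extends past the end of the time grid.")
  }
  if (shape == "damped_oscillation" && period > span) {
    abort("Oscillation period exceeds the grid span.")
  }
  t <- grid
  base <- switch(shape,
    flat = rep(0, length(t)),
    step = ifelse(t >= t_peak & t < t_peak + width, amplitude, 0),
    triangle = {
      half <- width / 2
      pmax(0, amplitude * (1 - abs(t - t_peak) / half)) * (t >= 0)
    },
    damped_oscillation = {
      v <- amplitude * exp(-pmax(t, 0) / decay_tau) * sin(2 * pi * pmax(t, 0) / period)
      pmax(v, 0) * (t >= 0)
    }
  )
  base[t < 0] <- 0
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, rnorm(length(t), sd = noise_sd))
  } else {
    rep(0, length(t))
  }
  y <- base + noise
  tibble(
    cell_id = cell_id, stimulus = stimulus, dose = dose,
    replicate = replicate, time_min = t,
    p38_activity = y, nfkb_activity = y, units = "AU"
  )
}
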