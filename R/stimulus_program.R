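#' Stimulus programs: parametric IKK and TAK1 input curves
#'
#' A stimulus program describes the two upstream kinase activities that drive
#' the pathway model: IKK (feeding both the NF-kB module and, via Tpl2/p105,
#' the MKK3/6 branch) and TAK1 (feeding the MKK4 branch). Each activity is a
#' difference-of-exponentials pulse, optionally followed by a delayed second
#' phase (used for the TRIF-dependent late phase of LPS signaling), bounded to
#' \eqn{[0, 1]}. Receptor-level biochemistry is deliberately not modeled; the
#' curves stand in for the output of the receptor-proximal machinery.
#'
#' `stimulus_program()` builds a program from explicit curve parameters;
#' `default_stimulus_program()` returns the shipped per-stimulus defaults at a
#' given dose. Dose scales each curve amplitude through a saturating
#' occupancy term \eqn{d / (d + \mathrm{EC}_{50})}, normalised so that the
#' reference (highest experimental) dose reproduces the nominal amplitude.
#' The TAK1 branch is given a higher dose \eqn{\mathrm{EC}_{50}} than the IKK
#' branch, so that p38 activation requires more ligand than NF-kB activation.
#' A dose of zero, or `stimulus = "mock"`, yields identically zero curves.
#'
#' @param stimulus One of `"P3C4"`, `"CpG"`, `"LPS"`, `"TNF"`, `"mock"`.
#' @param dose Non-negative scalar dose, in the units conventional for the
#'   stimulus (ng/ml for P3C4, LPS, TNF; nM for CpG).
#' @param ikk,tak1 Named lists of curve parameters: `amp` (peak activity,
#'   0-1), `t_rise`, `t_decay` (min), and optionally `amp2`, `delay2`,
#'   `t_rise2`, `t_decay2` for a delayed second phase, plus `ec50_dose` and
#'   `ref_dose` controlling dose scaling.
#' @param amp_scale Multiplier applied to both curves (the distributed
#'   "receptor amplitude" parameter of heterogeneous populations).
#'
#' @return An object of class `stimulus_program`.
#' @examples
#' prog <- default_stimulus_program("LPS", dose = 100)
#' t <- seq(0, 480, by = 5)
#' head(receptor_input(prog, t))
#' @export
stimulus_program <- function(stimulus, dose, ikk, tak1, amp_scale = 1) {
  stimulus <- match.arg(stimulus, c("P3C4", "CpG", "LPS", "TNF", "mock"))
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    abort("`dose` must be a single non-negative number.")
  }
  if (amp_scale < 0) abort("`amp_scale` must be non-negative.")
  structure(
    list(stimulus = stimulus, dose = dose,
         ikk = validate_curve_params(ikk),
         tak1 = validate_curve_params(tak1),
         amp_scale = amp_scale),
    class = "stimulus_program"
  )
}

validate_curve_params <- function(p) {
  defaults <- list(amp = 0, t_rise = 5, t_decay = 30,
                   amp2 = 0, delay2 = 0, t_rise2 = 30, t_decay2 = 120,
                   ec50_dose = 1, ref_dose = 100)
  p <- modifyList(defaults, as.list(p))
  stopifnot(p$amp >= 0, p$amp2 >= 0, p$t_rise > 0, p$t_decay > 0,
            p$t_rise2 > 0, p$t_decay2 > 0, p$delay2 >= 0,
            p$ec50_dose > 0, p$ref_dose > 0)
  if (p$t_rise >= p$t_decay) abort("curve requires t_rise < t_decay.")
  if (p$t_rise2 >= p$t_decay2) abort("curve requires t_rise2 < t_decay2.")
  p
}

# difference-of-exponentials pulse normalised to unit peak; zero for t < 0
unit_pulse <- function(t, t_rise, t_decay) {
  tpk <- t_rise * t_decay / (t_decay - t_rise) * log(t_decay / t_rise)
  pk <- exp(-tpk / t_decay) - exp(-tpk / t_rise)
  out <- (exp(-pmax(t, 0) / t_decay) - exp(-pmax(t, 0) / t_rise)) / pk
  out[t < 0] <- 0
  out
}

curve_value <- function(p, t, dose, amp_scale) {
  occ <- (dose / (dose + p$ec50_dose)) / (p$ref_dose / (p$ref_dose + p$ec50_dose))
  v <- p$amp * unit_pulse(t, p$t_rise, p$t_decay)
  if (p$amp2 > 0) {
    v <- v + p$amp2 * unit_pulse(t - p$delay2, p$t_rise2, p$t_decay2)
  }
  pmin(pmax(v * occ * amp_scale, 0), 1)
}

#' Evaluate the IKK and TAK1 activities of a program
#'
#' @param program A [stimulus_program()].
#' @param t Numeric vector of times (min, stimulus at 0).
#' @return A tibble with columns `time_min`, `ikk`, `tak1`.
#' @export
receptor_input <- function(program, t) {
  stopifnot(inherits(program, "stimulus_program"))
  if (program$stimulus == "mock" || program$dose == 0) {
    return(tibble(time_min = t, ikk = 0 * t, tak1 = 0 * t))
  }
  tibble(
    time_min = t,
    ikk = curve_value(program$ikk, t, program$dose, program$amp_scale),
    tak1 = curve_value(program$tak1, t, program$dose, program$amp_scale)
  )
}

#' @rdname stimulus_program
#' @export
default_stimulus_program <- function(stimulus = c("P3C4", "CpG", "LPS", "TNF", "mock"),
                                     dose = NULL, amp_scale = 1) {
  stimulus <- match.arg(stimulus)
  defs <- list(
    # amplitudes/time constants chosen so the four high-dose programs
    # reproduce the stimulus-specific p38 phenotypes: TNF fast + low,
    # LPS biphasic (fast MyD88 spike + delayed TRIF phase, slow TAK1),
    # CpG slow and broad, P3C4 high amplitude with moderate width.
    P3C4 = list(
      dose = 100,
      ikk  = list(amp = 0.60, t_rise = 5, t_decay = 60,
                  ec50_dose = 10, ref_dose = 100),
      tak1 = list(amp = 0.55, t_rise = 6, t_decay = 60,
                  ec50_dose = 67, ref_dose = 100)
    ),
    CpG = list(
      dose = 1000,
      ikk  = list(amp = 0.33, t_rise = 25, t_decay = 150,
                  ec50_dose = 100, ref_dose = 1000),
      tak1 = list(amp = 0.33, t_rise = 30, t_decay = 150,
                  ec50_dose = 260, ref_dose = 1000)
    ),
    LPS = list(
      dose = 100,
      ikk  = list(amp = 0.55, t_rise = 4, t_decay = 25,
                  amp2 = 0.30, delay2 = 45, t_rise2 = 30, t_decay2 = 200,
                  ec50_dose = 5, ref_dose = 100),
      tak1 = list(amp = 0.40, t_rise = 30, t_decay = 200,
                  ec50_dose = 40, ref_dose = 100)
    ),
    TNF = list(
      dose = 100,
      ikk  = list(amp = 0.65, t_rise = 2, t_decay = 20,
                  ec50_dose = 1, ref_dose = 100),
      tak1 = list(amp = 0.45, t_rise = 2, t_decay = 20,
                  ec50_dose = 13, ref_dose = 100)
    ),
    mock = list(
      dose = 0,
      ikk = list(amp = 0), tak1 = list(amp = 0)
    )
  )
  d <- defs[[stimulus]]
  stimulus_program(stimulus, dose %||% d$dose, d$ikk, d$tak1,
                   amp_scale = amp_scale)
}
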