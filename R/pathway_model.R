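#' Pathway model parameters
#'
#' Rate constants and total protein concentrations for the branched p38
#' activation model coupled to a reduced IkB--NF-kB negative-feedback module.
#' p38 is activated through two branches sharing upstream receptor input:
#' IKK degrades p105, releasing active Tpl2, which drives MKK3/6
#' phosphorylation; TAK1 drives MKK4 phosphorylation; MKK6-pp and MKK4-pp
#' each doubly phosphorylate p38. Every two-step phosphorylation is a
#' reduced Hill-type rate (pseudo-first-order maximal rate `v_*` in 1/min,
#' half-saturation `k_*`, Hill coefficient `n_*`) in the driving kinase,
#' linear in the substrate, so that kinase-family mass is conserved exactly
#' and response amplitude scales proportionally with the kinase totals. The NF-kB
#' module tracks IkB mRNA, free IkB, the cytoplasmic NF-kB:IkB complex and
#' nuclear NF-kB; IKK degrades IkB (free and complexed), freed NF-kB shuttles
#' into the nucleus and induces IkB resynthesis (the negative feedback).
#'
#' Concentrations are in uM, times in minutes. The defaults are the shipped
#' "representative cell": they were obtained by calibrating against the four
#' canonical high-dose stimulus phenotypes (see [fit_representative()]) and
#' are the reference values around which heterogeneous populations are
#' sampled.
#'
#' @param ... Named overrides of individual parameters.
#' @return A named numeric vector of class `pathway_parameters`.
#' @examples
#' p <- pathway_parameters()
#' p["p38_tot"]
#' @export
pathway_parameters <- function(...) {
  p <- c(
    # totals (uM)
    p38_tot = 0.4, mkk4_tot = 0.2, mkk6_tot = 0.2, nfkb_tot = 0.35,
    # p105 / Tpl2 activation (1/min)
    k_p105_syn = 0.05, k_p105_deg = 0.3, k_tpl2_act = 0.5, k_tpl2_inact = 0.15,
    # MKK6 phosphorylation by Tpl2 (driver Hill), dephosphorylation
    v_mkk6 = 0.5, k_mkk6 = 1.5, n_mkk6 = 2,
    kdp_mkk6_p = 0.05, kdp_mkk6_pp = 0.10,
    # MKK4 phosphorylation by TAK1
    v_mkk4 = 0.3, k_mkk4 = 0.35, n_mkk4 = 2,
    kdp_mkk4_p = 0.04, kdp_mkk4_pp = 0.06,
    # p38 phosphorylation by MKK6-pp / MKK4-pp
    v_p38_mkk6 = 0.15, k_p38_mkk6 = 0.15, n_p38_mkk6 = 2,
    v_p38_mkk4 = 0.18, k_p38_mkk4 = 0.2, n_p38_mkk4 = 2,
    kdp_p38_p = 0.08, kdp_p38_pp = 0.12,
    # IkB--NF-kB module
    k_txn_basal = 0.0002, k_txn = 0.3, k_txn_km = 0.12, k_txn_n = 2,
    k_mrna_deg = 0.03, k_transl = 1.5, k_ass = 30,
    k_ikb_deg_basal = 0.01, k_ikb_deg_ikk = 0.8,
    k_complex_deg_basal = 0.01, k_complex_deg_ikk = 0.3,
    k_imp = 0.5, k_exp = 0.08,
    # receptor-curve amplitude multiplier (distributed across cells)
    receptor_amp = 1
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      abort(paste0("Unknown pathway parameter(s): ",
                   paste(bad, collapse = ", "),
                   ". Valid names: ", paste(names(p), collapse = ", ")))
    }
    p[names(over)] <- over
  }
  validate_pathway_parameters(p)
  structure(p, class = c("pathway_parameters", "numeric"))
}

validate_pathway_parameters <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0)) {
    abort(paste0("All pathway parameters must be positive and finite; bad: ",
                 paste(names(p)[!is.finite(p) | p <= 0], collapse = ", ")))
  }
  hills <- p[grep("^n_", names(p))]
  if (any(hills < 0.1 | hills > 10)) {
    abort("Hill coefficients must lie in [0.1, 10].")
  }
  invisible(p)
}

#' Names of the distributed (heterogeneous) parameters
#'
#' The ten per-cell distributed parameters: the three kinase totals of the
#' p38 module, the shared receptor-curve amplitude, and six NF-kB-module
#' parameters (total NF-kB, IkB mRNA synthesis, translation, IKK-driven IkB
#' degradation, nuclear import and export).
#'
#' @return Character vector of length 10.
#' @export
distributed_parameter_names <- function() {
  c("p38_tot", "mkk4_tot", "mkk6_tot", "receptor_amp",
    "nfkb_tot", "k_txn", "k_transl", "k_ikb_deg_ikk", "k_imp", "k_exp")
}

state_names <- function() {
  c("p105", "tpl2a", "mkk6_p", "mkk6_pp", "mkk4_p", "mkk4_pp",
    "p38_p", "p38_pp", "ikb_mrna", "ikb", "complex", "nfkb_n")
}

hill <- function(x, km, n) {
  xn <- pmax(x, 0)^n
  xn / (km^n + xn)
}

# Fast closure form of the RHS used inside the integrator: parameters are
# extracted once and states addressed by position (see state_names()).
make_pathway_rhs <- function(p, ikk_fun, tak1_fun) {
  p38_tot <- p[["p38_tot"]]; mkk4_tot <- p[["mkk4_tot"]]
  mkk6_tot <- p[["mkk6_tot"]]; nfkb_tot <- p[["nfkb_tot"]]
  k_p105_syn <- p[["k_p105_syn"]]; k_p105_deg <- p[["k_p105_deg"]]
  k_tpl2_act <- p[["k_tpl2_act"]]; k_tpl2_inact <- p[["k_tpl2_inact"]]
  v_mkk6 <- p[["v_mkk6"]]; k_mkk6_n <- p[["k_mkk6"]]^p[["n_mkk6"]]
  n_mkk6 <- p[["n_mkk6"]]
  kdp_mkk6_p <- p[["kdp_mkk6_p"]]; kdp_mkk6_pp <- p[["kdp_mkk6_pp"]]
  v_mkk4 <- p[["v_mkk4"]]; k_mkk4_n <- p[["k_mkk4"]]^p[["n_mkk4"]]
  n_mkk4 <- p[["n_mkk4"]]
  kdp_mkk4_p <- p[["kdp_mkk4_p"]]; kdp_mkk4_pp <- p[["kdp_mkk4_pp"]]
  v_p38_mkk6 <- p[["v_p38_mkk6"]]; k_p38_mkk6_n <- p[["k_p38_mkk6"]]^p[["n_p38_mkk6"]]
  n_p38_mkk6 <- p[["n_p38_mkk6"]]
  v_p38_mkk4 <- p[["v_p38_mkk4"]]; k_p38_mkk4_n <- p[["k_p38_mkk4"]]^p[["n_p38_mkk4"]]
  n_p38_mkk4 <- p[["n_p38_mkk4"]]
  kdp_p38_p <- p[["kdp_p38_p"]]; kdp_p38_pp <- p[["kdp_p38_pp"]]
  k_txn_basal <- p[["k_txn_basal"]]; k_txn <- p[["k_txn"]]
  k_txn_km_n <- p[["k_txn_km"]]^p[["k_txn_n"]]; k_txn_n <- p[["k_txn_n"]]
  k_mrna_deg <- p[["k_mrna_deg"]]; k_transl <- p[["k_transl"]]
  k_ass <- p[["k_ass"]]
  k_ikb_deg_basal <- p[["k_ikb_deg_basal"]]; k_ikb_deg_ikk <- p[["k_ikb_deg_ikk"]]
  k_complex_deg_basal <- p[["k_complex_deg_basal"]]
  k_complex_deg_ikk <- p[["k_complex_deg_ikk"]]
  k_imp <- p[["k_imp"]]; k_exp <- p[["k_exp"]]

  function(t, y, parms) {
    ikk <- ikk_fun(t)
    tak1 <- tak1_fun(t)
    mkk6_u <- mkk6_tot - y[3] - y[4]
    mkk4_u <- mkk4_tot - y[5] - y[6]
    p38_u <- p38_tot - y[7] - y[8]
    nfkb_c <- nfkb_tot - y[11] - y[12]

    tp <- y[2]^n_mkk6
    a6 <- v_mkk6 * tp / (k_mkk6_n + tp)
    tk <- tak1^n_mkk4
    a4 <- v_mkk4 * tk / (k_mkk4_n + tk)
    m6 <- y[4]^n_p38_mkk6
    m4 <- y[6]^n_p38_mkk4
    ap <- v_p38_mkk6 * m6 / (k_p38_mkk6_n + m6) +
      v_p38_mkk4 * m4 / (k_p38_mkk4_n + m4)
    nn <- y[12]^k_txn_n

    list(c(
      k_p105_syn * (1 - y[1]) - k_p105_deg * ikk * y[1],
      k_tpl2_act * ikk * y[1] - k_tpl2_inact * y[2],
      a6 * (mkk6_u - y[3]) - kdp_mkk6_p * y[3] + kdp_mkk6_pp * y[4],
      a6 * y[3] - kdp_mkk6_pp * y[4],
      a4 * (mkk4_u - y[5]) - kdp_mkk4_p * y[5] + kdp_mkk4_pp * y[6],
      a4 * y[5] - kdp_mkk4_pp * y[6],
      ap * (p38_u - y[7]) - kdp_p38_p * y[7] + kdp_p38_pp * y[8],
      ap * y[7] - kdp_p38_pp * y[8],
      k_txn_basal + k_txn * nn / (k_txn_km_n + nn) - k_mrna_deg * y[9],
      k_transl * y[9] - k_ass * y[10] * nfkb_c -
        (k_ikb_deg_basal + k_ikb_deg_ikk * ikk) * y[10],
      k_ass * y[10] * nfkb_c -
        (k_complex_deg_basal + k_complex_deg_ikk * ikk) * y[11],
      k_imp * nfkb_c - k_exp * y[12]
    ))
  }
}

# Readable reference form of the RHS (used for equilibration checks);
# ikk_fun/tak1_fun map time (min) -> activity [0,1].
pathway_rhs <- function(t, y, p, ikk_fun, tak1_fun) {
  ikk <- ikk_fun(t)
  tak1 <- tak1_fun(t)

  mkk6_u <- p[["mkk6_tot"]] - y[["mkk6_p"]] - y[["mkk6_pp"]]
  mkk4_u <- p[["mkk4_tot"]] - y[["mkk4_p"]] - y[["mkk4_pp"]]
  p38_u <- p[["p38_tot"]] - y[["p38_p"]] - y[["p38_pp"]]
  nfkb_c <- p[["nfkb_tot"]] - y[["complex"]] - y[["nfkb_n"]]

  dp105 <- p[["k_p105_syn"]] * (1 - y[["p105"]]) -
    p[["k_p105_deg"]] * ikk * y[["p105"]]
  dtpl2a <- p[["k_tpl2_act"]] * ikk * y[["p105"]] -
    p[["k_tpl2_inact"]] * y[["tpl2a"]]

  a6 <- p[["v_mkk6"]] * hill(y[["tpl2a"]], p[["k_mkk6"]], p[["n_mkk6"]])
  dmkk6_p <- a6 * (mkk6_u - y[["mkk6_p"]]) -
    p[["kdp_mkk6_p"]] * y[["mkk6_p"]] + p[["kdp_mkk6_pp"]] * y[["mkk6_pp"]]
  dmkk6_pp <- a6 * y[["mkk6_p"]] -
    p[["kdp_mkk6_pp"]] * y[["mkk6_pp"]]

  a4 <- p[["v_mkk4"]] * hill(tak1, p[["k_mkk4"]], p[["n_mkk4"]])
  dmkk4_p <- a4 * (mkk4_u - y[["mkk4_p"]]) -
    p[["kdp_mkk4_p"]] * y[["mkk4_p"]] + p[["kdp_mkk4_pp"]] * y[["mkk4_pp"]]
  dmkk4_pp <- a4 * y[["mkk4_p"]] -
    p[["kdp_mkk4_pp"]] * y[["mkk4_pp"]]

  ap <- p[["v_p38_mkk6"]] * hill(y[["mkk6_pp"]], p[["k_p38_mkk6"]], p[["n_p38_mkk6"]]) +
    p[["v_p38_mkk4"]] * hill(y[["mkk4_pp"]], p[["k_p38_mkk4"]], p[["n_p38_mkk4"]])
  dp38_p <- ap * (p38_u - y[["p38_p"]]) -
    p[["kdp_p38_p"]] * y[["p38_p"]] + p[["kdp_p38_pp"]] * y[["p38_pp"]]
  dp38_pp <- ap * y[["p38_p"]] -
    p[["kdp_p38_pp"]] * y[["p38_pp"]]

  dmrna <- p[["k_txn_basal"]] +
    p[["k_txn"]] * hill(y[["nfkb_n"]], p[["k_txn_km"]], p[["k_txn_n"]]) -
    p[["k_mrna_deg"]] * y[["ikb_mrna"]]
  dikb <- p[["k_transl"]] * y[["ikb_mrna"]] -
    p[["k_ass"]] * y[["ikb"]] * nfkb_c -
    (p[["k_ikb_deg_basal"]] + p[["k_ikb_deg_ikk"]] * ikk) * y[["ikb"]]
  dcomplex <- p[["k_ass"]] * y[["ikb"]] * nfkb_c -
    (p[["k_complex_deg_basal"]] + p[["k_complex_deg_ikk"]] * ikk) * y[["complex"]]
  dnfkb_n <- p[["k_imp"]] * nfkb_c - p[["k_exp"]] * y[["nfkb_n"]]

  c(dp105, dtpl2a, dmkk6_p, dmkk6_pp, dmkk4_p, dmkk4_pp, dp38_p, dp38_pp,
    dmrna, dikb, dcomplex, dnfkb_n)
}

# Resting state with zero receptor input. The kinase cascade relaxes to
# fully dephosphorylated forms (p105 = 1, Tpl2a = 0) and the NF-kB module
# reduces to a one-dimensional root problem in nuclear NF-kB.
equilibrate_pathway <- function(params, tol = 1e-9, t_max = 5000) {
  p <- unclass(params)
  rest_nfkb <- function(nn) {
    nc <- (p[["k_exp"]] / p[["k_imp"]]) * nn
    m <- (p[["k_txn_basal"]] +
            p[["k_txn"]] * hill(nn, p[["k_txn_km"]], p[["k_txn_n"]])) /
      p[["k_mrna_deg"]]
    i <- p[["k_transl"]] * m /
      (p[["k_ass"]] * nc + p[["k_ikb_deg_basal"]])
    cplx <- p[["k_ass"]] * i * nc / p[["k_complex_deg_basal"]]
    list(nn = nn, nc = nc, m = m, i = i, cplx = cplx,
         gap = cplx + nn + nc - p[["nfkb_tot"]])
  }
  root <- uniroot(function(nn) rest_nfkb(nn)$gap,
                  lower = 1e-12, upper = p[["nfkb_tot"]], tol = 1e-14)
  r <- rest_nfkb(root$root)
  y0 <- setNames(c(1, 0, 0, 0, 0, 0, 0, 0, r$m, r$i, r$cplx, r$nn),
                 state_names())
  zero <- function(t) 0
  dy <- pathway_rhs(0, y0, p, zero, zero)
  if (max(abs(dy)) >= tol) {
    # fall back to relaxation for parameter sets where the algebraic
    # reduction is not accurate enough
    out <- deSolve::lsoda(y0, seq(0, t_max, by = 50),
                          make_pathway_rhs(p, zero, zero),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    y0 <- setNames(as.numeric(out[nrow(out), -1]), state_names())
    dy <- pathway_rhs(0, y0, p, zero, zero)
    if (max(abs(dy)) >= tol) {
      worst <- state_names()[which.max(abs(dy))]
      abort(paste0("Pre-stimulus equilibration failed to converge: species '",
                   worst, "' still changing at ",
                   signif(max(abs(dy)), 3), " uM/min."))
    }
  }
  y0
}

#' Simulate one cell's paired p38 / NF-kB response
#'
#' Integrates the pathway model for a single parameter set: the system is
#' first equilibrated with zero receptor input, then stimulated at time 0
#' with the program's IKK and TAK1 curves. The reported activities are
#' doubly phosphorylated p38 and nuclear NF-kB, each with the pre-stimulus
#' (baseline) level subtracted, in model units (uM).
#'
#' @param params A [pathway_parameters()] object.
#' @param program A [stimulus_program()].
#' @param grid Time grid in minutes; baseline frames carry negative times and
#'   stimulation starts at 0 (default [default_time_grid()]).
#' @param cell_id,replicate Metadata stamped on the output rows.
#' @param full_state If `TRUE`, attach the full species trace as attribute
#'   `"states"` (a tibble with one column per species, including the
#'   algebraically closed unphosphorylated forms and cytoplasmic NF-kB).
#'
#' @return A tibble in the long trajectory format: `cell_id`, `stimulus`,
#'   `dose`, `replicate`, `time_min`, `p38_activity`, `nfkb_activity`,
#'   `units` (`"model_uM"`).
#' @examples
#' traj <- simulate_cell(pathway_parameters(), default_stimulus_program("TNF"))
#' max(traj$p38_activity)
#' @export
simulate_cell <- function(params, program, grid = default_time_grid(),
                          cell_id = 1L, replicate = 1L, full_state = FALSE) {
  validate_pathway_parameters(params)
  stopifnot(inherits(program, "stimulus_program"))
  check_uniform_grid(grid)
  p <- unclass(params)

  mock <- program$stimulus == "mock" || program$dose == 0
  amp <- p[["receptor_amp"]] * program$amp_scale
  ikk_fun <- if (mock) function(t) 0 else
    function(t) curve_value(program$ikk, t, program$dose, amp)
  tak1_fun <- if (mock) function(t) 0 else
    function(t) curve_value(program$tak1, t, program$dose, amp)

  y0 <- equilibrate_pathway(params)
  times <- sort(unique(c(grid, 0)))
  out <- deSolve::lsoda(
    y0, times, make_pathway_rhs(p, ikk_fun, tak1_fun),
    parms = NULL, rtol = 1e-6, atol = 1e-9
  )
  if (nrow(out) < length(times)) {
    abort(paste0("ODE integration broke down at t = ",
                 signif(out[nrow(out), 1], 4), " min."))
  }
  sol <- as_tibble(as.data.frame(out))
  sol <- sol[match(grid, sol$time), ]

  traj <- tibble(
    cell_id = cell_id,
    stimulus = program$stimulus,
    dose = program$dose,
    replicate = replicate,
    time_min = grid,
    p38_activity = sol$p38_pp - y0[["p38_pp"]],
    nfkb_activity = sol$nfkb_n - y0[["nfkb_n"]],
    units = "model_uM"
  )
  if (full_state) {
    st <- sol |>
      rename(time_min = "time") |>
      mutate(
        mkk6_u = p[["mkk6_tot"]] - .data$mkk6_p - .data$mkk6_pp,
        mkk4_u = p[["mkk4_tot"]] - .data$mkk4_p - .data$mkk4_pp,
        p38_u = p[["p38_tot"]] - .data$p38_p - .data$p38_pp,
        nfkb_c = p[["nfkb_tot"]] - .data$complex - .data$nfkb_n
      )
    attr(traj, "states") <- st
  }
  traj
}

#' Default uniform sampling grid
#'
#' Six baseline frames before stimulation and 97 post-stimulus frames at the
#' standard 5-min imaging interval (0 to 480 min, i.e. 8 h).
#'
#' @param frame_min Frame interval (min).
#' @param n_baseline Number of baseline frames (negative times).
#' @param t_end Last post-stimulus time (min).
#' @return Numeric vector of times in minutes.
#' @export
default_time_grid <- function(frame_min = 5, n_baseline = 6, t_end = 480) {
  c(seq(-n_baseline * frame_min, -frame_min, by = frame_min),
    seq(0, t_end, by = frame_min))
}

check_uniform_grid <- function(grid) {
  if (length(grid) < 2L) abort("Time grid needs at least two frames.")
  d <- diff(grid)
  if (any(abs(d - d[1]) > 1e-8)) {
    abort("Time grid must be uniformly spaced.")
  }
  invisible(grid)
}
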