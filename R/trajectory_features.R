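#' The dynamic-feature catalog
#'
#' Names and definitions of the per-pathway dynamic features extracted from
#' single-cell activity trajectories: speed of activation and deactivation,
#' amplitude, oscillatory content, duration, early-vs-late balance, total
#' activity, and a bank of half-hour interval integrals. Time features are
#' in minutes measured from stimulation (t = 0); integrals are trapezoidal
#' in A.U. x min.
#'
#' @param interval_span_h Span covered by the 30-min interval integrals, in
#'   hours (default 8, giving 16 integrals).
#' @return A tibble with columns `name` and `description`.
#' @export
feature_catalog <- function(interval_span_h = 8) {
  core <- tibble(
    name = c("time_to_half_max", "time_to_max", "max_amplitude",
             "max_derivative", "min_derivative", "first_peak_width",
             "total_duration", "total_activity", "time_to_half_total",
             "dominant_frequency", "n_peaks", "early_late_ratio"),
    description = c(
      "first linearly interpolated crossing of half the maximum (min)",
      "time of the maximum (min)",
      "maximum activity (A.U.)",
      "maximum central-difference derivative (A.U./min)",
      "minimum central-difference derivative (A.U./min)",
      "width of the first supra-threshold peak at half prominence (min)",
      "total time above the responder threshold (min)",
      "trapezoidal integral of activity over the full window (A.U. min)",
      "time at which half the total activity is accumulated (min)",
      "argmax of DFT power of the detrended 0-4 h segment (1/min)",
      "number of supra-threshold local maxima separated by >= 2 frames",
      "0-2 h integral divided by 2-8 h integral"
    )
  )
  starts <- seq(0, interval_span_h * 60 - 30, by = 30)
  ints <- tibble(
    name = sprintf("integral_%03d_%03d", starts, starts + 30),
    description = sprintf("trapezoidal integral over %d-%d min (A.U. min)",
                          starts, starts + 30)
  )
  bind_rows(core, ints)
}

cell_key_vars <- function() c("cell_id", "stimulus", "dose", "replicate")

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Preprocess raw trajectories
#'
#' Per-cell baseline deduction followed by optional systemic-drift
#' correction. The baseline is the mean over the pre-stimulus frames
#' (negative `time_min`) of each cell and channel. If at least eight mock
#' (unstimulated) trajectories are supplied, a drift curve — their framewise
#' mean, smoothed by a centred moving average — is subtracted from every
#' trajectory; with fewer mocks the drift step is skipped with a warning.
#'
#' @param traj Long trajectory tibble.
#' @param mock Optional long trajectory tibble of mock-stimulated cells.
#' @param smooth_frames Width (frames) of the moving-average smoother
#'   applied to the drift curve.
#' @return The corrected trajectory tibble.
#' @export
preprocess <- function(traj, mock = NULL, smooth_frames = 5) {
  if (!any(traj$time_min < 0)) {
    abort("No baseline frames (negative `time_min`) found; cannot baseline-deduct.")
  }
  deduct <- function(df) {
    df |>
      group_by(across(all_of(intersect(cell_key_vars(), names(df))))) |>
      mutate(
        p38_activity = .data$p38_activity -
          mean(.data$p38_activity[.data$time_min < 0]),
        nfkb_activity = .data$nfkb_activity -
          mean(.data$nfkb_activity[.data$time_min < 0])
      ) |>
      ungroup()
  }
  out <- deduct(traj)
  if (!is.null(mock)) {
    n_mock <- mock |> distinct(across(all_of(intersect(cell_key_vars(), names(mock))))) |> nrow()
    if (n_mock < 8) {
      warn(paste0("Only ", n_mock, " mock trajectories supplied (need 8); ",
                  "skipping drift correction."))
    } else {
      drift <- deduct(mock) |>
        group_by(.data$time_min) |>
        summarise(p38 = mean(.data$p38_activity),
                  nfkb = mean(.data$nfkb_activity), .groups = "drop") |>
        arrange(.data$time_min) |>
        mutate(p38 = moving_average(.data$p38, smooth_frames),
               nfkb = moving_average(.data$nfkb, smooth_frames))
      out <- out |>
        left_join(drift, by = "time_min") |>
        mutate(
          p38_activity = .data$p38_activity - coalesce(.data$p38, 0),
          nfkb_activity = .data$nfkb_activity - coalesce(.data$nfkb, 0)
        ) |>
        select(-"p38", -"nfkb")
    }
  }
  out
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - k %/% 2)
    hi <- min(n, i + k %/% 2)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Quality-filter a trajectory set
#'
#' Removes cells failing any of a configurable set of rules, mirroring the
#' downstream post-processing applied to tracked-cell data: cells must be
#' present from the experiment start (baseline frames exist), persist for
#' the full time course with no missing frames, and not show extreme
#' activities or extreme baseline variability. Thresholds default to
#' permissive values and live entirely in `rules`.
#'
#' @param traj Long trajectory tibble.
#' @param rules A list as produced by [quality_rules()].
#' @return The filtered tibble, with a per-rule removal report attached as
#'   attribute `"quality_report"` (retrieve with [quality_report()]).
#' @export
quality_filter <- function(traj, rules = quality_rules()) {
  keys <- intersect(cell_key_vars(), names(traj))
  full_times <- sort(unique(traj$time_min))
  per_cell <- traj |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_frames = dplyr::n(),
      any_na = any(is.na(.data$p38_activity) | is.na(.data$nfkb_activity)),
      has_baseline = any(.data$time_min < 0),
      max_abs = max(abs(c(.data$p38_activity, .data$nfkb_activity)), na.rm = TRUE),
      baseline_sd = max(sd(.data$p38_activity[.data$time_min < 0]),
                        sd(.data$nfkb_activity[.data$time_min < 0]), na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      fail_duration = .data$n_frames < length(full_times) | .data$any_na,
      fail_start = !.data$has_baseline,
      fail_extreme = .data$max_abs > rules$max_abs_activity,
      fail_baseline = !is.na(.data$baseline_sd) &
        .data$baseline_sd > rules$max_baseline_sd
    )
  report <- tibble(
    rule = c("full_duration", "present_at_start", "extreme_activity",
             "noisy_baseline"),
    removed = c(sum(per_cell$fail_duration), sum(per_cell$fail_start),
                sum(per_cell$fail_extreme), sum(per_cell$fail_baseline))
  )
  keep <- per_cell |>
    filter(!.data$fail_duration, !.data$fail_start,
           !.data$fail_extreme, !.data$fail_baseline) |>
    select(all_of(keys))
  if (nrow(keep) == 0) {
    abort("All cells removed by quality filtering; review the rule thresholds.")
  }
  out <- semi_join(traj, keep, by = keys)
  attr(out, "quality_report") <- list(
    per_rule = report,
    n_input = nrow(per_cell),
    n_retained = nrow(keep),
    retained_fraction = nrow(keep) / nrow(per_cell)
  )
  out
}

#' @rdname quality_filter
#' @param x A tibble returned by `quality_filter()`.
#' @export
quality_report <- function(x) attr(x, "quality_report")

#' @rdname quality_filter
#' @param max_abs_activity Cap on the absolute activity in either channel.
#' @param max_baseline_sd Cap on the baseline standard deviation.
#' @export
quality_rules <- function(max_abs_activity = 20, max_baseline_sd = 5) {
  list(max_abs_activity = max_abs_activity, max_baseline_sd = max_baseline_sd)
}

#' Responder calling
#'
#' A cell is a responder if its activity exceeds `k_sd` times its own
#' baseline standard deviation for at least `n_consecutive` consecutive
#' frames within `window` minutes of stimulation. Cells whose baseline SD
#' is zero (noise-free fixtures) fall back to an absolute floor.
#'
#' `call_responders()` returns the per-cell calls; `responder_fraction()`
#' the fraction of responding cells.
#'
#' @param traj Long trajectory tibble (baseline-deducted).
#' @param pathway `"p38"` or `"nfkb"`.
#' @param k_sd Threshold multiplier on the baseline SD (default 3).
#' @param n_consecutive Required consecutive supra-threshold frames
#'   (default 3).
#' @param window Post-stimulus window searched (min, default 60).
#' @param sd_floor Absolute threshold floor used when the baseline SD is 0.
#' @return `call_responders()`: a tibble of cell keys plus `responder`
#'   (logical) and `threshold`; `responder_fraction()`: a single number in
#'   \eqn{[0, 1]}.
#' @export
call_responders <- function(traj, pathway = c("p38", "nfkb"), k_sd = 3,
                            n_consecutive = 3, window = 60,
                            sd_floor = 1e-3) {
  pathway <- match.arg(pathway)
  col <- paste0(pathway, "_activity")
  keys <- intersect(cell_key_vars(), names(traj))
  traj |>
    group_by(across(all_of(keys))) |>
    summarise(
      threshold = {
        base <- .data[[col]][.data$time_min < 0]
        if (length(base) < 3) {
          abort("Responder calling needs >= 3 baseline frames per cell.")
        }
        s <- sd(base)
        if (s == 0) {
          warn("Zero baseline SD; using the absolute threshold floor.")
          sd_floor
        } else {
          k_sd * s
        }
      },
      responder = {
        inwin <- .data$time_min >= 0 & .data$time_min <= window
        above <- .data[[col]][inwin] > threshold
        has_run(above, n_consecutive)
      },
      .groups = "drop"
    )
}

has_run <- function(x, n) {
  if (!length(x)) return(FALSE)
  r <- rle(x)
  any(r$values & r$lengths >= n)
}

#' @rdname call_responders
#' @export
responder_fraction <- function(traj, pathway = c("p38", "nfkb"), ...) {
  calls <- call_responders(traj, pathway, ...)
  mean(calls$responder)
}

#' Extract the dynamic-feature table
#'
#' Computes every catalog feature for both channels of every cell. Columns
#' are pathway-prefixed (`p38_*`, `nfkb_*`). Features whose support exceeds
#' the available grid are recorded as `NA` rather than raising an error.
#'
#' @param traj Long trajectory tibble (preprocessed: baseline-deducted).
#' @param catalog A [feature_catalog()] (subset rows to restrict the set).
#' @param k_sd,sd_floor Responder-threshold parameters used by the
#'   threshold-dependent features (duration, peak count, first-peak width).
#' @return A wide tibble: one row per cell, cell keys plus
#'   `<pathway>_<feature>` columns.
#' @examples
#' tri <- make_toy_trajectory("triangle", amplitude = 2, t_peak = 60,
#'                            width = 120)
#' ft <- extract_features(tri)
#' ft$p38_max_amplitude
#' @export
extract_features <- function(traj, catalog = feature_catalog(), k_sd = 3,
                             sd_floor = 1e-3) {
  keys <- intersect(cell_key_vars(), names(traj))
  wanted <- catalog$name
  per_cell <- traj |>
    group_by(across(all_of(keys))) |>
    group_split()
  rows <- map(per_cell, function(df) {
    df <- arrange(df, .data$time_min)
    meta <- df[1, keys]
    feats <- list()
    for (ch in c("p38", "nfkb")) {
      y_all <- df[[paste0(ch, "_activity")]]
      base <- y_all[df$time_min < 0]
      bsd <- if (length(base) >= 2) sd(base) else 0
      thr <- if (is.na(bsd) || bsd == 0) sd_floor else k_sd * bsd
      post <- df$time_min >= 0
      f <- compute_channel_features(df$time_min[post], y_all[post], thr,
                                    wanted)
      names(f) <- paste0(ch, "_", names(f))
      feats <- c(feats, as.list(f))
    }
    bind_cols(meta, as_tibble(feats))
  })
  list_rbind(rows)
}

compute_channel_features <- function(t, y, threshold, wanted) {
  n <- length(t)
  dt <- t[2] - t[1]
  out <- setNames(rep(NA_real_, length(wanted)), wanted)
  if (n < 3) return(out)

  peak <- max(y)
  ipk <- which.max(y)
  if ("max_amplitude" %in% wanted) out["max_amplitude"] <- peak
  if ("time_to_max" %in% wanted) out["time_to_max"] <- t[ipk]
  if ("time_to_half_max" %in% wanted) {
    out["time_to_half_max"] <- first_crossing(t, y, peak / 2)
  }
  if (any(c("max_derivative", "min_derivative") %in% wanted)) {
    dv <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
    out["max_derivative"] <- max(dv)
    out["min_derivative"] <- min(dv)
  }
  if ("total_duration" %in% wanted) {
    out["total_duration"] <- sum(y > threshold) * dt
  }
  total <- trapz(t, y)
  if ("total_activity" %in% wanted) out["total_activity"] <- total
  if ("time_to_half_total" %in% wanted) {
    cum <- c(0, cumsum((y[-1] + y[-n]) * diff(t) / 2))
    out["time_to_half_total"] <- first_crossing(t, cum, total / 2)
  }
  if ("dominant_frequency" %in% wanted) {
    out["dominant_frequency"] <- dominant_frequency(t, y)
  }
  peaks <- find_peaks(y, threshold, min_sep = 2)
  if ("n_peaks" %in% wanted) out["n_peaks"] <- length(peaks)
  if ("first_peak_width" %in% wanted && length(peaks)) {
    out["first_peak_width"] <- peak_width_half_prominence(t, y, peaks[1])
  }
  if ("early_late_ratio" %in% wanted) {
    early <- segment_integral(t, y, 0, 120)
    late <- segment_integral(t, y, 120, max(t))
    out["early_late_ratio"] <- if (!is.na(late) && late != 0) early / late else NA_real_
  }
  iv <- grep("^integral_\\d+_\\d+$", wanted, value = TRUE)
  for (nm in iv) {
    bounds <- as.numeric(strsplit(sub("integral_", "", nm), "_")[[1]])
    out[nm] <- segment_integral(t, y, bounds[1], bounds[2])
  }
  out
}

first_crossing <- function(t, y, level) {
  idx <- which(y >= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(t[1])
  # linear interpolation between the frame below and the crossing frame
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

segment_integral <- function(t, y, from, to) {
  sel <- t >= from - 1e-9 & t <= to + 1e-9
  if (sum(sel) < 2) return(NA_real_)
  trapz(t[sel], y[sel])
}

find_peaks <- function(y, threshold, min_sep = 2) {
  n <- length(y)
  if (n < 3) return(integer())
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] > threshold]
  if (!length(cand)) return(integer())
  # enforce the minimum separation, keeping the higher peak
  cand <- cand[order(-y[cand])]
  kept <- integer()
  for (i in cand) {
    if (all(abs(i - kept) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

peak_width_half_prominence <- function(t, y, ipk) {
  left_min <- min(y[1:ipk])
  right_min <- min(y[ipk:length(y)])
  prom <- y[ipk] - max(left_min, right_min)
  if (prom <= 0) return(NA_real_)
  level <- y[ipk] - prom / 2
  # walk outwards from the peak to the interpolated level crossings
  li <- ipk
  while (li > 1 && y[li - 1] >= level) li <- li - 1
  tl <- if (li == 1) t[1] else {
    t[li] - (y[li] - level) / (y[li] - y[li - 1]) * (t[li] - t[li - 1])
  }
  ri <- ipk
  while (ri < length(y) && y[ri + 1] >= level) ri <- ri + 1
  tr <- if (ri == length(y)) t[ri] else {
    t[ri] + (y[ri] - level) / (y[ri] - y[ri + 1]) * (t[ri + 1] - t[ri])
  }
  tr - tl
}

dominant_frequency <- function(t, y, span_min = 240) {
  sel <- t <= span_min
  if (sum(sel) < 8) return(NA_real_)
  ts <- t[sel]
  ys <- y[sel]
  detr <- stats::lm.fit(cbind(1, ts), ys)$residuals
  n <- length(detr)
  pw <- Mod(fft(detr))^2
  half <- 2:floor(n / 2 + 1)          # exclude the zero bin
  k <- half[which.max(pw[half])] - 1  # cycles over the window
  dt <- ts[2] - ts[1]
  k / (n * dt)
}
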