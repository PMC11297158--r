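#' Run a multi-stage analysis pipeline from a configuration
#'
#' Executes pipeline stages in their declared order, writing each stage's
#' artifact into `out_dir`. All randomness derives from the single global
#' seed: stage `i` runs with seed `seed + 1000 * i`, so any stage can be
#' reproduced in isolation. Every JSON artifact is stamped with the
#' configuration hash and the stage seed.
#'
#' Supported stages and their parameters:
#' \describe{
#'   \item{simulate}{`stimulus`, `dose` (optional), `n_cells`, `denoise`
#'     (optional) -> trajectory CSV `traj_<stimulus>.csv`.}
#'   \item{features}{`input` (trajectory CSV) -> `features.csv`.}
#'   \item{mi}{`input` (feature CSV), `label` column -> `mi.json`.}
#'   \item{classify}{`input` (feature CSV), `label` -> `classify.json`.}
#'   \item{dose}{`input` (trajectory CSV spanning doses) -> `hill.json`.}
#'   \item{correlate}{`input` (feature CSV) -> `correlation.json`.}
#'   \item{express}{`input` (trajectory CSV, model units) ->
#'     `expression.csv` + `expression.json`.}
#' }
#'
#' @param config A list, or path to a YAML file, with fields `seed`,
#'   `out_dir`, and `stages` (a named-list sequence: each element has a
#'   `stage` field plus stage parameters).
#' @return Invisibly, a tibble of executed stages and artifact paths.
#'   A failing stage aborts with the stage named.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$stages))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)

  log_msg <- function(level, ...) {
    message("[", level, "] ", ...)
  }

  done <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    stage_seed <- seed + 1000L * i
    name <- st$stage %||% st$name
    if (is.null(name)) abort("Each stage needs a `stage` field.")
    log_msg("INFO", "stage ", i, ": ", name, " (seed ", stage_seed, ")")
    artifact <- tryCatch(
      run_stage(name, st, stage_seed, out_dir, cfg_hash),
      error = function(e) {
        abort(paste0("Pipeline stage '", name, "' failed: ",
                     conditionMessage(e)))
      }
    )
    done[[i]] <- tibble(stage = name, seed = stage_seed, artifact = artifact)
  }
  invisible(list_rbind(done))
}

run_stage <- function(name, st, stage_seed, out_dir, cfg_hash) {
  stamp <- list(config_hash = cfg_hash, seed = stage_seed)
  write_report <- function(x, file) {
    jsonlite::write_json(c(stamp, x), file.path(out_dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    file.path(out_dir, file)
  }
  switch(
    name,
    simulate = {
      spec <- population_spec(n_cells = st$n_cells %||% 100,
                              denoise = as.character(st$denoise %||% character()),
                              seed = stage_seed)
      prog <- default_stimulus_program(st$stimulus, dose = st$dose)
      traj <- simulate_population(spec, prog)
      f <- file.path(out_dir, paste0("traj_", st$stimulus, ".csv"))
      write_trajectories(traj, f)
      f
    },
    features = {
      traj <- read_trajectories(st$input)
      f <- file.path(out_dir, "features.csv")
      readr::write_csv(extract_features(traj), f)
      f
    },
    mi = {
      ft <- readr::read_csv(st$input, show_col_types = FALSE)
      label <- st$label %||% "stimulus"
      res <- mi_extrapolated(ft[[label]],
                             ft[setdiff(names(ft), cell_key_vars())],
                             seed = stage_seed)
      write_report(list(mi_bits = res$mi_bits, k = res$k,
                        curve = res$curve), "mi.json")
    },
    classify = {
      ft <- readr::read_csv(st$input, show_col_types = FALSE)
      label <- st$label %||% "stimulus"
      rep <- train_eval_tree_ensemble(ft[setdiff(names(ft), cell_key_vars())],
                                      ft[[label]], seed = stage_seed)
      write_report(list(accuracy = rep$accuracy, f1 = as.list(rep$f1),
                        confusion = as.data.frame(rep$confusion)),
                   "classify.json")
    },
    dose = {
      traj <- read_trajectories(st$input)
      dr <- build_dose_response(traj)
      fits <- map(c("p38", "nfkb"), function(pw) fit_hill(dr, pw))
      write_report(list(
        dose_response = as.data.frame(dr),
        p38 = fits[[1]][c("maxA", "halfA_conc", "HillC", "intersect")],
        nfkb = fits[[2]][c("maxA", "halfA_conc", "HillC", "intersect")],
        fold_difference = half_max_fold_difference(fits[[1]], fits[[2]])
      ), "hill.json")
    },
    correlate = {
      ft <- readr::read_csv(st$input, show_col_types = FALSE)
      rep <- spearman_paired(ft, seed = stage_seed)
      write_report(list(pairs = rep$pairs, n_cells = rep$n_cells),
                   "correlation.json")
    },
    express = {
      traj <- read_trajectories(st$input)
      ed <- population_expression(traj)
      readr::write_csv(ed$cells, file.path(out_dir, "expression.csv"))
      write_report(list(summary = ed$summary), "expression.json")
    },
    abort(paste0("Unknown pipeline stage: '", name, "'."))
  )
}
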