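#' Read and write long-format trajectory CSVs
#'
#' The on-disk trajectory format is one long CSV with columns `cell_id`,
#' `stimulus`, `dose`, `replicate`, `time_min`, `p38_activity`,
#' `nfkb_activity`, `units`; baseline frames carry negative `time_min`.
#' Reading validates the schema and rejects non-uniform per-cell time
#' grids; a round trip reproduces values to better than 1e-12.
#'
#' @param path File path.
#' @return `read_trajectories()`: a long trajectory tibble.
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("cell_id", "stimulus", "dose", "replicate", "time_min",
                "p38_activity", "nfkb_activity", "units")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(paste0("Trajectory file is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad_rows <- which(is.na(df$time_min) | is.na(df$cell_id))
  if (length(bad_rows)) {
    abort(paste0("Malformed rows (missing cell_id/time_min) at line(s): ",
                 paste(head(bad_rows + 1L, 10), collapse = ", ")))
  }
  df |>
    group_by(across(all_of(intersect(cell_key_vars(), names(df))))) |>
    group_walk(function(g, key) {
      tt <- sort(g$time_min)
      if (length(tt) >= 2) {
        d <- diff(tt)
        if (any(abs(d - d[1]) > 1e-8)) {
          abort(paste0("Non-uniform time grid for cell ", key$cell_id[1], "."))
        }
      }
    }) |>
    ungroup()
}

#' @rdname read_trajectories
#' @param traj A long trajectory tibble.
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(traj, path)
  invisible(path)
}

#' Read a gene count matrix (CSV or MatrixMarket)
#'
#' CSV input is genes x cells with gene names in the first column and cell
#' names in the header. MatrixMarket (`.mtx`) input is read with
#' \pkg{Matrix}; optional sidecar files supply row (gene) and column (cell)
#' names, one per line.
#'
#' @param path Path to a `.csv` or `.mtx` file.
#' @param genes_file,cells_file Optional name sidecars for `.mtx` input.
#' @return A base dense matrix, genes in rows, with dimnames.
#' @export
read_counts <- function(path, genes_file = NULL, cells_file = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("Counts file is missing or empty: ", path))
  }
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (!is.null(genes_file)) rownames(m) <- readr::read_lines(genes_file)
    if (!is.null(cells_file)) colnames(m) <- readr::read_lines(cells_file)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- as.character(df[[1]])
  }
  if (any(m < 0)) abort("Counts must be non-negative.")
  m
}
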