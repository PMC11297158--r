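# Shared fixtures. The 500-cell LPS populations used by the model-property
# and gene-expression checks are expensive, so they are built once per test
# run and cached.

pop_cache <- new.env(parent = emptyenv())

lps_population <- function(denoise = character()) {
  key <- paste0("lps_", paste(c("pop", denoise), collapse = "_"))
  if (is.null(pop_cache[[key]])) {
    pop_cache[[key]] <- simulate_population(
      population_spec(n_cells = 500, seed = 1, denoise = denoise),
      default_stimulus_program("LPS")
    )
  }
  pop_cache[[key]]
}

lps_features <- function(denoise = character()) {
  key <- paste0("lps_", paste(c("ft", denoise), collapse = "_"))
  if (is.null(pop_cache[[key]])) {
    pop_cache[[key]] <- extract_features(lps_population(denoise))
  }
  pop_cache[[key]]
}

# n toy single-channel cells of a given pulse shape, with per-cell noise
make_toy_population <- function(n, shape, amplitude = 1, noise_sd = 0.05,
                                seed0 = 1, stimulus = shape, ...) {
  purrr::map(seq_len(n), function(i) {
    make_toy_trajectory(shape, amplitude = amplitude, noise_sd = noise_sd,
                        seed = seed0 + i, cell_id = i, stimulus = stimulus,
                        ...)
  }) |> purrr::list_rbind()
}

spearman_cc <- function(a, b) stats::cor(a, b, method = "spearman")
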