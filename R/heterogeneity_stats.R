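#' Paired p38 x NF-kB Spearman correlation structure
#'
#' Rank correlations between matching p38 and NF-kB dynamic features (or
#' 30-min activity integrals) computed across cells, with two-sided
#' p-values and a significance mask. A cross-feature pair is flagged
#' significant when \eqn{p < 0.05} **and** \eqn{|CC| > 0.15}. Ranks use
#' average-rank tie handling; p-values use the t approximation for
#' \eqn{n > 30} and a seeded permutation test (10,000 permutations) below.
#'
#' @param features A feature table with paired rows (one cell per row).
#' @param set_a,set_b Column names for the two pathways; default: every
#'   `p38_*` column paired with the matching `nfkb_*` column.
#' @param p_threshold,cc_threshold Mask criteria.
#' @param seed Seed for the small-n permutation p-values.
#' @return An object of class `correlation_report`: tibble `pairs`
#'   (feature, cc, p_value, significant), `n_cells`, thresholds.
#' @export
spearman_paired <- function(features,
                            set_a = NULL, set_b = NULL,
                            p_threshold = 0.05, cc_threshold = 0.15,
                            seed = 1L) {
  if (is.null(set_a)) {
    set_a <- grep("^p38_", names(features), value = TRUE)
    set_b <- sub("^p38_", "nfkb_", set_a)
    ok <- set_b %in% names(features)
    set_a <- set_a[ok]
    set_b <- set_b[ok]
  }
  stopifnot(length(set_a) == length(set_b), length(set_a) >= 1)
  n <- nrow(features)
  if (n < 10) abort("Need at least 10 paired cells for correlation analysis.")
  rows <- map(seq_along(set_a), function(j) {
    a <- features[[set_a[j]]]
    b <- features[[set_b[j]]]
    keep <- !is.na(a) & !is.na(b)
    res <- spearman_with_p(a[keep], b[keep], seed = seed + j)
    tibble(feature = sub("^p38_", "", set_a[j]),
           p38_feature = set_a[j], nfkb_feature = set_b[j],
           cc = res$cc, p_value = res$p, n = sum(keep))
  })
  pairs <- list_rbind(rows) |>
    mutate(significant = .data$p_value < p_threshold &
             abs(.data$cc) > cc_threshold)
  structure(
    list(pairs = pairs, n_cells = n,
         p_threshold = p_threshold, cc_threshold = cc_threshold),
    class = "correlation_report"
  )
}

spearman_with_p <- function(a, b, n_perm = 10000, seed = 1L) {
  n <- length(a)
  if (n < 4 || sd(a) == 0 || sd(b) == 0) {
    return(list(cc = NA_real_, p = NA_real_))
  }
  rho <- cor(a, b, method = "spearman")
  if (n > 30) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * pt(-abs(tt), df = n - 2)
  } else {
    ra <- rank(a)
    rb <- rank(b)
    obs <- abs(cor(ra, rb))
    perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) abs(cor(ra, sample(rb))), numeric(1))
    })
    p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  list(cc = rho, p = min(p, 1))
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Paired Spearman correlation report (", x$n_cells, " cells)\n", sep = "")
  print(x$pairs, n = 20)
  invisible(x)
}

#' Shuffling control for the paired correlation structure
#'
#' Permutes one pathway's feature rows (within each condition, when
#' condition columns are present) before recomputing the paired Spearman
#' correlations. With the cell pairing destroyed, correlations collapse
#' toward zero.
#'
#' @param features Paired feature table.
#' @param pathway_to_shuffle `"nfkb"` or `"p38"`.
#' @param seed Integer seed.
#' @inheritParams spearman_paired
#' @return A `correlation_report` on the shuffled table.
#' @export
shuffle_control <- function(features, pathway_to_shuffle = c("nfkb", "p38"),
                            seed = 1L, ...) {
  pathway_to_shuffle <- match.arg(pathway_to_shuffle)
  cols <- grep(paste0("^", pathway_to_shuffle, "_"), names(features),
               value = TRUE)
  conds <- intersect(c("stimulus", "dose", "replicate"), names(features))
  shuffled <- withr::with_seed(seed, {
    if (length(conds)) {
      features |>
        group_by(across(all_of(conds))) |>
        mutate(across(all_of(cols), ~ .x[sample.int(dplyr::n())])) |>
        ungroup()
    } else {
      idx <- sample.int(nrow(features))
      out <- features
      out[cols] <- features[idx, cols]
      out
    }
  })
  spearman_paired(shuffled, seed = seed, ...)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean: a mean-normalised measure
#' of across-cell variability.
#'
#' @param values Numeric vector with non-zero mean.
#' @return A single number.
#' @examples
#' coefficient_of_variation(c(1, 3))  # sqrt(2)/2
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) abort("Coefficient of variation undefined: mean is zero.")
  sd(values) / m
}
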