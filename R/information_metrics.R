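#' Clean and z-score a feature table
#'
#' Drops feature columns that contain any missing value or have zero
#' variance, then z-scores each remaining column (mean 0, SD 1). Metadata
#' (cell-key) columns are excluded from the matrix.
#'
#' @param features A feature table from [extract_features()], or any tibble
#'   of numeric feature columns plus optional cell-key metadata.
#' @return A list: `x` (numeric matrix, cells x kept features), `kept`
#'   (kept column names), `dropped` (named character vector of dropped
#'   columns and the reason).
#' @export
clean_and_scale <- function(features) {
  meta <- intersect(cell_key_vars(), names(features))
  num <- features |> select(-all_of(meta)) |> select(where(is.numeric))
  if (nrow(num) < 2) abort("Need at least two cells to scale features.")
  dropped <- character()
  keep <- character()
  for (nm in names(num)) {
    v <- num[[nm]]
    if (anyNA(v)) {
      dropped[nm] <- "contains missing values"
    } else if (sd(v) == 0) {
      dropped[nm] <- "zero variance"
    } else {
      keep <- c(keep, nm)
    }
  }
  if (!length(keep)) abort("All feature columns were dropped during cleaning.")
  if (length(dropped)) {
    inform(paste0("Dropped ", length(dropped), " feature column(s): ",
                  paste(names(dropped), collapse = ", ")))
  }
  x <- scale(as.matrix(num[keep]))
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  list(x = x, kept = keep, dropped = dropped)
}

#' k-nearest-neighbour mutual information between a discrete label and
#' continuous features
#'
#' The discrete-continuous kNN estimator: for each point, the distance to
#' its k-th nearest neighbour *within the same class* defines a radius, and
#' \eqn{m_i} counts the points of the full sample (all classes, excluding
#' the point itself) lying within that radius. Then
#' \deqn{I = \psi(N) - \langle\psi(N_c)\rangle + \psi(k) -
#'       \langle\psi(m_i)\rangle}
#' in nats, converted to bits. Distances are Euclidean; ties are resolved
#' in index order.
#'
#' @param labels Discrete label vector (factor or coercible).
#' @param x Numeric matrix (rows = samples), typically z-scored via
#'   [clean_and_scale()].
#' @param k Number of neighbours (default 3).
#' @return Mutual information in bits (a single number; may be slightly
#'   negative for independent data, by estimator noise).
#' @examples
#' set.seed(1)
#' x <- matrix(c(rnorm(100), rnorm(100, 10)), ncol = 1)
#' knn_mi(rep(c("a", "b"), each = 100), x)  # ~1 bit
#' @export
knn_mi <- function(labels, x, k = 3) {
  labels <- as.factor(labels)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  counts <- table(labels)
  if (any(counts <= k)) {
    abort(paste0("Class '", names(counts)[which(counts <= k)[1]],
                 "' has <= k = ", k, " members; cannot estimate MI."))
  }
  d <- as.matrix(dist(x))
  radius <- numeric(n)
  m <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- same[same != i]
    radius[i] <- sort(d[i, same], partial = k)[k]
    others <- d[i, -i]
    m[i] <- sum(others <= radius[i])
  }
  nats <- digamma(n) - mean(digamma(counts[labels])) +
    digamma(k) - mean(digamma(m))
  as.numeric(nats / log(2))
}

#' Subsample-extrapolated mutual information
#'
#' Controls for finite-sample bias of [knn_mi()] by computing MI on
#' `n_subsets` random subsamples whose sizes span `frac` of the data on an
#' even grid, regressing MI on 1/n, and reporting the infinite-sample
#' intercept.
#'
#' @param labels Discrete label vector.
#' @param features Feature table (cleaned and z-scored internally via
#'   [clean_and_scale()]), or a numeric matrix.
#' @param n_subsets Number of subsample sizes (default 12).
#' @param frac Length-2 range of subsample fractions (default 0.65-0.90).
#' @param k Neighbours for [knn_mi()].
#' @param seed Integer seed; one subsample draw per fraction.
#' @return An object of class `mi_result`: `mi_bits` (extrapolated
#'   estimate), `curve` (tibble of n and mi_bits per subsample),
#'   `intercept`, `slope`, `k`, `seed`.
#' @export
mi_extrapolated <- function(labels, features, n_subsets = 12,
                            frac = c(0.65, 0.90), k = 3, seed = 1L) {
  if (is.matrix(features)) {
    x <- features
  } else {
    x <- clean_and_scale(features)$x
  }
  labels <- as.factor(labels)
  n <- nrow(x)
  fracs <- seq(frac[1], frac[2], length.out = n_subsets)
  curve <- withr::with_seed(seed, {
    map(fracs, function(f) {
      ns <- max(2L, round(f * n))
      idx <- sample.int(n, ns)
      tibble(n = ns, mi_bits = knn_mi(labels[idx], x[idx, , drop = FALSE], k = k))
    }) |> list_rbind()
  })
  fit <- lm(mi_bits ~ I(1 / n), data = curve)
  structure(
    list(mi_bits = unname(coef(fit)[1]),
         curve = curve,
         intercept = unname(coef(fit)[1]),
         slope = unname(coef(fit)[2]),
         k = k, seed = seed, n_total = n),
    class = "mi_result"
  )
}

#' @export
print.mi_result <- function(x, ...) {
  cat("Extrapolated mutual information:", round(x$mi_bits, 3), "bits\n")
  cat("  ", nrow(x$curve), " subsamples of n = ", min(x$curve$n), "-",
      max(x$curve$n), " (of ", x$n_total, "), k = ", x$k, "\n", sep = "")
  invisible(x)
}
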