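#' Balance classes by downsampling
#'
#' Uniform random selection of cells so that every class has the size of
#' the smallest class.
#'
#' @param table A tibble of cells (any columns).
#' @param labels Class label vector, one per row.
#' @param seed Integer seed.
#' @return A list: `table` (subsampled rows), `labels` (matching labels).
#' @export
balance_classes <- function(table, labels, seed = 1L) {
  labels <- as.factor(labels)
  stopifnot(nrow(table) == length(labels))
  counts <- table(labels)
  if (any(counts == 0)) {
    abort(paste0("Empty class: ", names(counts)[counts == 0][1]))
  }
  n_min <- min(counts)
  idx <- withr::with_seed(seed, {
    unlist(map(levels(labels), function(cl) {
      pool <- which(labels == cl)
      if (length(pool) == n_min) pool else sample(pool, n_min)
    }))
  })
  list(table = table[idx, , drop = FALSE], labels = droplevels(labels[idx]))
}

#' Train and evaluate a bagged decision-tree stimulus/dose classifier
#'
#' Classifies single cells from their dynamic features with an ensemble of
#' bagged decision trees (30 trees, at most 20 splits each), evaluated by
#' stratified 5-fold cross-validation: features are z-scored across all
#' classes, classes are balanced by downsampling, each fold holds an equal
#' number of cells per class, and held-out predictions are aggregated over
#' folds into a confusion matrix, overall accuracy and per-class F1 scores
#' (harmonic mean of precision and sensitivity).
#'
#' @param features Feature table ([extract_features()]) or numeric tibble;
#'   cell-key metadata columns are dropped automatically. Columns with
#'   missing values or zero variance are removed before scaling.
#' @param labels Class labels (stimulus identity or dose), one per row.
#' @param n_trees Trees in the ensemble (default 30).
#' @param max_splits Maximum splits per tree (default 20).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed (balancing, bagging and fold assignment).
#' @return An object of class `classifier_report`: `confusion` (true x
#'   predicted counts), `accuracy`, `f1` (named per-class), `folds`
#'   (per-cell fold assignment), `config`, `seed`.
#' @export
train_eval_tree_ensemble <- function(features, labels, n_trees = 30,
                                     max_splits = 20, folds = 5, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    abort("Classification needs at least two classes.")
  }
  cleaned <- clean_and_scale(bind_cols(features))
  x <- cleaned$x
  bal <- balance_classes(as_tibble(x), labels, seed = seed)
  x <- as.matrix(bal$table)
  y <- bal$labels
  n_per_class <- table(y)[1]
  if (n_per_class < folds) {
    abort(paste0("Need at least ", folds, " cells per class for ", folds,
                 "-fold cross-validation."))
  }
  # z-score across all classes after balancing (training-set convention)
  x <- scale(x)

  fold_id <- withr::with_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      pool <- which(y == cl)
      id[pool] <- sample(rep_len(seq_len(folds), length(pool)))
    }
    id
  })

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  withr::with_seed(seed + 1L, {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- randomForest::randomForest(
        x = x[tr, , drop = FALSE], y = y[tr],
        ntree = n_trees,
        mtry = ncol(x),          # all predictors per split = bagging
        maxnodes = max_splits + 1L
      )
      pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])
    }
  })

  confusion <- table(true = y, predicted = pred)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  f1 <- vapply(levels(y), function(cl) {
    tp <- confusion[cl, cl]
    prec <- tp / sum(confusion[, cl])
    sens <- tp / sum(confusion[cl, ])
    if (is.nan(prec) || prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  }, numeric(1))

  structure(
    list(confusion = confusion, accuracy = accuracy, f1 = f1,
         folds = fold_id,
         config = list(n_trees = n_trees, max_splits = max_splits,
                       folds = folds, engine = "randomForest (bagged)",
                       mtry = ncol(x), dropped = cleaned$dropped),
         seed = seed),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Bagged decision-tree classifier (", x$config$n_trees, " trees, ",
      x$config$folds, "-fold CV)\n", sep = "")
  cat("  accuracy:", round(x$accuracy, 3), "\n")
  cat("  per-class F1:",
      paste(names(x$f1), round(x$f1, 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Shuffled cross-pathway pairing control
#'
#' Destroys the within-cell pairing of p38 and NF-kB features by permuting
#' one pathway's rows across *all* classes before re-joining with the other
#' pathway's correctly labeled rows. Classification of the result measures
#' how much information lives in the pairing itself. An identity
#' permutation is resampled (for n > 5) so the control is never a no-op.
#'
#' @param features_p38,features_nfkb Feature tibbles with identical row
#'   counts and cell-key metadata (same cells, same order).
#' @param mode Which pathway to shuffle: `"shuffle_p38"` or
#'   `"shuffle_nfkb"`.
#' @param seed Integer seed.
#' @return A combined feature tibble: metadata from the unshuffled pathway,
#'   all feature columns from both.
#' @export
shuffled_pairing <- function(features_p38, features_nfkb,
                             mode = c("shuffle_nfkb", "shuffle_p38"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(features_p38) != nrow(features_nfkb)) {
    abort("Feature tables must have equal row counts (same cells).")
  }
  keys <- intersect(cell_key_vars(), names(features_p38))
  if (!identical(keys, intersect(cell_key_vars(), names(features_nfkb)))) {
    abort("Feature tables carry different metadata schemas.")
  }
  n <- nrow(features_p38)
  perm <- withr::with_seed(seed, {
    p <- sample.int(n)
    while (n > 5 && identical(p, seq_len(n))) p <- sample.int(n)
    p
  })
  if (mode == "shuffle_nfkb") {
    shuffled <- features_nfkb[perm, setdiff(names(features_nfkb), keys), drop = FALSE]
    bind_cols(features_p38, shuffled)
  } else {
    shuffled <- features_p38[perm, setdiff(names(features_p38), keys), drop = FALSE]
    bind_cols(features_nfkb, shuffled)
  }
}
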