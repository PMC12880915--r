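# Per-organelle Random Forest polarity prediction: cell-height polarity
# stratification, stratified 5-fold cross-validated classifiers (one per
# structure), and accuracy-weighted feature importance ranking across
# organelles.

#' Stratify cells into polarity groups by height
#'
#' Splits cells into `n_groups` equal-count groups on cell height (taller
#' cells are more polarized). Three groups give the low / medium / high
#' polarity strata; two give a median split.
#'
#' @param heights numeric cell heights (um), or a cell table with a
#'   `height` column.
#' @param n_groups number of groups (default 3).
#' @return factor of group labels (`low` < `medium` < `high`, or
#'   `g1..gk` for other k); a degenerate split (ties across a boundary)
#'   is flagged with a warning.
#' @examples
#' stratify_by_height(1:9)
#' @export
stratify_by_height <- function(heights, n_groups = 3) {
  if (is.data.frame(heights)) heights <- heights$height
  n <- length(heights)
  if (n < n_groups) stop("fewer cells than groups")
  labs <- if (n_groups == 3) c("low", "medium", "high")
  else if (n_groups == 2) c("low", "high")
  else paste0("g", seq_len(n_groups))
  if (length(unique(heights)) == 1L) {
    warning("all heights equal: degenerate split")
    return(factor(rep(labs[1], n), levels = labs))
  }
  r <- rank(heights, ties.method = "first")
  g <- ceiling(r / n * n_groups)
  factor(labs[g], levels = labs)
}

# stratified k-fold assignment, deterministic for a seed-fixed RNG state
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a polarity classifier for one organelle
#'
#' Random Forest (500 trees) predicting the polarity class from the
#' organelle's feature columns, evaluated by stratified 5-fold
#' cross-validation. Accuracy is the mean held-out accuracy over folds;
#' impurity (Gini) importances are averaged over the fold models and
#' normalized to sum to 1.
#'
#' @param table data.frame of feature columns plus a `label` column
#'   (factor/character, >= 2 classes, >= 10 rows per class).
#' @param seed RNG seed (fold assignment and forests).
#' @param n_folds cross-validation folds.
#' @param ntree trees per forest.
#' @param organelle optional class name carried into the result.
#' @return object of class `polarity_model`: `accuracy`, `importance`
#'   (named, sums to 1), `weighted_importance` (importance x accuracy),
#'   `per_fold` accuracies.
#' @export
train_polarity_model <- function(table, seed = 0, n_folds = 5, ntree = 500,
                                 organelle = NULL) {
  if (!"label" %in% names(table)) stop("table needs a 'label' column")
  y <- factor(table$label)
  if (nlevels(y) < 2L) stop("need at least 2 polarity classes")
  if (any(table(y) < 10L)) stop("need >= 10 rows per class")
  x <- table[, setdiff(names(table), "label"), drop = FALSE]
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  if (!ncol(x)) stop("no numeric feature columns")
  for (j in seq_along(x)) {           # median imputation, features finite
    v <- x[[j]]
    v[!is.finite(v)] <- stats::median(v[is.finite(v)])
    x[[j]] <- v
  }
  with_seed(seed, {
    fold <- stratified_folds(y, n_folds)
    acc <- numeric(n_folds)
    imp <- matrix(0, ncol(x), n_folds,
                  dimnames = list(colnames(x), NULL))
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- fold == f
      rf <- randomForest::randomForest(x[tr, , drop = FALSE],
                                       droplevels(y[tr]), ntree = ntree)
      pred <- stats::predict(rf, x[te, , drop = FALSE])
      acc[f] <- mean(as.character(pred) == as.character(y[te]))
      gi <- randomForest::importance(rf)[, "MeanDecreaseGini"]
      imp[names(gi), f] <- gi
    }
    mi <- rowMeans(imp)
    if (sum(mi) > 0) mi <- mi / sum(mi)
    structure(list(organelle = organelle,
                   accuracy = mean(acc), per_fold = acc,
                   importance = mi,
                   weighted_importance = mi * mean(acc),
                   n = nrow(x), classes = levels(y), seed = seed),
              class = "polarity_model")
  })
}

#' @export
print.polarity_model <- function(x, ...) {
  cat(sprintf("polarity model%s: CV accuracy %.3f (n = %d, classes: %s)\n",
              if (is.null(x$organelle)) "" else paste0(" [", x$organelle, "]"),
              x$accuracy, x$n, paste(x$classes, collapse = "/")))
  top <- sort(x$importance, decreasing = TRUE)[seq_len(min(3, length(x$importance)))]
  cat("  top features:", paste(sprintf("%s (%.2f)", names(top), top),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Accuracy-weighted importance ranking across organelle models
#'
#' Multiplies each feature's importance by the accuracy of the model it
#' came from (the "true impact" score) and ranks features globally across
#' organelles.
#'
#' @param models list of `polarity_model` objects.
#' @return data.frame sorted by decreasing score: organelle, feature,
#'   importance, accuracy, score.
#' @export
weighted_importance <- function(models) {
  if (!length(models)) stop("need at least one model")
  rows <- lapply(models, function(m) {
    data.frame(organelle = if (is.null(m$organelle)) NA else m$organelle,
               feature = names(m$importance),
               importance = unname(m$importance),
               accuracy = m$accuracy,
               score = unname(m$weighted_importance))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}
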