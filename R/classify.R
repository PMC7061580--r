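#' Cross-validation / classifier configuration
#'
#' Defaults follow the standard protocol: stratified 10-fold
#' cross-validation of an RBF-kernel SVM with `C = 100` and `gamma = 0.1`.
#' Features are z-scored inside each fold using training-rows-only
#' statistics (the kernel width presupposes commensurate feature scales);
#' set `standardize = FALSE` to disable.
#'
#' @param n_folds number of folds (>= 2).
#' @param stratified preserve class proportions per fold (default TRUE).
#' @param seed integer seed for the fold assignment.
#' @param C SVM box constraint.
#' @param gamma RBF kernel width.
#' @param standardize z-score features per training fold.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, stratified = TRUE, seed = 0L,
                      C = 100, gamma = 0.1, standardize = TRUE) {
  stopifnot_scalar(n_folds, "n_folds", positive = TRUE, integerish = TRUE)
  if (n_folds < 2L) stop("`n_folds` must be >= 2", call. = FALSE)
  stopifnot_scalar(C, "C", positive = TRUE)
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  structure(list(n_folds = as.integer(n_folds), stratified = isTRUE(stratified),
                 seed = as.integer(seed), C = C, gamma = gamma,
                 standardize = isTRUE(standardize)),
            class = "cv_config")
}

#' Assemble a single-thickness dataset from a feature table
#'
#' Each film thickness is analyzed independently; this filters the feature
#' table to one thickness and validates the class structure.
#'
#' @param feature_table data.frame from [extract_feature_table()].
#' @param thickness_um the thickness to select, micrometres.
#' @param min_class_size minimum rows per class (set to the fold count
#'   before cross-validation; classes below it raise a named error).
#' @return An object of class `voc_dataset` with fields `features` (matrix),
#'   `labels` (factor), `groups` (replicate ids) and `thickness_um`.
#' @export
assemble_dataset <- function(feature_table, thickness_um,
                             min_class_size = 1L) {
  cols <- paste0("f", 1:12)
  need <- c("voc", "thickness_um", "replicate_id", "cycle_index", cols)
  if (nrow(feature_table) == 0L) stop("feature table is empty", call. = FALSE)
  miss <- setdiff(need, names(feature_table))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sel <- feature_table$thickness_um == thickness_um
  if (!any(sel))
    stop(sprintf("no rows with thickness %g um in the feature table",
                 thickness_um), call. = FALSE)
  tab <- feature_table[sel, , drop = FALSE]
  present <- intersect(voc_names(), unique(tab$voc))
  lev <- if (length(present)) c(present, setdiff(sort(unique(tab$voc)), present))
         else sort(unique(tab$voc))
  labels <- factor(tab$voc, levels = lev)
  counts <- table(labels)
  small <- names(counts)[counts < min_class_size]
  if (length(small))
    stop("classes with fewer than ", min_class_size, " cycles: ",
         paste(small, collapse = ", "), call. = FALSE)
  structure(list(features = as.matrix(tab[, cols]), labels = labels,
                 groups = tab$replicate_id, thickness_um = thickness_um),
            class = "voc_dataset")
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled with the seeded RNG and dealt round-robin over folds.
make_folds <- function(labels, n_folds, seed, stratified = TRUE) {
  fold <- integer(length(labels))
  with_seed(seed, {
    if (stratified) {
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      idx <- sample.int(length(labels))
      fold[idx] <- rep_len(seq_len(n_folds), length(labels))
    }
  })
  fold
}

#' Cross-validated per-cycle predictions
#'
#' Stratified k-fold cross-validation: every cycle is predicted exactly once
#' by a model that never saw it in training.  Feature standardization
#' statistics (mean, sd) are computed on each fold's training rows only and
#' applied to its held-out rows, so no information leaks across the split.
#' Deterministic given `cfg$seed`.
#'
#' @param dataset a `voc_dataset` from [assemble_dataset()].
#' @param cfg a [cv_config].
#' @return List with `predicted` (factor, one entry per row), `fold`
#'   (fold id per row) and `labels` (the true labels, for convenience).
#' @export
crossval_predict <- function(dataset, cfg = cv_config()) {
  stopifnot(inherits(dataset, "voc_dataset"), inherits(cfg, "cv_config"))
  labels <- dataset$labels
  if (nlevels(droplevels(labels)) < 2L) {
    warning("single-class dataset: predictions are trivially that class",
            call. = FALSE)
    return(list(predicted = labels, fold = rep(1L, length(labels)),
                labels = labels))
  }
  counts <- table(droplevels(labels))
  if (any(counts < cfg$n_folds))
    stop("classes with fewer rows than folds: ",
         paste(names(counts)[counts < cfg$n_folds], collapse = ", "),
         call. = FALSE)
  fold <- make_folds(labels, cfg$n_folds, cfg$seed, cfg$stratified)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (k in seq_len(cfg$n_folds)) {
    tr <- fold != k
    Xtr <- dataset$features[tr, , drop = FALSE]
    Xte <- dataset$features[!tr, , drop = FALSE]
    if (cfg$standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2L, sd)
      sdv[!is.finite(sdv) | sdv < 1e-12] <- 1   # constant features pass through
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
    }
    model <- svm_rbf(Xtr, droplevels(labels[tr]), C = cfg$C, gamma = cfg$gamma)
    p <- predict(model, Xte)
    pred[!tr] <- factor(as.character(p), levels = levels(labels))
  }
  list(predicted = pred, fold = fold, labels = labels)
}

#' Row-normalized confusion matrix
#'
#' Entry (i, j) is the fraction of class-i cycles predicted as class j.
#' Rows with zero support are all-zero and reported in the
#' `"zero_support"` attribute.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param label_order character vector fixing the row/column order.
#' @return Square numeric matrix with dimnames `label_order`.
#' @export
confusion_matrix_normalized <- function(true_labels, predicted_labels,
                                        label_order = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  if (is.null(label_order))
    label_order <- sort(unique(c(true_labels, predicted_labels)))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), label_order)
  if (length(bad))
    stop("labels outside `label_order`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tf <- factor(true_labels, levels = label_order)
  pf <- factor(predicted_labels, levels = label_order)
  counts <- table(tf, pf)
  support <- rowSums(counts)
  norm <- sweep(unclass(counts), 1L, pmax(support, 1L), "/")
  out <- matrix(as.numeric(norm), nrow = length(label_order),
                dimnames = list(true = label_order, predicted = label_order))
  attr(out, "zero_support") <- label_order[support == 0]
  out
}

#' Summarize cross-validated predictions into a classification report
#'
#' @param confusion row-normalized confusion matrix from
#'   [confusion_matrix_normalized()].
#' @param predictions output of [crossval_predict()] (needs `predicted` and
#'   `labels`).
#' @param thickness_um thickness the report refers to (metadata).
#' @return An object of class `classification_report`: `confusion`,
#'   `overall_accuracy` (pooled, micro), `mean_fold_accuracy` (when fold ids
#'   are available), `per_voc_accuracy` (confusion diagonal),
#'   `macro_precision` (unweighted mean of column-wise precision; classes
#'   never predicted contribute 0 and are listed in `never_predicted`),
#'   `micro_precision` (equals pooled accuracy in single-label problems)
#'   and `thickness_um`.
#' @export
summarize_report <- function(confusion, predictions,
                             thickness_um = NA_real_) {
  true <- as.character(predictions$labels)
  pred <- as.character(predictions$predicted)
  correct <- true == pred
  overall <- mean(correct)
  fold_acc <- if (!is.null(predictions$fold))
    tapply(correct, predictions$fold, mean) else NULL
  lev <- rownames(confusion)
  # column-wise precision on raw counts
  prec <- vapply(lev, function(lv) {
    denom <- sum(pred == lv)
    if (denom == 0) 0 else sum(pred == lv & true == lv) / denom
  }, 0)
  never <- lev[vapply(lev, function(lv) sum(pred == lv) == 0, TRUE)]
  structure(list(
    confusion = confusion,
    overall_accuracy = overall,
    mean_fold_accuracy = if (is.null(fold_acc)) NA_real_ else mean(fold_acc),
    per_voc_accuracy = diag(confusion),
    macro_precision = mean(prec),
    micro_precision = overall,
    precision_per_voc = prec,
    never_predicted = never,
    thickness_um = thickness_um
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report (thickness %s um)\n", format(x$thickness_um)))
  cat(sprintf("  overall accuracy: %.3f   macro precision: %.3f\n",
              x$overall_accuracy, x$macro_precision))
  cat("  per-VOC accuracy:\n")
  print(round(x$per_voc_accuracy, 3))
  invisible(x)
}
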