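#' Train a multiclass RBF-kernel SVM
#'
#' C-support-vector classifier with a radial-basis kernel
#' `K(x, z) = exp(-gamma * ||x - z||^2)`, trained by sequential minimal
#' optimization (maximal-violating-pair working-set selection, the standard
#' first-order rule).  Multiclass problems use one-vs-one voting over all
#' class pairs; vote ties are broken toward the earlier class in the factor
#' level order.  Training is deterministic: no randomness is involved.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels (coerced to factor; level order is preserved).
#' @param C box constraint (default 100).
#' @param gamma RBF kernel width (default 0.1).
#' @param eps SMO stopping tolerance on the maximal KKT violation.
#' @param max_iter iteration cap per binary subproblem.
#' @return An object of class `svm_rbf` usable with [predict.svm_rbf()].
#' @export
svm_rbf <- function(x, y, C = 100, gamma = 0.1, eps = 1e-3,
                    max_iter = 100000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  stopifnot_scalar(C, "C", positive = TRUE)
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  lev <- levels(droplevels(y))
  if (length(lev) < 2L) stop("need at least two classes", call. = FALSE)
  pairs <- utils::combn(length(lev), 2L)
  models <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- lev[pairs[1L, p]]; b <- lev[pairs[2L, p]]
    sel <- y %in% c(a, b)
    ys <- ifelse(y[sel] == a, 1, -1)
    fit <- .svm_smo_train(x[sel, , drop = FALSE], ys, C, gamma, eps,
                          as.integer(max_iter))
    list(a = a, b = b, X = x[sel, , drop = FALSE],
         coef = fit$alpha * ys, rho = fit$rho, iter = fit$iter)
  })
  structure(list(levels = lev, models = models, C = C, gamma = gamma),
            class = "svm_rbf")
}

#' Predict classes with a trained RBF SVM
#'
#' @param object an `svm_rbf` model.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @return Factor of predicted labels with the training level order.
#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  votes <- matrix(0L, nrow(newdata), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in object$models) {
    dv <- .svm_rbf_decision(m$X, m$coef, m$rho, object$gamma, newdata)
    win <- ifelse(dv >= 0, m$a, m$b)
    for (lv in c(m$a, m$b)) votes[win == lv, lv] <- votes[win == lv, lv] + 1L
  }
  factor(object$levels[apply(votes, 1L, which.max)], levels = object$levels)
}

#' @export
print.svm_rbf <- function(x, ...) {
  nsv <- sum(vapply(x$models, function(m) sum(m$coef != 0), 0))
  cat(sprintf("svm_rbf: %d classes, C=%g, gamma=%g, %d pairwise models, %d SV terms\n",
              length(x$levels), x$C, x$gamma, length(x$models), nsv))
  invisible(x)
}
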