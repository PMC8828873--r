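# Internal: fit one linear soft-margin SVM for the class pair (i, j) and
# return an oriented affine decision rule d(x) = w.x + b with d > 0 favoring
# class i, plus a logistic calibration slope 1 / median|d| on training data.
fit_pair_svm <- function(xs, y, ci, cj, C) {
  idx <- y %in% c(ci, cj)
  xi <- xs[idx, , drop = FALSE]
  yi <- factor(as.character(y[idx]), levels = c(ci, cj))
  fit <- e1071::svm(xi, yi, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  d <- drop(xi %*% w) + b
  if (mean(d[yi == ci]) < mean(d[yi == cj])) {
    w <- -w; b <- -b; d <- -d
  }
  med <- stats::median(abs(d))
  slope <- if (med > 0) 1 / med else 1
  list(classes = c(ci, cj), w = w, b = b, slope = slope)
}

#' Train an all-pairs linear-SVM subtype classifier
#'
#' Fits one soft-margin linear SVM per unordered class pair (K(K-1)/2 models
#' for K classes, C = 1 by default). Pairwise decision values are mapped to
#' win probabilities through a logistic link whose slope is calibrated on the
#' training margins (1 / median absolute decision value), and class
#' membership probabilities are obtained by uniform-weight additive
#' aggregation of the pairwise wins (see [aggregate_pairwise()]).
#'
#' @param x expression matrix, genes x samples (signature order fixed at
#'   training time).
#' @param labels class label per sample; every class needs >= 2 samples.
#' @param C soft-margin cost (default 1).
#' @return a `pairwise_svm`: `classes`, `models` (per-pair w, b, slope),
#'   `genes`, `C`, uniform aggregation `weights`.
#' @export
train_pairwise <- function(x, labels, C = 1) {
  train_pairwise_impl(x, labels, C, min_per_class = 2L)
}

train_pairwise_impl <- function(x, labels, C, min_per_class) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop_input("labels must have one entry per sample (column of x)")
  classes <- sort(unique(labels))
  cnt <- table(labels)
  small <- names(cnt)[cnt < min_per_class]
  if (length(small))
    stop_input("class(es) with fewer than ", min_per_class, " samples: ",
               paste(small, collapse = ", "))
  xs <- t(x)
  pairs <- utils::combn(classes, 2L)
  models <- lapply(seq_len(ncol(pairs)), function(p)
    fit_pair_svm(xs, labels, pairs[1L, p], pairs[2L, p], C))
  names(models) <- apply(pairs, 2L, paste, collapse = "|")
  structure(list(classes = classes, models = models, genes = rownames(x),
                 C = C, weights = rep(1 / length(models), length(models))),
            class = "pairwise_svm")
}

#' @export
print.pairwise_svm <- function(x, ...) {
  cat(sprintf("All-pairs linear SVM: %d classes, %d pairwise models (C = %g)\n",
              length(x$classes), length(x$models), x$C))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate pairwise win probabilities into class probabilities
#'
#' With uniform pair weights, each class scores the sum of its pairwise win
#' probabilities, score_i = sum_j p(i beats j) with p(j beats i) = 1 - p(i
#' beats j), and probabilities are the scores normalized to sum to one.
#'
#' @param p matrix (samples x pairs) or vector of win probabilities for the
#'   FIRST class of each pair, all in [0, 1].
#' @param pairs 2-row matrix of class indices (as from `combn(K, 2)`), one
#'   column per column of `p`.
#' @param n_classes number of classes K.
#' @return samples x K matrix of class probabilities (rows sum to 1).
#' @export
aggregate_pairwise <- function(p, pairs, n_classes) {
  if (is.vector(p)) p <- matrix(p, nrow = 1L)
  if (any(p < 0 | p > 1)) stop_input("pairwise probabilities must lie in [0, 1]")
  if (ncol(p) != ncol(pairs))
    stop_input("one pairwise probability column per class pair required")
  scores <- matrix(0, nrow(p), n_classes)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    scores[, a] <- scores[, a] + p[, j]
    scores[, b] <- scores[, b] + (1 - p[, j])
  }
  scores / rowSums(scores)
}

#' Predict subtype membership with a pairwise SVM ensemble
#'
#' @param object a [train_pairwise()] fit.
#' @param newdata expression matrix, genes x samples, aligned to the
#'   training signature (same genes, same order).
#' @param type `"class"` for hard labels (argmax probability, ties broken
#'   toward the lower class index) or `"prob"` for the probability matrix.
#' @param ... unused.
#' @return factor of labels or samples x K probability matrix.
#' @export
predict.pairwise_svm <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!identical(rownames(newdata), object$genes)) {
    if (!all(object$genes %in% rownames(newdata)))
      stop_input("newdata gene rows do not match the training signature")
    newdata <- newdata[object$genes, , drop = FALSE]
  }
  xs <- t(newdata)
  K <- length(object$classes)
  pairs <- utils::combn(seq_len(K), 2L)
  p <- vapply(seq_along(object$models), function(j) {
    m <- object$models[[j]]
    stats::plogis(m$slope * (drop(xs %*% m$w) + m$b))
  }, numeric(nrow(xs)))
  if (nrow(xs) == 1L) p <- matrix(p, nrow = 1L)
  probs <- aggregate_pairwise(p, pairs, K)
  dimnames(probs) <- list(rownames(xs), object$classes)
  if (type == "prob") return(probs)
  factor(object$classes[apply(probs, 1L, which.max)], levels = object$classes)
}

#' Leave-one-out cross-validation of the pairwise-SVM classifier
#'
#' Refits the all-pairs ensemble with each sample held out, records its
#' predicted class probabilities, and scores each class by its one-vs-rest
#' ROC AUC over the held-out probabilities (Mann-Whitney form), plus the
#' mean AUC across classes. Folds that would lose an entire class are
#' skipped with a warning and recorded.
#'
#' @inheritParams train_pairwise
#' @return a `cv_report`: `probabilities` (n x K), `predicted`, `auc`
#'   (per class), `mean_auc`, `skipped` fold indices.
#' @export
loocv_pairwise <- function(x, labels, C = 1) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- ncol(x)
  classes <- sort(unique(labels))
  if (n < length(classes) + 1L)
    stop_input("need at least K + 1 samples for leave-one-out")
  probs <- matrix(NA_real_, n, length(classes),
                  dimnames = list(colnames(x), classes))
  skipped <- integer(0)
  for (i in seq_len(n)) {
    tr_labels <- labels[-i]
    if (length(unique(tr_labels)) < length(classes)) {
      skipped <- c(skipped, i)
      next
    }
    ens <- train_pairwise_impl(x[, -i, drop = FALSE], tr_labels, C,
                               min_per_class = 1L)
    probs[i, ] <- predict(ens, x[, i, drop = FALSE], type = "prob")[1L, classes]
  }
  if (length(skipped))
    warning(length(skipped), " leave-one-out fold(s) skipped (class lost)")
  ok <- setdiff(seq_len(n), skipped)
  auc <- vapply(classes, function(cl)
    auc_rank(probs[ok, cl], labels[ok] == cl), numeric(1L))
  predicted <- factor(classes[apply(probs, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))], levels = classes)
  structure(list(probabilities = probs, predicted = predicted,
                 auc = auc, mean_auc = mean(auc, na.rm = TRUE),
                 skipped = skipped, classes = classes),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Leave-one-out cross-validation (one-vs-rest AUC)\n")
  for (cl in x$classes) cat(sprintf("  %-10s %.4f\n", cl, x$auc[[cl]]))
  cat(sprintf("  mean AUC   %.4f\n", x$mean_auc))
  if (length(x$skipped)) cat("  skipped folds:", length(x$skipped), "\n")
  invisible(x)
}
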