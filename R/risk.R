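#' Train the best-vs-worst prognosis SVM risk model
#'
#' Fits a binary soft-margin linear SVM on the samples of the best-prognosis
#' (negative label) and worst-prognosis (positive label) subtypes over the
#' signature genes. The continuous decision value r = w.x + b is the risk
#' score; the sign convention is fixed so that larger positive scores
#' indicate higher confidence in the worst-prognosis class.
#'
#' @param x expression matrix, genes x samples, restricted to the two
#'   extreme-prognosis groups.
#' @param group_labels group label per sample (exactly two distinct values).
#' @param negative_class label of the best-prognosis group (scores negative);
#'   defaults to the first sorted label.
#' @param positive_class label of the worst-prognosis group.
#' @param C soft-margin cost (default 1).
#' @return a `risk_svm`: `w` (named by gene), `b`, `C`, `negative_class`,
#'   `positive_class`, `genes`.
#' @export
train_risk <- function(x, group_labels, negative_class = NULL,
                       positive_class = NULL, C = 1) {
  x <- as.matrix(x)
  group_labels <- as.character(group_labels)
  classes <- sort(unique(group_labels))
  if (length(classes) != 2L)
    stop_input("exactly two groups required, got: ",
               paste(classes, collapse = ", "))
  if (is.null(negative_class)) negative_class <- classes[1L]
  if (is.null(positive_class)) positive_class <- setdiff(classes, negative_class)
  if (!all(c(negative_class, positive_class) %in% classes) ||
      negative_class == positive_class)
    stop_input("negative_class/positive_class must name the two groups")
  y <- factor(group_labels, levels = c(negative_class, positive_class))
  xs <- t(x)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  d <- drop(xs %*% w) + b
  if (mean(d[y == positive_class]) < mean(d[y == negative_class])) {
    w <- -w; b <- -b
  }
  names(w) <- rownames(x)
  structure(list(w = w, b = b, C = C, negative_class = negative_class,
                 positive_class = positive_class, genes = rownames(x)),
            class = "risk_svm")
}

#' @export
print.risk_svm <- function(x, ...) {
  cat(sprintf("Linear SVM risk model over %d genes (C = %g)\n",
              length(x$w), x$C))
  cat(sprintf("  negative (best prognosis): %s\n  positive (worst prognosis): %s\n",
              x$negative_class, x$positive_class))
  invisible(x)
}

#' @export
coef.risk_svm <- function(object, ...) c(object$w, `(bias)` = object$b)

#' Compute continuous risk scores
#'
#' Evaluates r = w.x + b for every sample; rows of `newdata` must match the
#' model's signature gene order (rows are realigned by name when possible).
#'
#' @param model a [train_risk()] fit.
#' @param newdata expression matrix, genes x samples.
#' @return named numeric vector of risk scores.
#' @export
risk_score <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  if (!identical(rownames(newdata), model$genes)) {
    if (!all(model$genes %in% rownames(newdata)))
      stop_input("newdata gene rows do not match the risk-model signature")
    newdata <- newdata[model$genes, , drop = FALSE]
  }
  drop(crossprod(newdata, model$w)) + model$b
}

#' @export
predict.risk_svm <- function(object, newdata, ...) risk_score(object, newdata)

#' Predicted five-year overall survival as a function of risk score
#'
#' Fits a Cox proportional-hazards model with the risk score as the single
#' linear covariate (raw SVM units, so the hazard ratio is per unit score),
#' derives the baseline survival by the Breslow estimator, and evaluates
#' predicted S(horizon | r) over a score grid with pointwise 95% confidence
#' intervals on the log-cumulative-hazard scale. Quartile cut points (25th
#' and 75th percentiles, type-7 quantiles) of the observed scores delimit
#' the low- and high-risk regions.
#'
#' @param scores observed risk scores.
#' @param time survival time in months.
#' @param event event indicator (1 = death); at least 10 events required.
#' @param horizon landmark in months (default 60 = five years).
#' @param grid score grid; default 100 points over the observed range.
#' @return an `os5_curve`: `grid`, `os`, `lower`, `upper`, `quartiles`,
#'   `hazard_ratio` (per unit score, with CI), `fit`.
#' @export
os5_curve <- function(scores, time, event, horizon = 60, grid = NULL) {
  if (sum(event) == 0L) stop_input("no events observed; cannot fit")
  if (sum(event) < 10L) stop_input("fewer than 10 events; curve unreliable")
  df <- data.frame(time = time, event = event, score = scores)
  fit <- survival::coxph(survival::Surv(time, event) ~ score, data = df,
                         ties = "efron")
  if (is.null(grid)) grid <- seq(min(scores), max(scores), length.out = 100L)
  sf <- survival::survfit(fit, newdata = data.frame(score = grid),
                          conf.type = "log")
  sm <- summary(sf, times = horizon, extend = TRUE)
  os <- as.vector(sm$surv); lo <- as.vector(sm$lower); up <- as.vector(sm$upper)
  s <- summary(fit)
  hr <- c(estimate = unname(s$conf.int[1L, "exp(coef)"]),
          lower = unname(s$conf.int[1L, "lower .95"]),
          upper = unname(s$conf.int[1L, "upper .95"]))
  structure(list(grid = grid, os = os, lower = lo, upper = up,
                 quartiles = stats::quantile(scores, c(0.25, 0.75), type = 7L),
                 horizon = horizon, hazard_ratio = hr, fit = fit),
            class = "os5_curve")
}

#' @export
print.os5_curve <- function(x, ...) {
  cat(sprintf("Predicted %g-month overall survival vs risk score\n", x$horizon))
  cat(sprintf("  HR per unit score: %.3f (95%% CI %.3f-%.3f)\n",
              x$hazard_ratio["estimate"], x$hazard_ratio["lower"],
              x$hazard_ratio["upper"]))
  cat(sprintf("  score quartile cut points: %.3f, %.3f\n",
              x$quartiles[1L], x$quartiles[2L]))
  invisible(x)
}

#' @export
plot.os5_curve <- function(x, ...) {
  graphics::plot(x$grid, x$os, type = "l", ylim = c(0, 1),
                 xlab = "risk score",
                 ylab = sprintf("predicted S(%g months)", x$horizon), ...)
  graphics::lines(x$grid, x$lower, lty = 2L)
  graphics::lines(x$grid, x$upper, lty = 2L)
  graphics::abline(v = x$quartiles, col = "grey60")
  invisible(x)
}
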