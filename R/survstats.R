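#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit curves per group and the standard (unweighted) log-rank
#' chi-square test with groups - 1 degrees of freedom.
#'
#' @param time survival time in months.
#' @param event event indicator (1 = death).
#' @param group group label per subject (>= 2 groups).
#' @return a `km_logrank`: `survfit`, `statistic`, `df`, `p.value`.
#' @export
km_logrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop_input("log-rank needs at least two groups")
  if (sum(event) == 0L) stop_input("no events observed")
  df <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- nlevels(group) - 1L
  structure(list(survfit = sf, statistic = sd$chisq, df = dfree,
                 p.value = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, ...) {
  graphics::plot(x$survfit, xlab = "months", ylab = "overall survival", ...)
  invisible(x)
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; categorical covariates
#' are expanded against their (first) reference level, whose hazard ratio is
#' 1 by construction. Reports the hazard ratio, Wald 95% CI and Wald p per
#' coefficient.
#'
#' @param time survival time in months.
#' @param event event indicator.
#' @param covariates data.frame of covariates (factors for categorical
#'   variables; relevel beforehand to choose references).
#' @return a `cox_result`: `table` (term, hr, lower, upper, p) and `fit`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1L))
  if (any(const))
    stop_input("constant covariate(s): ",
               paste(names(covariates)[const], collapse = ", "))
  if (sum(event) < ncol(covariates))
    stop_input("fewer events than covariates")
  dat <- data.frame(.time = time, .event = event, covariates,
                    check.names = FALSE)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron"),
    warning = function(w) stop_input("Cox fit did not converge cleanly: ",
                                     conditionMessage(w)))
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties)\n")
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f, %.2f)", tab$hr, tab$lower, tab$upper)
  print(tab[, c("term", "hr", "p")], row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Treatment-adjusted marginal survival curves
#'
#' G-computation-style adjusted Kaplan-Meier curves: a Cox model with
#' treatment plus covariates is fitted; for each treatment level every
#' subject's treatment is set to that level, individual survival curves are
#' predicted (Breslow baseline), and the curves are averaged over subjects.
#'
#' @param time survival time in months.
#' @param event event indicator.
#' @param treatment treatment level per subject.
#' @param covariates optional data.frame of additional covariates.
#' @return an `adjusted_km`: `times`, `curves` (matrix, one column per
#'   treatment level), `fit`, `skipped` empty levels.
#' @export
adjusted_km <- function(time, event, treatment, covariates = NULL) {
  treatment <- factor(treatment)
  counts <- table(treatment)
  skipped <- names(counts)[counts == 0L]
  if (length(skipped)) {
    warning("treatment level(s) with no subjects skipped: ",
            paste(skipped, collapse = ", "))
    treatment <- droplevels(treatment)
  }
  dat <- data.frame(.time = time, .event = event, treatment = treatment)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = "efron")
  sf0 <- survival::survfit(fit, newdata = dat[1L, , drop = FALSE])
  times <- sf0$time
  curves <- vapply(levels(treatment), function(lv) {
    nd <- dat
    nd$treatment <- factor(lv, levels = levels(treatment))
    sfi <- survival::survfit(fit, newdata = nd)
    rowMeans(sfi$surv)
  }, numeric(length(times)))
  structure(list(times = times, curves = curves, fit = fit,
                 skipped = skipped),
            class = "adjusted_km")
}

#' @export
print.adjusted_km <- function(x, ...) {
  cat(sprintf("Adjusted (averaged predicted) survival curves, %d treatment levels\n",
              ncol(x$curves)))
  invisible(x)
}

#' Bootstrap inference for lasso-penalized Cox regression
#'
#' Refits a lasso-penalized Cox model on bootstrap resamples (sampling
#' subjects with replacement; the penalty is chosen by inner cross-validation
#' within each resample) and summarizes each coefficient's empirical
#' distribution: hazard ratio at the mean coefficient, percentile 95% CI,
#' and an add-one-smoothed two-sided sign-based empirical p value for
#' H0: beta_j = 0.
#'
#' @param time survival time in months.
#' @param event event indicator.
#' @param covariates numeric matrix (or data.frame coercible to numeric) of
#'   predictors.
#' @param B number of bootstrap resamples (reference analysis: 10000;
#'   scale down for exploratory runs).
#' @param seed integer seed; each resample derives a child seed.
#' @param nlambda penalty-path length (default 50, log-spaced by glmnet).
#' @param nfolds inner cross-validation folds (default 5).
#' @return a `lasso_boot`: `table` (term, hr, lower, upper, p), `betas`
#'   (B x p bootstrap coefficients), `B`.
#' @export
lasso_cox_bootstrap <- function(time, event, covariates, B = 10000L,
                                seed = 1L, nlambda = 50L, nfolds = 5L) {
  if (B < 1L) stop_input("B must be >= 1")
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  n <- nrow(x)
  y <- survival::Surv(time, event)
  betas <- matrix(NA_real_, B, ncol(x),
                  dimnames = list(NULL, colnames(x)))
  for (b in seq_len(B)) {
    betas[b, ] <- with_seed(child_seed(seed, paste0("boot", b)), {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(event[idx]) >= 2L && length(unique(time[idx][event[idx] == 1])) >= 2L)
          break
      }
      cv <- cv.glmnet.quiet(x[idx, , drop = FALSE], y[idx, ],
                            nlambda = nlambda, nfolds = nfolds)
      as.vector(stats::coef(cv, s = "lambda.min"))
    })
  }
  mean_beta <- colMeans(betas)
  lo <- apply(betas, 2L, stats::quantile, 0.025, type = 7L)
  hi <- apply(betas, 2L, stats::quantile, 0.975, type = 7L)
  p <- apply(betas, 2L, function(bb)
    min(1, 2 * min((1 + sum(bb <= 0)) / (B + 1), (1 + sum(bb >= 0)) / (B + 1))))
  tab <- data.frame(term = colnames(x), hr = exp(mean_beta),
                    lower = exp(lo), upper = exp(hi), p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, betas = betas, B = as.integer(B)),
            class = "lasso_boot")
}

cv.glmnet.quiet <- function(x, y, nlambda, nfolds) {
  suppressWarnings(glmnet::cv.glmnet(x, y, family = "cox", nlambda = nlambda,
                                     nfolds = nfolds))
}

#' @export
print.lasso_boot <- function(x, ...) {
  cat(sprintf("Bootstrap lasso-Cox (%d resamples)\n", x$B))
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f, %.2f)", tab$hr, tab$lower, tab$upper)
  print(tab[, c("term", "hr", "p")], row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' No continuity correction at any table size; df = (r-1)(c-1). Rows or
#' columns for missing categories must be excluded before the table is
#' built (see [contingency()]).
#'
#' @param tab r x c matrix of non-negative integer counts, r, c >= 2.
#' @return list: `statistic`, `df`, `p.value`, `expected`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_input("contingency table must be at least 2 x 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop_input("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_input("zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = ct$expected)
}

#' Cross-tabulate two categorical variables, excluding missing values
#'
#' Rows with a missing value in either variable are removed before the
#' table is built, matching the convention of reporting tests over observed
#' categories only.
#'
#' @param x,y categorical vectors of equal length.
#' @param missing values (besides NA) treated as missing, default
#'   `c("Missing", "")`.
#' @return an r x c count matrix.
#' @export
contingency <- function(x, y, missing = c("Missing", "")) {
  keep <- !(is.na(x) | is.na(y) | x %in% missing | y %in% missing)
  as.matrix(table(droplevels(factor(x[keep])), droplevels(factor(y[keep]))))
}

#' One-way analysis of variance
#'
#' Standard one-way F test (equal-variance). Degenerate inputs with zero
#' variance everywhere and equal means return p = 1 by convention.
#'
#' @param values numeric response.
#' @param group group label (>= 2 groups, >= 2 observations each).
#' @return list: `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop_input("need at least two groups")
  if (any(table(group) < 2L)) stop_input("each group needs >= 2 observations")
  if (stats::var(values) < .Machine$double.eps)
    return(list(statistic = 0, df1 = nlevels(group) - 1L,
                df2 = length(values) - nlevels(group), p.value = 1))
  ft <- stats::oneway.test(values ~ group, var.equal = TRUE)
  list(statistic = unname(ft$statistic), df1 = unname(ft$parameter[1L]),
       df2 = unname(ft$parameter[2L]), p.value = ft$p.value)
}

#' Map RECIST categories to binary response
#'
#' Responder = complete or partial response (CR/PR); non-responder = stable
#' or progressive disease (SD/PD); anything else is NA.
#'
#' @param response character vector of RECIST categories.
#' @return factor with levels "responder", "non-responder".
#' @export
recist_response <- function(response) {
  out <- ifelse(response %in% c("CR", "PR"), "responder",
                ifelse(response %in% c("SD", "PD"), "non-responder", NA))
  factor(out, levels = c("responder", "non-responder"))
}
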