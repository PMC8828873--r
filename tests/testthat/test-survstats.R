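test_that("log-rank of a group against its own copy is exactly null", {
  time <- c(5, 10, 15, 20, 30, 40)
  event <- c(1L, 1L, 0L, 1L, 1L, 0L)
  res <- km_logrank(c(time, time), c(event, event), rep(c("a", "b"), each = 6L))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  expect_error(km_logrank(time, event, rep("a", 6L)), "two groups")
})

test_that("two-group log-rank p equals the df-1 chi-square tail", {
  with_seed(44L, {
    s <- sim_two_group_surv(60L, 1.8)
    res <- km_logrank(s$time, s$event, s$group)
    expect_equal(res$p.value, pchisq(res$statistic, 1L, lower.tail = FALSE))
  })
})

test_that("Cox fit recovers a known rate ratio and reference convention", {
  with_seed(12L, {
    s <- sim_two_group_surv(500L, 2)
    res <- cox_fit(s$time, s$event, data.frame(group = factor(s$group)))
    expect_gt(res$table$hr, 1.8)
    expect_lt(res$table$hr, 2.2)
    expect_true(res$table$lower <= res$table$hr &
                  res$table$hr <= res$table$upper)
  })
  expect_error(cox_fit(c(1, 2, 3), c(1L, 1L, 0L),
                       data.frame(x = c(1, 1, 1))), "constant")
})

test_that("null Cox confidence intervals achieve nominal coverage", {
  cover <- vapply(1:200, function(s) {
    with_seed(s, {
      n <- 120L
      x <- rnorm(n)
      time <- rexp(n, 0.02)
      cens <- runif(n, 0, 100)
      res <- cox_fit(pmin(time, cens), as.integer(time <= cens),
                     data.frame(x = x))
      res$table$lower <= 1 && 1 <= res$table$upper
    })
  }, logical(1L))
  expect_gte(mean(cover), 0.90)
})

test_that("adjusted curves match per-arm predictions without confounders", {
  with_seed(3L, {
    n <- 200L
    trt <- rep(c("none", "FU"), each = n / 2L)
    time <- rexp(n, ifelse(trt == "FU", 0.01, 0.02))
    cens <- runif(n, 0, 150)
    obs <- pmin(time, cens); event <- as.integer(time <= cens)
    adj <- adjusted_km(obs, event, trt)
    fit <- survival::coxph(survival::Surv(obs, event) ~ trt, ties = "efron")
    for (lv in c("FU", "none")) {
      direct <- survival::survfit(fit, newdata = data.frame(trt = lv))
      expect_lt(max(abs(adj$curves[, lv] - direct$surv)), 1e-6)
    }
    # marginal curves stay inside the convex hull of individual predictions
    nd <- data.frame(trt = factor("FU", levels = c("FU", "none")))
    expect_true(all(adj$curves >= 0 & adj$curves <= 1))
  })
})

test_that("a balanced confounder leaves the adjusted curves near raw KM", {
  with_seed(9L, {
    n <- 2000L
    trt <- rep(c("none", "FU"), each = n / 2L)
    z <- rep(c(0, 1), times = n / 2L)  # balanced across arms
    time <- rexp(n, 0.01 * exp(0.8 * z + ifelse(trt == "FU", -0.4, 0)))
    cens <- runif(n, 0, 250)
    obs <- pmin(time, cens); event <- as.integer(time <= cens)
    adj <- adjusted_km(obs, event, trt, data.frame(z = z))
    km <- survival::survfit(survival::Surv(obs, event) ~ trt)
    km_sum <- summary(km, times = adj$times, extend = TRUE)
    for (lv in c("FU", "none")) {
      raw <- km_sum$surv[km_sum$strata == paste0("trt=", lv)]
      expect_lt(max(abs(adj$curves[, lv] - raw)), 0.03)
    }
  })
})

test_that("a planted protective treatment effect is recovered in small strata", {
  cover <- vapply(1:50, function(s) {
    with_seed(s, {
      trt <- rep(c(0L, 1L), times = c(28L, 18L))  # Group-3-like stratum
      time <- rexp(46L, 0.015 * exp(log(0.28) * trt))
      cens <- runif(46L, 0, 250)
      res <- cox_fit(pmin(time, cens), as.integer(time <= cens),
                     data.frame(treated = trt))
      res$table$lower <= 0.28 && 0.28 <= res$table$upper
    })
  }, logical(1L))
  expect_gte(mean(cover), 0.90)
})

test_that("bootstrap lasso-Cox degenerates at B = 1 and is calibrated on noise", {
  with_seed(15L, {
    n <- 120L
    x <- matrix(rnorm(n * 3L), n, 3L, dimnames = list(NULL, paste0("v", 1:3)))
    time <- rexp(n, 0.02 * exp(0.8 * x[, 1L]))
    cens <- runif(n, 0, 150)
    obs <- pmin(time, cens); event <- as.integer(time <= cens)
    one <- lasso_cox_bootstrap(obs, event, x, B = 1L, seed = 7L)
    expect_equal(one$table$lower, one$table$upper, tolerance = 1e-12)
    expect_equal(one$table$hr, exp(one$betas[1L, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_error(lasso_cox_bootstrap(obs, event, x, B = 0L), "B must be")
  })
  with_seed(16L, {
    n <- 300L
    x <- matrix(rnorm(n * 5L), n, 5L, dimnames = list(NULL, paste0("v", 1:5)))
    time <- rexp(n, 0.02)
    cens <- runif(n, 0, 150)
    res <- lasso_cox_bootstrap(pmin(time, cens), as.integer(time <= cens),
                               x, B = 200L, seed = 9L)
    expect_gte(mean(res$table$p > 0.05), 0.9)
  })
})

test_that("chi-square matches the printed-table conventions", {
  tab <- rbind(c(43, 53, 90, 89), c(71, 76, 72, 73))
  res <- chisq_independence(tab)
  expect_identical(res$df, 3L)
  # permutation invariance
  res_p <- chisq_independence(tab[2:1, c(3, 1, 4, 2)])
  expect_equal(res_p$statistic, res$statistic, tolerance = 1e-12)
  # multiplying counts by m scales the statistic by m
  res_m <- chisq_independence(tab * 3L)
  expect_equal(res_m$statistic, 3 * res$statistic, tolerance = 1e-9)
  expect_identical(res_m$df, res$df)
  # proportional rows are exactly independent
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  res0 <- chisq_independence(prop)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p.value, 1, tolerance = 1e-12)
  expect_error(chisq_independence(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chisq_independence(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("contingency builder drops missing categories before testing", {
  x <- c("a", "a", "b", "Missing", NA, "b")
  y <- c("g1", "g2", "g1", "g1", "g2", "Missing")
  tab <- contingency(x, y)
  expect_identical(sum(tab), 3L)
  expect_identical(dim(tab), c(2L, 2L))
})

test_that("one-way ANOVA obeys the F = t-squared identity and power", {
  with_seed(25L, {
    vals <- rnorm(40L)
    grp <- rep(c("a", "b"), each = 20L)
    a <- anova_oneway(vals, grp)
    tt <- t.test(vals ~ grp, var.equal = TRUE)
    expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a$p.value, tt$p.value, tolerance = 1e-9)
  })
  # identical repeated data -> no group effect
  same <- rep(c(1, 2, 3), 2L)
  res <- anova_oneway(same, rep(c("a", "b"), each = 3L))
  expect_gt(res$p.value, 0.99)
  # degenerate equal constant groups return p = 1 by convention
  expect_equal(anova_oneway(rep(1, 6L), rep(c("a", "b"), 3L))$p.value, 1)
  # strong separation is detected essentially always
  hits <- vapply(1:100, function(s) {
    with_seed(s, anova_oneway(c(rnorm(50L), rnorm(50L, 2)),
                              rep(c("a", "b"), each = 50L))$p.value < 1e-6)
  }, logical(1L))
  expect_gte(mean(hits), 0.99)
})

test_that("RECIST categories collapse to the responder dichotomy", {
  r <- recist_response(c("CR", "PR", "SD", "PD", "NE", NA))
  expect_identical(as.character(r),
                   c("responder", "responder", "non-responder",
                     "non-responder", NA, NA))
})
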