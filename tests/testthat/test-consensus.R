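block_matrix <- function(k = 4L, per = 12L, sep = 10, noise = 0, seed = 1L) {
  g <- 4L * k
  centroid <- matrix(1, g, k)
  for (s in seq_len(k)) centroid[((s - 1L) * 4L + 1L):(s * 4L), s] <- 1 + sep
  X <- centroid[, rep(seq_len(k), each = per)]
  if (noise > 0) X <- pmax(X + with_seed(seed,
    matrix(rnorm(length(X), 0, noise), nrow(X))), 0)
  dimnames(X) <- list(sprintf("g%02d", seq_len(g)),
                      sprintf("s%02d", seq_len(ncol(X))))
  X
}

test_that("rank-1 NMF reconstructs an exactly rank-1 matrix", {
  w <- c(1, 2, 3, 0.5); h <- c(4, 1, 2, 5, 3)
  X <- outer(w, h)
  fit <- nmf_fit(X, 1L, seed = 2L, max_iter = 2000L, tol = 1e-14)
  expect_lt(sqrt(fit$objective) / sqrt(sum(X^2)), 1e-6)
})

test_that("NMF objective descends and fits are deterministic", {
  X <- with_seed(7L, matrix(rexp(32L * 100L), 32L, 100L))
  fit <- nmf_fit(X, 4L, seed = 7L, max_iter = 100L, tol = 0)
  expect_true(all(diff(fit$objective_trace) <= 1e-9 * max(fit$objective_trace)))
  fit2 <- nmf_fit(X, 4L, seed = 7L, max_iter = 100L, tol = 0)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$H, fit2$H)
  expect_error(nmf_fit(X - 10, 2L), "negative")
})

test_that("perfect block structure yields a 0/1 consensus with cophenetic 1", {
  X <- block_matrix(k = 4L, per = 10L)
  cr <- consensus_cluster(X, k_range = 4L, n_runs = 10L, seed = 3L)
  M <- cr$per_k$k4$consensus
  expect_true(all(M %in% c(0, 1)))
  expect_equal(cr$per_k$k4$cophenetic, 1.0)
  # labels recover the four blocks exactly (up to renaming)
  truth <- rep(1:4, each = 10L)
  tab <- table(cr$per_k$k4$labels, truth)
  expect_true(all(apply(tab, 1L, function(r) sum(r > 0)) == 1L))
})

test_that("consensus matrices are permutation-equivariant for stable inputs", {
  X <- block_matrix(k = 3L, per = 8L)
  perm <- with_seed(9L, sample(ncol(X)))
  cr1 <- consensus_cluster(X, k_range = 3L, n_runs = 8L, seed = 5L)
  cr2 <- consensus_cluster(X[, perm], k_range = 3L, n_runs = 8L, seed = 5L)
  expect_equal(unname(cr2$per_k$k3$consensus),
               unname(cr1$per_k$k3$consensus[perm, perm]))
})

test_that("delta areas follow the trapezoid CDF definition", {
  X <- block_matrix(k = 2L, per = 10L, noise = 0.5)
  cr <- consensus_cluster(X, k_range = 2:4, n_runs = 10L, seed = 11L)
  d <- cr$diagnostics
  expect_equal(d$delta_area[1L], d$area[1L])
  expect_equal(d$delta_area[-1L], diff(d$area))
  up <- cr$per_k$k2$consensus[upper.tri(cr$per_k$k2$consensus)]
  grid <- seq(0, 1, length.out = 101L)
  cdf <- vapply(grid, function(u) mean(up <= u), numeric(1L))
  area <- sum(diff(grid) * (head(cdf, -1L) + tail(cdf, -1L)) / 2)
  expect_equal(d$area[1L], area)
})

test_that("k selection follows the tolerance-tied max-cophenetic rule", {
  fake <- structure(list(diagnostics = data.frame(
    k = 2:4, cophenetic = c(0.8, 0.95, 0.95), area = 1:3, delta_area = 1:3)),
    class = "consensus_result")
  expect_identical(select_k(fake), 3L)
  fake$diagnostics$cophenetic <- c(0.99, 0.7, 0.6)
  expect_identical(select_k(fake), 2L)
  # singleton k range returns that k
  X <- block_matrix(k = 3L, per = 6L)
  cr <- consensus_cluster(X, k_range = 3L, n_runs = 4L, seed = 2L)
  expect_identical(select_k(cr), 3L)
  expect_error(consensus_cluster(X, k_range = 1:3, n_runs = 4L), "k_range")
})

test_that("clustering recovery degrades gracefully with separation", {
  aris <- vapply(c(0.5, 1.5, 3), function(eff) {
    d <- tiny_design(expression_effect = eff, seed = 21L)
    co <- simulate_expression_cohort(d)
    cr <- consensus_cluster(co$expression, k_range = 4L, n_runs = 15L,
                            seed = 13L)
    mclust::adjustedRandIndex(cr$per_k$k4$labels, co$true_subtype)
  }, numeric(1L))
  expect_true(all(diff(aris) >= -0.05))  # non-strict monotone trend
  expect_gt(aris[3L], aris[1L])
})

test_that("groups are renumbered best to worst by five-year survival", {
  with_seed(17L, {
    time <- c(rexp(80L, 0.004), rexp(80L, 0.02))
    event <- rep(1L, 160L)
    labels <- rep(c("B", "A"), each = 80L)  # B has the longer survival
    og <- order_groups(labels, time, event)
    expect_identical(og$mapping, c(A = 2L, B = 1L))
    expect_true(all(og$group[labels == "B"] == "Group 1"))
  })
  # an all-censored group warns and is ordered by mean follow-up
  time <- c(10, 20, 30, 5, 6, 7); event <- c(0L, 0L, 0L, 1L, 1L, 0L)
  labels <- rep(c("x", "y"), each = 3L)
  expect_warning(og <- order_groups(labels, time, event), "no events")
  expect_identical(unname(og$mapping["x"]), 1L)
})

test_that("prognosis relabeling recovers the planted order across seeds", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_expression_cohort(simulation_design(seed = s))
    og <- order_groups(co$true_subtype, co$clinical$time_months,
                       co$clinical$event)
    all(og$mapping[as.character(1:4)] == 1:4)
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})
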