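test_that("quantile normalization matches the hand-computed oracle", {
  x <- matrix(c(2, 4, 8, 8, 16, 32), 3L, 2L,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  out <- log2_quantile_normalize(x)
  expect_equal(unname(out), matrix(c(2, 3, 4, 2, 3, 4), 3L, 2L))
  # identical columns are only log-transformed
  xi <- matrix(c(2, 4, 8, 2, 4, 8), 3L, 2L,
               dimnames = dimnames(x))
  expect_equal(log2_quantile_normalize(xi), log2(xi))
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  x <- with_seed(10L, matrix(rexp(200L, 0.1) + 1, 40L, 5L,
                             dimnames = list(paste0("p", 1:40), paste0("s", 1:5))))
  out <- log2_quantile_normalize(x)
  for (j in 2:5) expect_equal(sort(out[, j]), sort(out[, 1L]),
                              ignore_attr = TRUE)
  expect_equal(log2_quantile_normalize(out, already_log = TRUE), out)
  expect_error(log2_quantile_normalize(x - 5), "non-positive")
})

test_that("probe collapsing averages probes and excludes incomplete genes", {
  x <- matrix(c(1, 3, 5, 2, 4, 6), 3L, 2L,
              dimnames = list(c("pr1", "pr2", "pr3"), c("s1", "s2")))
  map <- data.frame(probe_id = c("pr1", "pr2", "pr3"),
                    gene_id = c("gA", "gA", "gB"))
  out <- collapse_probes(x, map)
  expect_equal(out["gA", ], c(s1 = 2, s2 = 3))
  expect_equal(out["gB", ], c(s1 = 5, s2 = 6))
  # one probe per gene is a pure relabeling
  map1 <- data.frame(probe_id = rownames(x), gene_id = c("g1", "g2", "g3"))
  expect_equal(unname(collapse_probes(x, map1)), unname(x),
               ignore_attr = TRUE)
  # a missing value anywhere drops the gene
  xna <- x; xna[1L, 2L] <- NA
  outna <- collapse_probes(xna, map)
  expect_false("gA" %in% rownames(outna))
  expect_identical(attr(outna, "dropped_genes"), "gA")
  expect_warning(collapse_probes(x, map[1:2, ]), "unmapped")
  expect_error(collapse_probes(x, data.frame()), "non-empty")
})

test_that("collapse commutes with sample subsetting", {
  x <- with_seed(2L, matrix(rnorm(60L), 10L, 6L,
                            dimnames = list(paste0("pr", 1:10), paste0("s", 1:6))))
  map <- data.frame(probe_id = paste0("pr", 1:10),
                    gene_id = rep(paste0("g", 1:5), each = 2L))
  a <- collapse_probes(x, map)[, 1:3]
  b <- collapse_probes(x[, 1:3], map)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("batch adjustment removes planted location and scale shifts", {
  g <- 100L; n <- 200L
  base <- with_seed(31L, matrix(rnorm(g * n, 8, 1), g, n,
                                dimnames = list(paste0("g", 1:g), NULL)))
  b1 <- base[, 1:100]; b2 <- base[, 101:200] * 2 + 2
  colnames(b1) <- paste0("a", 1:100); colnames(b2) <- paste0("b", 1:100)
  adj <- batch_adjust(list(A = b1, B = b2))
  gap <- rowMeans(adj[, 1:100]) - rowMeans(adj[, 101:200])
  expect_lt(abs(mean(gap)), 0.05)
  ratio <- apply(adj[, 101:200], 1L, var) / apply(adj[, 1:100], 1L, var)
  expect_gt(mean(ratio), 0.8)
  expect_lt(mean(ratio), 1.25)
  # the weighted per-gene grand mean is preserved
  before <- rowMeans(cbind(b1, b2))
  expect_lt(max(abs(rowMeans(adj) - before)), 1e-6)
  expect_error(batch_adjust(cbind(b1, b2[, 1L]),
                            c(rep("A", 100L), "B")), ">= 2 samples")
})

test_that("single-batch adjustment is a no-op and ComBat agrees on shifts", {
  x <- with_seed(5L, matrix(rnorm(500L, 8, 1), 50L, 10L,
                            dimnames = list(paste0("g", 1:50), paste0("s", 1:10))))
  expect_identical(batch_adjust(x, rep("A", 10L)), x)
  skip_if_not_installed("sva")
  b <- rep(c("A", "B"), each = 5L)
  x2 <- x; x2[, b == "B"] <- x2[, b == "B"] + 2
  mine <- batch_adjust(x2, b)
  theirs <- suppressMessages(sva::ComBat(x2, batch = b))
  expect_gt(cor(as.vector(mine), as.vector(theirs)), 0.98)
})

test_that("signature intersection preserves order and enforces coverage", {
  x <- with_seed(1L, matrix(rnorm(20L), 4L, 5L,
                            dimnames = list(c("g4", "g1", "g3", "g2"),
                                            paste0("s", 1:5))))
  sig <- c("g1", "g2", "g3", "g4")
  out <- intersect_signature(x, sig)
  expect_identical(rownames(out), sig)
  out2 <- intersect_signature(x, c("g1", "g2", "gX", "gY"), min_coverage = 0.5)
  expect_identical(rownames(out2), c("g1", "g2"))
  expect_identical(attr(out2, "missing_genes"), c("gX", "gY"))
  expect_error(intersect_signature(x, c(sig, paste0("x", 1:4))), "coverage")
})
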