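test_that("input validation catches malformed factorization problems", {
  inst <- random_trifactor_instance(1L)
  Xbad <- inst$X; Xbad[1L, 1L] <- 2
  expect_error(fit_trifactor(Xbad, inst$types, inst$db$membership,
                             inst$network$laplacian), "binary")
  V0bad <- inst$db$membership; V0bad[, 2L] <- 0
  expect_error(fit_trifactor(inst$X, inst$types, V0bad,
                             inst$network$laplacian), "all-zero")
  fit <- fit_trifactor(inst$X, inst$types, inst$db$membership,
                       inst$network$laplacian, max_iter = 20L)
  expect_error(rank_pathways(fit, "no-such-type"), "unknown cancer type")
})

test_that("objective descends monotonically on random instances", {
  for (s in 1:20) {
    inst <- random_trifactor_instance(s)
    fit <- fit_trifactor(inst$X, inst$types, inst$db$membership,
                         inst$network$laplacian, max_iter = 80L, tol = 0,
                         seed = s)
    expect_true(all(diff(fit$objective_trace) <= 1e-9),
                info = paste("instance", s))
  }
})

test_that("a dominant prior pins V to the database membership", {
  inst <- random_trifactor_instance(3L)
  fit <- fit_trifactor(inst$X, inst$types, inst$db$membership,
                       inst$network$laplacian,
                       lambdas = c(s = 1e-6, l = 1e-6, v0 = 1e6),
                       max_iter = 300L, tol = 1e-10)
  V0 <- inst$db$membership
  expect_lt(sqrt(sum((fit$V - V0)^2)) / sqrt(sum(V0^2)), 1e-3)
})

test_that("a noiseless planted factorization is recovered exactly", {
  # 4 types x 3 disjoint pathways; X = U S* V0' is exactly representable
  genes <- sprintf("g%02d", 1:12)
  sets <- list(p1 = genes[1:4], p2 = genes[5:8], p3 = genes[9:12])
  db <- pathway_db(sets, universe = genes)
  S_star <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))
  types <- rep(paste0("t", 1:4), each = 10L)
  U <- outer(types, paste0("t", 1:4), "==") * 1
  X <- (U %*% S_star %*% t(db$membership) > 0.5) * 1
  dimnames(X) <- list(sprintf("p%02d", 1:40), genes)
  L <- diag(0, 12); dimnames(L) <- list(genes, genes)
  fit <- fit_trifactor(X, types, db$membership, gene_network(L)$laplacian,
                       lambdas = c(s = 0, l = 0, v0 = 0),
                       max_iter = 10000L, tol = 0)
  recon <- fit$U %*% fit$S %*% t(fit$V)
  expect_lt(sqrt(sum((X - recon)^2)) / sqrt(sum(X^2)), 1e-4)
  # unique-argmax rows recover their planted pathway; the tied row loads
  # its two planted pathways far above the unplanted one
  expect_identical(unname(apply(fit$S[1:3, ], 1L, which.max)), 1:3)
  expect_gt(min(fit$S[4L, 1:2]), 10 * fit$S[4L, 3L])
})

test_that("pathway ranking is a stable descending sort with index tie-breaks", {
  inst <- random_trifactor_instance(9L)
  fit <- fit_trifactor(inst$X, inst$types, inst$db$membership,
                       inst$network$laplacian, max_iter = 50L)
  r <- rank_pathways(fit, fit$types[1L])
  expect_identical(r$rank, seq_len(ncol(fit$S)))
  expect_true(all(diff(r$score) <= 0))
  # forced tie: identical duplicate columns rank in index order
  fit2 <- fit
  fit2$S[1L, ] <- c(5, 5, 3, 2, 1)
  r2 <- rank_pathways(fit2, fit$types[1L])
  expect_identical(r2$pathway[1:2], fit$pathways[1:2])
})

test_that("permutation p-values respect the add-one smoothing boundary", {
  # a constant matrix is invariant to within-patient shuffles, so every
  # permuted score ties the observed one and p must be exactly 1
  genes <- sprintf("g%02d", 1:10)
  X <- matrix(1L, 12L, 10L, dimnames = list(sprintf("p%02d", 1:12), genes))
  db <- pathway_db(list(a = genes[1:5], b = genes[6:10]), universe = genes)
  L <- diag(0, 10); dimnames(L) <- list(genes, genes)
  res <- permutation_fdr(X, rep(c("t1", "t2"), each = 6L), db$membership,
                         gene_network(L)$laplacian, n_perm = 19L, seed = 4L)
  expect_true(all(res$p == 1))
  expect_error(permutation_fdr(X, rep(c("t1", "t2"), each = 6L),
                               db$membership, L, n_perm = 0L), "n_perm")
})

test_that("BH q-values match a manual step-up within each cancer type", {
  inst <- random_trifactor_instance(5L, n = 24L, g = 30L, n_types = 2L)
  res <- permutation_fdr(inst$X, inst$types, inst$db$membership,
                         inst$network$laplacian, n_perm = 30L, seed = 2L)
  for (tt in unique(res$cancer_type)) {
    p <- res$p[res$cancer_type == tt]
    m <- length(p)
    ord <- order(p)
    stepup <- rev(cummin(rev(pmin(1, p[ord] * m / seq_len(m)))))
    expect_equal(res$q[res$cancer_type == tt][ord], stepup, tolerance = 1e-12)
  }
})

test_that("signature selection filters by rank and FDR and orders the union", {
  sets <- list(pw1 = c("a", "b", "c"), pw2 = c("b", "c", "d"),
               pw3 = c("x", "y"))
  ranking <- data.frame(cancer_type = "t", pathway = c("pw2", "pw1", "pw3"),
                        score = c(3, 2, 1), rank = 1:3,
                        q = c(0.01, 0.02, 0.5))
  sig <- select_signature(ranking, sets, top_n = 3L, fdr_cutoff = 0.05)
  expect_identical(sig, c("b", "c", "d", "a"))
  # top_n = 1 keeps only the leading set, in gene order
  expect_identical(select_signature(ranking, sets, top_n = 1L), c("b", "c", "d"))
  ranking$q <- 0.9
  expect_warning(sig0 <- select_signature(ranking, sets), "empty")
  expect_length(sig0, 0L)
})

test_that("over-representation p equals the hypergeometric tail", {
  universe <- sprintf("u%02d", 1:20)
  set5 <- universe[1:5]
  glist <- c(universe[1:4], universe[6:7])  # overlap 4, list size 6
  res <- overrepresentation_test(glist, list(s = set5), universe)
  # exhaustive enumeration over all 2x2 tables with these margins
  p_exact <- sum(vapply(4:5, function(a)
    choose(5, a) * choose(15, 6 - a), numeric(1L))) / choose(20, 6)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
  # list == universe is enrichment-free by construction
  res_all <- overrepresentation_test(universe,
                                     list(s1 = set5, s2 = universe[6:10]),
                                     universe)
  expect_true(all(res_all$p == 1))
  expect_error(overrepresentation_test(c("zz"), list(s = set5), universe),
               "outside the universe")
})
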