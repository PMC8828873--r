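#' Frobenius non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix X (genes x samples) as W H with
#' W (genes x k) and H (k x samples) non-negative, minimizing the Frobenius
#' reconstruction loss with the classical multiplicative updates from a
#' seeded random initialization. Per-sample cluster labels are the argmax
#' metagene (row of H).
#'
#' @param X non-negative numeric matrix, genes x samples.
#' @param k factorization rank (number of metagenes).
#' @param seed integer seed for the initialization.
#' @param max_iter maximum update sweeps.
#' @param tol relative objective-change convergence threshold.
#' @return an `nmf_fit`: `W`, `H`, `k`, `labels`, `objective`,
#'   `objective_trace`, `converged`, `seed`.
#' @export
nmf_fit <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  if (any(X < 0))
    stop_input("X has negative entries; NMF requires non-negative input ",
               "(shift the data explicitly before factorizing)")
  if (k < 1L) stop_input("k must be >= 1")
  n <- nrow(X); m <- ncol(X)
  scale0 <- sqrt(mean(X) / max(k, 1L))
  init <- with_seed(seed, list(W = matrix(runif(n * k, 0, 1), n, k) * scale0 + 1e-4,
                               H = matrix(runif(k * m, 0, 1), k, m) * scale0 + 1e-4))
  W <- init$W; H <- init$H
  eps <- 1e-12
  obj <- function(W, H) sum((X - W %*% H)^2)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj(W, H)
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    trace[it + 1L] <- obj(W, H)
    if (abs(trace[it] - trace[it + 1L]) <=
        tol * max(trace[it], .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  labels <- apply(H, 2L, which.max)
  structure(list(W = W, H = H, k = as.integer(k), labels = labels,
                 objective = trace[it + 1L],
                 objective_trace = trace[seq_len(it + 1L)],
                 converged = converged, seed = seed),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: rank %d, objective %.6g (%sconverged)\n",
              x$k, x$objective, if (x$converged) "" else "not "))
  invisible(x)
}

#' Consensus clustering over repeated NMF runs
#'
#' For each candidate rank k, runs `n_runs` NMF fits from distinct seeded
#' initializations, records per-run sample labels, and averages the
#' co-clustering connectivity into a consensus matrix M_k. Final labels come
#' from average-linkage hierarchical clustering of 1 - M_k cut at k. The
#' stability diagnostics are the cophenetic correlation (between 1 - M_k and
#' the dendrogram cophenetic distances), the empirical CDF of the consensus
#' entries (trapezoid area over 100 bins), and the delta areas between
#' consecutive k.
#'
#' @param X non-negative genes x samples matrix (signature-gene expression).
#' @param k_range candidate cluster counts, default 2:7.
#' @param n_runs NMF restarts per k, default 50.
#' @param seed integer seed; run b at rank k uses a derived child seed.
#' @param max_iter,tol per-run NMF controls.
#' @return a `consensus_result`: per-k consensus matrices, labels,
#'   cophenetic coefficients, CDFs, areas and delta areas.
#' @export
consensus_cluster <- function(X, k_range = 2:7, n_runs = 50L, seed = 1L,
                              max_iter = 200L, tol = 1e-5) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n_runs < 2L) stop_input("n_runs must be >= 2")
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop_input("k_range must lie within [2, n_samples - 1]")
  k_range <- sort(unique(as.integer(k_range)))
  sample_ids <- colnames(X)
  per_k <- lapply(k_range, function(k) {
    M <- matrix(0, n, n)
    for (b in seq_len(n_runs)) {
      fit <- nmf_fit(X, k, seed = child_seed(seed, sprintf("nmf-k%d-run%d", k, b)),
                     max_iter = max_iter, tol = tol)
      conn <- outer(fit$labels, fit$labels, "==") * 1
      M <- M + conn
    }
    M <- M / n_runs
    dimnames(M) <- list(sample_ids, sample_ids)
    d <- stats::as.dist(1 - M)
    hc <- stats::hclust(d, method = "average")
    labels <- stats::cutree(hc, k = k)
    coph_d <- stats::cophenetic(hc)
    rho <- if (stats::sd(d) < 1e-12 || stats::sd(coph_d) < 1e-12) NA_real_
           else stats::cor(d, coph_d)
    up <- M[upper.tri(M)]
    grid <- seq(0, 1, length.out = 101L)
    cdf <- vapply(grid, function(u) mean(up <= u), numeric(1L))
    area <- sum(diff(grid) * (utils::head(cdf, -1L) + utils::tail(cdf, -1L)) / 2)
    list(k = k, consensus = M, labels = labels, dendrogram = hc,
         cophenetic = rho, cdf_grid = grid, cdf = cdf, area = area)
  })
  names(per_k) <- paste0("k", k_range)
  areas <- vapply(per_k, `[[`, numeric(1L), "area")
  delta <- c(areas[1L], diff(areas))
  diagnostics <- data.frame(
    k = k_range,
    cophenetic = vapply(per_k, `[[`, numeric(1L), "cophenetic"),
    area = areas,
    delta_area = delta,
    row.names = NULL)
  structure(list(per_k = per_k, k_range = k_range, diagnostics = diagnostics,
                 n_runs = as.integer(n_runs), seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus NMF clustering: k in {%s}, %d runs per k\n",
              paste(x$k_range, collapse = ", "), x$n_runs))
  print(x$diagnostics, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(oldpar))
  graphics::plot(x$diagnostics$k, x$diagnostics$cophenetic, type = "b",
                 xlab = "k", ylab = "cophenetic correlation", ...)
  first <- TRUE
  for (pk in x$per_k) {
    if (first) {
      graphics::plot(pk$cdf_grid, pk$cdf, type = "l",
                     xlab = "consensus index", ylab = "CDF")
      first <- FALSE
    } else graphics::lines(pk$cdf_grid, pk$cdf, lty = pk$k)
  }
  invisible(x)
}

#' Select the number of clusters from consensus diagnostics
#'
#' Codified rule: the k maximizing the cophenetic correlation, where
#' coefficients within `tol` of the maximum are treated as tied and the
#' smallest tied k wins. The tolerance absorbs the Monte-Carlo noise of the
#' restart-averaged consensus (differences of a few thousandths are not
#' reproducible run to run). All diagnostics remain available on the
#' [consensus_cluster()] object for manual override.
#'
#' @param cr a `consensus_result`.
#' @param tol cophenetic-coefficient tie tolerance (default 0.01).
#' @return the selected integer k.
#' @export
select_k <- function(cr, tol = 0.01) {
  d <- cr$diagnostics
  ok <- !is.na(d$cophenetic)
  if (!any(ok)) return(d$k[1L])
  d <- d[ok, , drop = FALSE]
  min(d$k[d$cophenetic >= max(d$cophenetic) - tol])
}

#' Renumber cluster labels by prognosis
#'
#' Orders clusters by descending Kaplan-Meier five-year survival so that
#' Group 1 has the best outcome and Group k the worst. Groups with no
#' observed events fall back to mean follow-up ordering, with a warning.
#'
#' @param labels cluster label per sample.
#' @param time survival time in months.
#' @param event event indicator (1 = death).
#' @param horizon landmark in months (default 60 = five years).
#' @return list: `group` (factor "Group 1"... per sample, prognosis-ordered),
#'   `mapping` (named vector old label -> new index), `surv_at_horizon`.
#' @export
order_groups <- function(labels, time, event, horizon = 60) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  s_h <- numeric(length(lv)); mean_fu <- numeric(length(lv))
  all_censored <- logical(length(lv))
  for (i in seq_along(lv)) {
    idx <- labels == lv[i]
    mean_fu[i] <- mean(time[idx])
    all_censored[i] <- sum(event[idx]) == 0L
    if (all_censored[i]) {
      s_h[i] <- 1
    } else {
      sf <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
      s_h[i] <- summary(sf, times = horizon, extend = TRUE)$surv
    }
  }
  if (any(all_censored))
    warning("group(s) with no events ordered by mean follow-up: ",
            paste(lv[all_censored], collapse = ", "))
  ord <- order(-s_h, -mean_fu)
  mapping <- stats::setNames(match(seq_along(lv), ord), lv)
  group <- factor(paste("Group", mapping[labels]),
                  levels = paste("Group", seq_along(lv)))
  list(group = group, mapping = mapping,
       surv_at_horizon = stats::setNames(s_h, lv))
}
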