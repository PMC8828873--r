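#' Network-regularized non-negative tri-factorization of mutation profiles
#'
#' Factorizes a binary patients-by-genes somatic mutation matrix X as
#' U S V' where U is the fixed patients-by-types indicator, S >= 0 holds
#' cancer-type-by-pathway association scores and V >= 0 holds gene-by-pathway
#' memberships tethered to the pathway-database prior V0. The objective is
#'
#'   F(S, V) = ||X - U S V'||_F^2 + lambda_s ||S||_F^2
#'             + lambda_l tr(V' L V) + lambda_0 ||V - V0||_F^2
#'
#' minimized over S, V >= 0 by alternating multiplicative updates: the graph
#' Laplacian term smooths memberships over the interaction network (the
#' adjacency contributes to the update numerator, the degree to the
#' denominator) and the prior tether keeps V near the database membership.
#'
#' @param X binary mutation matrix, patients x genes (dimnames required).
#' @param type_labels cancer type per patient (length nrow(X)).
#' @param V0 binary genes x pathways prior membership matrix, or a
#'   [pathway_db()].
#' @param L graph Laplacian over the same genes (D - A), or a
#'   [gene_network()].
#' @param lambdas numeric vector `c(s =, l =, v0 =)` of penalty weights.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-change convergence threshold.
#' @param seed seed for the random initialization of S.
#' @return an object of class `trifactor` with elements `U`, `S`, `V`,
#'   `lambdas`, `objective_trace`, `converged`, `iterations`, `types`,
#'   `pathways`, `seed`.
#' @export
fit_trifactor <- function(X, type_labels, V0, L,
                          lambdas = c(s = 1, l = 1, v0 = 10),
                          max_iter = 500L, tol = 1e-6, seed = 1L) {
  if (inherits(V0, "pathway_db")) V0 <- V0$membership
  if (inherits(L, "gene_network")) L <- L$laplacian
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1)))
    stop_input("X must be a binary (0/1) mutation matrix")
  if (length(type_labels) != nrow(X))
    stop_input("type_labels must have one entry per patient")
  if (!all(V0 %in% c(0, 1))) stop_input("V0 must be binary")
  if (any(colSums(V0) == 0))
    stop_input("V0 contains an all-zero pathway column")
  if (nrow(V0) != ncol(X) || nrow(L) != ncol(X))
    stop_input("V0 and L must be defined over the genes (columns) of X")
  lam <- as.numeric(lambdas)
  if (length(lam) != 3L || any(lam < 0))
    stop_input("lambdas must be three non-negative weights (s, l, v0)")
  names(lam) <- c("s", "l", "v0")

  types <- if (is.factor(type_labels)) levels(droplevels(type_labels)) else
    unique(type_labels)
  U <- outer(as.character(type_labels), types, "==") * 1
  colnames(U) <- types
  ntype <- length(types); P <- ncol(V0)

  A <- -L; diag(A) <- 0
  dg <- diag(L)
  UtU <- crossprod(U)                 # diagonal type counts
  UtX <- crossprod(U, X)              # types x genes
  XtU <- t(UtX)                       # genes x types
  x2 <- sum(X^2)
  eps <- 1e-12

  V <- V0 + 0.01
  S <- with_seed(seed, matrix(runif(ntype * P, 0, 0.1), ntype, P))
  dimnames(S) <- list(types, colnames(V0))
  dimnames(V) <- dimnames(V0)

  objective <- function(S, V) {
    VtV <- crossprod(V)
    fit <- x2 - 2 * sum(S * (UtX %*% V)) + sum((UtU %*% S %*% VtV) * S)
    fit + lam["s"] * sum(S^2) + lam["l"] * sum(V * (L %*% V)) +
      lam["v0"] * sum((V - V0)^2)
  }

  trace <- numeric(max_iter + 1L)
  trace[1L] <- objective(S, V)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    VtV <- crossprod(V)
    S <- S * (UtX %*% V) / (UtU %*% S %*% VtV + lam["s"] * S + eps)
    StUtUS <- t(S) %*% UtU %*% S
    num <- XtU %*% S + lam["l"] * (A %*% V) + lam["v0"] * V0
    den <- V %*% StUtUS + lam["l"] * (dg * V) + lam["v0"] * V + eps
    V <- V * num / den
    trace[it + 1L] <- objective(S, V)
    if (abs(trace[it] - trace[it + 1L]) <=
        tol * max(abs(trace[it]), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  structure(list(U = U, S = S, V = V, V0 = V0, lambdas = lam,
                 objective_trace = trace[seq_len(it + 1L)],
                 converged = converged, iterations = it,
                 types = types, pathways = colnames(V0), seed = seed),
            class = "trifactor")
}

#' @export
print.trifactor <- function(x, ...) {
  cat(sprintf("Tri-factorization: %d types x %d pathways over %d genes\n",
              nrow(x$S), ncol(x$S), nrow(x$V)))
  cat(sprintf("  %d iterations, %sconverged; objective %.6g -> %.6g\n",
              x$iterations, if (x$converged) "" else "NOT ",
              x$objective_trace[1L], utils::tail(x$objective_trace, 1L)))
  invisible(x)
}

#' @export
summary.trifactor <- function(object, ...) {
  top <- lapply(object$types, function(tt) {
    r <- rank_pathways(object, tt)
    utils::head(r$pathway, 3L)
  })
  names(top) <- object$types
  out <- list(model = object, top_pathways = top)
  class(out) <- "summary.trifactor"
  out
}

#' @export
print.summary.trifactor <- function(x, ...) {
  print(x$model)
  cat("  top pathways per type:\n")
  for (tt in names(x$top_pathways))
    cat(sprintf("    %-10s %s\n", tt, paste(x$top_pathways[[tt]], collapse = ", ")))
  invisible(x)
}

#' @export
coef.trifactor <- function(object, ...) object$S

#' Rank pathways for one cancer type by association score
#'
#' Sorts the row of the association matrix S for `cancer_type` in descending
#' order; ties are broken by pathway index (stable). If a permutation result
#' from [permutation_fdr()] is supplied, its empirical p and BH q values are
#' merged in.
#'
#' @param model a fitted [fit_trifactor()] object.
#' @param cancer_type type label present in the model.
#' @param fdr optional result of [permutation_fdr()].
#' @return a `pathway_ranking` data.frame: cancer_type, pathway, score, rank,
#'   and (if available) p, q.
#' @export
rank_pathways <- function(model, cancer_type, fdr = NULL) {
  if (!cancer_type %in% model$types)
    stop_input("unknown cancer type: ", cancer_type)
  score <- model$S[cancer_type, ]
  ord <- order(-score, seq_along(score))
  out <- data.frame(cancer_type = cancer_type,
                    pathway = model$pathways[ord],
                    score = unname(score[ord]),
                    rank = seq_along(score),
                    stringsAsFactors = FALSE)
  if (!is.null(fdr)) {
    sub <- fdr[fdr$cancer_type == cancer_type, c("pathway", "p", "q")]
    out <- merge(out, sub, by = "pathway", sort = FALSE)
    out <- out[order(out$rank), ]
    rownames(out) <- NULL
  }
  class(out) <- c("pathway_ranking", "data.frame")
  out
}

#' Permutation-based empirical significance of pathway associations
#'
#' Refits the tri-factorization on permuted mutation data (each patient's
#' mutation vector independently shuffled across genes, preserving the
#' per-patient mutation burden) and converts each observed association score
#' into an add-one-smoothed empirical p value,
#' p = (1 + #\{permuted score >= observed\}) / (1 + n_perm),
#' with Benjamini-Hochberg adjustment applied within each cancer type.
#'
#' @inheritParams fit_trifactor
#' @param n_perm number of permutations (the reference analysis used 1000).
#' @param max_iter,tol fit controls used for the observed and every permuted
#'   fit alike (kept identical so scores are exchangeable under the null).
#' @return a data.frame: cancer_type, pathway, score, p, q.
#' @export
permutation_fdr <- function(X, type_labels, V0, L,
                            lambdas = c(s = 1, l = 1, v0 = 10),
                            n_perm = 1000L, seed = 1L,
                            max_iter = 200L, tol = 1e-5) {
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  init_seed <- child_seed(seed, "trifactor-init")
  fit0 <- fit_trifactor(X, type_labels, V0, L, lambdas, max_iter, tol,
                        seed = init_seed)
  S_obs <- fit0$S
  count_ge <- matrix(0L, nrow(S_obs), ncol(S_obs))
  X <- as.matrix(X)
  for (b in seq_len(n_perm)) {
    Xp <- with_seed(child_seed(seed, paste0("perm", b)),
                    t(apply(X, 1L, sample)))
    colnames(Xp) <- colnames(X)
    fitb <- fit_trifactor(Xp, type_labels, V0, L, lambdas, max_iter, tol,
                          seed = init_seed)
    count_ge <- count_ge + (fitb$S >= S_obs)
  }
  p <- (1 + count_ge) / (1 + n_perm)
  out <- data.frame(
    cancer_type = rep(rownames(S_obs), times = ncol(S_obs)),
    pathway = rep(colnames(S_obs), each = nrow(S_obs)),
    score = as.vector(S_obs),
    p = as.vector(p),
    stringsAsFactors = FALSE)
  out$q <- stats::ave(out$p, out$cancer_type,
                      FUN = function(v) stats::p.adjust(v, method = "BH"))
  out
}

#' Extract the gene signature of the top-ranked significant pathways
#'
#' Keeps pathways with rank <= `top_n` and BH q < `fdr_cutoff` and returns
#' the union of their member genes, ordered by (best pathway rank, gene id).
#' With the reference defaults (top three pathways, FDR 0.05) on the planted
#' synthetic database this yields the 32-gene signature.
#'
#' @param ranking a [rank_pathways()] result carrying a `q` column.
#' @param pathways a [pathway_db()] (or named gene-set list).
#' @param top_n number of top ranks considered (default 3).
#' @param fdr_cutoff BH q-value threshold (default 0.05).
#' @return character vector of signature genes (possibly empty, with a
#'   warning).
#' @export
select_signature <- function(ranking, pathways, top_n = 3L, fdr_cutoff = 0.05) {
  if (top_n < 1L) stop_input("top_n must be >= 1")
  sets <- if (inherits(pathways, "pathway_db")) pathways$sets else pathways
  if (!"q" %in% names(ranking))
    stop_input("ranking must carry q values (run permutation_fdr first)")
  keep <- ranking[ranking$rank <= top_n & ranking$q < fdr_cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no pathway passes rank/FDR filters; empty signature")
    return(character(0))
  }
  keep <- keep[order(keep$rank), , drop = FALSE]
  genes <- unique(unlist(sets[keep$pathway]))
  best_rank <- vapply(genes, function(g) {
    min(keep$rank[vapply(sets[keep$pathway], function(s) g %in% s, logical(1L))])
  }, numeric(1L))
  genes[order(best_rank, genes)]
}

#' One-sided Fisher over-representation test across a pathway database
#'
#' For each gene set, tests enrichment of `gene_list` against the universe
#' with a one-sided (greater) Fisher exact test on the 2x2 table of
#' in-list/in-set membership, then applies Benjamini-Hochberg adjustment
#' across sets.
#'
#' @param gene_list character vector of genes (subset of `universe`).
#' @param pathways a [pathway_db()] or named gene-set list.
#' @param universe character gene universe.
#' @return data.frame: pathway, overlap, size, p, q.
#' @export
overrepresentation_test <- function(gene_list, pathways, universe) {
  if (length(universe) == 0L) stop_input("empty universe")
  sets <- if (inherits(pathways, "pathway_db")) pathways$sets else pathways
  bad <- setdiff(gene_list, universe)
  if (length(bad)) stop_input("gene_list contains genes outside the universe: ",
                              paste(utils::head(bad, 5L), collapse = ", "))
  gene_list <- unique(gene_list)
  n_u <- length(universe); n_l <- length(gene_list)
  res <- lapply(sets, function(s) {
    s <- intersect(s, universe)
    a <- length(intersect(gene_list, s))
    tab <- matrix(c(a, length(s) - a, n_l - a, n_u - length(s) - n_l + a), 2L)
    data.frame(overlap = a, size = length(s),
               p = stats::fisher.test(tab, alternative = "greater")$p.value)
  })
  out <- do.call(rbind, res)
  out <- data.frame(pathway = names(sets), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
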