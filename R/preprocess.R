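#' Log2 transform and quantile-normalize a probe or gene matrix
#'
#' Values are log2-transformed (unless already on the log scale) and then
#' quantile-normalized: each column's values are replaced by the mean across
#' columns of the sorted values at the same rank, so every output column
#' shares one sorted-value multiset. Ties receive the mean of the reference
#' values across their tied ranks.
#'
#' @param x numeric matrix, probes (or genes) x samples.
#' @param already_log set TRUE if `x` is already log2 scale (skips the log).
#' @param pseudocount added before the log; 0 for microarray intensities
#'   (assumed >= 1), use 1 for RNA-seq TPM inputs.
#' @return normalized matrix with the input dimnames.
#' @export
log2_quantile_normalize <- function(x, already_log = FALSE, pseudocount = 0) {
  x <- as.matrix(x)
  if (!already_log) {
    shifted <- x + pseudocount
    if (any(shifted <= 0)) {
      bad <- which(shifted <= 0, arr.ind = TRUE)
      stop_input("non-positive values cannot be log2-transformed (first at row ",
                 bad[1L, 1L], ", column ", bad[1L, 2L],
                 "); supply a pseudocount or already_log = TRUE")
    }
    x <- log2(shifted)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse probe-level values to gene level by averaging
#'
#' Each gene's expression is the arithmetic mean of its probes per sample;
#' probes without a mapping are dropped with a warning, and genes with any
#' missing value are excluded entirely (no imputation).
#'
#' @param x probes x samples matrix with probe ids as rownames.
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`.
#' @return genes x samples matrix with an attribute `dropped_genes` listing
#'   genes excluded for missingness.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop_input("probe matrix must have probe rownames")
  if (!is.data.frame(probe_to_gene) ||
      !all(c("probe_id", "gene_id") %in% names(probe_to_gene)) ||
      nrow(probe_to_gene) == 0L)
    stop_input("probe_to_gene must be a non-empty data.frame with probe_id and gene_id")
  gene <- probe_to_gene$gene_id[match(rownames(x), probe_to_gene$probe_id)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    warning(sum(unmapped), " unmapped probes dropped")
    x <- x[!unmapped, , drop = FALSE]
    gene <- gene[!unmapped]
  }
  if (nrow(x) == 0L) stop_input("no mapped probes remain")
  sums <- rowsum(x, gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  incomplete <- rownames(out)[apply(out, 1L, function(r) any(is.na(r)))]
  if (length(incomplete)) out <- out[!rownames(out) %in% incomplete, , drop = FALSE]
  attr(out, "dropped_genes") <- incomplete
  out
}

#' Empirical-Bayes location-scale batch adjustment
#'
#' Harmonizes expression cohorts measured on different platforms with a
#' parametric empirical-Bayes location-scale model: per gene the data are
#' standardized against the weighted grand mean and pooled variance, batch
#' means and variances of the standardized residuals are shrunk toward
#' normal / inverse-gamma priors estimated across genes, the shrunken batch
#' effects are removed, and the data are rescaled. The weighted per-gene
#' grand mean is restored exactly after adjustment, so overall location is
#' preserved within numerical precision.
#'
#' @param x genes x samples matrix, or a named list of matrices (one per
#'   batch) whose shared gene set is used.
#' @param batch batch label per column of `x` (ignored when `x` is a list).
#' @return adjusted genes x samples matrix over the common gene set.
#' @export
batch_adjust <- function(x, batch = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    if (is.null(names(x))) names(x) <- paste0("batch", seq_along(x))
    common <- Reduce(intersect, lapply(x, rownames))
    if (length(common) == 0L) stop_input("no genes shared across batches")
    batch <- rep(names(x), vapply(x, ncol, integer(1L)))
    x <- do.call(cbind, lapply(x, function(m) m[common, , drop = FALSE]))
  }
  x <- as.matrix(x)
  if (is.null(batch) || length(batch) != ncol(x))
    stop_input("batch must label every sample (column)")
  batch <- factor(batch)
  nb <- table(batch)
  if (any(nb < 2L))
    stop_input("each batch needs >= 2 samples (variance undefined): ",
               paste(names(nb)[nb < 2L], collapse = ", "))
  if (nlevels(batch) == 1L) return(x)

  n <- ncol(x)
  w <- as.numeric(nb) / n
  batch_means <- vapply(levels(batch),
                        function(b) rowMeans(x[, batch == b, drop = FALSE]),
                        numeric(nrow(x)))
  grand <- drop(batch_means %*% w)
  pooled_var <- rowMeans((x - grand)^2)
  pooled_var[pooled_var < 1e-12] <- 1e-12
  s <- sqrt(pooled_var)
  z <- (x - grand) / s

  out <- z
  for (b in levels(batch)) {
    idx <- which(batch == b)
    zb <- z[, idx, drop = FALSE]
    m <- ncol(zb)
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1L, stats::var)
    gamma_bar <- mean(gamma_hat)
    tau2 <- stats::var(gamma_hat)
    Vd <- mean(delta_hat); S2d <- stats::var(delta_hat)
    lambda <- (Vd^2 + 2 * S2d) / S2d
    theta <- (Vd^3 + Vd * S2d) / S2d
    # iterative joint EB solution for the shrunken batch effects
    g_star <- gamma_hat
    d_star <- delta_hat
    for (i in seq_len(100L)) {
      g_new <- (m * tau2 * gamma_hat + d_star * gamma_bar) /
        (m * tau2 + d_star)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (theta + 0.5 * ss) / (m / 2 + lambda - 1)
      if (max(abs(g_new - g_star), abs(d_new - d_star)) < 1e-8) {
        g_star <- g_new; d_star <- d_new; break
      }
      g_star <- g_new; d_star <- d_new
    }
    out[, idx] <- (zb - g_star) / sqrt(pmax(d_star, 1e-12))
  }
  adj <- out * s + grand
  # restore the weighted per-gene grand mean exactly
  adj_means <- vapply(levels(batch),
                      function(b) rowMeans(adj[, batch == b, drop = FALSE]),
                      numeric(nrow(adj)))
  adj + (grand - drop(adj_means %*% w))
}

#' Restrict an expression matrix to a gene signature
#'
#' Returns the rows of `x` matching `signature`, ordered as the signature,
#' and reports missing genes. Errors when signature coverage falls below the
#' floor.
#'
#' @param x genes x samples matrix.
#' @param signature character vector of signature genes.
#' @param min_coverage minimum fraction of signature genes that must be
#'   present (default 0.8).
#' @return subset matrix with attribute `missing_genes`.
#' @export
intersect_signature <- function(x, signature, min_coverage = 0.8) {
  if (length(signature) == 0L) stop_input("signature must be non-empty")
  x <- as.matrix(x)
  present <- signature[signature %in% rownames(x)]
  missing <- setdiff(signature, present)
  coverage <- length(present) / length(signature)
  if (coverage < min_coverage)
    stop_input(sprintf(
      "signature coverage %.1f%% below the %.0f%% floor (%d of %d genes present)",
      100 * coverage, 100 * min_coverage, length(present), length(signature)))
  out <- x[present, , drop = FALSE]
  attr(out, "missing_genes") <- missing
  out
}
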