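#' Simulation design for the synthetic pan-cancer and cohort generators
#'
#' Bundles every tunable of the synthetic data generators and validates the
#' joint constraints once. The defaults emulate the study conditions the
#' pipeline was built for: a pan-cancer somatic-mutation matrix spanning 19
#' cancer types with three pathways (10 + 12 + 10 genes, a 32-gene union)
#' planted in the first ("gastric") type, and a 567-patient expression cohort
#' carrying four molecular subtypes in proportions 114/129/162/162 with
#' monotone best-to-worst planted hazards and subtype-dependent immunotherapy
#' response rates (0.48, 0.08, 0.50, 0.13).
#'
#' @param n_patients_per_type patients simulated per cancer type.
#' @param n_types number of cancer types; the first is the target type that
#'   carries the planted pathways.
#' @param n_genes size of the gene universe for the mutation arm.
#' @param background_mut_rate per-gene Bernoulli mutation probability.
#' @param planted_effect probability added to `background_mut_rate` for
#'   planted-pathway genes in the target type.
#' @param n_pathways number of gene sets in the synthetic pathway database.
#' @param pathway_sizes integer vector of set sizes (recycled to
#'   `n_pathways`); all sizes must be >= 2.
#' @param pathway_overlap expected fraction of genes shared between
#'   consecutive sets, in [0, 1).
#' @param n_cohort expression-cohort size.
#' @param k_subtypes number of planted molecular subtypes.
#' @param subtype_proportions simplex vector of length `k_subtypes`.
#' @param signature_size number of signature genes the cohort expresses.
#' @param expression_effect centroid separation between subtypes, in units of
#'   `noise_sd`.
#' @param noise_sd Gaussian noise standard deviation on the expression scale.
#' @param subtype_log_hazards log hazard ratios per subtype relative to the
#'   best-prognosis subtype (first entry conventionally 0).
#' @param censor_rate target fraction of censored observations.
#' @param response_probs per-subtype probability of objective response.
#' @param seed default integer seed consumed by the generators.
#' @return an object of class `simulation_design` (a validated list).
#' @export
simulation_design <- function(n_patients_per_type = 40L,
                              n_types = 19L,
                              n_genes = 400L,
                              background_mut_rate = 0.02,
                              planted_effect = 0.30,
                              n_pathways = 25L,
                              pathway_sizes = c(10L, 12L, 10L, rep(10L, 22L)),
                              pathway_overlap = 0,
                              n_cohort = 567L,
                              k_subtypes = 4L,
                              subtype_proportions = c(114, 129, 162, 162) / 567,
                              signature_size = 32L,
                              expression_effect = 2,
                              noise_sd = 1,
                              subtype_log_hazards = log(c(1, 1.6, 2.4, 3.4)),
                              censor_rate = 0.35,
                              response_probs = c(0.48, 0.08, 0.50, 0.13),
                              seed = 1L) {
  d <- list(n_patients_per_type = as.integer(n_patients_per_type),
            n_types = as.integer(n_types),
            n_genes = as.integer(n_genes),
            background_mut_rate = background_mut_rate,
            planted_effect = planted_effect,
            n_pathways = as.integer(n_pathways),
            pathway_sizes = as.integer(rep_len(pathway_sizes, n_pathways)),
            pathway_overlap = pathway_overlap,
            n_cohort = as.integer(n_cohort),
            k_subtypes = as.integer(k_subtypes),
            subtype_proportions = subtype_proportions,
            signature_size = as.integer(signature_size),
            expression_effect = expression_effect,
            noise_sd = noise_sd,
            subtype_log_hazards = subtype_log_hazards,
            censor_rate = censor_rate,
            response_probs = response_probs,
            seed = as.integer(seed))
  validate_design(d)
  structure(d, class = "simulation_design")
}

validate_design <- function(d) {
  probs <- c(d$background_mut_rate, d$planted_effect, d$censor_rate,
             d$response_probs, d$subtype_proportions)
  if (any(probs < 0 | probs > 1))
    stop_input("invalid design: all probabilities must lie in [0, 1]")
  if (d$background_mut_rate + d$planted_effect > 1)
    stop_input("invalid design: background_mut_rate + planted_effect exceeds 1")
  if (length(d$subtype_proportions) != d$k_subtypes)
    stop_input("invalid design: subtype_proportions length != k_subtypes")
  if (abs(sum(d$subtype_proportions) - 1) > 1e-9)
    stop_input("invalid design: subtype_proportions must sum to 1")
  if (length(d$subtype_log_hazards) != d$k_subtypes)
    stop_input("invalid design: subtype_log_hazards length != k_subtypes")
  if (length(d$response_probs) != d$k_subtypes)
    stop_input("invalid design: response_probs length != k_subtypes")
  if (any(d$pathway_sizes < 2L))
    stop_input("invalid design: pathway sizes must all be >= 2")
  if (d$pathway_overlap < 0 || d$pathway_overlap >= 1)
    stop_input("invalid design: pathway_overlap must lie in [0, 1)")
  if (d$noise_sd < 0) stop_input("invalid design: noise_sd must be >= 0")
  if (d$k_subtypes < 2L) stop_input("invalid design: k_subtypes must be >= 2")
  invisible(d)
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Simulation design\n")
  cat(sprintf("  mutation arm: %d types x %d patients, %d genes, %d pathways\n",
              x$n_types, x$n_patients_per_type, x$n_genes, x$n_pathways))
  cat(sprintf("  cohort arm:   n = %d, %d subtypes, %d signature genes\n",
              x$n_cohort, x$k_subtypes, x$signature_size))
  invisible(x)
}

#' Build a synthetic pathway database
#'
#' Draws `n_pathways` named gene sets from a universe of `n_genes` genes.
#' With `overlap = o`, each set shares, in expectation, a fraction `o` of its
#' members with the preceding set (each member is taken from the previous set
#' with probability `o`, otherwise from genes not yet used).
#'
#' @param n_genes size of the gene universe.
#' @param n_pathways number of sets.
#' @param pathway_sizes integer vector of set sizes.
#' @param overlap expected consecutive-set sharing fraction in [0, 1).
#' @param seed integer seed.
#' @return a `pathway_db` object: named gene-set list plus a binary
#'   genes-by-pathways membership matrix.
#' @export
make_pathway_db <- function(n_genes, n_pathways, pathway_sizes, overlap = 0,
                            seed = 1L) {
  pathway_sizes <- as.integer(rep_len(pathway_sizes, n_pathways))
  if (any(pathway_sizes < 2L)) stop_input("invalid design: set sizes must be >= 2")
  if (overlap < 0 || overlap >= 1) stop_input("invalid design: overlap in [0,1)")
  if (overlap == 0 && sum(pathway_sizes) > n_genes)
    stop_input("invalid design: pathway sizes exceed gene universe at overlap 0")
  genes <- sprintf("g%04d", seq_len(n_genes))
  sets <- with_seed(seed, {
    used <- character(0)
    out <- vector("list", n_pathways)
    for (j in seq_len(n_pathways)) {
      size <- pathway_sizes[j]
      take_prev <- if (j == 1L) 0L else rbinom(1L, size, overlap)
      prev <- if (j == 1L) character(0) else out[[j - 1L]]
      take_prev <- min(take_prev, length(prev))
      shared <- if (take_prev > 0L) sample(prev, take_prev) else character(0)
      pool <- setdiff(genes, c(used, shared))
      fresh_n <- size - take_prev
      if (fresh_n > length(pool))
        stop_input("invalid design: gene universe exhausted while building sets")
      fresh <- if (fresh_n > 0L) sample(pool, fresh_n) else character(0)
      out[[j]] <- sort(c(shared, fresh))
      used <- union(used, out[[j]])
    }
    names(out) <- sprintf("pathway%02d", seq_len(n_pathways))
    out
  })
  pathway_db(sets, universe = genes)
}

#' Construct a pathway database object from named gene sets
#'
#' @param sets named list of character gene vectors (all non-empty).
#' @param universe gene universe; defaults to the union of the sets.
#' @return a `pathway_db` with elements `sets`, `universe`, and `membership`
#'   (binary genes-by-pathways matrix `V0`).
#' @export
pathway_db <- function(sets, universe = NULL) {
  if (length(sets) == 0L || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_input("pathway sets must be a non-empty named list")
  if (any(lengths(sets) == 0L)) stop_input("every pathway set must be non-empty")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  miss <- setdiff(unlist(sets), universe)
  if (length(miss)) stop_input("set genes missing from universe: ",
                               paste(utils::head(miss, 5L), collapse = ", "))
  V0 <- matrix(0, length(universe), length(sets),
               dimnames = list(universe, names(sets)))
  for (j in seq_along(sets)) V0[sets[[j]], j] <- 1
  structure(list(sets = sets, universe = universe, membership = V0),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("Pathway database: %d sets over %d genes (sizes %s)\n",
              length(x$sets), length(x$universe),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Simulate a pan-cancer somatic mutation dataset with planted pathways
#'
#' Generates a binary patients-by-genes mutation matrix across
#' `design$n_types` cancer types. Every entry is Bernoulli(background) except
#' the genes of the planted pathways (the first three sets of the synthetic
#' database) in the target (first) type, which mutate at
#' `background + planted_effect`. A gene-gene interaction network is drawn
#' with denser connectivity inside each pathway than between random genes.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; defaults to `design$seed`.
#' @param n_planted number of pathways planted in the target type (default 3,
#'   the top-ranked sets whose union forms the signature).
#' @return a `pancancer_sim`: `mutations` (values, patient_ids, gene_ids,
#'   cancer_type), `network` (a [gene_network()]), `pathways`, and `planted`.
#' @export
simulate_pancancer <- function(design, seed = design$seed, n_planted = 3L) {
  validate_design(design)
  if (design$background_mut_rate + design$planted_effect > 1)
    stop_input("invalid design: background + planted_effect exceeds 1")
  pdb <- make_pathway_db(design$n_genes, design$n_pathways,
                         design$pathway_sizes, design$pathway_overlap,
                         seed = child_seed(seed, "pathways"))
  genes <- pdb$universe
  types <- c("gastric", sprintf("cancer%02d", seq_len(design$n_types - 1L) + 1L))
  type_of <- rep(types, each = design$n_patients_per_type)
  n <- length(type_of)
  planted_sets <- names(pdb$sets)[seq_len(min(n_planted, length(pdb$sets)))]
  planted_genes <- sort(unique(unlist(pdb$sets[planted_sets])))

  X <- with_seed(child_seed(seed, "mutations"), {
    p <- matrix(design$background_mut_rate, n, design$n_genes)
    p[type_of == types[1L], match(planted_genes, genes)] <-
      design$background_mut_rate + design$planted_effect
    matrix(rbinom(n * design$n_genes, 1L, p), n, design$n_genes)
  })
  dimnames(X) <- list(sprintf("pt%04d", seq_len(n)), genes)

  A <- with_seed(child_seed(seed, "network"), {
    g <- design$n_genes
    A <- matrix(0, g, g, dimnames = list(genes, genes))
    up <- upper.tri(A)
    A[up] <- rbinom(sum(up), 1L, 0.005)
    for (s in pdb$sets) {
      idx <- match(s, genes)
      sub <- A[idx, idx, drop = FALSE]
      subup <- upper.tri(sub)
      sub[subup] <- pmax(sub[subup], rbinom(sum(subup), 1L, 0.3))
      A[idx, idx] <- sub
    }
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    A
  })

  structure(list(
    mutations = list(values = X, patient_ids = rownames(X), gene_ids = genes,
                     cancer_type = type_of),
    network = gene_network(A),
    pathways = pdb,
    planted = list(type = types[1L], pathways = planted_sets,
                   genes = planted_genes)),
    class = "pancancer_sim")
}

#' @export
print.pancancer_sim <- function(x, ...) {
  cat(sprintf("Pan-cancer simulation: %d patients x %d genes, %d types\n",
              nrow(x$mutations$values), ncol(x$mutations$values),
              length(unique(x$mutations$cancer_type))))
  cat(sprintf("  planted: %s in type '%s' (%d genes)\n",
              paste(x$planted$pathways, collapse = ", "), x$planted$type,
              length(x$planted$genes)))
  invisible(x)
}

#' Construct a gene interaction network object
#'
#' @param adjacency symmetric non-negative adjacency matrix with zero
#'   diagonal, rows/columns named by gene.
#' @return a `gene_network` with `adjacency`, `degree` (diagonal vector) and
#'   `laplacian` L = D - A.
#' @export
gene_network <- function(adjacency) {
  if (!isSymmetric(unname(adjacency)))
    stop_input("adjacency must be symmetric")
  if (any(adjacency < 0)) stop_input("adjacency must be non-negative")
  if (any(diag(adjacency) != 0)) stop_input("adjacency diagonal must be zero")
  d <- rowSums(adjacency)
  L <- -adjacency
  diag(L) <- d
  structure(list(adjacency = adjacency, degree = d, laplacian = L,
                 gene_ids = rownames(adjacency)),
            class = "gene_network")
}

# Uniform-censoring horizon T such that the expected censored fraction over
# the subtype mixture of exponential event times equals `censor_rate`.
censor_horizon <- function(rates, weights, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  frac <- function(T) sum(weights * (1 - exp(-rates * T)) / (rates * T)) -
    censor_rate
  # frac is decreasing in T from 1 - censor_rate at T -> 0
  upper <- 1
  while (frac(upper) > 0 && upper < 1e9) upper <- upper * 2
  stats::uniroot(frac, c(1e-6, upper))$root
}

#' Simulate an expression cohort with planted subtypes, survival and response
#'
#' Samples are assigned to `k_subtypes` groups with deterministic
#' largest-remainder counts matching `subtype_proportions`. Expression over
#' the signature genes follows a block-centroid pattern: the genes are split
#' into k contiguous blocks and subtype s elevates block s by
#' `expression_effect * noise_sd` above a positive baseline, plus Gaussian
#' noise, clipped at zero so the matrix stays non-negative. Survival times
#' are exponential proportional hazards with per-subtype log hazard ratios;
#' censoring is independent uniform on [0, T] with T solved so the expected
#' censored fraction equals `censor_rate`. Objective response is Bernoulli
#' with subtype-specific rates, then refined to RECIST categories.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; defaults to `design$seed`.
#' @param genes optional character vector of `signature_size` gene ids to use
#'   as rownames (e.g. the planted signature from [simulate_pancancer()]).
#' @param baseline_median_os baseline (best subtype) median overall survival
#'   in months; default 110.
#' @return a `cohort_sim`: `expression` (genes x samples), `clinical`
#'   (data.frame), and `true_subtype` (integer vector).
#' @export
simulate_expression_cohort <- function(design, seed = design$seed,
                                       genes = NULL,
                                       baseline_median_os = 110) {
  validate_design(design)
  k <- design$k_subtypes
  n <- design$n_cohort
  if (is.null(genes)) genes <- sprintf("gene%03d", seq_len(design$signature_size))
  if (length(genes) != design$signature_size)
    stop_input("genes must have length signature_size")

  # deterministic largest-remainder group sizes
  raw <- design$subtype_proportions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }

  blocks <- split(seq_len(design$signature_size),
                  cut(seq_len(design$signature_size), k, labels = FALSE))
  baseline <- 8
  # separation is in noise-SD units; anchored at 1 when noise is switched off
  # so the noiseless limit keeps distinct subtype centroids
  sd_unit <- if (design$noise_sd > 0) design$noise_sd else 1
  centroids <- matrix(baseline, design$signature_size, k)
  for (s in seq_len(k))
    centroids[blocks[[s]], s] <- baseline + design$expression_effect * sd_unit

  out <- with_seed(child_seed(seed, "cohort"), {
    subtype <- sample(rep.int(seq_len(k), sizes))
    expr <- centroids[, subtype, drop = FALSE] +
      matrix(rnorm(design$signature_size * n, 0, design$noise_sd),
             design$signature_size, n)
    expr <- pmax(expr, 0)
    base_rate <- log(2) / baseline_median_os
    rates <- base_rate * exp(design$subtype_log_hazards)
    ev_time <- rexp(n, rates[subtype])
    Tc <- censor_horizon(rates, sizes / n, design$censor_rate)
    cens <- if (is.finite(Tc)) runif(n, 0, Tc) else rep(Inf, n)
    time <- pmin(ev_time, cens)
    event <- as.integer(ev_time <= cens)
    responder <- rbinom(n, 1L, design$response_probs[subtype])
    response <- ifelse(responder == 1L,
                       sample(c("CR", "PR"), n, TRUE, c(0.3, 0.7)),
                       sample(c("SD", "PD"), n, TRUE, c(0.4, 0.6)))
    age_group <- sample(c("<=60", ">60"), n, TRUE, c(0.485, 0.515))
    stage <- sample(c("I", "II", "III", "IV"), n, TRUE,
                    c(0.037, 0.259, 0.668, 0.036))
    treatment <- sample(c("none", "FU", "FU+platinum", "FU+other"), n, TRUE,
                        c(0.20, 0.25, 0.35, 0.20))
    list(subtype = subtype, expr = expr, time = time, event = event,
         response = response, age_group = age_group, stage = stage,
         treatment = treatment)
  })

  ids <- sprintf("s%04d", seq_len(n))
  dimnames(out$expr) <- list(genes, ids)
  clinical <- data.frame(
    sample_id = ids,
    time_months = out$time,
    event = out$event,
    age_group = out$age_group,
    stage = out$stage,
    treatment = out$treatment,
    response = out$response,
    stringsAsFactors = FALSE)
  structure(list(expression = out$expr, clinical = clinical,
                 true_subtype = out$subtype),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Cohort simulation: %d samples x %d signature genes, %d subtypes\n",
              ncol(x$expression), nrow(x$expression),
              length(unique(x$true_subtype))))
  cat("  subtype sizes:", paste(tabulate(x$true_subtype), collapse = ", "), "\n")
  invisible(x)
}
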