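# Small designs and random problem instances shared across test files.

tiny_design <- function(...) {
  simulation_design(
    n_patients_per_type = 15L, n_types = 3L, n_genes = 60L,
    n_pathways = 5L, pathway_sizes = c(6L, 8L, 6L, 5L, 5L),
    n_cohort = 120L, subtype_proportions = c(0.2, 0.25, 0.3, 0.25),
    signature_size = 20L, ...)
}

# random tri-factorization instance: binary X, random sets, sparse network
random_trifactor_instance <- function(seed, n = 30L, g = 40L, n_types = 3L,
                                      n_sets = 5L, rate = 0.15) {
  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(g))
    X <- matrix(rbinom(n * g, 1L, rate), n, g,
                dimnames = list(sprintf("p%03d", seq_len(n)), genes))
    types <- sample(paste0("t", seq_len(n_types)), n, replace = TRUE)
    sets <- lapply(seq_len(n_sets), function(i) sample(genes, 6L))
    names(sets) <- paste0("s", seq_len(n_sets))
    A <- matrix(rbinom(g * g, 1L, 0.05), g, g)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    dimnames(A) <- list(genes, genes)
    list(X = X, types = types, db = pathway_db(sets, universe = genes),
         network = gene_network(A))
  })
}

# exponential two-group survival data with a given hazard ratio
sim_two_group_surv <- function(n_per_group, hr, censor_frac = 0.4,
                               base_rate = 0.02) {
  grp <- rep(c("A", "B"), each = n_per_group)
  rate <- ifelse(grp == "B", base_rate * hr, base_rate)
  ev <- rexp(2 * n_per_group, rate)
  Tc <- if (censor_frac > 0) stats::quantile(ev, 1 - censor_frac / 2) else Inf
  cens <- runif(2 * n_per_group, 0, Tc)
  list(time = pmin(ev, cens), event = as.integer(ev <= cens), group = grp)
}
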