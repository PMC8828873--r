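#' Configuration for the end-to-end synthetic pipeline
#'
#' Collects every stage parameter with validated defaults. The permutation
#' count defaults to 250 here (the standalone [permutation_fdr()] default is
#' 1000) so a full synthetic run stays interactive; raise it for final
#' analyses.
#'
#' @param outdir output directory for stage artifacts and the manifest.
#' @param seed global integer seed; stages derive child seeds.
#' @param design a [simulation_design()].
#' @param lambdas tri-factorization penalty weights.
#' @param n_perm permutations for the empirical pathway significance.
#' @param top_n,fdr_cutoff signature selection rule.
#' @param k_range,n_runs consensus clustering controls.
#' @param C SVM cost for the classifier and risk model.
#' @param min_coverage signature coverage floor for expression matrices.
#' @return an `analysis_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("sig32-run-"),
                            seed = 1L,
                            design = simulation_design(seed = seed),
                            lambdas = c(s = 1, l = 1, v0 = 10),
                            n_perm = 250L,
                            top_n = 3L,
                            fdr_cutoff = 0.05,
                            k_range = 2:7,
                            n_runs = 50L,
                            C = 1,
                            min_coverage = 0.8) {
  validate_design(design)
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  structure(list(outdir = outdir, seed = as.integer(seed), design = design,
                 lambdas = lambdas, n_perm = as.integer(n_perm),
                 top_n = as.integer(top_n), fdr_cutoff = fdr_cutoff,
                 k_range = as.integer(k_range), n_runs = as.integer(n_runs),
                 C = C, min_coverage = min_coverage),
            class = "analysis_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> discover -> preprocess -> subtype -> classify ->
#' risk -> survive on synthetic data with planted structure, persisting each
#' stage's artifacts under `config$outdir` and recording a reproducibility
#' manifest (file hashes, seeds, parameters). Fully deterministic given the
#' config seed.
#'
#' @param config an [pipeline_config()] object.
#' @return a `run_manifest`; the fitted objects are attached as the
#'   `results` attribute-free list element for programmatic use.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stages <- list()
  art <- function(...) file.path(config$outdir, ...)
  record <- function(name, files, params = list()) {
    stages[[name]] <<- list(stage = name, files = as.list(files),
                            md5 = as.list(unname(tools::md5sum(files))),
                            params = params,
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }
  design <- config$design
  seed <- config$seed

  # 1. simulate --------------------------------------------------------------
  pan <- simulate_pancancer(design, seed = child_seed(seed, "simulate"))
  cohort <- simulate_expression_cohort(design,
                                       seed = child_seed(seed, "simulate"),
                                       genes = pan$planted$genes)
  write_matrix_tsv(pan$mutations$values, art("mutations.tsv"),
                   id_col = "patient_id")
  writeLines(paste(pan$mutations$patient_ids, pan$mutations$cancer_type,
                   sep = ","), art("patient_types.csv"))
  write_gmt(pan$pathways, art("pathways.gmt"))
  write_edgelist(pan$network, art("network.tsv"))
  write_matrix_tsv(cohort$expression, art("expression.tsv"))
  write_clinical_csv(cohort$clinical, art("clinical.csv"))
  record("simulate",
         art(c("mutations.tsv", "patient_types.csv", "pathways.gmt",
               "network.tsv", "expression.tsv", "clinical.csv")),
         params = list(seed = seed))

  # 2. discover --------------------------------------------------------------
  fdr <- permutation_fdr(pan$mutations$values, pan$mutations$cancer_type,
                         pan$pathways$membership, pan$network$laplacian,
                         lambdas = config$lambdas, n_perm = config$n_perm,
                         seed = child_seed(seed, "discover"))
  fit <- fit_trifactor(pan$mutations$values, pan$mutations$cancer_type,
                       pan$pathways$membership, pan$network$laplacian,
                       lambdas = config$lambdas,
                       seed = child_seed(child_seed(seed, "discover"),
                                         "trifactor-init"))
  ranking <- rank_pathways(fit, pan$planted$type, fdr = fdr)
  signature <- select_signature(ranking, pan$pathways,
                                top_n = config$top_n,
                                fdr_cutoff = config$fdr_cutoff)
  utils::write.csv(ranking, art("ranking.csv"), row.names = FALSE)
  writeLines(signature, art("signature.txt"))
  record("discover", art(c("ranking.csv", "signature.txt")),
         params = list(n_perm = config$n_perm, lambdas = as.list(config$lambdas)))

  # 3. preprocess ------------------------------------------------------------
  expr <- log2_quantile_normalize(cohort$expression, already_log = TRUE)
  expr <- intersect_signature(expr, signature,
                              min_coverage = config$min_coverage)
  write_matrix_tsv(expr, art("expression_signature.tsv"))
  record("preprocess", art("expression_signature.tsv"),
         params = list(min_coverage = config$min_coverage))

  # 4. subtype ---------------------------------------------------------------
  cons <- consensus_cluster(expr, k_range = config$k_range,
                            n_runs = config$n_runs,
                            seed = child_seed(seed, "subtype"))
  k_star <- select_k(cons)
  raw_labels <- cons$per_k[[paste0("k", k_star)]]$labels
  clin <- cohort$clinical
  grp <- order_groups(raw_labels, clin$time_months, clin$event)
  labels_df <- data.frame(sample_id = clin$sample_id, group = grp$group)
  utils::write.csv(labels_df, art("subtypes.csv"), row.names = FALSE)
  utils::write.csv(cons$diagnostics, art("consensus_diagnostics.csv"),
                   row.names = FALSE)
  record("subtype", art(c("subtypes.csv", "consensus_diagnostics.csv")),
         params = list(k_range = config$k_range, n_runs = config$n_runs,
                       selected_k = k_star))

  # 5. classify --------------------------------------------------------------
  ens <- train_pairwise(expr, as.character(grp$group), C = config$C)
  cv <- loocv_pairwise(expr, as.character(grp$group), C = config$C)
  write_model_json(ens, art("classifier.json"))
  utils::write.csv(data.frame(class = cv$classes, auc = unname(cv$auc)),
                   art("loocv_auc.csv"), row.names = FALSE)
  record("classify", art(c("classifier.json", "loocv_auc.csv")),
         params = list(C = config$C, mean_auc = cv$mean_auc))

  # 6. risk ------------------------------------------------------------------
  best <- "Group 1"; worst <- paste("Group", k_star)
  extreme <- grp$group %in% c(best, worst)
  rm_fit <- train_risk(expr[, extreme, drop = FALSE],
                       as.character(grp$group[extreme]),
                       negative_class = best, positive_class = worst,
                       C = config$C)
  scores <- risk_score(rm_fit, expr)
  curve <- os5_curve(scores, clin$time_months, clin$event)
  write_model_json(rm_fit, art("risk_model.json"))
  utils::write.csv(data.frame(sample_id = clin$sample_id,
                              risk_score = unname(scores)),
                   art("risk_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(score = curve$grid, os5 = curve$os,
                              lower = curve$lower, upper = curve$upper),
                   art("os5_curve.csv"), row.names = FALSE)
  record("risk",
         art(c("risk_model.json", "risk_scores.csv", "os5_curve.csv")),
         params = list(C = config$C))

  # 7. survive ---------------------------------------------------------------
  km <- km_logrank(clin$time_months, clin$event, grp$group)
  cox <- cox_fit(clin$time_months, clin$event,
                 data.frame(age_group = factor(clin$age_group),
                            stage = factor(clin$stage),
                            group = grp$group))
  resp_tab <- contingency(recist_response(clin$response), grp$group)
  chisq <- chisq_independence(resp_tab)
  utils::write.csv(cox$table, art("cox_multivariable.csv"), row.names = FALSE)
  report <- data.frame(sample_id = clin$sample_id, group = grp$group,
                       risk_score = unname(scores),
                       time_months = clin$time_months, event = clin$event,
                       response = clin$response)
  utils::write.csv(report, art("report.csv"), row.names = FALSE)
  record("survive", art(c("cox_multivariable.csv", "report.csv")),
         params = list(logrank_p = km$p.value, response_chisq_p = chisq$p.value))

  manifest <- structure(list(package_version = as.character(utils::packageVersion("sig32")),
                             seed = seed, outdir = config$outdir,
                             stages = stages,
                             elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                               units = "secs")),
                             results = list(signature = signature,
                                            selected_k = k_star,
                                            groups = grp$group,
                                            ranking = ranking,
                                            cv = cv,
                                            risk_model = rm_fit,
                                            scores = scores,
                                            curve = curve,
                                            km = km, cox = cox,
                                            response_test = chisq)),
                        class = "run_manifest")
  jsonlite::write_json(manifest_hashes(manifest),
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Extract the reproducibility fingerprint of a manifest
#'
#' The fingerprint lists stage names, artifact files and their md5 hashes
#' (no timestamps), so two runs are identical iff their fingerprints are.
#'
#' @param manifest a `run_manifest`.
#' @return nested list of stage -> file -> md5.
#' @export
manifest_hashes <- function(manifest) {
  lapply(manifest$stages, function(s)
    stats::setNames(s$md5, basename(unlist(s$files))))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d), %d stages, %.1f s\n",
              x$seed, length(x$stages), x$elapsed_sec))
  cat(sprintf("  signature size %d, selected k = %d, mean LOOCV AUC %.3f\n",
              length(x$results$signature), x$results$selected_k,
              x$results$cv$mean_auc))
  cat(sprintf("  log-rank p = %.3g, response chi-square p = %.3g\n",
              x$results$km$p.value, x$results$response_test$p.value))
  invisible(x)
}
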