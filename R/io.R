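# File formats: tab-separated matrices (first column = row id, header row of
# sample ids), GMT gene sets, two-column edge lists, clinical CSV with a
# strict header, and JSON for fitted models. Numeric values are written with
# 17 significant digits so read(write(x)) round-trips exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read an expression (or mutation) matrix as TSV
#'
#' Tab-separated, UTF-8, header row of sample ids, first column of row ids.
#' Values round-trip bit-exactly.
#'
#' @param x numeric matrix with full dimnames.
#' @param path file path.
#' @param id_col name for the id column header (default "gene_id").
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene_id") {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_input("matrix must have full dimnames")
  header <- paste(c(id_col, colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], fmt_num(x[i, ])), collapse = "\t"), character(1L))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop_input("matrix file has no data rows: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(parts[[1L]])
  ragged <- which(lengths(parts) != ncols)
  if (length(ragged))
    stop_input("ragged row(s) at line(s) ", paste(utils::head(ragged, 5L),
                                                  collapse = ", "))
  ids <- vapply(parts[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop_input("duplicate row ids at line(s) ",
               paste(which(duplicated(ids)) + 1L, collapse = ", "))
  samples <- parts[[1L]][-1L]
  if (anyDuplicated(samples)) stop_input("duplicate sample ids in header")
  vals <- vapply(parts[-1L], function(p) as.numeric(p[-1L]),
                 numeric(ncols - 1L))
  out <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncols - 1L)
  dimnames(out) <- list(ids, samples)
  out
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param db a [pathway_db()] or named gene-set list.
#' @param path file path.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` returns a
#'   [pathway_db()].
#' @export
write_gmt <- function(db, path) {
  sets <- if (inherits(db, "pathway_db")) db$sets else db
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gmt
#' @param universe optional gene universe for the membership matrix.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop_input("GMT line(s) with fewer than 3 fields: ",
               paste(utils::head(short, 5L), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) stop_input("duplicate set names in GMT")
  pathway_db(sets, universe = universe)
}

#' Write / read a gene-gene edge list as TSV
#'
#' Two tab-separated columns (geneA, geneB) with a header.
#'
#' @param network a [gene_network()] or adjacency matrix.
#' @param path file path.
#' @return `write_edgelist` returns `path`; `read_edgelist` returns a
#'   [gene_network()] over `genes` (default: genes seen in the file).
#' @export
write_edgelist <- function(network, path) {
  A <- if (inherits(network, "gene_network")) network$adjacency else network
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  lines <- c("geneA\tgeneB",
             sprintf("%s\t%s", rownames(A)[idx[, 1L]], colnames(A)[idx[, 2L]]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_edgelist
#' @param genes optional gene universe for the adjacency matrix.
#' @export
read_edgelist <- function(path, genes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("geneA", "geneB") %in% names(df)))
    stop_input("edge list must have columns geneA and geneB")
  if (is.null(genes)) genes <- sort(unique(c(df$geneA, df$geneB)))
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  A[cbind(match(df$geneA, genes), match(df$geneB, genes))] <- 1
  A[cbind(match(df$geneB, genes), match(df$geneA, genes))] <- 1
  diag(A) <- 0
  gene_network(A)
}

clinical_required <- c("sample_id", "time_months", "event")
clinical_known <- c(clinical_required,
                    c("age_group", "stage", "location", "lauren_type",
                      "perineural_invasion", "group", "treatment", "response"))

#' Write / read a clinical table as CSV
#'
#' Required columns: sample_id, time_months, event. Optional columns:
#' age_group, stage, location, lauren_type, perineural_invasion, group,
#' treatment, response. Unknown headers, duplicate sample ids, or a missing
#' required column raise parse errors naming the offender.
#'
#' @param clinical data.frame following the schema above.
#' @param path file path.
#' @return `write_clinical_csv` returns `path`; `read_clinical_csv` the
#'   data.frame.
#' @export
write_clinical_csv <- function(clinical, path) {
  miss <- setdiff(clinical_required, names(clinical))
  if (length(miss)) stop_input("clinical table missing column(s): ",
                               paste(miss, collapse = ", "))
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(clinical_required, names(df))
  if (length(miss)) stop_input("clinical table missing column(s): ",
                               paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), clinical_known)
  if (length(unknown)) stop_input("unknown clinical column(s): ",
                                  paste(unknown, collapse = ", "))
  dup <- which(duplicated(df$sample_id))
  if (length(dup)) stop_input("duplicate sample_id at row(s) ",
                              paste(utils::head(dup, 5L), collapse = ", "))
  df$time_months <- as.numeric(df$time_months)
  if (any(df$time_months < 0)) stop_input("negative time_months")
  if (!all(df$event %in% c(0L, 1L))) stop_input("event must be 0/1")
  df
}

#' Serialize / restore fitted SVM models as JSON
#'
#' Stores the gene order, per-pair weight vectors, biases, calibration
#' slopes and class names at full numeric precision.
#'
#' @param model a `pairwise_svm` or `risk_svm`.
#' @param path file path.
#' @return `write_model_json` returns `path`; `read_model_json` the model.
#' @export
write_model_json <- function(model, path) {
  if (!inherits(model, c("pairwise_svm", "risk_svm")))
    stop_input("model must be a pairwise_svm or risk_svm")
  payload <- c(list(.class = class(model)[1L]), unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (cls == "risk_svm") obj$w <- stats::setNames(as.numeric(obj$w), obj$genes)
  if (cls == "pairwise_svm")
    obj$models <- lapply(obj$models, function(m) {
      m$w <- stats::setNames(as.numeric(m$w), obj$genes)
      m
    })
  structure(obj, class = cls)
}
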