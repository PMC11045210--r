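# End-to-end orchestration: differential expression -> disease-term
# enrichment filter -> Wilks' lambda trimming -> RBF-SVM gate (split, tune,
# evaluate, ROC, PCA) -> single-gene prognostic screen. Gene sets contract
# monotonically across stages: signature subset-of filtered DEGs subset-of
# DEGs.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. All thresholds
#' are overridable; the seed is mandatory and deterministically derives the
#' split and cross-validation fold seeds.
#'
#' @param seed Integer global seed (mandatory).
#' @param p_cut DE adjusted-p cutoff. @param fc_cut Absolute log2FC cutoff.
#' @param n_input Input size: DEGs carried into enrichment (default 100).
#' @param epsilon Linear-scale pseudo-count for fold changes.
#' @param enrich_p Enrichment adjusted-p cutoff.
#' @param universe_mode `"intersection"` (genes in both the dataset and the
#'   annotation map) or `"annotated"` (all annotated genes).
#' @param propagate Propagate annotations up is_a edges before testing?
#' @param min_term_size Smallest term tested.
#' @param niveau_init,niveau_floor,niveau_step Trimming-loop schedule.
#' @param train_frac Training fraction of the stratified split.
#' @param grid A [tune_grid()].
#' @param kappa_cut,spec_cut,gate_p Classifier acceptance gates.
#' @param pca_k Components for the variance-coverage diagnostic.
#' @param surv_p Log-rank cutoff of the prognostic screen.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, p_cut = 0.05, fc_cut = 1.5, n_input = 100,
                            epsilon = 0.25, enrich_p = 0.05,
                            universe_mode = c("intersection", "annotated"),
                            propagate = FALSE, min_term_size = 2,
                            niveau_init = 0.1, niveau_floor = 0.05,
                            niveau_step = 0.01, train_frac = 0.8,
                            grid = tune_grid(), kappa_cut = 0.8,
                            spec_cut = 0.8, gate_p = 0.05, pca_k = 2,
                            surv_p = 0.05) {
  if (missing(seed)) stop("`seed` is mandatory")
  universe_mode <- match.arg(universe_mode)
  stopifnot(p_cut > 0, p_cut <= 1, fc_cut >= 0, n_input >= 1,
            enrich_p > 0, enrich_p <= 1, niveau_init >= niveau_floor,
            niveau_floor > 0, niveau_step > 0, train_frac > 0, train_frac < 1,
            inherits(grid, "tune_grid"))
  structure(list(seed = as.integer(seed), p_cut = p_cut, fc_cut = fc_cut,
                 n_input = n_input, epsilon = epsilon, enrich_p = enrich_p,
                 universe_mode = universe_mode, propagate = propagate,
                 min_term_size = min_term_size, niveau_init = niveau_init,
                 niveau_floor = niveau_floor, niveau_step = niveau_step,
                 train_frac = train_frac, grid = grid, kappa_cut = kappa_cut,
                 spec_cut = spec_cut, gate_p = gate_p, pca_k = pca_k,
                 surv_p = surv_p),
            class = "pipeline_config")
}

# samples x genes matrix on the log2 scale, the working space of selection
# and classification
log2_matrix <- function(ds, epsilon) {
  m <- t(ds$values)
  if (ds$scale == "linear") m <- log2(m + epsilon)
  m
}

#' Run the full signature-discovery pipeline
#'
#' Executes every stage in order and records per-stage timings. A stage
#' producing an empty gene set ends the run early with a structured status
#' naming that stage; the partial results up to it are kept. The
#' classification gate failing does NOT abort: the signature and its report
#' are returned with `report$accepted = FALSE`.
#'
#' @param ds An [expression_dataset()].
#' @param map An [annotation_map()].
#' @param surv Optional `survival_table` for the prognostic screen.
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `status` (`"ok"` or
#'   `"empty_<stage>"`), `deg`, `enrichment`, `filtered_genes`, `trace`,
#'   `signature`, `report`, `auc`, `pca`, `prognosis`, and `provenance`
#'   (config echo, seed, stage timings).
#' @export
run_pipeline <- function(ds, map, surv = NULL, config) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(map, "annotation_map"),
            inherits(config, "pipeline_config"))
  res <- list(status = "ok", deg = NULL, enrichment = NULL,
              filtered_genes = NULL, trace = NULL, signature = NULL,
              report = NULL, auc = NULL, pca = NULL, prognosis = NULL)
  timings <- c()
  tic <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(code)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  finish <- function(res) {
    res$provenance <- list(config = unclass(config), seed = config$seed,
                           timings = as.list(timings))
    structure(res, class = "pipeline_result")
  }

  res$deg <- tic("diffexpr",
    run_differential_expression(ds, config$p_cut, config$fc_cut,
                                config$n_input, config$epsilon))
  if (!nrow(res$deg)) { res$status <- "empty_diffexpr"; return(finish(res)) }

  res$enrichment <- tic("enrichment", {
    emap <- if (config$propagate) propagate_annotations(map) else map
    annotated <- unique(unlist(emap$term_to_genes, use.names = FALSE))
    universe <- switch(config$universe_mode,
                       intersection = intersect(rownames(ds$values), annotated),
                       annotated = annotated)
    query <- intersect(res$deg$gene_id, universe)
    enrich(query, emap, universe, config$min_term_size, config$enrich_p)
  })
  res$filtered_genes <- filter_genes_by_enrichment(res$deg$gene_id,
                                                   res$enrichment,
                                                   config$enrich_p)
  if (!length(res$filtered_genes)) {
    res$status <- "empty_enrichment"; return(finish(res))
  }

  X <- log2_matrix(ds, config$epsilon)[, res$filtered_genes, drop = FALSE]
  sel <- tic("selection", {
    if (length(res$filtered_genes) < 2) {
      list(genes = res$filtered_genes, trace = NULL)
    } else {
      tryCatch(trimming_loop(X, ds$labels, config$niveau_init,
                             config$niveau_floor, config$niveau_step),
               error = function(e) list(genes = character(), trace = NULL))
    }
  })
  res$trace <- sel$trace
  res$signature <- sel$genes
  if (!length(res$signature)) { res$status <- "empty_selection"; return(finish(res)) }

  Xs <- X[, res$signature, drop = FALSE]
  res$report <- tic("classification", {
    sp <- stratified_split(ds$labels, config$train_frac,
                           derive_seed(config$seed, "split"))
    tuned <- tune_rbf_svm(Xs[sp$train, , drop = FALSE], ds$labels[sp$train],
                          config$grid, derive_seed(config$seed, "folds"))
    model <- fit_rbf_svm(Xs[sp$train, , drop = FALSE], ds$labels[sp$train],
                         tuned$best_gamma, tuned$best_cost)
    rep <- evaluate_classifier(model, Xs[sp$test, , drop = FALSE],
                               ds$labels[sp$test], config$kappa_cut,
                               config$spec_cut, config$gate_p)
    rep$cv_accuracy <- tuned$cv_accuracy
    rep$test_labels <- unname(ds$labels[sp$test])
    rep
  })
  res$auc <- roc_auc(res$report$scores, res$report$test_labels)
  res$pca <- pca_variance_check(Xs, config$pca_k)

  if (!is.null(surv)) {
    res$prognosis <- tic("survival",
      suppressWarnings(prognostic_screen(ds, res$signature, surv,
                                         config$surv_p)))
  }
  finish(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result — status:", x$status, "\n")
  if (!is.null(x$deg)) cat(sprintf("  DEGs: %d\n", nrow(x$deg)))
  if (!is.null(x$filtered_genes))
    cat(sprintf("  disease-filtered: %d\n", length(x$filtered_genes)))
  if (length(x$signature))
    cat("  signature:", paste(x$signature, collapse = ", "), "\n")
  if (!is.null(x$report))
    cat(sprintf("  test accuracy %.3f, kappa %.3f, AUC %.3f, accepted %s\n",
                x$report$accuracy, x$report$kappa, x$auc, x$report$accepted))
  if (!is.null(x$prognosis))
    cat(sprintf("  prognostic genes (log-rank p < cutoff): %d\n",
                nrow(x$prognosis)))
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' @param result A `pipeline_result`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @param include_timings Keep the stage timings (set `FALSE` for
#'   byte-identical reruns).
#' @return The JSON string, invisibly when written to `path`.
#' @export
pipeline_result_json <- function(result, path = NULL, include_timings = TRUE) {
  x <- unclass(result)
  x$report <- unclass(x$report)
  x$report$scores <- NULL
  x$report$test_labels <- NULL
  x$enrichment <- if (!is.null(x$enrichment)) {
    e <- as.data.frame(x$enrichment[, setdiff(names(x$enrichment), "member_genes")])
    e$member_genes <- vapply(x$enrichment$member_genes, paste, character(1),
                             collapse = ",")
    e
  }
  x$deg <- if (!is.null(x$deg)) as.data.frame(x$deg)
  x$trace <- if (!is.null(x$trace)) unclass(x$trace)
  x$provenance$config$grid <- unclass(x$provenance$config$grid)
  if (!include_timings) x$provenance$timings <- NULL
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits `deg.tsv`, `enrichment.tsv`, `selection.tsv`, `report.json`,
#' `roc.tsv`, `prognosis.tsv` (when present) and `provenance.json`.
#'
#' @param result A `pipeline_result`. @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(result$deg))
    write_deg_table(result$deg, file.path(dir, "deg.tsv"))
  if (!is.null(result$enrichment))
    write_enrichment(result$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(result$trace))
    write_selection_trace(result$trace, file.path(dir, "selection.tsv"))
  if (!is.null(result$report)) {
    rep <- result$report
    if (!is.null(rep$scores) && !is.null(rep$test_labels)) {
      roc <- roc_points(rep$scores, rep$test_labels)
      utils::write.table(roc, file.path(dir, "roc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    rep$scores <- NULL; rep$test_labels <- NULL
    jsonlite::write_json(c(unclass(rep), list(auc = result$auc,
                                              pca_fraction = result$pca$fraction,
                                              signature = as.list(result$signature))),
                         file.path(dir, "report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(result$prognosis))
    utils::write.table(result$prognosis, file.path(dir, "prognosis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- result$provenance
  prov$config$grid <- unclass(prov$config$grid)
  prov$status <- result$status
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# empirical ROC points (fpr, tpr, threshold), tumor positive
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- labels[ord] == "tumor"
  data.frame(threshold = c(Inf, s),
             tpr = c(0, cumsum(pos)) / max(sum(pos), 1),
             fpr = c(0, cumsum(!pos)) / max(sum(!pos), 1))
}
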