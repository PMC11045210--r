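# Deterministic synthetic-fixture generator. Emulates the statistical
# structure the pipeline assumes: a two-class log-normal expression matrix
# with planted differential genes, a disease annotation map with one planted
# enriched term, and exponential survival times whose log-hazard is linear
# in one designated planted gene's expression.

#' Specification of a synthetic fixture
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: 1000 genes, 30 tumor + 30 normal samples, 15 planted differential
#' genes at a log2 shift of 2 over within-class noise of SD 0.5 (log2
#' scale), one planted disease term covering 80% of the planted genes, and
#' a planted prognostic gene whose median split carries roughly a two-fold
#' hazard ratio.
#'
#' @param n_genes,n_tumor,n_normal Matrix dimensions.
#' @param n_planted_deg Number of genes given a tumor-specific shift
#'   (alternating up/down).
#' @param shift_log2 Planted log2 fold change.
#' @param noise_sd_log2 Within-class SD on the log2 scale.
#' @param n_terms Number of annotation terms (one is the planted term).
#' @param planted_term_coverage Fraction of planted genes annotated to the
#'   planted term.
#' @param background_annotation_rate Probability a non-planted gene also
#'   lands in the planted term.
#' @param baseline_rate Exponential event rate (per day) at average
#'   expression of the prognostic gene.
#' @param hazard_log2_slope Log2-hazard increase per SD of the prognostic
#'   gene's expression (default 0.625: about a two-fold rate ratio between
#'   median-split halves).
#' @param censoring_rate Target fraction of censored subjects.
#' @param scale Output value scale, `"linear"` (exponentiated) or `"log2"`.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 1000, n_tumor = 30, n_normal = 30,
                         n_planted_deg = 15, shift_log2 = 2,
                         noise_sd_log2 = 0.5, n_terms = 20,
                         planted_term_coverage = 0.8,
                         background_annotation_rate = 0.02,
                         baseline_rate = 0.001, hazard_log2_slope = 0.625,
                         censoring_rate = 0.3,
                         scale = c("linear", "log2"), seed = 1) {
  scale <- match.arg(scale)
  spec <- list(n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
               n_planted_deg = n_planted_deg, shift_log2 = shift_log2,
               noise_sd_log2 = noise_sd_log2, n_terms = n_terms,
               planted_term_coverage = planted_term_coverage,
               background_annotation_rate = background_annotation_rate,
               baseline_rate = baseline_rate,
               hazard_log2_slope = hazard_log2_slope,
               censoring_rate = censoring_rate, scale = scale,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_genes >= 1, n_tumor >= 1, n_normal >= 1, n_planted_deg >= 0,
              noise_sd_log2 > 0, n_terms >= 1,
              planted_term_coverage >= 0, planted_term_coverage <= 1,
              background_annotation_rate >= 0, background_annotation_rate <= 1,
              censoring_rate >= 0, censoring_rate <= 1, baseline_rate > 0)
  })
  if (spec$n_planted_deg > spec$n_genes)
    stop("more planted genes than total genes")
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' Per gene, a baseline log2 level is drawn once from Uniform(3, 8); sample
#' values are Normal(baseline, noise_sd_log2), with `+/- shift_log2` added
#' to planted genes in tumor samples (alternating sign so both up- and
#' down-regulation occur). Values are exponentiated when
#' `scale = "linear"`. One annotation term collects the planted genes (at
#' the requested coverage) plus background genes; the remaining terms draw
#' random gene sets. Survival times (all samples) are exponential with
#' log2-hazard linear in the standardized expression of one designated
#' planted-and-annotated gene; censoring is independent exponential.
#'
#' @param spec A [fixture_spec()].
#' @return List with `dataset` ([expression_dataset()]), `map`
#'   ([annotation_map()]), `survival` (`survival_table`), and `truth`
#'   (list: `planted_degs`, `planted_term`, `prognostic_gene`).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    samples <- c(sprintf("T%03d", seq_len(spec$n_tumor)),
                 sprintf("N%03d", seq_len(spec$n_normal)))
    labels <- rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal))
    planted <- sort(sample(genes, spec$n_planted_deg))
    baseline <- stats::runif(spec$n_genes, 3, 8)
    m <- matrix(stats::rnorm(spec$n_genes * length(samples),
                             mean = baseline, sd = spec$noise_sd_log2),
                nrow = spec$n_genes, dimnames = list(genes, samples))
    if (spec$n_planted_deg > 0) {
      sign <- rep_len(c(1, -1), spec$n_planted_deg)
      tum <- labels == "tumor"
      m[planted, tum] <- m[planted, tum] + sign * spec$shift_log2
    }
    values <- if (spec$scale == "linear") 2^m else m
    ds <- expression_dataset(values, stats::setNames(labels, samples), spec$scale)

    # planted enriched term + random background terms
    n_cov <- round(spec$planted_term_coverage * spec$n_planted_deg)
    covered <- if (n_cov > 0) planted[seq_len(n_cov)] else character()
    backg <- setdiff(genes, planted)
    extra <- backg[stats::runif(length(backg)) < spec$background_annotation_rate]
    sets <- list()
    sets[["DIS:0001"]] <- union(covered, extra)
    if (!length(sets[["DIS:0001"]])) sets[["DIS:0001"]] <- genes[1]
    if (spec$n_terms > 1) {
      for (i in seq_len(spec$n_terms - 1)) {
        sz <- sample(5:30, 1)
        sets[[sprintf("DIS:%04d", i + 1)]] <- sample(genes, min(sz, length(genes)))
      }
    }
    nms <- stats::setNames(c("planted disease",
                             sprintf("background disease %d",
                                     seq_len(length(sets) - 1))),
                           names(sets))
    map <- annotation_map(sets, nms)

    # survival with the hazard tied to one planted, annotated gene
    prog_pool <- if (length(covered)) covered else if (length(planted)) planted else genes
    prog <- prog_pool[1]
    z <- as.numeric(scale(m[prog, ]))
    rate <- spec$baseline_rate * 2^(spec$hazard_log2_slope * z)
    t_event <- stats::rexp(length(samples), rate)
    surv <- if (spec$censoring_rate > 0 && spec$censoring_rate < 1) {
      c_rate <- spec$baseline_rate * spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- stats::rexp(length(samples), c_rate)
      data.frame(sample = samples, time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample = samples, time = t_event,
                 event = rep(1L, length(samples)), stringsAsFactors = FALSE)
    }
    list(dataset = ds, map = map, survival = survival_table(surv),
         truth = list(planted_degs = planted, planted_term = "DIS:0001",
                      prognostic_gene = prog))
  })
}

#' Write a fixture bundle to a directory
#'
#' Emits exactly the formats the readers consume: `expression.tsv`,
#' `labels.tsv`, `annotations.gmt`, `survival.tsv`, plus `truth.json`.
#'
#' @param bundle Output of [generate_fixture()].
#' @param dir Target directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             gmt = file.path(dir, "annotations.gmt"),
             survival = file.path(dir, "survival.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(bundle$dataset, paths[["expression"]], paths[["labels"]])
  write_gmt(bundle$map, paths[["gmt"]])
  utils::write.table(bundle$survival, paths[["survival"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
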