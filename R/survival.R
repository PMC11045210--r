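# Single-gene prognostic screening: per gene, samples are split at the
# median expression into low/high groups, compared by the log-rank test,
# and the hazard ratio is estimated by the Pike O/E ratio.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator over the distinct event times. Ties between an
#' event and a censoring at the same time follow the standard convention:
#' events precede censorings, so censored subjects at time t are still at
#' risk for the event at t.
#'
#' @param times Positive follow-up times.
#' @param events 0 (censored) / 1 (event) per subject.
#' @return data.frame of class `km_curve` with columns `time` (ascending
#'   distinct event times), `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test with Pike hazard-ratio estimate
#'
#' At each distinct event time with d events among N at risk (n_A in group
#' A), the expected group-A events accrue as d * n_A / N and the
#' hypergeometric variance as d * (n_A/N) * (1 - n_A/N) * (N - d)/(N - 1)
#' (0 when N = 1). chi2 = (O_A - E_A)^2 / V on 1 df. The hazard ratio is
#' the Pike estimator (O_A/E_A) / (O_B/E_B), group A over group B.
#'
#' @param times_a,events_a Group A follow-up times and event indicators.
#' @param times_b,events_b Group B likewise.
#' @return List of class `logrank_result` with `O_A`, `O_B`, `E_A`, `E_B`,
#'   `V`, `chi2`, `p`, `hazard_ratio`. A degenerate table (V = 0) returns
#'   p = 1 with a warning.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) < 1) stop("need at least one event overall")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  et <- sort(unique(times[events == 1]))
  E_A <- V <- 0
  for (t in et) {
    at_risk <- times >= t
    N <- sum(at_risk)
    nA <- sum(at_risk & grp_a)
    d <- sum(times == t & events == 1)
    E_A <- E_A + d * nA / N
    if (N > 1)
      V <- V + d * (nA / N) * (1 - nA / N) * (N - d) / (N - 1)
  }
  O_A <- sum(events_a); O_B <- sum(events_b)
  E_B <- (O_A + O_B) - E_A
  if (V == 0) {
    warning("degenerate risk tables: log-rank variance is zero")
    chi2 <- 0; p <- 1
  } else {
    chi2 <- (O_A - E_A)^2 / V
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  hr <- if (E_A > 0 && E_B > 0 && O_B > 0) (O_A / E_A) / (O_B / E_B)
        else NA_real_
  structure(list(O_A = O_A, O_B = O_B, E_A = E_A, E_B = E_B, V = V,
                 chi2 = chi2, p = p, hazard_ratio = hr),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: O=%g/%g E=%.3f/%.3f chi2=%.3f p=%.4g HR=%.3g\n",
              x$O_A, x$O_B, x$E_A, x$E_B, x$chi2, x$p, x$hazard_ratio))
  invisible(x)
}

#' Median dichotomization of samples by one gene
#'
#' Splits samples at the median expression of the gene; values at or below
#' the median go to `"low"`, above to `"high"`.
#'
#' @param ds An [expression_dataset()].
#' @param gene_id Gene to split on.
#' @param sample_ids Samples to use (default: all in `ds`).
#' @return Named character vector of `"low"`/`"high"` per sample.
#' @export
dichotomize_by_gene <- function(ds, gene_id, sample_ids = colnames(ds$values)) {
  if (!gene_id %in% rownames(ds$values)) stop("gene not in dataset: ", gene_id)
  x <- ds$values[gene_id, sample_ids]
  if (stats::sd(x) == 0) stop("non-informative gene (constant expression): ", gene_id)
  med <- stats::median(x)
  grp <- ifelse(x > med, "high", "low")
  stats::setNames(grp, sample_ids)
}

#' Single-gene prognostic screen over a signature
#'
#' Per gene: dichotomize samples at the median, run the log-rank test
#' (high vs low), and keep genes with p below the cutoff. Genes that cannot
#' be split (constant expression, or a side with fewer than 2 samples) are
#' skipped with a warning.
#'
#' @param ds An [expression_dataset()].
#' @param signature Character vector of gene ids.
#' @param surv A `survival_table`; at least 10 of its samples must overlap
#'   the expression dataset.
#' @param p_cut Log-rank significance cutoff (default 0.05).
#' @return data.frame with columns `gene`, `logrank_p`, `hazard_ratio`
#'   (high over low), sorted by p ascending; only significant genes.
#' @export
prognostic_screen <- function(ds, signature, surv, p_cut = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  samples <- intersect(colnames(ds$values), surv$sample)
  if (!length(samples))
    stop("no overlap between expression samples and survival table")
  if (length(samples) < 10)
    stop("need >= 10 samples with survival records")
  sv <- surv[match(samples, surv$sample), ]
  out <- data.frame(gene = character(), logrank_p = numeric(),
                    hazard_ratio = numeric(), stringsAsFactors = FALSE)
  for (g in intersect(signature, rownames(ds$values))) {
    grp <- tryCatch(dichotomize_by_gene(ds, g, samples),
                    error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(grp)) next
    hi <- grp == "high"
    if (sum(hi) < 2 || sum(!hi) < 2) {
      warning("median split leaves fewer than 2 samples on one side for ", g)
      next
    }
    lr <- suppressWarnings(
      logrank_test(sv$time[hi], sv$event[hi], sv$time[!hi], sv$event[!hi]))
    if (lr$p < p_cut)
      out <- rbind(out, data.frame(gene = g, logrank_p = lr$p,
                                   hazard_ratio = lr$hazard_ratio,
                                   stringsAsFactors = FALSE))
  }
  out <- out[order(out$logrank_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
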