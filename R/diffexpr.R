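# Per-gene differential expression between tumor and normal samples.
#
# Each gene is routed by an Anderson-Darling normality gate: when both
# classes look normal (and each has >= 8 samples) a two-sample z-test is
# used, otherwise the Mann-Whitney U test. Raw p-values are BH-adjusted
# across all genes; significance requires adjusted p below a cutoff AND an
# absolute log2 fold change at or above a cutoff; the surviving list is
# ranked and truncated to a user-chosen input size n.

#' Anderson-Darling normality test
#'
#' Composite-hypothesis Anderson-Darling test with the small-sample
#' correction A* = A^2 (1 + 0.75/n + 2.25/n^2) and the case-based
#' D'Agostino-Stephens p-value approximation (the form used by standard
#' normality-test implementations). Samples of fewer than 8 values or with
#' zero variance cannot be assessed; these raise a condition of class
#' `dosig_normality_fallback`, which callers interpret as "route this gene
#' to the nonparametric test".
#'
#' @param x Numeric vector, `length(x) >= 8`, positive variance.
#' @return List with `A2star` (corrected statistic) and `p`.
#' @export
anderson_darling <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8)
    stop_with_class("Anderson-Darling needs n >= 8; falling back to nonparametric test",
                    "dosig_normality_fallback")
  if (stats::sd(x) == 0)
    stop_with_class("zero variance; falling back to nonparametric test",
                    "dosig_normality_fallback")
  ht <- nortest::ad.test(x)
  a2 <- unname(ht$statistic)
  list(A2star = a2 * (1 + 0.75 / n + 2.25 / n^2), p = ht$p.value)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midranks for ties. The p-value is exact (full null
#' enumeration of the U distribution) when the pooled sample size is at most
#' 16 and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors (first group's U is reported).
#' @return List with `U` (U statistic of group `a`) and two-sided `p`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 16) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Two-sample z-test (two-sided)
#'
#' Large-sample z-test with the sample variances plugged in as known sigmas:
#' z = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b).
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return List with `z` and two-sided `p`.
#' @export
two_sample_z <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 values")
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 == 0) stop("zero pooled variance in z-test")
  z <- (mean(a) - mean(b)) / sqrt(se2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Log2 fold change, tumor vs normal
#'
#' On the linear scale the ratio of group means is taken with a small
#' pseudo-count epsilon added to both to avoid infinities at zero means; on
#' the log2 scale the difference of group means is already the log2 fold
#' change.
#'
#' @param a Tumor values. @param b Normal values.
#' @param scale `"linear"` or `"log2"`.
#' @param epsilon Pseudo-count for the linear scale (default 0.25).
#' @return Log2 fold change (positive = higher in tumor).
#' @export
log2_fold_change <- function(a, b, scale = c("linear", "log2"), epsilon = 0.25) {
  scale <- match.arg(scale)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (scale == "linear") log2((mean(a) + epsilon) / (mean(b) + epsilon))
  else mean(a) - mean(b)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between tumor and normal classes
#'
#' Runs the normality-gated per-gene test (see module header), BH-adjusts
#' across all genes, retains genes with `p_adj < p_cut` and
#' `|log2FC| >= fc_cut`, ranks them by adjusted p (ties: larger `|log2FC|`,
#' then gene id), and truncates the combined up/down list to the top `n`.
#'
#' @param ds An [expression_dataset()]; each class needs >= 3 samples.
#' @param p_cut Adjusted-p significance cutoff (default 0.05).
#' @param fc_cut Absolute log2-fold-change cutoff (default 1.5).
#' @param n Input size: maximum number of genes retained (default `Inf`).
#' @param epsilon Pseudo-count for linear-scale fold changes.
#' @param normality_alpha Anderson-Darling acceptance level for the gate
#'   (default 0.05: both classes must have AD p above this to use the
#'   z-test).
#' @return A `deg_table`: data.frame with columns `gene_id`, `test_used`,
#'   `statistic`, `p_raw`, `p_adj`, `log2fc`, `direction`, carrying the
#'   thresholds as attributes. Zero rows when nothing qualifies.
#' @export
run_differential_expression <- function(ds, p_cut = 0.05, fc_cut = 1.5, n = Inf,
                                        epsilon = 0.25, normality_alpha = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  tum <- ds$labels == "tumor"
  if (sum(tum) < 3 || sum(!tum) < 3)
    stop("each class needs at least 3 samples")
  genes <- rownames(ds$values)
  res <- lapply(genes, function(g) {
    a <- ds$values[g, tum]
    b <- ds$values[g, !tum]
    use_z <- length(a) >= 8 && length(b) >= 8 &&
      ad_gate(a, normality_alpha) && ad_gate(b, normality_alpha)
    if (use_z) {
      t <- two_sample_z(a, b)
      stat <- t$z; p <- t$p; used <- "z_test"
    } else {
      t <- mann_whitney_u(a, b)
      stat <- t$U; p <- t$p; used <- "mann_whitney"
    }
    fc <- log2_fold_change(a, b, ds$scale, epsilon)
    data.frame(gene_id = g, test_used = used, statistic = stat,
               p_raw = p, log2fc = fc, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$direction <- ifelse(tab$log2fc > 0, "up", "down")
  keep <- tab$p_adj < p_cut & abs(tab$log2fc) >= fc_cut
  tab <- tab[keep, , drop = FALSE]
  ord <- order(tab$p_adj, -abs(tab$log2fc), tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  if (is.finite(n) && nrow(tab) > n) tab <- tab[seq_len(n), , drop = FALSE]
  tab <- tab[, c("gene_id", "test_used", "statistic", "p_raw", "p_adj",
                 "log2fc", "direction")]
  rownames(tab) <- NULL
  structure(tab, class = c("deg_table", "data.frame"),
            p_cut = p_cut, fc_cut = fc_cut, input_size = n)
}

# TRUE when the Anderson-Darling test accepts normality at level alpha;
# unassessable samples (too small, zero variance) gate to FALSE.
ad_gate <- function(x, alpha) {
  tryCatch(anderson_darling(x)$p > alpha,
           dosig_normality_fallback = function(e) FALSE)
}

#' Write a DEG table to TSV
#'
#' @param deg A `deg_table` from [run_differential_expression()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(as.data.frame(deg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_deg_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(tab, class = c("deg_table", "data.frame"))
}
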