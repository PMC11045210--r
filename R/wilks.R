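# Stepwise forward feature selection by Wilks' lambda with partial-F entry
# tests, wrapped in an adaptive "niveau" trimming loop: selection starts at
# an entry threshold of 0.1 which is lowered stepwise until every entered
# feature's inclusion p-value is at or below 0.05.

#' Wilks' lambda for a feature set
#'
#' Lambda = det(W) / det(W + B), where W is the pooled within-group
#' cross-product of deviations and B the between-group cross-product. Values
#' near 0 indicate strong group separation; 1 means none.
#'
#' @param X Numeric matrix, samples x selected features.
#' @param labels Two-class vector, one label per row of `X`.
#' @return Lambda in `(0, 1]`. Raises a condition of class
#'   `dosig_singular` when W (or the total scatter) is singular, which the
#'   stepwise driver interprets as "skip this candidate".
#' @examples
#' wilks_lambda(matrix(c(1, 2, 3, 4)), rep(c("a", "b"), each = 2))  # 0.2
#' @export
wilks_lambda <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two classes required")
  N <- nrow(X); p <- ncol(X)
  if (N <= p + length(groups))
    stop_with_class("too few samples for this many features", "dosig_singular")
  W <- matrix(0, p, p)
  for (g in groups) {
    Xg <- X[labels == g, , drop = FALSE]
    W <- W + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  ldW <- determinant(W, logarithm = TRUE)
  ldT <- determinant(Tm, logarithm = TRUE)
  if (ldW$sign <= 0 || ldT$sign <= 0 || !is.finite(ldW$modulus) || !is.finite(ldT$modulus))
    stop_with_class("singular within-group scatter; candidate must be skipped",
                    "dosig_singular")
  lam <- exp(as.numeric(ldW$modulus - ldT$modulus))
  min(lam, 1)
}

#' Partial-F test for entering one feature
#'
#' Tests the improvement in Wilks' lambda from adding the latest feature:
#' with partial lambda = lambda_new / lambda_old,
#' F = ((1 - L) / L) * (N - g - p + 1) / (g - 1) on (g - 1, N - g - p + 1)
#' degrees of freedom, where `p_after` features are in the model after
#' entry and g is the number of groups (2 here).
#'
#' @param lambda_new Overall lambda with the candidate included.
#' @param lambda_old Overall lambda before (1 for the first entry).
#' @param N Number of samples. @param g Number of groups.
#' @param p_after Number of features in the model after the entry.
#' @return List with `F`, `p`, `df1`, `df2`. Raises class
#'   `dosig_df_exhausted` when `df2 <= 0` (selection must stop).
#' @export
partial_f_enter <- function(lambda_new, lambda_old, N, g = 2, p_after = 1) {
  if (!(lambda_new > 0 && lambda_new <= lambda_old + 1e-12 && lambda_old <= 1))
    stop("need 0 < lambda_new <= lambda_old <= 1")
  df1 <- g - 1
  df2 <- N - g - p_after + 1
  if (df2 <= 0)
    stop_with_class("no residual degrees of freedom; selection must stop",
                    "dosig_df_exhausted")
  Lp <- min(lambda_new / lambda_old, 1)
  Fst <- (1 - Lp) / Lp * df2 / df1
  list(F = Fst, p = stats::pf(Fst, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Greedy forward selection under Wilks' lambda
#'
#' Iteratively enters the candidate that minimizes the overall lambda (ties:
#' larger partial F, then lexicographic gene id). Stops when the best
#' candidate's entry p-value exceeds `niveau`, when residual degrees of
#' freedom are exhausted, or when candidates run out. Collinear candidates
#' (singular within-scatter) are skipped with a warning.
#'
#' @param X Numeric matrix, samples x candidate features, with feature
#'   colnames.
#' @param labels Two-class vector per sample.
#' @param niveau Entry threshold on the inclusion p-value.
#' @return A `selection_trace`: list with `steps` (data.frame `step_index`,
#'   `gene_id`, `lambda_overall`, `partial_F`, `p_enter`), `niveau_used`,
#'   and `converged` (`FALSE` only when no feature could enter at step 1).
#' @export
greedy_forward_select <- function(X, labels, niveau) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs feature colnames")
  labels <- as.character(labels)
  if (ncol(X) < 2) stop("need at least 2 candidate features")
  if (min(table(labels)) < 2) stop("both classes need >= 2 samples")
  N <- nrow(X); g <- 2L
  selected <- character()
  lambda_old <- 1
  steps <- list()
  skipped <- character()
  repeat {
    cands <- sort(setdiff(colnames(X), selected))
    if (!length(cands)) break
    p_after <- length(selected) + 1L
    best <- NULL
    for (cand in cands) {
      lam <- tryCatch(wilks_lambda(X[, c(selected, cand), drop = FALSE], labels),
                      dosig_singular = function(e) NA_real_)
      if (is.na(lam)) { skipped <- c(skipped, cand); next }
      if (is.null(best) || lam < best$lambda - 1e-12) best <- list(gene = cand, lambda = lam)
      # ties at equal lambda resolve to the first (lexicographically
      # smallest) candidate; partial F is identical at equal lambda
    }
    if (is.null(best)) break
    ft <- tryCatch(partial_f_enter(best$lambda, lambda_old, N, g, p_after),
                   dosig_df_exhausted = function(e) NULL)
    if (is.null(ft)) break
    if (ft$p > niveau) break
    selected <- c(selected, best$gene)
    steps[[p_after]] <- data.frame(step_index = p_after, gene_id = best$gene,
                                   lambda_overall = best$lambda,
                                   partial_F = ft$F, p_enter = ft$p,
                                   stringsAsFactors = FALSE)
    lambda_old <- best$lambda
  }
  if (length(unique(skipped)))
    warning("skipped collinear candidate(s): ",
            paste(unique(skipped), collapse = ", "))
  steps <- if (length(steps)) do.call(rbind, steps)
           else data.frame(step_index = integer(), gene_id = character(),
                           lambda_overall = numeric(), partial_F = numeric(),
                           p_enter = numeric(), stringsAsFactors = FALSE)
  structure(list(steps = steps, niveau_used = niveau,
                 converged = nrow(steps) > 0),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: %d feature(s) entered at niveau %.3g%s\n",
              nrow(x$steps), x$niveau_used,
              if (x$converged) "" else " (no admissible feature)"))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Adaptive niveau trimming loop
#'
#' Runs [greedy_forward_select()] at `niveau_init`; whenever some entered
#' feature's inclusion p-value exceeds 0.05, the niveau is lowered by `step`
#' and selection is rerun, down to `niveau_floor`. The loop returns the last
#' non-empty selection, so every retained feature enters at p <= 0.05 when
#' the loop converges.
#'
#' @inheritParams greedy_forward_select
#' @param niveau_init Starting entry threshold (default 0.1).
#' @param niveau_floor Final threshold all entries must meet (default 0.05).
#' @param step Arithmetic reduction per iteration (default 0.01).
#' @return List with `genes` (selected feature ids, entry order) and
#'   `trace` (the final `selection_trace`).
#' @export
trimming_loop <- function(X, labels, niveau_init = 0.1, niveau_floor = 0.05,
                          step = 0.01) {
  stopifnot(niveau_init >= niveau_floor, step > 0)
  niveau <- niveau_init
  last <- NULL
  repeat {
    tr <- greedy_forward_select(X, labels, niveau)
    if (nrow(tr$steps)) last <- tr
    if (nrow(tr$steps) && all(tr$steps$p_enter <= niveau_floor)) break
    niveau <- niveau - step
    if (niveau < niveau_floor - 1e-12) break
  }
  if (is.null(last)) stop("no discriminative set found at any niveau")
  list(genes = last$steps$gene_id, trace = last)
}

#' Write a selection trace to TSV (with a JSON header line)
#'
#' @param trace A `selection_trace`. @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection_trace <- function(trace, path) {
  hdr <- jsonlite::toJSON(list(niveau_used = trace$niveau_used,
                               converged = trace$converged),
                          auto_unbox = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.table(trace$steps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
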