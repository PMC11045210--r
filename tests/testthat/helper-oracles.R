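# Independent oracles used across the suite. Each re-derives a quantity by
# brute force or through an unrelated library routine, never through the
# code path it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact two-sided Mann-Whitney p by full enumeration of all group
# assignments of the pooled sample (no ties assumed).
mw_enum_p <- function(a, b) {
  comb <- c(a, b)
  na <- length(a)
  r <- rank(comb)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(length(comb), na)
  Us <- apply(splits, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# Hypergeometric upper tail by direct binomial-coefficient arithmetic.
hyper_enum_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Anderson-Darling A2*, and p via the case-based approximation for
# estimated parameters, computed from the raw formula.
ad_formula <- function(x) {
  n <- length(x)
  w <- sort((x - mean(x)) / stats::sd(x))
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (stats::pnorm(w, log.p = TRUE) +
                                   stats::pnorm(rev(w), lower.tail = FALSE, log.p = TRUE)))
  A <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (A <= 0.2) 1 - exp(-13.436 + 101.14 * A - 223.73 * A^2)
  else if (A <= 0.34) 1 - exp(-8.318 + 42.796 * A - 59.938 * A^2)
  else if (A < 0.6) exp(0.9177 - 4.279 * A - 1.38 * A^2)
  else exp(1.2937 - 5.709 * A + 0.0186 * A^2)
  list(A2star = A, p = p)
}

# Wilks' lambda through an unrelated route: one-way ANOVA sum-of-squares
# ratio for a single feature, summary.manova for several.
oracle_lambda <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (ncol(X) == 1) {
    a <- stats::anova(stats::lm(X[, 1] ~ y))
    a["Residuals", "Sum Sq"] / sum(a[, "Sum Sq"])
  } else {
    sm <- summary(stats::manova(X ~ y), test = "Wilks")
    unname(sm$stats[1, "Wilks"])
  }
}

# Stepwise selection replayed with oracle_lambda and the same entry rule;
# independent of wilks_lambda / greedy_forward_select internals.
oracle_forward_select <- function(X, y, niveau) {
  X <- as.matrix(X)
  N <- nrow(X)
  selected <- character()
  lam_old <- 1
  repeat {
    cands <- sort(setdiff(colnames(X), selected))
    if (!length(cands)) break
    p_after <- length(selected) + 1L
    df2 <- N - 2 - p_after + 1
    if (df2 <= 0) break
    lams <- vapply(cands, function(g)
      oracle_lambda(X[, c(selected, g), drop = FALSE], y), numeric(1))
    best <- which.min(lams)  # sorted candidates: lexicographic tie-break
    Lp <- lams[best] / lam_old
    Fs <- (1 - Lp) / Lp * df2
    if (stats::pf(Fs, 1, df2, lower.tail = FALSE) > niveau) break
    selected <- c(selected, cands[best])
    lam_old <- lams[best]
  }
  selected
}

# Small two-class dataset helpers
toy_dataset <- function(values, n_tumor, scale = "log2") {
  n <- ncol(values)
  labels <- rep(c("tumor", "normal"), c(n_tumor, n - n_tumor))
  expression_dataset(values, labels, scale)
}

random_gene_matrix <- function(n_samples, genes, seed) {
  set.seed(seed)
  matrix(rnorm(n_samples * length(genes)), n_samples,
         dimnames = list(NULL, genes))
}
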