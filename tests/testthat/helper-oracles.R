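# Independent oracle implementations used to cross-check the package.
# Each deliberately takes a different computational route than the code
# under test (enumeration, closed forms, or an unrelated fitting library).

# brute-force evaluation of the soft transcript filter, rule by rule
oracle_filter_keep <- function(counts, gene, n_allow, min_count, min_prop) {
  keep <- character(0)
  for (tx in rownames(counts)) {
    g <- gene[match(tx, rownames(counts))]
    totals <- colSums(counts[gene == g, , drop = FALSE])
    fails_count <- 0; fails_prop <- 0
    for (s in colnames(counts)) {
      if (counts[tx, s] < min_count) fails_count <- fails_count + 1
      u <- if (totals[s] > 0) counts[tx, s] / totals[s] else NA
      if (is.na(u) || u < min_prop) fails_prop <- fails_prop + 1
    }
    if (fails_count <= n_allow && fails_prop <= n_allow) keep <- c(keep, tx)
  }
  keep
}

# closed-testing Shaffer oracle: with >= 2 non-null transcripts in a gene
# showing DTU, at most K - 2 nulls can hold; adjusted p for transcript t is
# the max Bonferroni local p over all admissible null sets containing t
oracle_shaffer <- function(p) {
  K <- length(p)
  stopifnot(K >= 3)
  vapply(seq_len(K), function(t) {
    best <- 0
    for (s in seq_len(K - 2)) {
      subs <- utils::combn(K, s)
      for (j in seq_len(ncol(subs))) {
        S <- subs[, j]
        if (t %in% S) best <- max(best, min(1, s * min(p[S])))
      }
    }
    best
  }, numeric(1))
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fisher2x2 <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  xs <- max(0, n1 - m2):min(n1, m1)
  probs <- stats::dhyper(xs, m1, m2, n1)
  pobs <- stats::dhyper(a, m1, m2, n1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# upper-tail hypergeometric by explicit tail summation
oracle_hyper_upper <- function(overlap, n_hits, n_universe, set_size) {
  xs <- overlap:min(n_hits, set_size)
  sum(stats::dhyper(xs, n_hits, n_universe - n_hits, set_size))
}

# chi-square upper tail for even df via the closed-form series
oracle_chisq_upper_even <- function(x, df) {
  m <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(m - 1)) / factorial(0:(m - 1)))
}

# multinomial-logit likelihood-ratio p-value via nnet (independent fitter)
oracle_multinom_p <- function(Y, X) {
  df <- as.data.frame(X[, setdiff(colnames(X), "intercept"), drop = FALSE])
  fit1 <- nnet::multinom(Y ~ ., data = df, trace = FALSE, maxit = 2000)
  df0 <- df[, setdiff(names(df), "condition"), drop = FALSE]
  fit0 <- if (ncol(df0) == 0)
    nnet::multinom(Y ~ 1, data = df, trace = FALSE, maxit = 2000)
  else nnet::multinom(Y ~ ., data = df0, trace = FALSE, maxit = 2000)
  lr <- fit0$deviance - fit1$deviance
  stats::pchisq(lr, df = ncol(Y) - 1, lower.tail = FALSE)
}

# Poisson GLM LRT on independently constructed this-vs-rest long data
oracle_poisson_lrt_p <- function(yk, rest, condition) {
  n <- length(yk)
  d <- data.frame(y = c(yk, rest), this = rep(c(1, 0), each = n),
                  samp = factor(rep(seq_len(n), 2)),
                  cond = rep(condition, 2))
  f1 <- stats::glm(y ~ 0 + samp + this + this:cond, data = d, family = stats::poisson())
  f0 <- stats::glm(y ~ 0 + samp + this, data = d, family = stats::poisson())
  stats::pchisq(f0$deviance - f1$deviance, df = 1, lower.tail = FALSE)
}

# independent greedy kappa clustering (recursive, recomputes everything
# from scratch each step; no shared code with cluster_pathways)
oracle_cluster <- function(sets, threshold, universe) {
  clusters <- lapply(names(sets), identity)
  repeat {
    if (length(clusters) < 2) return(clusters)
    pairs <- utils::combn(length(clusters), 2)
    stats_ <- apply(pairs, 2, function(ij) {
      gi <- unique(unlist(sets[clusters[[ij[1]]]]))
      gj <- unique(unlist(sets[clusters[[ij[2]]]]))
      c(kappa = kappa_sets(gi, gj, universe),
        size = length(union(gi, gj)))
    })
    ord <- order(-stats_["kappa", ], stats_["size", ],
                 apply(pairs, 2, function(ij)
                   min(c(clusters[[ij[1]]], clusters[[ij[2]]]))))
    top <- ord[1]
    if (stats_["kappa", top] <= threshold) return(clusters)
    i <- pairs[1, top]; j <- pairs[2, top]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[-c(i, j)], list(merged))
  }
}
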