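# small in-code fixtures and generators shared across test files

make_annotation <- function(tx, gene, biotype = NULL, chromosome = NULL) {
  data.frame(transcript_id = tx, gene_id = gene, gene_name = gene,
             biotype = if (is.null(biotype)) "protein_coding" else biotype,
             chromosome = if (is.null(chromosome)) "1" else chromosome)
}

make_samples <- function(n_control, n_case, seed = 1) {
  set.seed(seed)
  n <- n_control + n_case
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             condition = rep(c("control", "case"), c(n_control, n_case)),
             RIN = round(runif(n, 5, 9), 1),
             age = sample(55:90, n, replace = TRUE),
             sex = sample(c("F", "M"), n, replace = TRUE),
             cohort = "test")
}

# random tx_counts for property tests
random_tx_counts <- function(n_genes = 6, max_k = 4, n_samples = 8, seed = 1) {
  set.seed(seed)
  K <- sample(1:max_k, n_genes, replace = TRUE)
  gene <- rep(sprintf("g%02d", seq_len(n_genes)), K)
  tx <- paste0(gene, ".t", unlist(lapply(K, seq_len)))
  m <- matrix(rpois(length(tx) * n_samples, lambda = 40),
              nrow = length(tx),
              dimnames = list(tx, sprintf("s%02d", seq_len(n_samples))))
  tx_counts(m, make_annotation(tx, gene))
}

# one gene's counts (samples x transcripts) drawn from a DM with
# group-specific softmax proportions; used for fit/test checks
gen_dm_gene <- function(n_control, n_case, base_logit, case_shift = 0,
                        total = 500, gamma = Inf, seed = 1) {
  set.seed(seed)
  K <- length(base_logit)
  n <- n_control + n_case
  cond <- rep(c(0, 1), c(n_control, n_case))
  Y <- matrix(0L, n, K, dimnames = list(NULL, paste0("t", seq_len(K))))
  shift <- if (length(case_shift) == 1) c(case_shift, rep(0, K - 1)) else case_shift
  for (i in seq_len(n)) {
    lp <- base_logit + cond[i] * shift
    p <- exp(lp - max(lp)); p <- p / sum(p)
    if (is.finite(gamma)) {
      x <- rgamma(K, shape = gamma * p, rate = 1)
      p <- x / sum(x)
    }
    Y[i, ] <- rmultinom(1, total, p)
  }
  list(Y = Y, design = cbind(intercept = 1, condition = cond))
}
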