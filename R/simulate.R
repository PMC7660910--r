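## Seeded simulator for transcript-level count matrices with known DTU
## structure. Gene totals are negative binomial (log-normal gene means times
## log-normal library factors, optionally shifted by a gene-level DGE
## effect); the per-sample transcript split is Dirichlet-multinomial around
## group-specific proportions. DTU genes carry a paired isoform switch: a
## +delta / -delta perturbation of the two affected transcripts'
## log-abundances, renormalised within the pair so that the pair's combined
## share -- and hence every other transcript's expected usage -- is exactly
## unchanged. The realised per-transcript usage effects (on the
## transcript-vs-rest log-odds scale, the scale the estimators report) are
## recorded in the truth table alongside the nominal signed delta.

#' Simulation configuration
#'
#' Defaults emulate an rRNA-depleted bulk brain RNA-seq case-control cohort
#' sized like a small post-mortem study (17 cases / 11 controls), with
#' moderate Dirichlet-multinomial overdispersion and a 10% fraction of
#' genes carrying an isoform switch.
#'
#' @param n_genes number of genes.
#' @param tx_per_gene_probs categorical distribution of transcripts per gene
#'   over 2..10 (named or positional; normalised internally).
#' @param n_control,n_case per-group sample sizes.
#' @param dirichlet_a0 symmetric Dirichlet concentration for baseline
#'   proportions.
#' @param gamma DM precision of the transcript split (`Inf` = multinomial).
#' @param gene_mean_log,gene_mean_sdlog log-normal parameters of the gene
#'   expression mean.
#' @param libsize_sdlog log-normal sd of the per-sample library factor.
#' @param nb_size negative-binomial size of the gene totals.
#' @param frac_dtu fraction of genes carrying a DTU effect.
#' @param delta usage effect magnitude (log scale, applied as +delta and
#'   -delta to the affected pair).
#' @param dge_lfc gene-level log-fold change applied to DTU genes' totals in
#'   cases (default 0: pure isoform switches).
#' @param rin_effect,age_effect,sex_effect,cell_effect covariate effect
#'   sizes on the usage logits (default 0).
#' @param cell_shift mean shift of the two cell-type scores in cases.
#' @param biotype_freq named biotype frequency table for annotation labels.
#' @param cohort cohort label written to the sample table.
#' @param seed integer seed; all draws derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 500,
                       tx_per_gene_probs = c(`2` = 0.30, `3` = 0.22,
                                             `4` = 0.16, `5` = 0.11,
                                             `6` = 0.08, `7` = 0.05,
                                             `8` = 0.04, `9` = 0.02,
                                             `10` = 0.02),
                       n_control = 11, n_case = 17,
                       dirichlet_a0 = 2, gamma = 50,
                       gene_mean_log = log(500), gene_mean_sdlog = 1,
                       libsize_sdlog = 0.3, nb_size = 10,
                       frac_dtu = 0.1, delta = 1, dge_lfc = 0,
                       rin_effect = 0, age_effect = 0, sex_effect = 0,
                       cell_effect = 0, cell_shift = 0,
                       biotype_freq = c(protein_coding = 0.45,
                                        processed_transcript = 0.15,
                                        retained_intron = 0.15,
                                        nonsense_mediated_decay = 0.08,
                                        antisense = 0.07,
                                        lincRNA = 0.05,
                                        pseudogene = 0.05),
                       cohort = "simulated", seed = 1L) {
  stopifnot(n_genes >= 1, n_control >= 2, n_case >= 2,
            frac_dtu >= 0, frac_dtu <= 1,
            dirichlet_a0 > 0, gamma > 0, nb_size > 0,
            all(tx_per_gene_probs >= 0), sum(tx_per_gene_probs) > 0,
            all(biotype_freq >= 0))
  structure(as.list(environment()), class = "sim_config")
}

sub_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# +delta/-delta on log-abundance of the pair (up, down), pair share kept
switch_pair <- function(p, up, down, delta) {
  s <- p[up] + p[down]
  w_up <- p[up] * exp(delta)
  w_dn <- p[down] * exp(-delta)
  p2 <- p
  p2[up] <- s * w_up / (w_up + w_dn)
  p2[down] <- s * w_dn / (w_up + w_dn)
  p2
}

#' Simulate a transcript count matrix with known DTU structure
#'
#' @param config a [sim_config] object.
#' @return list with `counts` (a [tx_counts]), `samples` (sample table),
#'   `annotation`, and `truth` -- a list of `gene` (gene_id, dtu, tx_up,
#'   tx_down, delta, dge_lfc) and `transcript` (transcript_id, gene_id,
#'   `effect` = realised condition effect on the transcript-vs-rest
#'   log-odds usage scale, 0 for null transcripts).
#' @export
simulate_dtu <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- cf$n_control + cf$n_case

  set.seed(sub_seed(cf$seed, "samples"))
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    condition = rep(c("control", "case"), c(cf$n_control, cf$n_case)),
    RIN = pmin(10, pmax(3, stats::rnorm(n, 7, 1))),
    age = round(stats::rnorm(n, 72, 8)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cohort = cf$cohort)
  cond <- as.numeric(samples$condition == "case")
  samples$oligo_score <- stats::rnorm(n) + cf$cell_shift * cond
  samples$micro_score <- stats::rnorm(n) + cf$cell_shift * cond
  lib <- exp(stats::rnorm(n, 0, cf$libsize_sdlog))

  set.seed(sub_seed(cf$seed, "genes"))
  kk <- as.integer(names(cf$tx_per_gene_probs))
  if (is.null(names(cf$tx_per_gene_probs))) kk <- seq(2, length.out = length(cf$tx_per_gene_probs))
  K <- kk[sample.int(length(kk), cf$n_genes, replace = TRUE,
                     prob = cf$tx_per_gene_probs / sum(cf$tx_per_gene_probs))]
  gene_id <- sprintf("g%05d", seq_len(cf$n_genes))
  gene_mean <- exp(stats::rnorm(cf$n_genes, cf$gene_mean_log,
                                cf$gene_mean_sdlog))
  is_dtu <- seq_len(cf$n_genes) <= round(cf$frac_dtu * cf$n_genes)

  tx_id <- unlist(lapply(seq_len(cf$n_genes), function(g)
    sprintf("%s.t%d", gene_id[g], seq_len(K[g]))))
  tx_gene <- rep(gene_id, K)
  annotation <- data.frame(
    transcript_id = tx_id, gene_id = tx_gene, gene_name = tx_gene,
    biotype = sample(names(cf$biotype_freq), length(tx_id), replace = TRUE,
                     prob = cf$biotype_freq),
    chromosome = as.character(rep(sample(1:22, cf$n_genes, replace = TRUE), K)))

  set.seed(sub_seed(cf$seed, "effects"))
  baseline <- lapply(seq_len(cf$n_genes), function(g)
    rdirichlet1(rep(cf$dirichlet_a0, K[g])))
  truth_gene <- data.frame(gene_id = gene_id, dtu = is_dtu,
                           tx_up = NA_character_, tx_down = NA_character_,
                           delta = 0, dge_lfc = 0)
  case_p <- baseline
  tx_effect <- stats::setNames(rep(0, length(tx_id)), tx_id)
  for (g in which(is_dtu)) {
    pair <- sample(seq_len(K[g]), 2)
    # increase the minor isoform: keeps case proportions well inside the simplex
    up <- pair[which.min(baseline[[g]][pair])]
    down <- setdiff(pair, up)
    case_p[[g]] <- switch_pair(baseline[[g]], up, down, cf$delta)
    ids <- sprintf("%s.t%d", gene_id[g], seq_len(K[g]))
    truth_gene$tx_up[g] <- ids[up]
    truth_gene$tx_down[g] <- ids[down]
    truth_gene$delta[g] <- cf$delta
    truth_gene$dge_lfc[g] <- cf$dge_lfc
    tx_effect[ids[up]] <- stats::qlogis(case_p[[g]][up]) -
      stats::qlogis(baseline[[g]][up])
    tx_effect[ids[down]] <- stats::qlogis(case_p[[g]][down]) -
      stats::qlogis(baseline[[g]][down])
  }

  cov_load <- NULL
  cov_sum <- cf$rin_effect * scale(samples$RIN)[, 1] +
    cf$age_effect * scale(samples$age)[, 1] +
    cf$sex_effect * (as.numeric(factor(samples$sex)) - 1) +
    cf$cell_effect * (samples$oligo_score + samples$micro_score) / 2
  has_cov <- any(abs(cov_sum) > 0)
  if (has_cov)
    cov_load <- lapply(seq_len(cf$n_genes), function(g)
      sample(seq_len(K[g]), 1))

  set.seed(sub_seed(cf$seed, "counts"))
  counts <- matrix(0, nrow = length(tx_id), ncol = n,
                   dimnames = list(tx_id, samples$sample_id))
  row0 <- c(0, cumsum(K))
  for (g in seq_len(cf$n_genes)) {
    mu <- gene_mean[g] * lib * exp(truth_gene$dge_lfc[g] * cond)
    tot <- stats::rnbinom(n, size = cf$nb_size, mu = mu)
    for (i in seq_len(n)) {
      p <- if (cond[i] == 1) case_p[[g]] else baseline[[g]]
      if (has_cov && cov_sum[i] != 0) {
        lp <- log(pmax(p, 1e-12))
        lp[cov_load[[g]]] <- lp[cov_load[[g]]] + cov_sum[i]
        p <- exp(lp - max(lp)); p <- p / sum(p)
      }
      pp <- if (is.finite(cf$gamma)) rdirichlet1(cf$gamma * p) else p
      counts[(row0[g] + 1):row0[g + 1], i] <-
        stats::rmultinom(1, tot[i], pp)
    }
  }

  truth_tx <- data.frame(transcript_id = tx_id, gene_id = tx_gene,
                         effect = unname(tx_effect[tx_id]))
  list(counts = tx_counts(counts, annotation),
       samples = validate_samples(samples),
       annotation = annotation,
       truth = list(gene = truth_gene, transcript = truth_tx))
}

binom_se <- function(p, n) if (n > 0) sqrt(p * (1 - p) / n) else NA_real_

#' Evaluate DTU calls against simulation ground truth
#'
#' @param stage a `stage_result` from [stagewise_dtu()] on simulated data.
#' @param truth the `truth` element returned by [simulate_dtu()].
#' @param alpha nominal level used for the transcript type-I error rate
#'   (default 0.05).
#' @return list of metrics, each with a binomial standard error where
#'   defined: gene-level `fdr` and `power`, `tx_type1` (fraction of
#'   truly-null transcripts with nominal p <= alpha), `fwer_within`
#'   (fraction of screened true-DTU genes with any truly-null transcript
#'   confirmed), and -- when `stage` carries an `effect_size` column --
#'   `effect_bias` and `effect_rmse` over the affected transcripts.
#' @export
evaluate_calls <- function(stage, truth, alpha = 0.05) {
  if (!all(stage$transcript_id %in% truth$transcript$transcript_id))
    stop("stage result contains transcripts unknown to the truth table")
  calls <- call_events(stage)
  true_genes <- truth$gene$gene_id[truth$gene$dtu]
  called <- calls$genes
  tp <- sum(called %in% true_genes)
  fdr <- if (length(called)) (length(called) - tp) / length(called) else NA_real_
  power <- if (length(true_genes)) tp / length(true_genes) else NA_real_

  eff <- truth$transcript$effect[match(stage$transcript_id,
                                       truth$transcript$transcript_id)]
  is_null_tx <- eff == 0
  tested_null <- is_null_tx & !is.na(stage$pvalue)
  tx_type1 <- if (any(tested_null))
    mean(stage$pvalue[tested_null] <= alpha) else NA_real_

  scr_true <- intersect(unique(stage$gene_id[stage$screened]), true_genes)
  fwer <- if (length(scr_true)) {
    bad <- vapply(scr_true, function(g) {
      i <- stage$gene_id == g
      any(stage$confirmed[i] & is_null_tx[i])
    }, logical(1))
    mean(bad)
  } else NA_real_

  out <- list(
    fdr = c(value = fdr, se = binom_se(fdr, length(called))),
    power = c(value = power, se = binom_se(power, length(true_genes))),
    tx_type1 = c(value = tx_type1, se = binom_se(tx_type1, sum(tested_null))),
    fwer_within = c(value = fwer, se = binom_se(fwer, length(scr_true))),
    n_called_genes = length(called), n_true_genes = length(true_genes),
    n_screened_true = length(scr_true))
  if ("effect_size" %in% names(stage)) {
    aff <- which(eff != 0 & !is.na(stage$effect_size))
    if (length(aff)) {
      err <- stage$effect_size[aff] - eff[aff]
      out$effect_bias <- mean(err)
      out$effect_rmse <- sqrt(mean(err^2))
    }
  }
  out
}
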