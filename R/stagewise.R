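## Two-stage error control for DTU: Benjamini-Hochberg screening of
## gene-level p-values, then within-gene confirmation of transcripts with a
## Shaffer-modified Holm procedure exploiting the DTU logical constraint
## that a gene with any differential usage must have at least two non-null
## transcripts (usage proportions sum to one, so a change in one transcript
## forces a compensating change elsewhere). At most K - 2 null hypotheses
## can therefore be true in a screened gene, capping the Holm multipliers at
## K - 2: m_j = max(1, min(K - j + 1, K - 2)) for the j-th smallest p.

#' Stage 1: screen genes by Benjamini-Hochberg FDR
#'
#' @param pvalues named numeric vector of gene-level p-values.
#' @param alpha screening level (default 0.05).
#' @return data.frame with `gene_id`, `pvalue`, `qvalue` (BH-adjusted) and
#'   `screened` (`qvalue <= alpha`).
#' @export
screen_genes <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues))
    return(data.frame(gene_id = character(), pvalue = numeric(),
                      qvalue = numeric(), screened = logical()))
  q <- stats::p.adjust(pvalues, method = "BH")
  data.frame(gene_id = if (is.null(names(pvalues)))
               as.character(seq_along(pvalues)) else names(pvalues),
             pvalue = unname(pvalues), qvalue = unname(q),
             screened = unname(q <= alpha))
}

#' Stage 2: within-gene Shaffer-Holm confirmation of transcripts
#'
#' Orders the gene's transcript p-values, applies the step-down multipliers
#' `m_j = max(1, min(K - j + 1, K - 2))` with a running maximum
#' (`adjusted p_(j) = min(1, cummax(m_j * p_(j)))`), and confirms transcripts
#' with adjusted p strictly below `alpha`. For K = 2 the compositional
#' constraint makes the two transcripts a logical pair: if either is
#' confirmed both are, and the compensating transcript inherits the smaller
#' adjusted p. Ties in p are broken by transcript id for determinism.
#' Missing p-values are treated as 1.
#'
#' @param pvalues numeric vector of the gene's transcript p-values, named by
#'   transcript id.
#' @param alpha confirmation level (default 0.05).
#' @return data.frame with `transcript_id`, `pvalue`, `p_adj_within`,
#'   `confirmed`, in the input order.
#' @export
confirm_transcripts <- function(pvalues, alpha = 0.05) {
  K <- length(pvalues)
  if (K < 2L) stop("confirmation needs at least two transcripts")
  ids <- names(pvalues)
  if (is.null(ids)) ids <- as.character(seq_len(K))
  p <- ifelse(is.na(pvalues), 1, pvalues)
  ord <- order(p, ids)
  m <- pmax(1, pmin(K - seq_len(K) + 1L, K - 2L))
  adj_sorted <- pmin(1, cummax(m * p[ord]))
  adj <- numeric(K)
  adj[ord] <- adj_sorted
  if (K == 2L && any(adj < alpha)) adj[] <- min(adj)
  data.frame(transcript_id = ids, pvalue = unname(pvalues),
             p_adj_within = adj, confirmed = adj < alpha)
}

#' Two-stage DTU significance over full result tables
#'
#' Combines [screen_genes()] and [confirm_transcripts()]: transcripts of
#' genes that fail screening are never assessed (their adjusted p is `NA`
#' and they cannot be confirmed).
#'
#' @param gene_results data.frame with columns `gene_id`, `pvalue`.
#' @param transcript_results data.frame with columns `transcript_id`,
#'   `gene_id`, `pvalue` (and optionally `effect_size`, carried through).
#' @param alpha significance level for both stages (default 0.05).
#' @return a `stage_result` data.frame with one row per transcript: gene and
#'   transcript ids, `gene_pvalue`, `gene_qvalue`, `screened`, `pvalue`,
#'   `p_adj_within`, `confirmed`, plus carried-through columns.
#' @export
stagewise_dtu <- function(gene_results, transcript_results, alpha = 0.05) {
  stopifnot(all(c("gene_id", "pvalue") %in% names(gene_results)),
            all(c("transcript_id", "gene_id", "pvalue") %in%
                  names(transcript_results)))
  gp <- stats::setNames(gene_results$pvalue, gene_results$gene_id)
  scr <- screen_genes(gp, alpha)
  tr <- transcript_results
  tr$gene_pvalue <- gp[tr$gene_id]
  tr$gene_qvalue <- scr$qvalue[match(tr$gene_id, scr$gene_id)]
  tr$screened <- scr$screened[match(tr$gene_id, scr$gene_id)]
  tr$screened[is.na(tr$screened)] <- FALSE
  tr$p_adj_within <- NA_real_
  tr$confirmed <- FALSE
  for (g in unique(tr$gene_id[tr$screened])) {
    idx <- which(tr$gene_id == g)
    if (length(idx) < 2L) next
    conf <- confirm_transcripts(
      stats::setNames(tr$pvalue[idx], tr$transcript_id[idx]), alpha)
    tr$p_adj_within[idx] <- conf$p_adj_within
    tr$confirmed[idx] <- conf$confirmed
  }
  class(tr) <- c("stage_result", class(tr))
  tr
}

#' Call DTU events and DTU genes from a stage-wise result
#'
#' A DTU event is a confirmed transcript (within-gene FWER-adjusted
#' p < alpha in a screened gene); a DTU gene is any gene with at least one
#' event.
#'
#' @param stage a `stage_result` from [stagewise_dtu()].
#' @return list with `events` (transcript ids), `genes` (gene ids),
#'   `events_per_gene` (named integer vector over DTU genes), and
#'   `histogram` (table of the events-per-gene distribution).
#' @export
call_events <- function(stage) {
  ev <- stage$transcript_id[stage$confirmed]
  per_gene <- table(stage$gene_id[stage$confirmed])
  list(events = ev,
       genes = names(per_gene),
       events_per_gene = stats::setNames(as.integer(per_gene),
                                         names(per_gene)),
       histogram = table(as.integer(per_gene)))
}
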