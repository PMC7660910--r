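## Downstream characterisation of DTU calls: cross-cohort replication
## concordance, overlap with a conventional gene-level DGE analysis, and
## biotype overrepresentation.

sign_agreement <- function(a, b) {
  # exactly-zero effects count as disagreement (conservative)
  ok <- sign(a) == sign(b) & a != 0 & b != 0
  100 * mean(ok)
}

cor_or_na <- function(a, b) {
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Cross-cohort replication concordance of DTU effect sizes
#'
#' Partitions the transcripts common to a discovery and a replication result
#' set into four categories by nominal significance (`p <= alpha`) in each
#' cohort -- neither / discovery-only / both / replication-only -- and
#' reports, per category, the transcript count, the Pearson correlation of
#' effect sizes and the percentage of transcripts whose effect sizes agree
#' in sign. If the discovery table has a logical `event` column the same
#' quantities are also computed on the discovery DTU-event subset.
#'
#' @param discovery,replication data.frames with columns `transcript_id`,
#'   `effect_size`, `pvalue` (discovery may add a logical `event` column).
#' @param alpha nominal significance level (default 0.05).
#' @return list with `categories` (one row per category) and, when
#'   available, `events` (the discovery-event subset summary).
#' @export
replication_concordance <- function(discovery, replication, alpha = 0.05) {
  common <- intersect(discovery$transcript_id, replication$transcript_id)
  if (length(common) < 2)
    stop("fewer than two transcripts shared between discovery and ",
         "replication results")
  d <- discovery[match(common, discovery$transcript_id), ]
  r <- replication[match(common, replication$transcript_id), ]
  sig_d <- !is.na(d$pvalue) & d$pvalue <= alpha
  sig_r <- !is.na(r$pvalue) & r$pvalue <= alpha
  cat_of <- ifelse(sig_d & sig_r, "both",
            ifelse(sig_d, "discovery-only",
            ifelse(sig_r, "replication-only", "neither")))
  lvls <- c("neither", "discovery-only", "both", "replication-only")
  rows <- lapply(lvls, function(cc) {
    i <- cat_of == cc
    data.frame(category = cc, n = sum(i),
               pearson_r = if (sum(i)) cor_or_na(d$effect_size[i],
                                                 r$effect_size[i]) else NA_real_,
               pct_sign_agree = if (sum(i)) sign_agreement(d$effect_size[i],
                                                           r$effect_size[i])
                                else NA_real_)
  })
  out <- list(categories = do.call(rbind, rows))
  if ("event" %in% names(discovery)) {
    i <- d$event %in% TRUE
    out$events <- data.frame(
      n = sum(i),
      pearson_r = cor_or_na(d$effect_size[i], r$effect_size[i]),
      pct_sign_agree = if (sum(i)) sign_agreement(d$effect_size[i],
                                                  r$effect_size[i]) else NA_real_)
  }
  out
}

#' Overlap DTU events with a gene-level DGE result table
#'
#' Identifies DTU genes that are also significant in an external DGE
#' analysis (`FDR < fdr_threshold`), and for genes with a single DTU event
#' whether the DTU and DGE effects share the direction of change.
#'
#' @param dtu_events data.frame of DTU events with columns `gene_id` (or
#'   `gene`), `transcript_id`, `effect_size`.
#' @param dge data.frame with columns `gene_id` (or `gene`), `effect_size`,
#'   `fdr`.
#' @param fdr_threshold DGE significance cutoff (default 0.05).
#' @return list with `table` (per overlapping gene and event: effect sizes,
#'   `n_events`, `single_event`, `sign_match`) and `summary`
#'   (`n_overlap_genes`, `n_single_event`, `n_single_sign_match`).
#' @export
dge_overlap <- function(dtu_events, dge, fdr_threshold = 0.05) {
  norm_gene <- function(df) {
    if (!"gene_id" %in% names(df) && "gene" %in% names(df))
      names(df)[names(df) == "gene"] <- "gene_id"
    df
  }
  dtu_events <- norm_gene(dtu_events); dge <- norm_gene(dge)
  if (!all(c("gene_id", "effect_size") %in% names(dtu_events)))
    stop("dtu_events needs columns gene_id (or gene) and effect_size")
  if (!all(c("gene_id", "effect_size", "fdr") %in% names(dge)))
    stop("dge needs columns gene_id (or gene), effect_size and fdr")
  sig_dge <- dge[!is.na(dge$fdr) & dge$fdr < fdr_threshold, ]
  overlap_genes <- sort(intersect(unique(dtu_events$gene_id),
                                  unique(sig_dge$gene_id)))
  tab <- dtu_events[dtu_events$gene_id %in% overlap_genes, , drop = FALSE]
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  n_ev <- table(tab$gene_id)
  tab$n_events <- as.integer(n_ev[tab$gene_id])
  tab$single_event <- tab$n_events == 1L
  tab$dge_effect <- sig_dge$effect_size[match(tab$gene_id, sig_dge$gene_id)]
  tab$dge_fdr <- sig_dge$fdr[match(tab$gene_id, sig_dge$gene_id)]
  tab$sign_match <- sign(tab$effect_size) == sign(tab$dge_effect) &
    tab$effect_size != 0 & tab$dge_effect != 0
  rownames(tab) <- NULL
  single <- tab[tab$single_event, ]
  list(table = tab,
       summary = list(
         n_overlap_genes = length(overlap_genes),
         n_single_event = nrow(single),
         n_single_sign_match = sum(single$sign_match)))
}

#' Biotype overrepresentation of DTU events
#'
#' For each transcript biotype, builds the 2x2 table of event membership
#' versus biotype membership over the tested transcript universe and applies
#' a two-sided Fisher exact test; p-values are Bonferroni-adjusted over the
#' number of biotypes tested. The odds ratio is the conditional maximum
#' likelihood estimate (infinite values allowed for degenerate tables).
#'
#' @param events character vector of DTU event transcript ids (must be a
#'   subset of `tested`).
#' @param tested character vector: the tested transcript universe.
#' @param annotation annotation data.frame (see [tx_counts()]).
#' @return data.frame with one row per biotype: counts, `odds_ratio`,
#'   `pvalue`, `p_bonferroni`, sorted by increasing p.
#' @export
biotype_enrichment <- function(events, tested, annotation) {
  if (!all(events %in% tested))
    stop("events must be a subset of the tested transcript universe")
  annotation <- validate_annotation(annotation)
  bt <- annotation$biotype[match(tested, annotation$transcript_id)]
  if (anyNA(bt)) stop("tested transcripts missing from annotation")
  is_event <- tested %in% events
  biotypes <- sort(unique(bt))
  rows <- lapply(biotypes, function(b) {
    in_b <- bt == b
    tab <- matrix(c(sum(is_event & in_b), sum(is_event & !in_b),
                    sum(!is_event & in_b), sum(!is_event & !in_b)),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(biotype = b,
               events_in = tab[1, 1], events_out = tab[1, 2],
               rest_in = tab[2, 1], rest_out = tab[2, 2],
               odds_ratio = unname(ft$estimate), pvalue = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$pvalue * nrow(out))
  out[order(out$pvalue), ]
}
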