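#' Soft expression filter parameters
#'
#' Thresholds for the pre-analysis expression filter. A transcript fails the
#' count criterion in a sample when its count is below `min_count`, and the
#' proportion criterion when its within-gene usage is below `min_prop`; it is
#' removed when it fails either criterion in more than `fail_allowance`
#' samples. `fail_allowance` defaults to the size of the smaller condition
#' group, `min(#controls, #cases)`, and is always recomputed from the sample
#' table -- a "soft" filter that tolerates absence of expression confined to
#' one group (which may itself be the DTU signal).
#'
#' @param min_count minimum per-sample read count for a transcript (default 10).
#' @param min_prop minimum within-gene usage proportion (default 0.01).
#' @param min_gene_count minimum per-sample gene total; genes below it in any
#'   one sample are removed (default 10).
#' @param min_transcripts minimum surviving transcripts per gene (default 2;
#'   usage is undefined for a single transcript).
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_count = 10, min_prop = 0.01,
                          min_gene_count = 10, min_transcripts = 2) {
  stopifnot(min_count > 0, min_prop > 0, min_gene_count > 0,
            min_transcripts >= 1)
  structure(list(min_count = min_count, min_prop = min_prop,
                 min_gene_count = min_gene_count,
                 min_transcripts = min_transcripts),
            class = "filter_params")
}

fail_allowance <- function(samples) {
  samples <- validate_samples(samples)
  n <- table(samples$condition)
  if (any(n == 0L)) stop("both condition groups must be non-empty")
  as.integer(min(n))
}

#' Select transcripts passing the soft expression filter
#'
#' A transcript is dropped iff strictly more than `n = min(#controls, #cases)`
#' samples have its count below `min_count`, OR strictly more than `n` samples
#' have its within-gene usage below `min_prop`. Usage is computed on the
#' unfiltered counts (single-pass filtering). The decision is independent of
#' row and column order.
#'
#' @param x a [tx_counts] object.
#' @param samples validated sample table (supplies the fail allowance).
#' @param params a [filter_params] object.
#' @return character vector of kept transcript ids.
#' @export
filter_transcripts <- function(x, samples, params = filter_params()) {
  stopifnot(inherits(x, "tx_counts"))
  n <- fail_allowance(samples)
  usage <- transcript_usage(x)
  low_count <- rowSums(x$counts < params$min_count)
  # undefined usage (gene total 0) counts as below min_prop: no expression
  low_prop <- rowSums(usage < params$min_prop | is.na(usage))
  keep <- low_count <= n & low_prop <= n
  rownames(x$counts)[keep]
}

#' Select genes passing the gene-level filter
#'
#' A gene is dropped iff its total count (over the transcripts present in the
#' matrix) is below `min_gene_count` in any one sample, or fewer than
#' `min_transcripts` of its transcripts survive in the matrix.
#'
#' @param x a [tx_counts] object (typically already subset to kept
#'   transcripts).
#' @param params a [filter_params] object.
#' @return character vector of kept gene ids.
#' @export
filter_genes <- function(x, params = filter_params()) {
  stopifnot(inherits(x, "tx_counts"))
  gene <- x$annotation$gene_id
  totals <- rowsum(x$counts, gene, reorder = FALSE)
  ok_counts <- rownames(totals)[apply(totals >= params$min_gene_count, 1, all)]
  ntx <- table(gene)
  ok_ntx <- names(ntx)[ntx >= params$min_transcripts]
  intersect(ok_counts, ok_ntx)
}

#' Apply the full expression filter
#'
#' Runs [filter_transcripts()] then [filter_genes()] on the reduced matrix and
#' returns the filtered object together with a [filter_report()].
#'
#' @inheritParams filter_transcripts
#' @return list with elements `counts` (filtered [tx_counts]), `kept_transcripts`,
#'   `kept_genes`, and `report`.
#' @export
dtu_filter <- function(x, samples, params = filter_params()) {
  kept_tx <- filter_transcripts(x, samples, params)
  sub <- subset_tx(x, kept_tx)
  kept_genes <- filter_genes(sub, params)
  sub2 <- subset_tx(sub, rownames(sub$counts)[sub$annotation$gene_id %in% kept_genes])
  list(counts = sub2,
       kept_transcripts = rownames(sub2$counts),
       kept_genes = kept_genes,
       report = filter_report(x, sub2))
}

#' Subset a tx_counts object to a transcript set
#' @param x a [tx_counts] object.
#' @param transcripts character vector of transcript ids to keep.
#' @return a [tx_counts] object.
#' @export
subset_tx <- function(x, transcripts) {
  keep <- rownames(x$counts) %in% transcripts
  tx_counts(x$counts[keep, , drop = FALSE], x$annotation)
}

#' Before/after filtering statistics
#'
#' Summarises the effect of filtering: transcript and gene attrition,
#' medians of per-transcript mean counts and of transcripts-per-gene, and the
#' biotype composition (relative frequencies within each stage).
#'
#' @param before,after [tx_counts] objects; `after`'s transcripts must be a
#'   subset of `before`'s.
#' @return a `filter_report` list.
#' @export
filter_report <- function(before, after) {
  if (!all(rownames(after$counts) %in% rownames(before$counts)))
    stop("'after' must be a transcript subset of 'before'")
  stat <- function(x) {
    list(n_transcripts = nrow(x$counts),
         n_genes = length(unique(x$annotation$gene_id)),
         median_mean_count = stats::median(rowMeans(x$counts)),
         median_tx_per_gene = stats::median(as.numeric(table(x$annotation$gene_id))),
         biotype_freq = prop.table(table(x$annotation$biotype)))
  }
  b <- stat(before); a <- stat(after)
  structure(list(
    before = b, after = a,
    pct_transcripts_removed = 100 * (1 - a$n_transcripts / b$n_transcripts),
    pct_genes_removed = 100 * (1 - a$n_genes / b$n_genes)),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d -> %d transcripts (%.1f%% removed), %d -> %d genes (%.1f%% removed)\n",
    x$before$n_transcripts, x$after$n_transcripts, x$pct_transcripts_removed,
    x$before$n_genes, x$after$n_genes, x$pct_genes_removed))
  cat(sprintf("median mean count %.1f -> %.1f; median transcripts/gene %g -> %g\n",
              x$before$median_mean_count, x$after$median_mean_count,
              x$before$median_tx_per_gene, x$after$median_tx_per_gene))
  invisible(x)
}
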