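## Marker gene profiles (MGPs): relative cellularity scores for bulk-tissue
## samples, computed as the first principal component of cell-type marker
## gene expression. Cell types whose score differs between cases and
## controls are candidate design covariates, guarding DTU tests against
## cell-composition confounding.

#' Read cell-type marker gene lists
#'
#' @param path tab-separated file with columns `cell_type`, `gene_id`.
#' @return named list: cell type -> character vector of marker gene ids.
#' @export
read_markers <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(c("cell_type", "gene_id") %in% names(tab)))
  split(as.character(tab$gene_id), tab$cell_type)
}

#' Compute marker gene profiles
#'
#' Per cell type: the marker genes' expression is CPM-normalised,
#' `log2(CPM + 0.5)`-transformed, gene-centred, and summarised by the first
#' principal component across samples. The component's sign is oriented so
#' that the score correlates positively with the markers' mean expression
#' (higher score = more of that cell type). Cell types with fewer than
#' `min_markers` usable markers, or a zero-variance marker block, are
#' skipped with a warning.
#'
#' @param gene_counts numeric gene x sample count matrix (gene ids as
#'   rownames).
#' @param markers named list of marker gene id vectors (see
#'   [read_markers()]).
#' @param min_markers minimum markers present per cell type (default 3).
#' @return numeric sample x cell-type matrix of MGP scores.
#' @export
compute_mgp <- function(gene_counts, markers, min_markers = 3) {
  gene_counts <- as.matrix(gene_counts)
  if (ncol(gene_counts) < 3L) stop("need at least three samples")
  cpm <- sweep(gene_counts, 2, colSums(gene_counts) / 1e6, `/`)
  logcpm <- log2(cpm + 0.5)
  scores <- list()
  for (ct in names(markers)) {
    mk <- intersect(markers[[ct]], rownames(logcpm))
    if (length(mk) < min_markers) {
      warning("cell type '", ct, "' skipped: fewer than ", min_markers,
              " markers present")
      next
    }
    block <- logcpm[mk, , drop = FALSE]
    centered <- block - rowMeans(block)
    if (all(abs(centered) < 1e-12)) {
      warning("cell type '", ct, "' skipped: zero-variance marker block")
      next
    }
    pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
    s <- pc$x[, 1]
    if (stats::cor(s, colMeans(block)) < 0) s <- -s
    scores[[ct]] <- s
  }
  if (!length(scores)) stop("no usable cell type")
  do.call(cbind, scores)
}

#' Test MGP scores for association with disease status
#'
#' Two-sided Wilcoxon rank-sum test of each cell type's scores between the
#' two condition groups; cell types with `p <= alpha` are selected as design
#' covariates.
#'
#' @param mgp sample x cell-type score matrix from [compute_mgp()], rows
#'   aligned with `samples`.
#' @param samples validated sample table.
#' @param alpha selection level (default 0.05).
#' @return list with `table` (cell_type, statistic, pvalue, selected) and
#'   `selected` (score matrix restricted to the selected cell types, ready
#'   for [build_design()]'s `extra`; `NULL` when none selected).
#' @export
associate_condition <- function(mgp, samples, alpha = 0.05) {
  samples <- validate_samples(samples)
  stopifnot(nrow(mgp) == nrow(samples))
  grp <- samples$condition == levels(samples$condition)[2]
  res <- lapply(colnames(mgp), function(ct) {
    w <- stats::wilcox.test(mgp[grp, ct], mgp[!grp, ct], exact = FALSE)
    data.frame(cell_type = ct, statistic = unname(w$statistic),
               pvalue = w$p.value)
  })
  tab <- do.call(rbind, res)
  tab$selected <- tab$pvalue <= alpha
  sel <- tab$cell_type[tab$selected]
  list(table = tab,
       selected = if (length(sel)) mgp[, sel, drop = FALSE] else NULL)
}
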