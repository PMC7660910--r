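#' Transcript-level count matrix bound to its annotation
#'
#' Container tying a transcripts-by-samples matrix of (possibly fractional,
#' scaledTPM-style) counts to a transcript-to-gene annotation table. All
#' downstream stages -- filtering, usage computation, DTU testing -- operate
#' on this object.
#'
#' @param counts numeric matrix, transcripts in rows (rownames = transcript
#'   ids), samples in columns (colnames = sample ids). Values must be
#'   non-negative; fractional values are allowed (count models round at model
#'   entry).
#' @param annotation data.frame with columns `transcript_id`, `gene_id`,
#'   `gene_name`, `biotype`, `chromosome`. Every row of `counts` must resolve
#'   to exactly one annotation row.
#' @return An object of class `tx_counts`: a list with elements `counts`
#'   (the validated matrix) and `annotation` (rows aligned to the matrix).
#' @export
tx_counts <- function(counts, annotation) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate transcript ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (anyNA(counts))
    stop("missing values in count matrix are not allowed")
  if (any(counts < 0))
    stop("negative values in count matrix")
  annotation <- validate_annotation(annotation)
  idx <- match(rownames(counts), annotation$transcript_id)
  if (anyNA(idx))
    stop("transcripts missing from annotation: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  structure(list(counts = counts,
                 annotation = annotation[idx, , drop = FALSE]),
            class = "tx_counts")
}

#' @export
print.tx_counts <- function(x, ...) {
  cat(sprintf("tx_counts: %d transcripts x %d samples, %d genes\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$annotation$gene_id))))
  invisible(x)
}

#' @export
dim.tx_counts <- function(x) dim(x$counts)

validate_annotation <- function(annotation) {
  need <- c("transcript_id", "gene_id", "gene_name", "biotype", "chromosome")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  annotation <- as.data.frame(annotation)[need]
  if (anyDuplicated(annotation$transcript_id))
    stop("duplicate transcript ids in annotation")
  if (anyNA(annotation$chromosome) || any(annotation$chromosome == ""))
    stop("annotation chromosome labels must be present")
  rownames(annotation) <- NULL
  annotation
}

#' Read a transcript count matrix and its annotation from tab-separated files
#'
#' The count file must have a header of sample ids with the first column named
#' `transcript_id`. Transcripts without an annotation entry are dropped with a
#' message; transcripts on excluded chromosomes (sex chromosomes by default)
#' are dropped as well, mirroring quantification restricted to autosomes.
#'
#' @param counts_path path to the tab-separated count file.
#' @param annotation_path path to the tab-separated annotation file with
#'   columns `transcript_id, gene_id, gene_name, biotype, chromosome`.
#' @param exclude_chrom character vector of chromosome labels to drop
#'   (default `c("X", "Y")`).
#' @return A [tx_counts] object.
#' @export
read_counts <- function(counts_path, annotation_path,
                        exclude_chrom = c("X", "Y")) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           comment.char = "#")
  if (names(tab)[1] != "transcript_id")
    stop("first column of the count file must be 'transcript_id'")
  if (anyDuplicated(tab$transcript_id))
    stop("duplicate transcript ids in count file")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$transcript_id
  annotation <- validate_annotation(
    utils::read.delim(annotation_path, comment.char = "#"))
  known <- rownames(counts) %in% annotation$transcript_id
  if (!any(known))
    stop("no transcript in the count file is present in the annotation")
  if (any(!known))
    message(sum(!known), " transcripts without annotation dropped")
  counts <- counts[known, , drop = FALSE]
  chrom <- annotation$chromosome[match(rownames(counts),
                                       annotation$transcript_id)]
  drop_chr <- chrom %in% exclude_chrom
  if (any(drop_chr))
    message(sum(drop_chr), " transcripts on excluded chromosomes (",
            paste(exclude_chrom, collapse = ", "), ") dropped")
  counts <- counts[!drop_chr, , drop = FALSE]
  if (nrow(counts) == 0L)
    stop("no transcripts left after chromosome exclusion")
  tx_counts(counts, annotation)
}

#' Write a transcript count matrix to a tab-separated file
#'
#' Inverse of [read_counts()]: writes a `transcript_id` column followed by one
#' column per sample, at full double precision so a round trip is bit-exact.
#'
#' @param x a [tx_counts] object or a numeric matrix with dimnames.
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  m <- if (inherits(x, "tx_counts")) x$counts else x
  df <- data.frame(transcript_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert TPM abundances to scaledTPM counts
#'
#' Rescales each sample's TPM column to library-size magnitude:
#' `scaledTPM[, j] = tpm[, j] * library_sizes[j] / 1e6`. The result behaves
#' like estimated counts and is the favoured input scale for transcript
#' usage models.
#'
#' @param tpm non-negative numeric matrix of TPM values.
#' @param library_sizes positive numeric vector, one entry per column of
#'   `tpm` (mapped reads per sample).
#' @return matrix of the same shape on the count scale.
#' @export
scale_tpm <- function(tpm, library_sizes) {
  tpm <- as.matrix(tpm)
  if (length(library_sizes) != ncol(tpm))
    stop("need one library size per sample")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stop("library sizes must be strictly positive")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  sweep(tpm, 2, library_sizes / 1e6, `*`)
}

#' Per-sample within-gene transcript usage
#'
#' For every transcript i of gene j in sample s, usage is the transcript's
#' count divided by the summed counts of all transcripts of the gene in that
#' sample. Where a gene's total is zero the ratio is undefined and flagged
#' `NA` (never imputed as 0).
#'
#' @param x a [tx_counts] object.
#' @return numeric matrix of the same shape; entries in `[0, 1]` where the
#'   gene total is positive, `NA` where it is zero. Carries the gene ids as
#'   attribute `gene_id`.
#' @export
transcript_usage <- function(x) {
  stopifnot(inherits(x, "tx_counts"))
  gene <- x$annotation$gene_id
  totals <- rowsum(x$counts, gene, reorder = FALSE)
  denom <- totals[match(gene, rownames(totals)), , drop = FALSE]
  usage <- x$counts / denom
  usage[denom == 0] <- NA_real_
  attr(usage, "gene_id") <- gene
  usage
}

#' Validate a sample metadata table
#'
#' @param samples data.frame with columns `sample_id, condition, RIN, age,
#'   sex, cohort` and optionally cellularity-score columns. `condition` must
#'   have exactly two levels with at least two samples each; the control level
#'   (coded 0 in designs) is `"control"` when present, otherwise the
#'   alphabetically first level.
#' @return the validated data.frame with `condition` and `sex` as factors.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "condition", "RIN", "age", "sex", "cohort")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")
  lev <- unique(as.character(samples$condition))
  if (length(lev) != 2L)
    stop("condition must have exactly two levels, found: ",
         paste(lev, collapse = ", "))
  ref <- if ("control" %in% lev) "control" else sort(lev)[1]
  samples$condition <- factor(samples$condition, levels = c(ref, setdiff(lev, ref)))
  if (any(table(samples$condition) < 2L))
    stop("each condition level needs at least two samples")
  if (any(samples$RIN < 1 | samples$RIN > 10, na.rm = TRUE))
    stop("RIN values must lie in [1, 10]")
  samples$sex <- factor(samples$sex)
  samples
}

#' Read sample metadata from a tab-separated file
#' @param path tab-separated file with the columns described in
#'   [validate_samples()].
#' @return validated sample data.frame.
#' @export
read_samples <- function(path) {
  validate_samples(utils::read.delim(path, comment.char = "#"))
}

#' Build the per-sample design matrix for the DTU models
#'
#' Columns: intercept, condition indicator (reference level = 0, case = 1),
#' RIN, age, sex indicator, plus any extra covariate columns (e.g. selected
#' marker-gene-profile scores). All columns except the intercept and the
#' condition indicator are standardised to zero mean and unit variance, which
#' improves conditioning without changing the condition coefficient.
#'
#' @param samples validated sample table (see [validate_samples()]).
#' @param extra optional numeric matrix/data.frame of additional covariates,
#'   rows aligned with `samples` (e.g. output of [compute_mgp()]).
#' @param covariates which of the standard clinical covariates to include.
#' @return numeric design matrix with rownames = sample ids; the treatment
#'   column is named `"condition"`.
#' @export
build_design <- function(samples, extra = NULL,
                         covariates = c("RIN", "age", "sex")) {
  samples <- validate_samples(samples)
  X <- cbind(intercept = 1,
             condition = as.numeric(samples$condition) - 1)
  if ("RIN" %in% covariates) X <- cbind(X, RIN = samples$RIN)
  if ("age" %in% covariates) X <- cbind(X, age = samples$age)
  if ("sex" %in% covariates && nlevels(samples$sex) > 1L)
    X <- cbind(X, sex = as.numeric(samples$sex) - 1)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (nrow(extra) != nrow(samples))
      stop("extra covariates must have one row per sample")
    X <- cbind(X, extra)
  }
  std <- setdiff(colnames(X), c("intercept", "condition"))
  for (v in std) {
    s <- stats::sd(X[, v])
    if (s > 0) X[, v] <- (X[, v] - mean(X[, v])) / s
  }
  rownames(X) <- samples$sample_id
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}
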