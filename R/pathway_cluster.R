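## Gene-set enrichment of DTU genes against the filtered background,
## followed by redundancy reduction: significant pathways are merged by
## iterative nearest-neighbour joining under Cohen's kappa similarity of
## their gene memberships, each final cluster receiving a deterministic
## representative title and a Fisher-method aggregated p-value.

#' Read a GMT gene-set file
#'
#' Thin wrapper around `fgsea::gmtPathways()` returning a named list of
#' member gene vectors.
#'
#' @param path path to a GMT file.
#' @return named list: set id -> character vector of member genes.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric enrichment of a hit list against gene sets
#'
#' Upper-tail hypergeometric test of the overlap between `hits` and each
#' set, with all sets first intersected with `background`. FDR is
#' Benjamini-Hochberg, computed within each category when a `categories`
#' labelling is given (mirroring separate testing of GO ontologies),
#' otherwise over all sets.
#'
#' @param hits character vector of hit genes, a subset of `background`.
#' @param background character vector: the gene universe (e.g. all genes
#'   surviving filtering).
#' @param sets named list of gene sets.
#' @param categories optional named character vector mapping set id ->
#'   category label.
#' @param fdr_threshold significance cutoff on the FDR (default 0.05).
#' @return data.frame with `set_id`, `category`, `set_size` (within
#'   background), `overlap`, `pvalue`, `fdr`, `significant`.
#' @export
enrich <- function(hits, background, sets, categories = NULL,
                   fdr_threshold = 0.05) {
  if (!all(hits %in% background))
    stop("hits must be a subset of the background")
  hits <- unique(hits); background <- unique(background)
  sets_bg <- lapply(sets, intersect, background)
  keep <- lengths(sets_bg) > 0
  sets_bg <- sets_bg[keep]
  N <- length(background); H <- length(hits)
  ov <- vapply(sets_bg, function(s) length(intersect(s, hits)), integer(1))
  sz <- lengths(sets_bg)
  p <- stats::phyper(ov - 1, H, N - H, sz, lower.tail = FALSE)
  cat_lab <- if (is.null(categories)) rep("all", length(sets_bg))
             else unname(categories[names(sets_bg)])
  out <- data.frame(set_id = names(sets_bg), category = cat_lab,
                    set_size = sz, overlap = ov, pvalue = unname(p),
                    row.names = NULL)
  out$fdr <- NA_real_
  for (cc in unique(out$category)) {
    i <- out$category == cc
    out$fdr[i] <- stats::p.adjust(out$pvalue[i], method = "BH")
  }
  out$significant <- out$fdr < fdr_threshold
  out
}

#' Cohen's kappa similarity of two gene sets over a universe
#'
#' Chance-corrected agreement of the two membership indicators across the
#' universe: `kappa = (Po - Pe) / (1 - Pe)` from the 2x2 joint membership
#' table. The degenerate case `Pe = 1` returns 1 when agreement is perfect
#' and 0 otherwise.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of at least 2 genes.
#' @return kappa in `[-1, 1]`.
#' @export
kappa_sets <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (length(universe) < 2) stop("universe must contain at least 2 genes")
  inA <- universe %in% setA
  inB <- universe %in% setB
  N <- length(universe)
  a <- sum(inA & inB); b <- sum(inA & !inB)
  c <- sum(!inA & inB); d <- sum(!inA & !inB)
  po <- (a + d) / N
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Cluster significant pathways by kappa similarity
#'
#' Agglomerative nearest-neighbour joining: starting from singleton
#' clusters, the pair of clusters with the highest kappa (computed on the
#' union of the member sets' genes) is merged while that kappa exceeds
#' `threshold`. Ties are broken by the smaller combined gene-set size, then
#' by the lexicographically smallest member set id. By default the kappa
#' universe is the union of all significant sets' genes.
#'
#' @param significant character vector of significant set ids.
#' @param sets named list of gene sets (already background-intersected).
#' @param threshold merging stops when no inter-cluster kappa exceeds this
#'   (default 0.4).
#' @param universe optional kappa universe; defaults to the union of the
#'   significant sets' genes.
#' @return list of clusters, each a character vector of member set ids.
#' @export
cluster_pathways <- function(significant, sets, threshold = 0.4,
                             universe = NULL) {
  stopifnot(length(significant) > 0, all(significant %in% names(sets)))
  sets <- sets[significant]
  if (is.null(universe)) universe <- unique(unlist(sets))
  clusters <- lapply(significant, identity)
  genes_of <- function(cl) unique(unlist(sets[cl]))
  repeat {
    if (length(clusters) < 2) break
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      gi <- genes_of(clusters[[i]])
      for (j in seq(i + 1, length(clusters))) {
        gj <- genes_of(clusters[[j]])
        k <- kappa_sets(gi, gj, universe)
        cand <- list(i = i, j = j, kappa = k,
                     size = length(union(gi, gj)),
                     id = min(c(clusters[[i]], clusters[[j]])))
        if (is.null(best) ||
            k > best$kappa + 1e-12 ||
            (abs(k - best$kappa) <= 1e-12 &&
             (cand$size < best$size ||
              (cand$size == best$size && cand$id < best$id))))
          best <- cand
      }
    }
    if (best$kappa <= threshold) break
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  clusters
}

#' Title and aggregated p-value of a pathway cluster
#'
#' Fisher's method over the member p-values: `X2 = -2 * sum(log(p))`
#' referred to a chi-square with `2 * m` degrees of freedom (p floored at
#' 1e-300 before the log). The representative title is the member with the
#' smallest p-value; ties go to the larger gene set, then the
#' lexicographically smaller id.
#'
#' @param members character vector of member set ids.
#' @param enrichment enrichment table from [enrich()].
#' @param names_map optional named character vector set id -> display name
#'   (defaults to the ids themselves).
#' @return list with `title`, `statistic`, `df`, `pvalue`.
#' @export
title_and_p <- function(members, enrichment, names_map = NULL) {
  rows <- enrichment[match(members, enrichment$set_id), ]
  if (anyNA(rows$pvalue)) stop("cluster members missing from enrichment")
  p <- pmax(rows$pvalue, 1e-300)
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  ord <- order(rows$pvalue, -rows$set_size, rows$set_id)
  top <- rows$set_id[ord[1]]
  title <- if (!is.null(names_map) && top %in% names(names_map))
    unname(names_map[top]) else top
  list(title = title, statistic = x2, df = df,
       pvalue = stats::pchisq(x2, df = df, lower.tail = FALSE))
}

#' Full pathway enrichment and clustering pipeline
#'
#' Runs [enrich()], clusters the significant sets per category with
#' [cluster_pathways()], titles each cluster and aggregates member p-values
#' with [title_and_p()], and sorts clusters by aggregated p-value.
#'
#' @inheritParams enrich
#' @inheritParams cluster_pathways
#' @param names_map optional set id -> display name mapping.
#' @return list with `enrichment` (the full [enrich()] table) and
#'   `clusters` (data.frame: `title`, `category`, `n_members`, `members`
#'   (comma-separated), `statistic`, `df`, `pvalue`, ascending in `pvalue`).
#' @export
pathway_clusters <- function(hits, background, sets, categories = NULL,
                             threshold = 0.4, fdr_threshold = 0.05,
                             names_map = NULL, universe = NULL) {
  er <- enrich(hits, background, sets, categories, fdr_threshold)
  sets_bg <- lapply(sets, intersect, unique(background))
  out <- list()
  for (cc in unique(er$category)) {
    sig <- er$set_id[er$significant & er$category == cc]
    if (!length(sig)) next
    cls <- cluster_pathways(sig, sets_bg, threshold, universe)
    for (cl in cls) {
      tp <- title_and_p(cl, er, names_map)
      out[[length(out) + 1]] <- data.frame(
        title = tp$title, category = cc, n_members = length(cl),
        members = paste(cl, collapse = ","),
        statistic = tp$statistic, df = tp$df, pvalue = tp$pvalue)
    }
  }
  clusters <- if (length(out)) do.call(rbind, out) else
    data.frame(title = character(), category = character(),
               n_members = integer(), members = character(),
               statistic = numeric(), df = integer(), pvalue = numeric())
  clusters <- clusters[order(clusters$pvalue), ]
  rownames(clusters) <- NULL
  list(enrichment = er, clusters = clusters)
}
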