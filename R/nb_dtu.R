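## Negative-binomial "this transcript vs rest of gene" interaction model.
## Each transcript contributes two observations per sample (its own count
## and the remainder of the gene); per-sample free intercepts absorb library
## size and gene expression level, and a condition x this-transcript
## interaction captures a shift in the transcript's share. Dispersion is
## estimated per transcript by adjusted profile likelihood (Cox-Reid) and
## shrunk halfway, on the log scale, toward a log-linear mean-dispersion
## trend fitted across transcripts.

nb_long_data <- function(yk, rest, design, condition = "condition") {
  n <- length(yk)
  covars <- setdiff(colnames(design), c("intercept", condition))
  df <- data.frame(
    y = c(yk, rest),
    this = rep(c(1, 0), each = n),
    sample = factor(rep(seq_len(n), 2)))
  for (v in covars) df[[v]] <- rep(design[, v], 2)
  df$condition <- rep(design[, condition], 2)
  terms_full <- c("0", "sample", "this",
                  if (length(covars)) paste0("this:", covars),
                  "this:condition")
  terms_null <- setdiff(terms_full, "this:condition")
  list(data = df,
       full = stats::as.formula(paste("y ~", paste(terms_full, collapse = " + "))),
       null = stats::as.formula(paste("y ~", paste(terms_null, collapse = " + "))))
}

# Cox-Reid adjusted profile log-likelihood of the NB dispersion alpha
# (variance mu + alpha mu^2) for a fixed model formula
nb_apl <- function(log_alpha, formula, data) {
  theta <- exp(-log_alpha)
  fit <- tryCatch(
    suppressWarnings(stats::glm(formula, data = data,
                                family = MASS::negative.binomial(theta))),
    error = function(e) NULL)
  if (is.null(fit)) return(-Inf)
  mu <- stats::fitted(fit)
  ll <- sum(stats::dnbinom(data$y, size = theta, mu = mu, log = TRUE))
  X <- stats::model.matrix(fit)
  w <- mu / (1 + mu / theta)
  cr <- 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
  as.numeric(ll - cr)
}

nb_estimate_dispersion <- function(formula, data,
                                   range = c(-8, 4)) {
  opt <- stats::optimize(function(la) nb_apl(la, formula, data),
                         interval = range, maximum = TRUE, tol = 1e-3)
  exp(opt$maximum)
}

nb_lrt <- function(spec, alpha_disp, condition = "condition") {
  theta <- 1 / alpha_disp
  fam <- MASS::negative.binomial(theta)
  full <- suppressWarnings(stats::glm(spec$full, data = spec$data, family = fam))
  null <- suppressWarnings(stats::glm(spec$null, data = spec$data, family = fam))
  llik <- function(fit) sum(stats::dnbinom(spec$data$y, size = theta,
                                           mu = stats::fitted(fit), log = TRUE))
  lr <- 2 * (llik(full) - llik(null))
  if (lr < 0 && lr > -1e-6) lr <- 0
  cf <- stats::coef(full)
  eff <- unname(cf[grep("this:condition|condition:this", names(cf))][1])
  list(effect_size = eff, lr = lr,
       pvalue = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Per-transcript negative-binomial usage test for one gene
#'
#' For each transcript of the gene, fits the NB interaction model described
#' above and tests the condition-by-transcript interaction with a df = 1
#' likelihood-ratio test. The interaction coefficient is the log-fold change
#' (natural log) of the transcript's share in cases versus controls.
#'
#' @param Y integer count matrix, samples x transcripts (colnames =
#'   transcript ids).
#' @param design design matrix from [build_design()] (must contain an
#'   `intercept` and a `condition` column).
#' @param log_disp_trend optional function mapping log mean count to log
#'   dispersion (the fitted trend from a full run); when `NULL` the trend is
#'   fitted across the transcripts of this gene alone (or no shrinkage is
#'   applied if there are fewer than 3 usable transcripts).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `effect_size`, `dispersion`, `lr`, `df`, `pvalue`. All-`NA` rows when
#'   the gene total is zero everywhere.
#' @export
fit_nb_usage <- function(Y, design, log_disp_trend = NULL) {
  Y <- dm_check_counts(Y)
  K <- ncol(Y)
  if (K < 2L) stop("need at least two transcripts")
  tot <- rowSums(Y)
  out <- data.frame(transcript_id = colnames(Y),
                    effect_size = NA_real_, dispersion = NA_real_,
                    lr = NA_real_, df = 1L, pvalue = NA_real_)
  if (all(tot == 0)) return(out)
  specs <- lapply(seq_len(K), function(k)
    nb_long_data(Y[, k], tot - Y[, k], design))
  raw <- vapply(seq_len(K), function(k)
    nb_estimate_dispersion(specs[[k]]$full, specs[[k]]$data), numeric(1))
  mean_count <- colMeans(Y)
  log_disp <- shrink_dispersion(raw, mean_count, log_disp_trend)
  for (k in seq_len(K)) {
    r <- nb_lrt(specs[[k]], exp(log_disp[k]))
    out$effect_size[k] <- r$effect_size
    out$dispersion[k] <- exp(log_disp[k])
    out$lr[k] <- r$lr
    out$pvalue[k] <- r$pvalue
  }
  out
}

# halfway log-scale shrinkage toward the mean-dispersion trend
shrink_dispersion <- function(raw, mean_count, log_disp_trend = NULL) {
  raw <- pmax(raw, 1e-8)
  if (is.null(log_disp_trend)) {
    if (length(raw) >= 3) {
      fit <- stats::lm(log(raw) ~ log(mean_count + 1))
      trend <- stats::fitted(fit)
    } else trend <- log(raw)   # too few points to fit a trend
  } else trend <- log_disp_trend(log(mean_count + 1))
  0.5 * log(raw) + 0.5 * trend
}

#' Aggregate transcript p-values of one gene to a gene-level p
#'
#' Sidak correction applied to the minimum transcript p-value:
#' `p_gene = 1 - (1 - min(p))^K` with `K` the number of non-missing
#' p-values. Monotone: decreasing any transcript p never increases the
#' gene p.
#'
#' @param p numeric vector of transcript p-values (may contain `NA`).
#' @return a single gene-level p-value, `NA` if all inputs are missing.
#' @export
per_gene_p <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  1 - (1 - min(p))^length(p)
}

#' Run the negative-binomial DTU analysis over a filtered count matrix
#'
#' Two passes: first, per-transcript Cox-Reid dispersion estimates across all
#' genes and a log-linear mean-dispersion trend; second, per-transcript
#' likelihood-ratio tests at the trend-shrunken dispersions. Gene-level
#' p-values aggregate transcript p-values via [per_gene_p()].
#'
#' @inheritParams dm_dtu
#' @return list with data.frames `transcript` (transcript_id, gene_id,
#'   effect_size, dispersion, lr, df, pvalue) and `gene` (gene_id, pvalue).
#' @export
nb_dtu <- function(x, design) {
  stopifnot(inherits(x, "tx_counts"))
  Yall <- round(x$counts)
  gene <- x$annotation$gene_id
  genes <- unique(gene[duplicated(gene)])
  gene_counts <- lapply(genes, function(g) t(Yall[gene == g, , drop = FALSE]))
  names(gene_counts) <- genes

  # pass 1: raw dispersions over all transcripts
  raw <- list(); mc <- list()
  for (g in genes) {
    Y <- gene_counts[[g]]
    tot <- rowSums(Y)
    if (all(tot == 0)) next
    specs <- lapply(seq_len(ncol(Y)), function(k)
      nb_long_data(Y[, k], tot - Y[, k], design))
    raw[[g]] <- vapply(seq_len(ncol(Y)), function(k)
      nb_estimate_dispersion(specs[[k]]$full, specs[[k]]$data), numeric(1))
    mc[[g]] <- colMeans(Y)
  }
  rall <- pmax(unlist(raw), 1e-8)
  lall <- log(unlist(mc) + 1)
  trend_fit <- stats::lm(log(rall) ~ lall)
  trend <- function(logmc) as.numeric(cbind(1, logmc) %*% stats::coef(trend_fit))

  tres <- lapply(genes, function(g) {
    res <- fit_nb_usage(gene_counts[[g]], design, log_disp_trend = trend)
    cbind(res[1], gene_id = g, res[-1])
  })
  tdf <- do.call(rbind, tres)
  gdf <- data.frame(
    gene_id = genes,
    pvalue = vapply(genes, function(g)
      per_gene_p(tdf$pvalue[tdf$gene_id == g]), numeric(1)))
  list(transcript = tdf, gene = gdf)
}
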