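## Dirichlet-multinomial (DM) proportion regression for differential
## transcript usage. For one gene with K transcripts observed in n samples,
## counts y_i | total m_i ~ DM(m_i, gamma * pi_i) with
## pi_ik = softmax(x_i' beta_k), beta_ref = 0. The condition coefficient on
## a transcript's log-odds usage is the DTU effect size. gamma is the
## gene-wise precision (gamma -> Inf recovers the multinomial).

dm_check_counts <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("negative counts")
  if (max(abs(Y - round(Y))) > 1e-8)
    stop("counts must be integers at model entry (round upstream)")
  storage.mode(Y) <- "double"
  round(Y)
}

# negative penalized log-likelihood and gradient; par = vec(beta), beta is
# (K-1) x P with the K-th (reference) transcript fixed at 0
dm_nll <- function(par, Y, X, gamma, lambda = 1e-6) {
  K <- ncol(Y); P <- ncol(X)
  beta <- matrix(par, K - 1L, P)
  eta <- cbind(tcrossprod(X, beta), 0)
  eta <- eta - apply(eta, 1, max)
  pi <- exp(eta); pi <- pi / rowSums(pi)
  alpha <- gamma * pi
  m <- rowSums(Y)
  ll <- sum(lgamma(gamma) - lgamma(m + gamma)) +
    sum(lgamma(Y + alpha) - lgamma(alpha))
  -(ll - lambda * sum(par^2))
}

dm_nll_grad <- function(par, Y, X, gamma, lambda = 1e-6) {
  K <- ncol(Y); P <- ncol(X)
  beta <- matrix(par, K - 1L, P)
  eta <- cbind(tcrossprod(X, beta), 0)
  eta <- eta - apply(eta, 1, max)
  pi <- exp(eta); pi <- pi / rowSums(pi)
  alpha <- gamma * pi
  G <- digamma(Y + alpha) - digamma(alpha)
  sbar <- rowSums(pi * G)
  W <- gamma * pi * (G - sbar)
  grad <- crossprod(W[, seq_len(K - 1L), drop = FALSE], X)  # (K-1) x P
  -(as.vector(grad) - 2 * lambda * par)
}

dm_init <- function(Y, X) {
  K <- ncol(Y); P <- ncol(X)
  beta <- matrix(0, K - 1L, P)
  pbar <- colSums(Y) + 0.5
  pbar <- pbar / sum(pbar)
  ic <- match("intercept", colnames(X))
  if (!is.na(ic))
    beta[, ic] <- log(pbar[-K] / pbar[K])
  beta
}

# maximize the penalized DM log-likelihood; warm-startable. BFGS does the
# bulk of the work; damped Newton steps on the analytic gradient polish the
# solution to the gradient tolerance (BFGS's relative-value stop can leave
# the gradient above it).
dm_optim <- function(Y, X, gamma, lambda = 1e-6, init = NULL,
                     tol_grad = 1e-6, maxit = 500L, newton_steps = 10L) {
  if (is.null(init)) init <- dm_init(Y, X)
  par <- as.vector(init)
  fit <- stats::optim(par, dm_nll, dm_nll_grad, Y = Y, X = X,
                      gamma = gamma, lambda = lambda, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  par <- fit$par
  val <- fit$value
  iters <- fit$counts[["function"]]
  grad <- dm_nll_grad(par, Y, X, gamma, lambda)
  for (s in seq_len(newton_steps)) {
    if (max(abs(grad)) <= tol_grad) break
    H <- dm_num_hessian(par, Y, X, gamma, lambda)
    step <- tryCatch(solve(H, grad), error = function(e) grad)
    damp <- 1
    repeat {   # halve the step until the objective does not increase
      cand <- par - damp * step
      vc <- dm_nll(cand, Y, X, gamma, lambda)
      if (vc <= val + 1e-12 || damp < 1e-4) break
      damp <- damp / 2
    }
    if (vc > val + 1e-12) break
    par <- cand; val <- vc
    grad <- dm_nll_grad(par, Y, X, gamma, lambda)
    iters <- iters + 1L
  }
  gmax <- max(abs(grad))
  list(beta = matrix(par, ncol(Y) - 1L, ncol(X),
                     dimnames = list(NULL, colnames(X))),
       objective = -val,            # penalized log-likelihood
       loglik = -dm_nll(par, Y, X, gamma, lambda = 0),
       converged = gmax <= tol_grad, grad_max = gmax, iterations = iters)
}

# profile log-likelihood over beta at fixed gamma (penalized objective).
# With adjust = TRUE, returns the Cox-Reid adjusted profile likelihood
# (subtracting half the log-determinant of the observed information of
# beta), which removes the upward bias of plain profile-ML precision
# estimates caused by per-gene coefficient overfitting.
dm_profile <- function(Y, X, gamma, init = NULL, tol_grad = 1e-3,
                       adjust = FALSE) {
  fit <- dm_optim(Y, X, gamma, init = init, tol_grad = tol_grad)
  if (adjust) {
    H <- dm_num_hessian(as.vector(fit$beta), Y, X, gamma)
    ld <- determinant(H, logarithm = TRUE)
    # non-positive-definite Hessian signals a failed fit; leave unadjusted
    if (ld$sign > 0) fit$objective <- fit$objective - 0.5 * as.numeric(ld$modulus)
  }
  fit
}

# finite-difference Hessian of the negative penalized log-likelihood
dm_num_hessian <- function(par, Y, X, gamma, lambda = 1e-6, eps = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- eps
    gp <- dm_nll_grad(par + e, Y, X, gamma, lambda)
    gm <- dm_nll_grad(par - e, Y, X, gamma, lambda)
    H[j, ] <- (gp - gm) / (2 * eps)
  }
  (H + t(H)) / 2
}

golden_section <- function(f, lower, upper, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
    else { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
  }
  x <- (a + b) / 2
  list(maximum = x, objective = f(x))
}

#' Estimate the common and gene-wise Dirichlet-multinomial precision
#'
#' The common precision `gamma0` maximizes the pooled profile log-likelihood
#' (each gene's regression coefficients profiled out) over a log-spaced grid
#' refined by golden-section search. Each gene's precision then maximizes its
#' own profile likelihood penalized on the log scale toward `log(gamma0)`,
#' with a quadratic penalty worth `moderation` pseudo-genes, one pseudo-gene
#' being the curvature of an average gene's adjusted profile log-likelihood
#' at the common optimum -- a moderation that stabilises small-sample
#' estimates. All profiles carry a Cox-Reid adjustment (half the
#' log-determinant of the coefficient information), without which
#' profile-ML precision estimates are biased upward by coefficient
#' overfitting and downstream tests become anti-conservative.
#'
#' @param gene_counts named list of per-gene integer count matrices
#'   (samples x transcripts).
#' @param design numeric design matrix (samples x covariates).
#' @param moderation penalty weight toward the common log-precision,
#'   in pseudo-gene units (default 10).
#' @param bounds search range for gamma (default `c(1e-2, 1e6)`).
#' @param grid_size number of log-spaced grid points for the common search.
#' @param common_subsample optional integer; if smaller than the number of
#'   genes, the common precision is estimated on this many genes (the ones
#'   with the highest totals), a runtime device that leaves per-gene
#'   moderation untouched.
#' @return list with `gamma0` (common precision) and `gamma` (named vector of
#'   per-gene precisions). Genes with fewer than two samples with positive
#'   totals are excluded with a warning and get `NA`.
#' @export
estimate_precision <- function(gene_counts, design, moderation = 10,
                               bounds = c(1e-2, 1e6), grid_size = 8,
                               common_subsample = NULL) {
  ok <- vapply(gene_counts, function(Y) sum(rowSums(Y) > 0) >= 2, logical(1))
  if (!any(ok)) stop("no gene with >= 2 samples with positive totals")
  if (any(!ok))
    warning(sum(!ok), " gene(s) with < 2 informative samples excluded ",
            "from precision estimation")
  usable <- gene_counts[ok]
  usable <- lapply(usable, dm_check_counts)

  pool <- usable
  if (!is.null(common_subsample) && common_subsample < length(pool)) {
    tot <- vapply(pool, sum, numeric(1))
    pool <- pool[order(tot, decreasing = TRUE)[seq_len(common_subsample)]]
  }
  warm <- vector("list", length(pool))
  pooled_profile <- function(lg) {
    g <- exp(lg)
    s <- 0
    for (i in seq_along(pool)) {
      fit <- dm_profile(pool[[i]], design, g, init = warm[[i]],
                        adjust = TRUE)
      warm[[i]] <<- fit$beta
      s <- s + fit$objective
    }
    s
  }
  lgrid <- seq(log(max(bounds[1], 1e-1)), log(min(bounds[2], 1e5)),
               length.out = grid_size)
  vals <- vapply(lgrid, pooled_profile, numeric(1))
  i <- which.max(vals)
  lo <- lgrid[max(1, i - 1)]; hi <- lgrid[min(length(lgrid), i + 1)]
  opt <- golden_section(pooled_profile, lo, hi, tol = 1e-2)
  gamma0 <- min(max(exp(opt$maximum), bounds[1]), bounds[2])

  lg0 <- log(gamma0)
  # one "pseudo-gene" of penalty = the curvature of an average gene's
  # adjusted profile log-likelihood in log gamma at the common optimum
  h <- 0.3
  curv <- -(pooled_profile(lg0 + h) - 2 * pooled_profile(lg0) +
              pooled_profile(lg0 - h)) / h^2 / length(pool)
  if (!is.finite(curv) || curv <= 0) curv <- 1
  wpen <- moderation * curv / 2
  gamma_g <- rep(NA_real_, length(gene_counts))
  names(gamma_g) <- names(gene_counts)
  for (gname in names(usable)) {
    Y <- usable[[gname]]
    warm_b <- NULL
    f <- function(lg) {
      fit <- dm_profile(Y, design, exp(lg), init = warm_b, adjust = TRUE)
      warm_b <<- fit$beta
      fit$objective - wpen * (lg - lg0)^2
    }
    # the moderation penalty keeps gamma_g near gamma0; search locally
    opt_g <- golden_section(f, max(log(bounds[1]), lg0 - 6),
                            min(log(bounds[2]), lg0 + 6), tol = 1e-2)
    gamma_g[gname] <- min(max(exp(opt_g$maximum), bounds[1]), bounds[2])
  }
  list(gamma0 = gamma0, gamma = gamma_g)
}

#' Fit the Dirichlet-multinomial usage regression for one gene
#'
#' Maximizes the DM log-likelihood (gene totals conditioned on) with
#' proportions `softmax(X beta)` and a fixed precision, under a small ridge
#' penalty (`lambda * sum(beta^2)`, `lambda = 1e-6`) that keeps coefficients
#' finite under separation. The reference transcript (linear predictor fixed
#' at zero) is the one with the largest mean count; the fit is invariant to
#' this choice, which only aids conditioning.
#'
#' @param Y integer count matrix, samples x transcripts (K >= 2 columns,
#'   transcript ids as colnames).
#' @param design numeric design matrix, full column rank.
#' @param gamma DM precision (> 0).
#' @param lambda ridge penalty weight (default 1e-6).
#' @param tol_grad gradient max-norm convergence tolerance.
#' @return a `dm_fit` list: `beta` ((K-1) x P, rows named by non-reference
#'   transcripts), `reference`, `gamma`, `loglik`, `objective` (penalized),
#'   `converged`, `iterations`.
#' @export
fit_dm <- function(Y, design, gamma, lambda = 1e-6, tol_grad = 1e-6) {
  Y <- dm_check_counts(Y)
  if (ncol(Y) < 2L) stop("need at least two transcripts")
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  ref <- which.max(colMeans(Y))
  ord <- c(setdiff(seq_len(ncol(Y)), ref), ref)
  Yo <- Y[, ord, drop = FALSE]
  fit <- dm_optim(Yo, design, gamma, lambda = lambda, tol_grad = tol_grad)
  rownames(fit$beta) <- colnames(Yo)[seq_len(ncol(Yo) - 1L)]
  structure(c(fit, list(gamma = gamma, K = ncol(Y),
                        reference = colnames(Y)[ref])),
            class = "dm_fit")
}

#' Gene-level DTU likelihood-ratio test
#'
#' Compares the full design against the null design with the condition
#' column removed; the statistic `2 * (llik_full - llik_null)` is referred to
#' a chi-square with `K - 1` degrees of freedom. Small negative statistics
#' (within -1e-6, optimizer noise) are clamped to zero.
#'
#' @inheritParams fit_dm
#' @param condition name of the treatment column in `design`
#'   (default `"condition"`).
#' @return list with `lr`, `df`, `pvalue`, and the two fits. `pvalue` is `NA`
#'   with a warning if the null fit fails.
#' @export
test_gene <- function(Y, design, gamma, condition = "condition",
                      lambda = 1e-6, tol_grad = 1e-6) {
  if (!condition %in% colnames(design))
    stop("design has no column '", condition, "'")
  full <- fit_dm(Y, design, gamma, lambda, tol_grad)
  null_design <- design[, setdiff(colnames(design), condition), drop = FALSE]
  null <- tryCatch(fit_dm(Y, null_design, gamma, lambda, tol_grad),
                   error = function(e) NULL)
  K <- ncol(Y)
  if (is.null(null)) {
    warning("null fit failed; p-value set to NA")
    return(list(lr = NA_real_, df = K - 1L, pvalue = NA_real_,
                full = full, null = NULL))
  }
  lr <- 2 * (full$objective - null$objective)
  if (lr < 0 && lr > -1e-6) lr <- 0
  list(lr = lr, df = K - 1L,
       pvalue = stats::pchisq(lr, df = K - 1L, lower.tail = FALSE),
       full = full, null = null)
}

#' Transcript-level beta-binomial DTU test
#'
#' Collapses the gene to "this transcript vs the rest" -- counts
#' `(y_k, total - y_k)` -- and fits the two-category DM (a beta-binomial
#' regression on the logit of transcript usage) with the same design and
#' precision. The condition coefficient is the DTU effect size on the
#' natural-log-odds usage scale (positive = increased usage in cases); the
#' p-value is a df = 1 likelihood-ratio test dropping the condition column.
#'
#' @inheritParams test_gene
#' @param k transcript to test: column index or colname of `Y`.
#' @return list with `effect_size`, `lr`, `df = 1`, `pvalue`; all `NA` when
#'   the transcript has zero counts in every sample.
#' @export
test_transcript <- function(Y, design, gamma, k, condition = "condition",
                            lambda = 1e-6, tol_grad = 1e-6) {
  Y <- dm_check_counts(Y)
  if (is.character(k)) k <- match(k, colnames(Y))
  yk <- Y[, k]
  rest <- rowSums(Y) - yk
  if (all(yk == 0))
    return(list(effect_size = NA_real_, lr = NA_real_, df = 1L,
                pvalue = NA_real_))
  Y2 <- cbind(this = yk, rest = rest)
  full <- dm_optim(Y2, design, gamma, lambda = lambda, tol_grad = tol_grad)
  null_design <- design[, setdiff(colnames(design), condition), drop = FALSE]
  null <- dm_optim(Y2, null_design, gamma, lambda = lambda,
                   tol_grad = tol_grad)
  lr <- 2 * (full$objective - null$objective)
  if (lr < 0 && lr > -1e-6) lr <- 0
  list(effect_size = unname(full$beta[1, condition]), lr = lr, df = 1L,
       pvalue = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       converged = full$converged && null$converged)
}

#' Run the Dirichlet-multinomial DTU analysis over a filtered count matrix
#'
#' Rounds the (scaledTPM-scale) counts to integers, groups transcripts by
#' gene, estimates the moderated gene-wise precisions, and applies
#' [test_gene()] and [test_transcript()] to every multi-transcript gene.
#'
#' @param x a filtered [tx_counts] object.
#' @param design design matrix from [build_design()].
#' @param moderation,common_subsample passed to [estimate_precision()].
#' @param precision optional list as returned by [estimate_precision()]; if
#'   supplied, estimation is skipped.
#' @return list with data.frames `gene` (gene_id, lr, df, pvalue) and
#'   `transcript` (transcript_id, gene_id, effect_size, lr, df, pvalue), and
#'   `precision`.
#' @export
dm_dtu <- function(x, design, moderation = 10, common_subsample = NULL,
                   precision = NULL) {
  stopifnot(inherits(x, "tx_counts"))
  Yall <- round(x$counts)
  gene <- x$annotation$gene_id
  genes <- unique(gene[duplicated(gene)])  # >= 2 transcripts
  gene_counts <- lapply(genes, function(g)
    t(Yall[gene == g, , drop = FALSE]))
  names(gene_counts) <- genes
  if (is.null(precision))
    precision <- estimate_precision(gene_counts, design,
                                    moderation = moderation,
                                    common_subsample = common_subsample)
  gres <- vector("list", length(genes))
  tres <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    Y <- gene_counts[[g]]
    gm <- precision$gamma[[g]]
    if (is.na(gm)) gm <- precision$gamma0
    tg <- test_gene(Y, design, gm)
    gres[[i]] <- data.frame(gene_id = g, lr = tg$lr, df = tg$df,
                            pvalue = tg$pvalue)
    tt <- lapply(seq_len(ncol(Y)), function(k)
      test_transcript(Y, design, gm, k))
    tres[[i]] <- data.frame(
      transcript_id = colnames(Y),
      gene_id = g,
      effect_size = vapply(tt, `[[`, numeric(1), "effect_size"),
      lr = vapply(tt, `[[`, numeric(1), "lr"),
      df = 1L,
      pvalue = vapply(tt, `[[`, numeric(1), "pvalue"))
  }
  list(gene = do.call(rbind, gres),
       transcript = do.call(rbind, tres),
       precision = precision)
}
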