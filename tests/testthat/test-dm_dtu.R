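test_that("identical group profiles give a null condition coefficient", {
  # cases exactly duplicate controls -> the condition term has nothing to fit
  set.seed(2)
  half <- t(rmultinom(10, 400, c(0.5, 0.3, 0.2)))
  Y <- rbind(half, half)
  X <- cbind(intercept = 1, condition = rep(c(0, 1), each = 10))
  fit <- fit_dm(Y, X, gamma = 100)
  expect_true(fit$converged)
  expect_true(all(abs(fit$beta[, "condition"]) < 1e-4))
  tg <- test_gene(Y, X, gamma = 100)
  expect_equal(tg$lr, 0, tolerance = 1e-6)
  expect_equal(tg$pvalue, 1, tolerance = 1e-5)
})

test_that("ridge keeps separated fits finite and converged", {
  # transcript 2 observed only in cases
  Y <- cbind(t1 = c(rep(100L, 6), rep(60L, 6)),
             t2 = c(rep(0L, 6), rep(40L, 6)))
  X <- cbind(intercept = 1, condition = rep(c(0, 1), each = 6))
  fit <- fit_dm(Y, X, gamma = 50)
  expect_true(all(is.finite(fit$beta)))
  expect_true(fit$converged)
})

test_that("model entry rejects rank-deficient designs and fractional counts", {
  Y <- cbind(t1 = c(5L, 6L, 7L, 8L), t2 = c(5L, 4L, 3L, 2L))
  X <- cbind(intercept = 1, condition = c(0, 0, 1, 1))
  expect_error(fit_dm(Y, cbind(X, dup = X[, "condition"]), 50),
               "rank deficient")
  Yf <- Y; Yf[1, 1] <- 5.4
  expect_error(fit_dm(Yf, X, 50), "integer")
})

test_that("two-transcript genes: transcript test equals gene test, antisymmetric effects", {
  g <- gen_dm_gene(8, 8, base_logit = c(0.4, 0), case_shift = 0.8,
                   total = 300, gamma = 60, seed = 4)
  tg <- test_gene(g$Y, g$design, gamma = 60)
  t1 <- test_transcript(g$Y, g$design, gamma = 60, k = 1)
  t2 <- test_transcript(g$Y, g$design, gamma = 60, k = 2)
  expect_equal(t1$pvalue, tg$pvalue, tolerance = 1e-6)
  expect_equal(t1$effect_size, -t2$effect_size, tolerance = 1e-6)
  expect_gt(t1$effect_size, 0)  # increased usage in cases
})

test_that("at extreme precision the DM reduces to the multinomial", {
  g <- gen_dm_gene(10, 10, base_logit = c(0.5, -0.2, 0), case_shift = 0.7,
                   total = 200, gamma = Inf, seed = 6)
  # log-likelihood agreement at a fixed coefficient value
  beta <- matrix(c(0.3, -0.1, 0.2, 0.1), 2, 2)
  nll_dm <- usagekit:::dm_nll(as.vector(beta), g$Y, g$design,
                              gamma = 1e6, lambda = 0)
  eta <- cbind(g$design %*% t(beta), 0)
  pim <- exp(eta - apply(eta, 1, max)); pim <- pim / rowSums(pim)
  ll_multinom <- sum(g$Y * log(pim))
  expect_equal(-nll_dm, ll_multinom, tolerance = 1e-4)
  # p-value agreement with an independently fitted multinomial logit
  tg <- test_gene(g$Y, g$design, gamma = 1e6)
  expect_equal(tg$pvalue, oracle_multinom_p(g$Y, g$design), tolerance = 1e-3)
})

test_that("condition coefficient recovers a known log-odds shift", {
  # +1.0 softmax shift on transcript 1; reference is the dominant transcript
  g <- gen_dm_gene(30, 30, base_logit = c(-0.5, 0.2, 1.5), case_shift = 1.0,
                   total = 2000, gamma = 100, seed = 8)
  fit <- fit_dm(g$Y, g$design, gamma = 100)
  expect_equal(unname(fit$beta["t1", "condition"]), 1.0, tolerance = 0.25)
})

test_that("optimizer objective is monotone under warm-start continuation", {
  g <- gen_dm_gene(8, 8, base_logit = c(0.3, -0.4, 0), case_shift = 0.5,
                   total = 150, gamma = 40, seed = 10)
  init <- usagekit:::dm_init(g$Y, g$design)
  par <- as.vector(init)
  vals <- numeric(8)
  for (i in seq_len(8)) {
    o <- optim(par, usagekit:::dm_nll, usagekit:::dm_nll_grad,
               Y = g$Y, X = g$design, gamma = 40, lambda = 1e-6,
               method = "BFGS", control = list(maxit = 3))
    par <- o$par
    vals[i] <- o$value
  }
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("statistics are invariant to sample permutation", {
  g <- gen_dm_gene(7, 9, base_logit = c(0.2, -0.3, 0), case_shift = 0.6,
                   total = 250, gamma = 50, seed = 12)
  set.seed(1); perm <- sample(nrow(g$Y))
  tg1 <- test_gene(g$Y, g$design, gamma = 50)
  tg2 <- test_gene(g$Y[perm, ], g$design[perm, ], gamma = 50)
  expect_equal(tg1$lr, tg2$lr, tolerance = 1e-6)
  t1 <- test_transcript(g$Y, g$design, gamma = 50, k = 2)
  t2 <- test_transcript(g$Y[perm, ], g$design[perm, ], gamma = 50, k = 2)
  expect_equal(t1$effect_size, t2$effect_size, tolerance = 1e-6)
})

test_that("precision estimation recovers the simulated regime", {
  # moderate scale here; the full recovery bound runs in the acceptance suite
  set.seed(14)
  genes <- lapply(1:40, function(i)
    gen_dm_gene(8, 8, base_logit = c(rnorm(2, 0, 0.7), 0),
                total = 400, gamma = 50, seed = 100 + i)$Y)
  names(genes) <- sprintf("g%02d", 1:40)
  X <- cbind(intercept = 1, condition = rep(c(0, 1), each = 8))
  est <- estimate_precision(genes, X)
  expect_gt(median(est$gamma), 50 * 0.5)
  expect_lt(median(est$gamma), 50 * 2)

  # pure multinomial data drives the estimate to the upper region
  genes_m <- lapply(1:25, function(i)
    gen_dm_gene(8, 8, base_logit = c(rnorm(2, 0, 0.7), 0),
                total = 400, gamma = Inf, seed = 200 + i)$Y)
  names(genes_m) <- sprintf("m%02d", 1:25)
  est_m <- estimate_precision(genes_m, X)
  expect_gte(est_m$gamma0, 1e4)

  # a gene observed in a single sample is excluded with a warning
  bad <- genes[1:3]
  bad$degenerate <- matrix(0L, 16, 2)
  bad$degenerate[1, ] <- c(10L, 5L)
  expect_warning(est_b <- estimate_precision(bad, X), "excluded")
  expect_true(is.na(est_b$gamma[["degenerate"]]))
  expect_false(anyNA(est_b$gamma[names(genes)[1:3]]))
})

test_that("all-zero transcripts yield missing transcript results", {
  Y <- cbind(t1 = rep(50L, 8), t2 = rep(0L, 8), t3 = rep(30L, 8))
  X <- cbind(intercept = 1, condition = rep(c(0, 1), each = 4))
  tt <- test_transcript(Y, X, gamma = 50, k = 2)
  expect_true(is.na(tt$pvalue))
  expect_true(is.na(tt$effect_size))
})
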