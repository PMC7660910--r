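test_that("hypergeometric enrichment matches explicit tail summation", {
  bg <- sprintf("G%04d", 1:1000)
  hits <- bg[1:20]
  sets <- list(hot = c(bg[1:5], bg[101:145]),    # 5 of 50 are hits
               cold = bg[501:550])
  er <- enrich(hits, bg, sets)
  expect_equal(er$pvalue[er$set_id == "hot"],
               oracle_hyper_upper(5, 20, 1000, 50), tolerance = 1e-12)
  expect_gte(er$pvalue[er$set_id == "cold"], 0.5)  # disjoint from hits
  expect_error(enrich(c(hits, "OTHER"), bg, sets), "subset")
})

test_that("a fully-hit set attains the minimum enrichment p", {
  bg <- sprintf("G%03d", 1:400)
  hits <- bg[1:12]
  sets <- c(list(full = hits),
            lapply(setNames(1:100, paste0("s", 1:100)), function(i)
              bg[(i * 3):(i * 3 + 15)]))
  er <- enrich(hits, bg, sets)
  expect_equal(er$set_id[which.min(er$pvalue)], "full")
})

test_that("kappa agrees with the hand-computed contingency example", {
  u6 <- paste0("g", 1:6)
  expect_equal(kappa_sets(c("g1", "g2", "g3"), c("g2", "g3", "g4"), u6), 1 / 3)
  expect_equal(kappa_sets(u6[1:3], u6[1:3], u6), 1)
  expect_lt(kappa_sets(u6[1:3], u6[4:6], u6), 0)  # complementary partition
  # degenerate Pe = 1 cases
  expect_equal(kappa_sets(u6, u6, u6), 1)
  expect_error(kappa_sets("g1", "g1", "g1"), "at least 2")
})

test_that("clustering merges duplicates and respects the threshold", {
  u <- paste0("g", 1:30)
  sets <- list(a = u[1:10], b = u[1:10], c = u[21:28])
  cl <- cluster_pathways(names(sets), sets, threshold = 0.4, universe = u)
  expect_equal(sort(vapply(cl, paste, "", collapse = "+")),
               c("a+b", "c"))
  # far-apart sets stay singletons
  sets2 <- list(x = u[1:5], y = u[11:15], z = u[21:25])
  cl2 <- cluster_pathways(names(sets2), sets2, threshold = 0.4, universe = u)
  expect_length(cl2, 3)
})

test_that("greedy merging equals an independent reimplementation", {
  set.seed(61)
  u <- paste0("g", 1:40)
  for (i in 1:8) {
    sets <- lapply(setNames(1:4, paste0("s", 1:4)), function(j)
      sample(u, sample(6:18, 1)))
    got <- cluster_pathways(names(sets), sets, threshold = 0.3, universe = u)
    want <- oracle_cluster(sets, threshold = 0.3, universe = u)
    expect_setequal(vapply(got, paste, "", collapse = "+"),
                    vapply(want, paste, "", collapse = "+"))
    # termination: no inter-cluster kappa above the threshold remains
    if (length(got) > 1) {
      gsets <- lapply(got, function(cl) unique(unlist(sets[cl])))
      pairs <- combn(length(gsets), 2)
      kmax <- max(apply(pairs, 2, function(ij)
        kappa_sets(gsets[[ij[1]]], gsets[[ij[2]]], u)))
      expect_lte(kmax, 0.3)
    }
  }
})

test_that("Fisher aggregation matches the closed-form chi-square tail", {
  bg <- paste0("G", 1:50)
  er <- data.frame(set_id = c("p1", "p2"), category = "all",
                   set_size = c(10, 20), overlap = c(3, 2),
                   pvalue = c(0.01, 0.04))
  tp <- title_and_p(c("p1", "p2"), er)
  expect_equal(tp$statistic, -2 * (log(0.01) + log(0.04)), tolerance = 1e-12)
  expect_equal(tp$statistic, 15.65, tolerance = 0.01)
  expect_equal(tp$df, 4)
  expect_equal(tp$pvalue, oracle_chisq_upper_even(tp$statistic, 4),
               tolerance = 1e-12)
  expect_equal(tp$title, "p1")   # smallest p wins the title
  # singleton aggregation is the identity; all-ones aggregate to one
  expect_equal(title_and_p("p1", er)$pvalue, 0.01, tolerance = 1e-12)
  er1 <- er; er1$pvalue <- c(1, 1)
  expect_equal(title_and_p(c("p1", "p2"), er1)$pvalue, 1)
  # aggregating m copies of p = 0.01 is strictly decreasing in m
  agg <- vapply(1:5, function(m) {
    erm <- data.frame(set_id = paste0("q", 1:m), category = "all",
                      set_size = 10, overlap = 1, pvalue = 0.01)
    title_and_p(erm$set_id, erm)$pvalue
  }, numeric(1))
  expect_true(all(diff(agg) < 0))
})

test_that("full pipeline orders clusters by aggregated p-value", {
  set.seed(62)
  bg <- paste0("G", 1:300)
  hits <- bg[1:30]
  sets <- c(
    list(strong1 = c(hits[1:12], bg[40:60]),
         strong2 = c(hits[2:13], bg[41:61]),       # heavy overlap with strong1
         mild = c(hits[1:6], bg[100:160])),
    lapply(setNames(1:20, paste0("bgset", 1:20)), function(i)
      bg[seq(10 * i, 10 * i + 30)]))
  out <- pathway_clusters(hits, bg, sets)
  expect_true(all(diff(out$clusters$pvalue) >= 0))
  expect_true(any(grepl("strong1", out$clusters$members) &
                    grepl("strong2", out$clusters$members)))
  expect_true(all(out$enrichment$fdr >= out$enrichment$pvalue - 1e-15))
})

test_that("GMT round trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc A\tg1\tg2\tg3",
               "setB\tdesc B\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, c("g2", "g4"))
})
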