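test_that("closed-form depletion probability matches direct evaluation", {
  # log-space evaluation vs naive power as independent check
  expect_equal(depletionProbability(3861, 4629812, 4368),
               (1 - 3861 / 4629812)^4368, tolerance = 1e-12)
  expect_equal(depletionProbability(3861, 4629812, 4368), 0.0261,
               tolerance = 0.01)
  expect_equal(depletionProbability(0, 100, 50), 1)
  expect_equal(depletionProbability(10, 100, 0), 1)
  expect_equal(depletionProbability(100, 100, 3), 0)
  expect_error(depletionProbability(200, 100, 1), "\\[0, g\\]")
})

test_that("depletion probability decreases in target size and count", {
  p <- vapply(seq(0, 1000, by = 100),
              function(t) depletionProbability(t, 10000, 100), numeric(1))
  expect_true(all(diff(p) < 0))
  p2 <- vapply(seq(0, 500, by = 50),
               function(n) depletionProbability(100, 10000, n), numeric(1))
  expect_true(all(diff(p2) < 0))
})

test_that("effective target size rescales physical size by local density", {
  lay <- GenomeLayout(4600, 17, 46L)
  genes <- data.frame(gene = c("a", "b"), start = c(101, 301),
                      end = c(200, 350), strand = c(1, -1))
  # exactly uniform density (every position once): t_eff = physical t
  mu <- do.call(rbind, lapply(seq(1, 4600, by = 4),
                              function(p) mut_row(position = p)))
  t_eff <- effectiveTargetSize(c("a", "b"), mu, lay, genes = genes,
                               annotation_filter = NULL)
  expect_equal(t_eff, 150)
  # gene set in a bin with half the genome-mean density: t_eff = t/2
  lay2 <- GenomeLayout(1000, 251, 2L)  # bins: positions 751..250 / 251..750
  g2 <- data.frame(gene = "a", start = 401, end = 500, strand = 1)
  m2 <- rbind(
    do.call(rbind, lapply(1:100, function(i)
      mut_row(position = sample(251:750, 1)))),        # bin 1: 100 muts
    do.call(rbind, lapply(1:300, function(i)
      mut_row(position = sample(c(1:250, 751:1000), 1)))))  # bin 0: 300
  expect_equal(effectiveTargetSize("a", m2, lay2, genes = g2,
                                   annotation_filter = NULL), 50)
  expect_error(effectiveTargetSize("a", m2[0, ], lay2, genes = g2,
                                   annotation_filter = NULL), "no mutations")
})

test_that("bin-spanning genes use length-weighted bin densities", {
  lay <- GenomeLayout(1000, 251, 2L)   # bin 1 = positions 251..750
  # 3-gene set: one fully in bin 1, one fully in bin 0, one split 50:50
  genes <- data.frame(gene = c("a", "b", "c"),
                      start = c(301, 801, 701), end = c(400, 850, 800),
                      strand = c(1, 1, 1))
  # bin densities: bin1 = 400/500, bin0 = 100/500; mean = 500/1000
  m <- rbind(
    do.call(rbind, lapply(seq(260, 740, length.out = 400), function(p)
      mut_row(position = round(p)))),
    do.call(rbind, lapply(seq(860, 990, length.out = 100), function(p)
      mut_row(position = round(p)))))
  # hand-computed: a: 100 * (0.8/0.5); b: 50 * (0.2/0.5);
  #                c: 50 * (0.8/0.5) + 50 * (0.2/0.5)
  expected <- 100 * 1.6 + 50 * 0.4 + 50 * 1.6 + 50 * 0.4
  expect_equal(effectiveTargetSize(c("a", "b", "c"), m, lay, genes = genes,
                                   annotation_filter = NULL), expected)
  # whole-chromosome bin recovers the physical size
  expect_equal(effectiveTargetSize(c("a", "b", "c"), m, lay, genes = genes,
                                   bin_size = 1000, annotation_filter = NULL),
               250)
})

test_that("randomization depletion test matches the closed form under a uniform null", {
  g <- 10000; t_bp <- 500; n <- 50
  lay <- GenomeLayout(g, 1, 1L)    # single whole-chromosome bin
  genes <- data.frame(gene = "set", start = 2001, end = 2500, strand = 1)
  set.seed(123)
  pos <- sample(setdiff(1:g, 2001:2500), n)   # zero observed hits
  m <- do.call(rbind, lapply(pos, function(p) mut_row(position = p)))
  r <- depletionRandomizationTest("set", m, lay, genes = genes,
                                  n_boot = 10000, seed = 17,
                                  annotation_filter = NULL)
  p_exact <- depletionProbability(t_bp, g, n)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(pValue(r) - p_exact), 3 * mc_se + 1e-4)
  expect_equal(testStatistic(r), 0)
})

test_that("depletion test is one-tailed: excess mutations give p ~ 1", {
  lay <- GenomeLayout(10000, 1, 10L)
  genes <- data.frame(gene = "set", start = 2001, end = 2100, strand = 1)
  m <- do.call(rbind, lapply(sample(2001:2100, 60, replace = TRUE),
                             function(p) mut_row(position = p)))
  m <- rbind(m, do.call(rbind, lapply(seq(100, 9900, by = 200),
                                      function(p) mut_row(position = p))))
  r <- depletionRandomizationTest("set", m, lay, genes = genes,
                                  n_boot = 500, seed = 2,
                                  annotation_filter = NULL)
  expect_gt(pValue(r), 0.95)
})

test_that("depletion bin scan covers local to whole-chromosome nulls", {
  lay <- GenomeLayout(4629812, 3886082, 46L)
  genes <- data.frame(gene = c("topA", "dusB", "fis"),
                      start = c(1330000, 3410000, 3412000),
                      end = c(1330000 + 2597, 3410965, 3412296),
                      strand = c(-1, -1, 1))
  m <- simulatePopulation(flat_timeline(T = 500, point = 8), lay, genes,
                          seed = 41)
  sc <- depletionBinScan(c("topA", "fis", "dusB"), m, lay, genes = genes,
                         n_boot = 500, seed = 7, annotation_filter = NULL)
  expect_equal(nrow(sc), 5)
  expect_equal(sc$n_bins[nrow(sc)], 1)
  expect_true(all(sc$p_value > 0 & sc$p_value <= 1))
})

test_that("gene-set resampling test has correct degenerate and signal behavior", {
  lay <- tiny_layout(50000, 100, 10L)
  genes <- tile_genes(n = 50, len = 600, L = 50000, from = 500)
  m <- simulatePopulation(flat_timeline(T = 2000, point = 1), lay, genes,
                          seed = 13)
  # degenerate set = all genes: null statistic equals observed, p = 1
  r_all <- stimsTest(m, genes$gene, genes, "X", n_boot = 200, seed = 3)
  expect_equal(pValue(r_all), 1)
  # strong purifying signal: empty the focal genes of mutations
  focal <- paste0("g", 1:10)
  m2 <- m[!m$gene %in% focal, ]
  r_dep <- stimsTest(m2, focal, genes, "X", n_boot = 2000, seed = 5,
                     tail = "lower")
  expect_lt(pValue(r_dep), 0.01)
  # and the upper tail sees nothing
  r_up <- stimsTest(m2, focal, genes, "X", n_boot = 500, seed = 5,
                    tail = "upper")
  expect_gt(pValue(r_up), 0.5)
  expect_error(stimsTest(m, "absent_gene", genes, "X", n_boot = 10, seed = 1),
               "missing from annotation")
  expect_error(stimsTest(m, character(0), genes, "X", seed = 1), "nonempty")
})

test_that("length-matched resampling keeps null set sizes near the target", {
  lay <- tiny_layout(50000, 100, 10L)
  genes <- tile_genes(n = 30, len = 900, L = 50000)
  genes$end <- genes$start + rep(c(199, 399, 799), 10)  # mixed lengths
  m <- simulatePopulation(flat_timeline(T = 1500, point = 1), lay, genes,
                          seed = 19)
  r <- stimsTest(m, c("g1", "g2", "g3"), genes, "X", n_boot = 200, seed = 23,
                 match = "length")
  expect_s4_class(r, "TestResult")
  expect_match(nullDescription(r), "length-matched")
})

test_that("randomization p-values are reproducible and never zero", {
  lay <- GenomeLayout(10000, 1, 5L)
  genes <- data.frame(gene = "set", start = 1, end = 9999, strand = 1)
  m <- do.call(rbind, lapply(seq(10, 9990, by = 10),
                             function(p) mut_row(position = p)))
  r1 <- depletionRandomizationTest("set", m, lay, genes = genes,
                                   n_boot = 200, seed = 11,
                                   annotation_filter = NULL)
  r2 <- depletionRandomizationTest("set", m, lay, genes = genes,
                                   n_boot = 200, seed = 11,
                                   annotation_filter = NULL)
  expect_identical(pValue(r1), pValue(r2))
  expect_gt(pValue(r1), 0)
  expect_warning(depletionRandomizationTest("set", m, lay, genes = genes,
                                            n_boot = 50, seed = 1,
                                            annotation_filter = NULL),
                 "unstable")
})
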