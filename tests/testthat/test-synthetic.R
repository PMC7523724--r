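test_that("simulation is byte-identical under a fixed seed", {
  lay <- tiny_layout(50000, 100, 10L)
  genes <- tile_genes()
  tl <- flat_timeline(point = 0.5, indel = 0.1, sv = 0.05)
  a <- simulatePopulation(tl, lay, genes, wave = WaveParams(0.3),
                          beta = 2, seed = 7)
  b <- simulatePopulation(tl, lay, genes, wave = WaveParams(0.3),
                          beta = 2, seed = 7)
  expect_identical(a, b)
  c <- simulatePopulation(tl, lay, genes, wave = WaveParams(0.3),
                          beta = 2, seed = 8)
  expect_false(identical(a$position, c$position))
  expect_error(simulatePopulation(tl, lay, genes), "seed is mandatory")
})

test_that("zero rates produce an empty record list", {
  lay <- tiny_layout(50000, 100, 10L)
  m <- simulatePopulation(flat_timeline(point = 0, indel = 0, sv = 0),
                          lay, NULL, seed = 1)
  expect_equal(nrow(m), 0)
  expect_equal(names(m), mutationColumns())
})

test_that("flat simulation is uniform over bins (chi-square GOF)", {
  lay <- GenomeLayout(46000, 12345, 46L)
  tl <- flat_timeline(T = 100, point = 50)  # ~5000 points per seed
  n_ok <- 0
  for (s in 1:20) {
    m <- simulatePopulation(tl, lay, NULL, wave = WaveParams(0), seed = s)
    cnt <- binnedDistribution(m, lay)$count
    stat <- sum((cnt - mean(cnt))^2 / mean(cnt))
    if (stat < qchisq(0.999, df = 45)) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 19)
})

test_that("wave amplitude is recovered from binned counts", {
  lay <- GenomeLayout(4629812, 3886082, 46L)
  tl <- flat_timeline(T = 400, point = 50)  # ~20000 mutations
  for (s in 1:3) {
    m <- simulatePopulation(tl, lay, NULL, wave = WaveParams(0.5), seed = s)
    cnt <- binnedDistribution(m, lay)$count
    expect_lt(abs(estimateWaveAmplitude(cnt, lay, "minmax") - 0.5), 0.1)
    expect_lt(abs(estimateWaveAmplitude(cnt, lay, "cosfit") - 0.5), 0.05)
  }
  # A = 0.5 means a 1:3 trough-to-peak rate ratio by construction
  expect_equal(troughPeakRatio(WaveParams(0.5)), 1 / 3)
  expect_equal(troughPeakRatio(WaveParams(0)), 1)
})

test_that("orientation bias converges to beta-weighted coding composition", {
  lay <- GenomeLayout(50000, 100, 10L)
  genes <- tile_genes(n = 40, len = 800, L = 50000, from = 600)
  ori <- suppressWarnings(geneOrientation(genes, lay))
  cc <- codingComposition(genes[!is.na(ori), ], lay,
                          stratify_by = "orientation")
  nt_co <- cc$nt[cc$stratum == "co-directional"]
  nt_ho <- cc$nt[cc$stratum == "head-on"]
  beta <- 3
  m <- simulatePopulation(flat_timeline(T = 600, point = 50), lay, genes,
                          beta = beta, seed = 11)
  glk_ori <- as.character(ori)[match(m$gene, genes$gene)]
  k_ho <- sum(glk_ori == "head-on", na.rm = TRUE)
  k_co <- sum(glk_ori == "co-directional", na.rm = TRUE)
  expected <- beta * nt_ho / (beta * nt_ho + nt_co)
  expect_lt(abs(k_ho / (k_ho + k_co) - expected), 0.03)
})

test_that("presets span the documented mutator regimes", {
  pre <- presetPopulations()
  expect_length(pre, 12)
  expect_setequal(names(pre), paste0(rep(c("Ara-", "Ara+"), each = 6), 1:6))
  # mutT-like: spectrum concentrated on A:T->C:G after the switch
  iv6 <- timelineIntervals(pre[["Ara+6"]])
  expect_gt(iv6$wAT_CG[2], 0.5)
  expect_lt(iv6$wAT_CG[1], 0.5)
  # nonmutator point rate is far below the MMR hypermutator rate
  ivn <- timelineIntervals(pre[["Ara+2"]])
  ivh <- timelineIntervals(pre[["Ara+3"]])
  expect_lt(ivn$point_rate[1] * 10, ivh$point_rate[nrow(ivh)])
  # mutL phase reversion restores pre-hypermutator rates exactly
  iv2 <- timelineIntervals(pre[["Ara-2"]])
  last <- nrow(iv2)
  expect_equal(iv2$point_rate[last], iv2$point_rate[1])
  expect_equal(iv2$indel_rate[last], iv2$indel_rate[1])
  expect_equal(iv2$sv_rate[last], iv2$sv_rate[1])
  # every preset covers [0, T] contiguously (validity already enforces it)
  for (tlx in pre) expect_equal(totalGenerations(tlx), 60000)
})

test_that("timeline validity rejects gaps, overlaps and bad weights", {
  iv <- timelineIntervals(flat_timeline())
  bad <- rbind(iv, iv)             # duplicate: overlapping
  expect_error(MutatorTimeline("X", bad), "contiguous")
  iv2 <- iv; iv2$t_start <- 10     # does not start at 0
  expect_error(MutatorTimeline("X", iv2), "start at 0")
  iv3 <- iv; iv3$point_rate <- -1
  expect_error(MutatorTimeline("X", iv3), "non-negative")
  iv4 <- iv; iv4$wAT_CG <- -0.5
  expect_error(MutatorTimeline("X", iv4), "weights")
})

test_that("simulated spectra follow the interval weights", {
  lay <- tiny_layout(50000, 100, 10L)
  pre <- presetPopulations(T = 20000)
  m <- simulatePopulation(pre[["Ara+6"]], lay, NULL, seed = 3)
  post <- m[m$mclass == "point" & m$appearance_time > 4750, ]
  cls <- classifySpectrum(post$base_from, post$base_to)
  expect_equal(names(which.max(table(cls))), "A:T->C:G")
  expect_gt(mean(cls == "A:T->C:G"), 0.8)
})
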