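test_that("oriC-centered offsets follow circular arithmetic", {
  lay <- tiny_layout(100, 10)
  expect_equal(oricOffset(10, lay), 0)
  expect_equal(oricOffset(60, lay), 50)   # antipode resolves to +L/2
  expect_equal(oricOffset(11, lay), 1)
  expect_equal(oricOffset(9, lay), -1)
  # direct modular-arithmetic oracle on a genome-sized chromosome
  big <- GenomeLayout(4629812, 1000)
  expect_equal(oricOffset(1000 + 100000, big), 100000)
  expect_equal(oricOffset(4629812, big), -1000)
  expect_error(oricOffset(0, lay), "out of range")
  expect_error(oricOffset(101, lay), "out of range")
})

test_that("offset mapping is a bijection invertible by offsetToPos", {
  for (L in c(10, 11, 100, 101)) {
    lay <- GenomeLayout(L, 3)
    off <- oricOffset(1:L, lay)
    expect_length(unique(off), L)
    expect_true(all(off > -L / 2 & off <= L / 2))
    expect_equal(offsetToPos(off, lay), 1:L)
  }
})

test_that("equal-width bins partition all positions with centered convention", {
  lay <- GenomeLayout(4600, 17, 46L)
  bins <- assignBin(1:4600, lay)
  tab <- table(factor(bins, levels = 0:45))
  expect_true(all(tab == 100))           # exact equal partition
  expect_equal(assignBin(17, lay), 23L)  # oriC -> first bin right of center
  # indivisible length: bin sizes differ by at most 1, still gap-free
  lay2 <- GenomeLayout(1003, 5, 7L)
  tab2 <- table(factor(assignBin(1:1003, lay2), levels = 0:6))
  expect_equal(sum(tab2), 1003)
  expect_lte(diff(range(tab2)), 1)
  # degenerate single-bin partition
  lay1 <- GenomeLayout(100, 10, 1L)
  expect_true(all(assignBin(1:100, lay1) == 0L))
})

test_that("binning conserves counts for arbitrary position multisets", {
  lay <- GenomeLayout(997, 300, 13L)
  set.seed(42)
  for (i in 1:5) {
    pos <- sample.int(997, 200, replace = TRUE)
    b <- assignBin(pos, lay)
    expect_length(b, 200)
    expect_true(all(b >= 0 & b < 13))
  }
})

test_that("gene orientation matches replisome travel and flips correctly", {
  lay <- GenomeLayout(1000, 100, 4L)
  # two genes per replichore, alternating strands: 2 co-directional, 2 head-on
  g <- data.frame(gene = c("a", "b", "c", "d"),
                  start = c(200, 300, 700, 800),
                  end = c(250, 350, 750, 850),
                  strand = c(1, -1, -1, 1))
  ori <- geneOrientation(g, lay)
  expect_equal(as.character(ori),
               c("co-directional", "head-on", "co-directional", "head-on"))
  # strand flip at fixed location flips the class
  g2 <- g; g2$strand <- -g$strand
  expect_equal(as.character(geneOrientation(g2, lay)),
               c("head-on", "co-directional", "head-on", "co-directional"))
  # mirroring across oriC at fixed strand flips the class
  gm <- data.frame(gene = "a", start = 950, end = 1000, strand = 1)
  expect_equal(as.character(geneOrientation(gm, lay)), "head-on")
})

test_that("genes spanning oriC or the antipode are flagged ambiguous", {
  lay <- GenomeLayout(1000, 100, 4L)
  g <- data.frame(gene = c("span_oric", "span_anti", "ok"),
                  start = c(90, 580, 200), end = c(110, 620, 260),
                  strand = c(1, 1, 1))
  expect_warning(ori <- geneOrientation(g, lay), "span_oric")
  expect_true(is.na(ori[1]))
  expect_true(is.na(ori[2]))
  expect_equal(as.character(ori[3]), "co-directional")
})

test_that("coding composition conserves nucleotides across strata", {
  lay <- GenomeLayout(1000, 100, 4L)
  g <- data.frame(gene = c("a", "b"), start = c(200, 700),
                  end = c(499, 999), strand = c(1, 1))
  cc <- codingComposition(g, lay, stratify_by = "orientation")
  expect_equal(sort(cc$nt), c(300, 300))
  expect_equal(sum(cc$nt), sum(g$end - g$start + 1))
  # single 10 bp gene: strata sum to 10 under every stratification
  g1 <- data.frame(gene = "x", start = 201, end = 210, strand = -1)
  for (s in c("strand", "orientation", "bin"))
    expect_equal(sum(codingComposition(g1, lay, stratify_by = s)$nt), 10)
  # bin stratification splits a bin-spanning gene without loss
  lay2 <- GenomeLayout(1000, 100, 10L)
  gs <- data.frame(gene = "y", start = 101, end = 400, strand = 1)
  ccb <- codingComposition(gs, lay2, stratify_by = "bin")
  expect_equal(sum(ccb$nt), 300)
  expect_gt(sum(ccb$nt > 0), 1)
})

test_that("overlap policies are enforced", {
  lay <- GenomeLayout(1000, 100, 4L)
  g <- data.frame(gene = c("a", "b"), start = c(200, 250),
                  end = c(300, 350), strand = c(1, 1))
  expect_error(codingComposition(g, lay, stratify_by = "strand",
                                 overlap = "strict"), "overlapping")
  expect_message(cc <- codingComposition(g, lay, stratify_by = "strand"),
                 "51 overlapping")
  expect_equal(sum(cc$nt), 202)  # gene-centric: overlap counted per gene
})

test_that("gene table reader parses strand dialects and validates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstart\tend\tstrand\tproduct",
               "topA\t100\t2697\t+\ttopoisomerase I",
               "fis\t3000\t3296\t-1\tDNA-binding protein"), f)
  g <- readGeneTable(f)
  expect_equal(g$strand, c(1, -1))
  expect_equal(g$end - g$start + 1, c(2598, 297))
  writeLines(c("gene\tstart\tend", "x\t1\t10"), f)
  expect_error(readGeneTable(f), "missing required columns")
})

test_that("GFF3 CDS reader produces a valid gene table", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t100\t400\t.\t+\t.\tID=gene1;gene=topA",
               "chr\tsrc\tCDS\t100\t400\t.\t+\t0\tID=cds1;gene=topA",
               "chr\tsrc\tCDS\t600\t896\t.\t-\t0\tID=cds2;gene=fis"), f)
  g <- readGenesGFF3(f)
  expect_equal(nrow(g), 2)
  expect_equal(g$gene, c("topA", "fis"))
  expect_equal(g$strand, c(1, -1))
})
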