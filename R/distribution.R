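#' Binned oriC-centered genomic distribution of mutations
#'
#' Counts mutations per equal-width bin on the oriC-centered axis,
#' optionally restricted to a set of populations and stratified by
#' functional annotation or by the strand/orientation of the containing
#' gene. Counts always conserve the input: every selected record lands in
#' exactly one bin (and, when stratifying by gene properties, intergenic
#' records form their own `"intergenic"` stratum).
#'
#' @param muts A validated mutation `data.frame`.
#' @param layout A [GenomeLayout-class].
#' @param populations Populations to include (default: all).
#' @param strata `NULL`, `"annotation"`, `"strand"` or `"orientation"`.
#' @param genes Gene annotation, required for `"strand"`/`"orientation"`.
#' @return A `data.frame` with `bin` (0-based), `stratum` (if stratified)
#'   and `count`; attribute `layout` carries the binning scheme.
#' @export
binnedDistribution <- function(muts, layout, populations = NULL,
                               strata = NULL, genes = NULL) {
  m <- if (is.null(populations)) muts
       else muts[muts$population %in% populations, , drop = FALSE]
  bins <- factor(assignBin(m$position, layout), levels = 0:(nBins(layout) - 1L))
  if (is.null(strata)) {
    out <- data.frame(bin = 0:(nBins(layout) - 1L),
                      count = as.integer(table(bins)))
  } else {
    strata <- match.arg(strata, c("annotation", "strand", "orientation"))
    if (strata == "annotation") {
      s <- factor(m$annotation, levels = .annotations)
    } else {
      if (is.null(genes))
        stop("genes annotation required for strand/orientation strata")
      glk <- .gene_lookup(genes, layout)
      gname <- .lookup_gene(m$position, glk)
      idx <- match(gname, glk$gene)
      if (strata == "strand") {
        og <- genes[order(genes$start), , drop = FALSE]
        lab <- as.character(og$strand[idx])
      } else {
        lab <- ifelse(glk$head_on[idx], "head-on", "co-directional")
      }
      lab[is.na(gname)] <- "intergenic"
      s <- factor(lab)
    }
    tab <- table(bins, s)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("bin", "stratum", "count")
    out$bin <- as.integer(as.character(out$bin))
  }
  attr(out, "layout") <- layout
  out
}

#' Exact two-tailed binomial test of gene-orientation mutation bias
#'
#' Tests whether mutations split between the two gene orientations (or
#' strands) in proportion to the coding nucleotides each contains. Under the
#' null, each of the `k_with + k_against` mutations independently falls in
#' the first category with probability `nt_with / (nt_with + nt_against)`;
#' the p-value is the exact two-tailed binomial probability by the
#' minimum-likelihood method (the sum over all outcomes at most as probable
#' as the one observed).
#'
#' @param k_with,k_against Observed mutation counts in the two categories.
#' @param nt_with,nt_against Coding nucleotide totals of the two categories
#'   (the null weights, from [codingComposition()]).
#' @return A [TestResult-class]; the statistic is the observed proportion
#'   `k_with / (k_with + k_against)`.
#' @examples
#' orientationBinomialTest(2066, 2664, 1730238, 2066587)
#' @export
orientationBinomialTest <- function(k_with, k_against, nt_with, nt_against) {
  if (k_with < 0 || k_against < 0 || nt_with < 0 || nt_against < 0)
    stop("counts must be non-negative")
  n <- k_with + k_against
  if (n == 0) stop("zero trials: no mutations to test")
  if (nt_with + nt_against <= 0) stop("coding composition totals must be > 0")
  p0 <- nt_with / (nt_with + nt_against)
  bt <- stats::binom.test(k_with, n, p0)
  .test_result(
    method = "exact binomial test of orientation bias",
    statistic = k_with / n, p_value = bt$p.value, tails = "two-tailed",
    null = sprintf(paste0("mutations fall in category 1 with probability ",
                          "%d/%d = %.5f (coding-composition null); ",
                          "two-tailed by minimum likelihood"),
                   nt_with, nt_with + nt_against, p0),
    n = n)
}

#' Two-sample Kolmogorov-Smirnov test on oriC-centered positions
#'
#' Compares two sets of mutation positions after mapping both onto the
#' oriC-centered axis. `D` is the supremum distance between the two
#' empirical CDFs; the p-value uses the asymptotic two-sample distribution.
#' The statistic is invariant under any common strictly monotone transform
#' of both samples, so the choice of axis affects only interpretability,
#' not `D`, as long as both samples share it.
#'
#' @param positions_a,positions_b Non-empty vectors of 1-based positions.
#' @param layout A [GenomeLayout-class], or `NULL` to compare the raw
#'   values without remapping.
#' @return A [TestResult-class] with statistic `D`.
#' @export
ksTwoSample <- function(positions_a, positions_b, layout = NULL) {
  if (!length(positions_a) || !length(positions_b))
    stop("both samples must be non-empty")
  a <- if (is.null(layout)) positions_a else oricOffset(positions_a, layout)
  b <- if (is.null(layout)) positions_b else oricOffset(positions_b, layout)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  .test_result(
    method = "two-sample Kolmogorov-Smirnov test",
    statistic = unname(kt$statistic), p_value = kt$p.value,
    tails = "two-tailed",
    null = "both position samples drawn from the same distribution on the oriC-centered axis",
    n = c(length(a), length(b)))
}

#' Binned chi-square comparison of two position samples
#'
#' A coarser alternative to [ksTwoSample()]: both samples are binned on the
#' oriC-centered axis and compared with a chi-square test of homogeneity on
#' the resulting `2 x n_bins` table. Non-default; the KS test on raw
#' positions is the primary comparison.
#'
#' @inheritParams ksTwoSample
#' @param layout A [GenomeLayout-class] (required here).
#' @return A [TestResult-class] with the X-squared statistic.
#' @export
binnedChisqTest <- function(positions_a, positions_b, layout) {
  if (!length(positions_a) || !length(positions_b))
    stop("both samples must be non-empty")
  lev <- 0:(nBins(layout) - 1L)
  ta <- table(factor(assignBin(positions_a, layout), levels = lev))
  tb <- table(factor(assignBin(positions_b, layout), levels = lev))
  keep <- (ta + tb) > 0
  ct <- suppressWarnings(stats::chisq.test(rbind(ta[keep], tb[keep])))
  .test_result(
    method = "binned chi-square homogeneity test",
    statistic = unname(ct$statistic), p_value = ct$p.value,
    tails = "upper",
    null = sprintf("equal per-bin proportions across %d oriC-centered bins",
                   nBins(layout)),
    n = c(length(positions_a), length(positions_b)))
}
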