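#' Closed-form gene-set depletion probability
#'
#' The probability that none of `n` uniformly and independently placed
#' mutations hits a target of `t` bp on a chromosome of `g` bp:
#' `P = (1 - t/g)^n`, evaluated in log space. For the three DNA-topology
#' genes topA, fis and dusB (combined physical target 3,861 bp) on a
#' 4,629,812 bp chromosome with 4,368 observed mutations this is ~0.026.
#'
#' @param t Target size in bp (`0 <= t <= g`).
#' @param g Chromosome length in bp.
#' @param n Number of placed mutations.
#' @return The probability `(1 - t/g)^n`.
#' @examples
#' depletionProbability(3861, 4629812, 4368)
#' @export
depletionProbability <- function(t, g, n) {
  if (g <= 0) stop("g must be > 0")
  if (t < 0 || t > g) stop("t must lie in [0, g]")
  if (n < 0) stop("n must be >= 0")
  if (t == g) return(as.numeric(n == 0))
  exp(n * log1p(-t / g))
}

.gene_set_df <- function(gene_set, genes) {
  if (is.character(gene_set)) {
    miss <- setdiff(gene_set, genes$gene)
    if (length(miss))
      stop("gene set members missing from annotation: ",
           paste(miss, collapse = ", "))
    genes[genes$gene %in% gene_set, , drop = FALSE]
  } else gene_set
}

.layout_for_bin_size <- function(layout, bin_size) {
  if (is.null(bin_size)) return(layout)
  L <- genomeLength(layout)
  if (bin_size < 1 || bin_size > L) stop("bin_size must lie in [1, g]")
  GenomeLayout(L, oricPos(layout), max(1L, as.integer(round(L / bin_size))))
}

.filter_annotation <- function(muts, annotation_filter) {
  if (is.null(annotation_filter)) muts
  else muts[muts$annotation %in% annotation_filter, , drop = FALSE]
}

#' Effective mutational target size of a gene set
#'
#' Rescales a gene set's physical length by the local mutation density:
#' each gene's length is multiplied by the mutation density of the
#' oriC-centered bin(s) it occupies, relative to the genome-wide mean
#' density. A gene set sitting in the trough of a rate wave therefore has a
#' smaller effective than physical target. Genes spanning two bins
#' contribute length-weighted bin densities. Under exactly uniform density
#' the effective size equals the physical size.
#'
#' @param gene_set Character vector of gene names, or a gene annotation
#'   subset `data.frame`.
#' @param muts A validated mutation `data.frame` (already restricted to the
#'   population of interest).
#' @param layout A [GenomeLayout-class].
#' @param genes Full gene annotation (needed when `gene_set` is names).
#' @param bin_size Optional bin size in bp overriding `nBins(layout)`.
#' @param annotation_filter Annotation classes to count (default: missense,
#'   indel and structural mutations, i.e. excluding synonymous); `NULL` for
#'   all.
#' @return Effective target size in bp.
#' @export
effectiveTargetSize <- function(gene_set, muts, layout, genes = NULL,
                                bin_size = NULL,
                                annotation_filter = c("missense", "indel",
                                                      "sv")) {
  gs <- .gene_set_df(gene_set, genes)
  lay <- .layout_for_bin_size(layout, bin_size)
  m <- .filter_annotation(muts, annotation_filter)
  N <- nrow(m)
  if (N == 0) stop("no mutations after filtering; density undefined")
  cnt <- as.integer(table(factor(assignBin(m$position, lay),
                                 levels = 0:(nBins(lay) - 1L))))
  # t_eff = sum_g sum_k ovl_{g,k} * (count_k / w) / (N / L)
  #       = sum_g sum_k ovl_{g,k} * count_k * n_bins / N
  ovl <- matrix(vapply(seq_len(nrow(gs)),
                       function(i) .bin_overlap(gs$start[i], gs$end[i], lay),
                       numeric(nBins(lay))),
                nrow = nBins(lay))
  sum(t(ovl) %*% cnt) * nBins(lay) / N
}

#' One-tailed randomization test for gene-set mutation depletion
#'
#' Tests whether a gene set contains fewer mutations than expected under a
#' placement null that respects large-scale rate variation: `n` mutations
#' are re-scattered over the chromosome by a multinomial draw over
#' oriC-centered bins with the empirical per-bin probabilities, uniformly
#' within each bin, and the number landing inside the gene set is compared
#' with the observed count. With a single whole-chromosome bin this reduces
#' exactly to uniform placement, against which the test is validated by the
#' closed form [depletionProbability()]. The one-tailed p-value carries the
#' `(1 + b)/(1 + n_boot)` correction, so it is never zero.
#'
#' @inheritParams effectiveTargetSize
#' @param n_boot Number of bootstrap replicates (default 10000; fewer than
#'   100 triggers a warning).
#' @param seed Mandatory RNG seed.
#' @return A [TestResult-class]; the statistic is the observed mutation
#'   count inside the gene set.
#' @export
depletionRandomizationTest <- function(gene_set, muts, layout, genes = NULL,
                                       bin_size = NULL, n_boot = 10000,
                                       seed,
                                       annotation_filter = c("missense",
                                                             "indel", "sv")) {
  if (missing(seed)) stop("seed is mandatory for randomization tests")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (n_boot < 100) warning("n_boot < 100 gives unstable p-values")
  gs <- .gene_set_df(gene_set, genes)
  lay <- .layout_for_bin_size(layout, bin_size)
  m <- .filter_annotation(muts, annotation_filter)
  N <- nrow(m)
  if (N == 0) stop("no mutations after filtering")
  glk <- .gene_lookup(gs, lay)
  obs <- sum(!is.na(.lookup_gene(m$position, glk)))
  nb <- nBins(lay)
  cnt <- as.integer(table(factor(assignBin(m$position, lay),
                                 levels = 0:(nb - 1L))))
  set.seed(seed)
  # per-bin gene-set coverage fraction (integer positions)
  cov <- rowSums(matrix(vapply(seq_len(nrow(gs)),
                               function(i) .bin_overlap(gs$start[i],
                                                        gs$end[i], lay),
                               numeric(nb)),
                        nrow = nb))
  frac <- cov / .bin_sizes(lay)
  draws <- stats::rmultinom(n_boot, N, prob = cnt / N)
  hits <- colSums(matrix(stats::rbinom(length(draws), as.vector(draws),
                                       rep(frac, n_boot)),
                         nrow = nb))
  p <- (1 + sum(hits <= obs)) / (1 + n_boot)
  .test_result(
    method = "gene-set depletion randomization test",
    statistic = obs, p_value = p, tails = "lower",
    null = sprintf(paste0("%d mutations re-placed by multinomial over %d ",
                          "oriC-centered bins with empirical bin ",
                          "probabilities, uniform within bins"), N, nb),
    n = N, seed = seed)
}

#' Scan depletion tests over a grid of bin sizes
#'
#' Runs [depletionRandomizationTest()] at several bin sizes, from local
#' (100 kb) to a single whole-chromosome bin, to check that a depletion
#' signal is not an artifact of the spatial scale at which the null density
#' is estimated.
#'
#' @inheritParams depletionRandomizationTest
#' @param bin_sizes Bin sizes in bp; `Inf` means one whole-chromosome bin.
#' @return A `data.frame` with `bin_size`, `n_bins`, `observed`, `p_value`.
#' @export
depletionBinScan <- function(gene_set, muts, layout, genes = NULL,
                             bin_sizes = c(1e5, 2e5, 5e5, 1e6, Inf),
                             n_boot = 10000, seed,
                             annotation_filter = c("missense", "indel",
                                                   "sv")) {
  if (missing(seed)) stop("seed is mandatory for randomization tests")
  res <- lapply(seq_along(bin_sizes), function(i) {
    bs <- min(bin_sizes[i], genomeLength(layout))
    tr <- depletionRandomizationTest(gene_set, muts, layout, genes,
                                     bin_size = bs, n_boot = n_boot,
                                     seed = seed + i - 1,
                                     annotation_filter = annotation_filter)
    data.frame(bin_size = bs,
               n_bins = nBins(.layout_for_bin_size(layout, bs)),
               observed = testStatistic(tr), p_value = pValue(tr))
  })
  do.call(rbind, res)
}

#' Gene-set resampling test for selection (STIMS style)
#'
#' Compares the number of mutations observed in a focal gene set against a
#' null distribution built by resampling random gene sets of equal
#' cardinality (optionally matched on total length) from the annotation.
#' The lower tail tests for purifying selection (fewer mutations than random
#' gene sets), the upper tail for positive selection. P-values carry the
#' `(1 + b)/(1 + n_boot)` correction.
#'
#' @param muts A validated mutation `data.frame`.
#' @param gene_set Character vector of focal gene names.
#' @param genes Full gene annotation `data.frame`.
#' @param population Population to test.
#' @param annotation_filter Annotation classes to count (e.g.
#'   `"synonymous"` for a neutral-marker test); `NULL` for all.
#' @param n_boot Number of resampled gene sets (default 10000).
#' @param seed Mandatory RNG seed.
#' @param tail `"lower"` (purifying) or `"upper"` (positive selection).
#' @param match One of `"count"` (null sets match cardinality only) or
#'   `"length"` (additionally accept only sets whose total length is within
#'   `length_tol` of the focal set's; the closest draw is used if none
#'   qualifies after 50 attempts per replicate).
#' @param length_tol Relative length tolerance for `match = "length"`.
#' @return A [TestResult-class]; the statistic is the observed count.
#' @export
stimsTest <- function(muts, gene_set, genes, population,
                      annotation_filter = NULL, n_boot = 10000, seed,
                      tail = c("lower", "upper"), match = c("count", "length"),
                      length_tol = 0.1) {
  tail <- match.arg(tail)
  match <- match.arg(match)
  if (missing(seed)) stop("seed is mandatory for randomization tests")
  if (!length(gene_set)) stop("gene set must be nonempty")
  if (length(gene_set) > nrow(genes))
    stop("gene set larger than the annotation")
  miss <- setdiff(gene_set, genes$gene)
  if (length(miss))
    stop("gene set members missing from annotation: ",
         paste(miss, collapse = ", "))
  .check_population(muts, population)
  m <- muts[muts$population == population, , drop = FALSE]
  m <- .filter_annotation(m, annotation_filter)
  per_gene <- table(factor(m$gene, levels = genes$gene))
  obs <- sum(per_gene[gene_set])
  k <- length(gene_set)
  glen <- genes$end - genes$start + 1
  target_len <- sum(glen[genes$gene %in% gene_set])
  set.seed(seed)
  null_stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    if (match == "count") {
      idx <- sample.int(nrow(genes), k)
    } else {
      best <- NULL
      best_dev <- Inf
      for (try in 1:50) {
        cand <- sample.int(nrow(genes), k)
        dev <- abs(sum(glen[cand]) - target_len) / target_len
        if (dev < best_dev) { best <- cand; best_dev <- dev }
        if (dev <= length_tol) break
      }
      idx <- best
    }
    null_stat[b] <- sum(per_gene[idx])
  }
  p <- if (tail == "lower") (1 + sum(null_stat <= obs)) / (1 + n_boot)
       else (1 + sum(null_stat >= obs)) / (1 + n_boot)
  .test_result(
    method = "gene-set resampling selection test (STIMS style)",
    statistic = obs, p_value = p, tails = tail,
    null = sprintf(paste0("mutation count in %d random gene sets of %d ",
                          "gene(s)%s resampled from %d annotated genes"),
                   n_boot, k,
                   if (match == "length") " (length-matched)" else "",
                   nrow(genes)),
    n = nrow(m), seed = seed)
}
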