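# Rejection sampler for positions with density proportional to the wave
# multiplier times an orientation-bias factor inside genes.
.sample_positions <- function(n, layout, wave, beta, glookup) {
  if (n == 0) return(numeric(0))
  L <- genomeLength(layout)
  A <- waveAmplitude(wave)
  wmax <- (1 + A) * max(1, beta)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * wmax / max(1 - A, 0.05)) + 20
    pos <- floor(runif(m, 1, L + 1))
    wv <- 1 - A * cos(2 * pi * abs(oricOffset(pos, layout)) / (L / 2))
    wb <- rep(1, m)
    if (beta != 1 && length(glookup$starts)) {
      i <- findInterval(pos, glookup$starts)
      inside <- i >= 1 & pos <= glookup$ends[pmax(i, 1)]
      ho <- inside & glookup$head_on[pmax(i, 1)]
      wb[ho] <- beta
    }
    keep <- runif(m) < (wv * wb) / wmax
    out <- c(out, pos[keep])
  }
  out[seq_len(n)]
}

# Gene interval lookup on sorted, non-overlapping genes.
.gene_lookup <- function(genes, layout) {
  if (is.null(genes) || !nrow(genes))
    return(list(starts = numeric(0), ends = numeric(0),
                gene = character(0), head_on = logical(0)))
  o <- order(genes$start)
  g <- genes[o, , drop = FALSE]
  ori <- suppressWarnings(geneOrientation(g, layout))
  list(starts = g$start, ends = g$end, gene = g$gene,
       head_on = !is.na(ori) & ori == "head-on")
}

.lookup_gene <- function(pos, glookup) {
  if (!length(glookup$starts)) return(rep(NA_character_, length(pos)))
  i <- findInterval(pos, glookup$starts)
  inside <- i >= 1 & pos <= glookup$ends[pmax(i, 1)]
  ifelse(inside, glookup$gene[pmax(i, 1)], NA_character_)
}

# The two ordered base pairs representing each spectrum class, in the order
# of spectrumClasses().
.class_pairs <- list(
  rbind(c("A", "C"), c("T", "G")), rbind(c("A", "G"), c("T", "C")),
  rbind(c("A", "T"), c("T", "A")), rbind(c("G", "A"), c("C", "T")),
  rbind(c("G", "T"), c("C", "A")), rbind(c("G", "C"), c("C", "G")))

#' Simulate an annotated mutation table for one population
#'
#' Generates observed mutations under a known ground truth: per-interval
#' counts of each mutation class are Poisson with mean rate x duration;
#' positions are drawn with density proportional to the oriC-centered wave
#' multiplier, additionally weighted by `beta` inside head-on genes; point
#' mutations get a spectrum class from the interval's weights (and one of
#' the class's two ordered base pairs uniformly); appearance times are
#' uniform within their interval. Point mutations inside genes are annotated
#' synonymous/missense/nonsense with configurable probabilities, noncoding
#' outside genes. Output is byte-identical for a fixed seed.
#'
#' @param timeline A [MutatorTimeline-class].
#' @param layout A [GenomeLayout-class].
#' @param genes Gene annotation `data.frame` (non-overlapping genes assumed
#'   for position-to-gene assignment), or `NULL` for a gene-free chromosome.
#' @param wave A [WaveParams-class] (default: flat, `A = 0`).
#' @param beta Orientation bias: relative mutation rate of head-on versus
#'   co-directional genes (1 = unbiased). Must be > 0.
#' @param seed Mandatory RNG seed.
#' @param annotation_probs Probabilities of synonymous/missense/nonsense for
#'   genic point mutations (an arbitrary default of 0.25/0.70/0.05; the
#'   split carries no biological fit).
#' @param is_assoc_prob Probability that a structural variant is IS-element
#'   associated (default 0.8).
#' @param fate_probs Probabilities of fixed/extinct/polymorphic fates.
#' @return A validated mutation `data.frame` sorted by appearance time, with
#'   the ground-truth parameters attached as attribute `"params"`.
#' @examples
#' lay <- GenomeLayout(50000, 100, 10L)
#' tl <- presetPopulations(T = 5000)[["Ara+3"]]
#' m <- simulatePopulation(tl, lay, genes = NULL, seed = 1)
#' table(m$mclass)
#' @export
simulatePopulation <- function(timeline, layout, genes = NULL,
                               wave = WaveParams(0), beta = 1, seed,
                               annotation_probs = c(synonymous = 0.25,
                                                    missense = 0.70,
                                                    nonsense = 0.05),
                               is_assoc_prob = 0.8,
                               fate_probs = c(fixed = 0.30, extinct = 0.55,
                                              polymorphic = 0.15)) {
  if (missing(seed)) stop("seed is mandatory for simulation")
  if (beta <= 0) stop("beta must be > 0")
  iv <- timelineIntervals(timeline)
  if (totalGenerations(timeline) <= 0) stop("zero-length simulation horizon")
  if (!is.null(genes)) .validate_genes(genes, layout)
  set.seed(seed)
  glookup <- .gene_lookup(genes, layout)
  ap <- annotation_probs / sum(annotation_probs)
  recs <- vector("list", nrow(iv) * 3)
  ri <- 0
  emit <- function(n, i, mclass) {
    if (n == 0) return(NULL)
    pos <- .sample_positions(n, layout, wave, beta, glookup)
    gene <- .lookup_gene(pos, glookup)
    genic <- !is.na(gene)
    df <- data.frame(
      population = timelinePopulation(timeline),
      position = pos, mclass = mclass,
      base_from = NA_character_, base_to = NA_character_,
      annotation = mclass, gene = ifelse(genic, gene, "intergenic"),
      appearance_time = runif(n, iv$t_start[i], iv$t_end[i]),
      fate = sample(names(fate_probs), n, TRUE, fate_probs),
      is_associated = NA, stringsAsFactors = FALSE)
    if (mclass == "point") {
      cls <- sample.int(6, n, TRUE, prob = as.numeric(iv[i, .weight_cols]))
      strand_pick <- sample.int(2, n, TRUE)
      bp <- t(vapply(seq_len(n),
                     function(j) .class_pairs[[cls[j]]][strand_pick[j], ],
                     character(2)))
      df$base_from <- bp[, 1]
      df$base_to <- bp[, 2]
      df$annotation <- ifelse(genic,
                              sample(names(ap), n, TRUE, ap), "noncoding")
    } else if (mclass == "sv") {
      df$is_associated <- runif(n) < is_assoc_prob
    }
    df
  }
  for (i in seq_len(nrow(iv))) {
    dur <- iv$t_end[i] - iv$t_start[i]
    for (mc in c("point", "indel", "sv")) {
      rate <- iv[[paste0(switch(mc, point = "point", indel = "indel",
                                sv = "sv"), "_rate")]][i]
      ri <- ri + 1
      recs[[ri]] <- emit(rpois(1, rate * dur), i, mc)
    }
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(population = character(0), position = numeric(0),
                      mclass = character(0), base_from = character(0),
                      base_to = character(0), annotation = character(0),
                      gene = character(0), appearance_time = numeric(0),
                      fate = character(0), is_associated = logical(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$appearance_time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- list(timeline = timeline, wave = wave, beta = beta,
                              seed = seed)
  validateMutations(out)
}

#' Simulate all preset populations into one mutation table
#'
#' Convenience wrapper running [simulatePopulation()] for every preset of
#' [presetPopulations()]. Each population gets a sub-seed derived from
#' `seed`, and only the named populations in `wave_pops` receive the wave
#' (emulating a single wave-patterned population among many).
#'
#' @param layout A [GenomeLayout-class].
#' @param genes Gene annotation or `NULL`.
#' @param seed Mandatory RNG seed.
#' @param T Horizon in generations.
#' @param wave A [WaveParams-class] applied to `wave_pops`.
#' @param wave_pops Populations receiving the wave (default `"Ara+3"`).
#' @param beta Orientation bias, applied to all populations.
#' @return A combined validated mutation `data.frame`.
#' @export
simulateExperiment <- function(layout, genes = NULL, seed, T = 60000,
                               wave = WaveParams(0.5),
                               wave_pops = "Ara+3", beta = 1) {
  if (missing(seed)) stop("seed is mandatory for simulation")
  presets <- presetPopulations(T = T)
  tabs <- lapply(seq_along(presets), function(i) {
    w <- if (names(presets)[i] %in% wave_pops) wave else WaveParams(0)
    simulatePopulation(presets[[i]], layout, genes, wave = w, beta = beta,
                       seed = (seed * 131 + i) %% .Machine$integer.max)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
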