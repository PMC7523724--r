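# Shared fixture builders. Everything is generated in code; no data files.

tiny_layout <- function(L = 100, oric = 10, n_bins = 4L) {
  GenomeLayout(L, oric, n_bins)
}

# Evenly tiled non-overlapping genes of equal length, alternating strands.
tile_genes <- function(n = 20, len = 500, L = 50000, from = 1000) {
  start <- round(seq(from, L - len - 100, length.out = n))
  data.frame(gene = paste0("g", seq_len(n)), start = start,
             end = start + len - 1, strand = rep(c(1, -1), length.out = n),
             stringsAsFactors = FALSE)
}

# Single-interval timeline with a flat rate and uniform spectrum.
flat_timeline <- function(pop = "X", T = 1000, point = 1, indel = 0, sv = 0) {
  MutatorTimeline(pop, data.frame(
    t_start = 0, t_end = T, genotype = "flat",
    point_rate = point, indel_rate = indel, sv_rate = sv,
    wAT_CG = 1/6, wAT_GC = 1/6, wAT_TA = 1/6,
    wGC_AT = 1/6, wGC_TA = 1/6, wGC_CG = 1/6,
    stringsAsFactors = FALSE))
}

# Minimal hand-built mutation table.
mut_row <- function(population = "P1", position = 1, mclass = "point",
                    base_from = "A", base_to = "C",
                    annotation = "synonymous", gene = "g1",
                    appearance_time = 0, fate = "fixed",
                    is_associated = NA) {
  data.frame(population = population, position = position, mclass = mclass,
             base_from = base_from, base_to = base_to,
             annotation = annotation, gene = gene,
             appearance_time = appearance_time, fate = fate,
             is_associated = is_associated, stringsAsFactors = FALSE)
}

# Independent two-sided minimum-likelihood binomial p-value by enumeration.
enum_binom_p <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Independent brute-force two-sample KS statistic over all jump points.
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}
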