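#' GenomeLayout: a circular chromosome with an origin of replication
#'
#' Describes the coordinate system every genomic analysis in this package
#' uses: a circular chromosome of `length_bp` base pairs, the position of the
#' origin of bidirectional replication (oriC), and an equal-width binning
#' scheme centered on the origin.
#'
#' @slot length_bp Chromosome length in base pairs.
#' @slot oric_pos 1-based position of oriC.
#' @slot n_bins Number of equal-width bins partitioning the chromosome
#'   (default 46, i.e. ~100 kb bins for an E. coli-sized genome).
#'
#' @name GenomeLayout-class
#' @aliases GenomeLayout-class
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(length_bp = "numeric", oric_pos = "numeric", n_bins = "integer"))

setValidity("GenomeLayout", function(object) {
  msgs <- character(0)
  L <- object@length_bp
  if (length(L) != 1L || is.na(L) || L < 1 || L != floor(L))
    msgs <- c(msgs, "length_bp must be a single positive integer")
  o <- object@oric_pos
  if (length(o) != 1L || is.na(o) || o < 1 || o > L || o != floor(o))
    msgs <- c(msgs, "oric_pos must lie in [1, length_bp]")
  nb <- object@n_bins
  if (length(nb) != 1L || is.na(nb) || nb < 1L)
    msgs <- c(msgs, "n_bins must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeLayout
#'
#' @param length_bp Chromosome length in base pairs (e.g. 4629812 for the
#'   REL606 chromosome).
#' @param oric_pos 1-based position of the replication origin.
#' @param n_bins Number of equal-width bins for genomic distributions
#'   (default 46).
#' @return A [GenomeLayout-class] object.
#' @examples
#' rel606 <- GenomeLayout(4629812, oric_pos = 3886082)
#' binWidth(rel606)
#' @export
GenomeLayout <- function(length_bp, oric_pos, n_bins = 46L) {
  new("GenomeLayout", length_bp = as.numeric(length_bp),
      oric_pos = as.numeric(oric_pos), n_bins = as.integer(n_bins))
}

#' @describeIn GenomeLayout Chromosome length in bp.
#' @param layout A [GenomeLayout-class].
#' @export
genomeLength <- function(layout) layout@length_bp

#' @describeIn GenomeLayout oriC position (1-based).
#' @export
oricPos <- function(layout) layout@oric_pos

#' @describeIn GenomeLayout Number of bins.
#' @export
nBins <- function(layout) layout@n_bins

#' @describeIn GenomeLayout Real-valued bin width, `length_bp / n_bins`.
#' @export
binWidth <- function(layout) layout@length_bp / layout@n_bins

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout: circular chromosome of ",
      format(object@length_bp, big.mark = ","), " bp\n",
      "  oriC at position ", format(object@oric_pos, big.mark = ","), "\n",
      "  ", object@n_bins, " bins of ",
      format(round(binWidth(object), 1), big.mark = ","), " bp\n", sep = "")
})

.check_positions <- function(pos, layout) {
  bad <- which(is.na(pos) | pos < 1 | pos > layout@length_bp)
  if (length(bad))
    stop("positions out of range [1, ", layout@length_bp, "]: ",
         paste(utils::head(pos[bad], 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  invisible(TRUE)
}

#' oriC-centered signed offset of chromosome positions
#'
#' Maps a position on the circular chromosome to a signed offset in
#' `(-L/2, L/2]` relative to the replication origin: positive offsets are on
#' the replichore replicated in the increasing-coordinate direction, negative
#' offsets on the other. The antipodal point (circular distance exactly
#' `L/2`) resolves to `+L/2` by convention. The mapping is a bijection from
#' positions to offsets.
#'
#' @param pos Vector of 1-based positions.
#' @param layout A [GenomeLayout-class].
#' @return Numeric vector of signed offsets in bp.
#' @examples
#' lay <- GenomeLayout(100, 10, 4L)
#' oricOffset(c(10, 60, 11), lay)  # 0, +50 (antipode), +1
#' @export
oricOffset <- function(pos, layout) {
  .check_positions(pos, layout)
  L <- layout@length_bp
  d <- (pos - layout@oric_pos) %% L
  ifelse(d <= L / 2, d, d - L)
}

#' Invert an oriC-centered offset to a chromosome position
#'
#' @param offset Signed offsets as returned by [oricOffset()].
#' @param layout A [GenomeLayout-class].
#' @return 1-based positions.
#' @export
offsetToPos <- function(offset, layout) {
  L <- layout@length_bp
  ((layout@oric_pos - 1 + offset) %% L) + 1
}

#' Assign chromosome positions to oriC-centered bins
#'
#' Positions are mapped onto the oriC-centered axis and partitioned into
#' `nBins(layout)` equal-width bins. Bin indices are 0-based, counted from
#' the most-negative offset; for an even number of bins oriC itself falls in
#' bin `n_bins / 2`, the first bin to the right of center. Bin edges are
#' real-valued (`length_bp / n_bins`), so the partition is gap-free and every
#' bin receives either `floor(L / n_bins)` or `ceiling(L / n_bins)`
#' positions.
#'
#' @inheritParams oricOffset
#' @return Integer vector of bin indices in `[0, n_bins)`.
#' @export
assignBin <- function(pos, layout) {
  off <- oricOffset(pos, layout)
  L <- layout@length_bp
  x <- (off + L / 2) %% L
  b <- floor(x / binWidth(layout))
  as.integer(pmin(b, layout@n_bins - 1L))
}

# Number of integer positions falling in each bin (bins differ by at most 1).
.bin_sizes <- function(layout) {
  L <- layout@length_bp
  w <- binWidth(layout)
  k <- seq_len(layout@n_bins) - 1
  lo <- ceiling(k * w - 1e-9)
  hi <- ceiling((k + 1) * w - 1e-9) - 1
  hi - lo + 1
}

# Overlap (in integer positions) of the gene [start, end] with each
# oriC-centered bin. Follows the same x = (offset + L/2) mod L unrolling as
# assignBin, so a gene crossing the antipode wraps to the left edge.
.bin_overlap <- function(start, end, layout) {
  L <- layout@length_bp
  w <- binWidth(layout)
  n <- layout@n_bins
  x0 <- ((start - layout@oric_pos) %% L + L / 2) %% L
  len <- end - start + 1
  out <- numeric(n)
  # gene occupies x0, x0+1, ..., x0+len-1 (mod L): up to two linear pieces
  pieces <- if (x0 + len - 1 < L) list(c(x0, x0 + len - 1))
            else list(c(x0, L - 1), c(0, x0 + len - 1 - L))
  for (p in pieces) {
    ks <- floor(p[1] / w):min(floor(p[2] / w), n - 1)
    lo_k <- ceiling(ks * w - 1e-9)
    hi_k <- ceiling((ks + 1) * w - 1e-9) - 1
    cnt <- pmax(0, pmin(p[2], hi_k) - pmax(p[1], lo_k) + 1)
    out[ks + 1] <- out[ks + 1] + cnt
  }
  out
}

.validate_genes <- function(genes, layout = NULL) {
  req <- c("gene", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("gene table missing required columns: ", paste(miss, collapse = ", "))
  if (any(genes$start > genes$end))
    stop("gene table has start > end (origin-spanning genes are not supported): ",
         paste(genes$gene[genes$start > genes$end], collapse = ", "))
  if (!all(genes$strand %in% c(-1, 1)))
    stop("gene strand must be +1 or -1")
  if (!is.null(layout) && any(genes$end > layout@length_bp | genes$start < 1))
    stop("gene coordinates outside [1, length_bp]")
  invisible(TRUE)
}

#' Gene orientation relative to replisome travel
#'
#' Classifies each gene as co-directional (transcribed in the same direction
#' as the replisome travels through it) or head-on (transcribed against it).
#' Replichore 1 is the arc from oriC in the increasing-coordinate direction
#' to the antipode, where the replisome travels in increasing coordinates; a
#' `+1`-strand gene there is co-directional, and the classification flips
#' when either the strand flips or the gene is mirrored across oriC. Genes
#' spanning oriC or the antipode are ambiguous: they return `NA` with a
#' warning and are excluded from orientation tallies.
#'
#' @param genes Gene annotation `data.frame` with columns `gene`, `start`,
#'   `end`, `strand` (+1/-1); see [readGeneTable()].
#' @param layout A [GenomeLayout-class].
#' @return Factor with levels `"co-directional"` and `"head-on"`, `NA` for
#'   ambiguous genes.
#' @export
geneOrientation <- function(genes, layout) {
  .validate_genes(genes, layout)
  off_s <- oricOffset(genes$start, layout)
  off_e <- oricOffset(genes$end, layout)
  spans_oric <- genes$start <= layout@oric_pos & layout@oric_pos <= genes$end
  spans_anti <- off_s > 0 & off_e < 0
  flagged <- spans_oric | spans_anti
  mid <- floor((genes$start + genes$end) / 2)
  repl <- sign(oricOffset(mid, layout))
  ori <- ifelse(genes$strand == repl, "co-directional", "head-on")
  ori[flagged] <- NA
  if (any(flagged))
    warning("excluding ", sum(flagged), " gene(s) spanning oriC or its antipode ",
            "from orientation assignment: ",
            paste(genes$gene[flagged], collapse = ", "))
  factor(ori, levels = c("co-directional", "head-on"))
}

#' Coding-sequence composition per stratum
#'
#' Tallies coding nucleotides (and G:C nucleotides when a `gc_count` column
#' is present) per stratum of the gene annotation. This is the null
#' expectation for mutation counts inside genes: absent any bias, mutations
#' should split across strata in proportion to the coding sequence they
#' contain (gene density times gene length). Overlapping genes are counted
#' once per gene (a gene-centric tally) under the default policy; the strict
#' policy refuses overlapping annotations.
#'
#' @param genes Gene annotation `data.frame` (columns `gene`, `start`, `end`,
#'   `strand`, optional `gc_count`).
#' @param layout A [GenomeLayout-class].
#' @param stratify_by One of `"strand"`, `"orientation"`, `"bin"`.
#' @param overlap `"gene-centric"` (default; overlap bases counted once per
#'   gene, with a message giving the number of overlapping bases) or
#'   `"strict"` (error on any overlap).
#' @return A `data.frame` with columns `stratum`, `nt` and, if available,
#'   `gc`. Strata always sum to the total gene-centric coding length.
#' @export
codingComposition <- function(genes, layout,
                              stratify_by = c("strand", "orientation", "bin"),
                              overlap = c("gene-centric", "strict")) {
  stratify_by <- match.arg(stratify_by)
  overlap <- match.arg(overlap)
  .validate_genes(genes, layout)
  og <- genes[order(genes$start), , drop = FALSE]
  if (nrow(og) > 1) {
    ovl_bp <- sum(pmax(0, utils::head(og$end, -1) - og$start[-1] + 1))
    if (ovl_bp > 0) {
      if (overlap == "strict") {
        bad <- which(utils::head(og$end, -1) >= og$start[-1])
        stop("overlapping genes under strict policy: ",
             paste(unique(c(og$gene[bad], og$gene[bad + 1])), collapse = ", "))
      }
      message("gene-centric tally: ", ovl_bp,
              " overlapping base(s) counted once per gene")
    }
  }
  len <- genes$end - genes$start + 1
  has_gc <- "gc_count" %in% names(genes)
  if (stratify_by == "bin") {
    ov <- vapply(seq_len(nrow(genes)),
                 function(i) .bin_overlap(genes$start[i], genes$end[i], layout),
                 numeric(layout@n_bins))
    nt <- rowSums(ov)
    out <- data.frame(stratum = factor(seq_len(layout@n_bins) - 1L),
                      nt = nt)
    if (has_gc)  # per-bin gc split length-proportionally within each gene
      out$gc <- as.numeric(ov %*% (genes$gc_count / len))
    return(out)
  }
  strat <- switch(stratify_by,
    strand = factor(genes$strand, levels = c(1, -1),
                    labels = c("1", "-1")),
    orientation = geneOrientation(genes, layout))
  keep <- !is.na(strat)
  nt <- tapply(len[keep], strat[keep], sum, default = 0)
  out <- data.frame(stratum = factor(names(nt), levels = levels(strat)),
                    nt = as.numeric(nt))
  if (has_gc)
    out$gc <- as.numeric(tapply(genes$gc_count[keep], strat[keep], sum,
                                default = 0))
  out
}

#' Read a gene annotation table
#'
#' Reads a tab-separated annotation with header columns `gene`, `start`,
#' `end`, `strand` and optionally `product` and `gc_count`. Coordinates are
#' 1-based inclusive; strand accepts `+1`/`-1`/`1` or `+`/`-`.
#'
#' @param path Path to the TSV file.
#' @return A validated gene annotation `data.frame`.
#' @export
readGeneTable <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "start", "end", "strand")
  miss <- setdiff(req, names(g))
  if (length(miss))
    stop("gene table missing required columns: ", paste(miss, collapse = ", "))
  s <- as.character(g$strand)
  g$strand <- ifelse(s %in% c("+", "+1", "1"), 1,
                     ifelse(s %in% c("-", "-1"), -1, NA))
  if (anyNA(g$strand)) stop("unrecognized strand labels in ", path)
  .validate_genes(g)
  g
}

#' Read CDS features from a GFF3 file as a gene annotation table
#'
#' A minimal import of the CDS features of a GFF3 annotation (via
#' `rtracklayer::readGFF`). Gene names are taken from the `gene`, `Name` or
#' `ID` attribute, in that order of preference.
#'
#' @param path Path to a GFF3 file.
#' @return A gene annotation `data.frame` as for [readGeneTable()].
#' @export
readGenesGFF3 <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features found in ", path)
  nm <- rep(NA_character_, nrow(cds))
  for (attr in c("gene", "Name", "ID"))
    if (attr %in% names(cds)) {
      v <- as.character(cds[[attr]])
      nm[is.na(nm) & !is.na(v)] <- v[is.na(nm) & !is.na(v)]
    }
  g <- data.frame(gene = nm, start = cds$start, end = cds$end,
                  strand = ifelse(as.character(cds$strand) == "+", 1, -1),
                  stringsAsFactors = FALSE)
  .validate_genes(g)
  g
}
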