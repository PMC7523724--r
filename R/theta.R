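#' ModelFit: a fitted Poisson model of per-gene mutation counts
#'
#' Both per-gene mutation-rate models in this package are one-parameter
#' Poisson models fitted by closed-form maximum likelihood and ranked by
#' AIC = 2k - 2 lnL with k = 1 (the common scale parameter). Because both
#' models share k and the `sum(log k!)` data term, AIC differences depend
#' only on the fitted means.
#'
#' @slot model `"uniform"` or `"theta"`.
#' @slot logLik Maximized log-likelihood.
#' @slot k Number of free parameters (1).
#' @slot aic Akaike's Information Criterion.
#' @slot scale Fitted scale `c` (mutations per bp, or per theta-weighted bp).
#' @slot n_genes,total_count Data summary.
#' @slot data_hash Fingerprint of the fitted data, used to refuse AIC
#'   comparisons across different data.
#' @name ModelFit-class
#' @exportClass ModelFit
setClass("ModelFit",
  representation(model = "character", logLik = "numeric", k = "numeric",
                 aic = "numeric", scale = "numeric", n_genes = "numeric",
                 total_count = "numeric", data_hash = "character"))

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit '%s': lnL = %.3f, k = %d, AIC = %.1f, scale = %.4g\n",
              object@model, object@logLik, as.integer(object@k), object@aic,
              object@scale),
      sprintf("  data: %d genes, %d mutations\n", as.integer(object@n_genes),
              as.integer(object@total_count)))
})

#' @describeIn ModelFit AIC accessor.
#' @param x A [ModelFit-class].
#' @export
modelAIC <- function(x) x@aic

#' @describeIn ModelFit Log-likelihood accessor.
#' @export
modelLogLik <- function(x) x@logLik

#' @describeIn ModelFit Fitted scale accessor.
#' @export
modelScale <- function(x) x@scale

.data_hash <- function(counts, lengths) {
  paste(length(counts), sum(counts), format(sum(lengths), digits = 15),
        format(sum(counts * seq_along(counts)), digits = 15), sep = ":")
}

.poisson_loglik <- function(counts, mu) {
  term <- ifelse(counts > 0, counts * log(mu), 0) - mu - lfactorial(counts)
  if (any(counts > 0 & mu == 0)) -Inf else sum(term)
}

.check_counts <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("counts and lengths must have equal length")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (any(lengths <= 0)) stop("lengths must be > 0")
  invisible(TRUE)
}

#' Fit the uniform-rate Poisson model of per-gene mutation counts
#'
#' The null model: mutations occur uniformly over the chromosome, so gene
#' `g` with length `L_g` accrues `k_g ~ Poisson(c L_g)`. The MLE is
#' `c = sum(k) / sum(L)` in closed form.
#'
#' @param counts Per-gene mutation counts.
#' @param lengths Per-gene lengths in bp (synonymous-site lengths may be
#'   supplied instead when available).
#' @return A [ModelFit-class].
#' @export
fitUniform <- function(counts, lengths) {
  .check_counts(counts, lengths)
  c_hat <- sum(counts) / sum(lengths)
  ll <- .poisson_loglik(counts, c_hat * lengths)
  new("ModelFit", model = "uniform", logLik = ll, k = 1,
      aic = 2 - 2 * ll, scale = c_hat, n_genes = length(counts),
      total_count = sum(counts), data_hash = .data_hash(counts, lengths))
}

#' Fit the diversity-informed Poisson model of per-gene mutation counts
#'
#' Treats per-gene synonymous nucleotide diversity `theta_g` (estimated from
#' natural isolates) as a gene-specific relative mutation rate per bp:
#' `k_g ~ Poisson(c theta_g L_g)`, MLE `c = sum(k) / sum(theta L)`. A gene
#' with `theta_g = 0` but observed mutations makes the likelihood zero
#' (`lnL = -Inf`, infinite AIC), which is reported as such.
#'
#' @inheritParams fitUniform
#' @param theta Per-gene diversity values `theta_g >= 0`, aligned with
#'   `counts`.
#' @return A [ModelFit-class].
#' @export
fitTheta <- function(counts, lengths, theta) {
  .check_counts(counts, lengths)
  if (length(theta) != length(counts))
    stop("theta must align with counts")
  if (any(is.na(theta)) || any(theta < 0))
    stop("theta must be non-negative and non-missing (drop missing genes ",
         "from both fits first)")
  denom <- sum(theta * lengths)
  if (denom == 0) stop("all theta values are zero")
  c_hat <- sum(counts) / denom
  mu <- c_hat * theta * lengths
  if (any(counts > 0 & mu == 0))
    warning("theta = 0 for gene(s) with observed mutations: lnL = -Inf")
  ll <- .poisson_loglik(counts, mu)
  new("ModelFit", model = "theta", logLik = ll, k = 1,
      aic = 2 - 2 * ll, scale = c_hat, n_genes = length(counts),
      total_count = sum(counts), data_hash = .data_hash(counts, lengths))
}

#' Rank model fits by AIC
#'
#' @param fits A list of [ModelFit-class] objects fitted to identical data
#'   (enforced through the data fingerprint).
#' @return A `data.frame` sorted by AIC ascending (ties keep input order),
#'   with `dAIC` relative to the best model.
#' @export
compareModels <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  hashes <- vapply(fits, function(f) f@data_hash, character(1))
  if (length(unique(hashes)) != 1)
    stop("fits were made on different data (gene list or counts differ)")
  out <- data.frame(
    model = vapply(fits, function(f) f@model, character(1)),
    logLik = vapply(fits, function(f) f@logLik, numeric(1)),
    k = vapply(fits, function(f) f@k, numeric(1)),
    AIC = vapply(fits, function(f) f@aic, numeric(1)))
  out <- out[order(out$AIC), , drop = FALSE]  # stable: ties keep input order
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

#' Per-gene mutation counts from a mutation table
#'
#' @param muts A validated mutation `data.frame`.
#' @param genes Gene annotation `data.frame`.
#' @param population Optional population restriction.
#' @param annotation_filter Annotation classes to count (default
#'   `"synonymous"`); `NULL` for all.
#' @return A `data.frame` with `gene`, `length`, `count`.
#' @export
geneCounts <- function(muts, genes, population = NULL,
                       annotation_filter = "synonymous") {
  m <- if (is.null(population)) muts else {
    .check_population(muts, population)
    muts[muts$population == population, , drop = FALSE]
  }
  m <- .filter_annotation(m, annotation_filter)
  data.frame(gene = genes$gene,
             length = genes$end - genes$start + 1,
             count = as.integer(table(factor(m$gene, levels = genes$gene))))
}

#' Fit and compare the uniform and theta models on a counts table
#'
#' Merges a per-gene counts table with a theta table, drops genes missing
#' from the theta table from both fits (reporting how many), fits both
#' models and ranks them by AIC.
#'
#' @param counts_df Output of [geneCounts()].
#' @param theta_df `data.frame` with columns `gene` and `theta` (and
#'   optionally `syn_length`, used as the exposure length when present).
#' @return A list with elements `fits` (the two [ModelFit-class] objects),
#'   `comparison` (the [compareModels()] table) and `n_dropped`.
#' @export
compareRateModels <- function(counts_df, theta_df) {
  merged <- merge(counts_df, theta_df, by = "gene")
  n_dropped <- nrow(counts_df) - nrow(merged)
  if (n_dropped > 0)
    message(n_dropped, " gene(s) missing from the theta table dropped ",
            "from both fits")
  if (!nrow(merged)) stop("no genes shared between counts and theta tables")
  len <- if ("syn_length" %in% names(merged)) merged$syn_length
         else merged$length
  fu <- fitUniform(merged$count, len)
  ft <- fitTheta(merged$count, len, merged$theta)
  list(fits = list(uniform = fu, theta = ft),
       comparison = compareModels(list(fu, ft)),
       n_dropped = n_dropped)
}
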