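#' MutatorTimeline: piecewise-constant mutation-rate regimes
#'
#' A population's mutation-rate history as contiguous intervals, each with
#' its own genotype label, per-class rates (expected observed mutations per
#' generation for the whole population) and six-class point-mutation
#' spectrum weights. Hypermutator sweeps, antimutator reversions and
#' repair-pathway-specific spectrum shifts are all expressed as interval
#' boundaries.
#'
#' @slot population Population label.
#' @slot intervals `data.frame` with columns `t_start`, `t_end`, `genotype`,
#'   `point_rate`, `indel_rate`, `sv_rate` and six spectrum-weight columns
#'   `wAT_CG`, `wAT_GC`, `wAT_TA`, `wGC_AT`, `wGC_TA`, `wGC_CG` (each row
#'   sums to 1).
#' @name MutatorTimeline-class
#' @exportClass MutatorTimeline
setClass("MutatorTimeline",
  representation(population = "character", intervals = "data.frame"))

.weight_cols <- c("wAT_CG", "wAT_GC", "wAT_TA", "wGC_AT", "wGC_TA", "wGC_CG")

setValidity("MutatorTimeline", function(object) {
  iv <- object@intervals
  req <- c("t_start", "t_end", "genotype", "point_rate", "indel_rate",
           "sv_rate", .weight_cols)
  miss <- setdiff(req, names(iv))
  if (length(miss))
    return(paste("intervals missing columns:", paste(miss, collapse = ", ")))
  msgs <- character(0)
  if (!nrow(iv)) msgs <- c(msgs, "timeline must have at least one interval")
  else {
    if (iv$t_start[1] != 0) msgs <- c(msgs, "first interval must start at 0")
    if (any(iv$t_end <= iv$t_start))
      msgs <- c(msgs, "intervals must have t_end > t_start")
    if (nrow(iv) > 1 &&
        any(abs(iv$t_start[-1] - iv$t_end[-nrow(iv)]) > 1e-9))
      msgs <- c(msgs, "intervals must be contiguous and non-overlapping")
    if (any(as.matrix(iv[, c("point_rate", "indel_rate", "sv_rate")]) < 0))
      msgs <- c(msgs, "rates must be non-negative")
    w <- as.matrix(iv[, .weight_cols])
    if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-6))
      msgs <- c(msgs, "spectrum weights must be non-negative and sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a mutator timeline
#'
#' @param population Population label.
#' @param intervals Interval `data.frame`; see [MutatorTimeline-class].
#'   Spectrum weights are renormalized to sum to exactly 1.
#' @return A [MutatorTimeline-class] object.
#' @export
MutatorTimeline <- function(population, intervals) {
  w <- as.matrix(intervals[, .weight_cols])
  intervals[, .weight_cols] <- w / rowSums(w)
  new("MutatorTimeline", population = population, intervals = intervals)
}

#' @describeIn MutatorTimeline Interval table accessor.
#' @param timeline A [MutatorTimeline-class].
#' @export
timelineIntervals <- function(timeline) timeline@intervals

#' @describeIn MutatorTimeline Population label accessor.
#' @export
timelinePopulation <- function(timeline) timeline@population

#' @describeIn MutatorTimeline Total simulated horizon in generations.
#' @export
totalGenerations <- function(timeline) max(timeline@intervals$t_end)

setMethod("show", "MutatorTimeline", function(object) {
  iv <- object@intervals
  cat("MutatorTimeline for ", object@population, ": ", nrow(iv),
      " interval(s) over ", format(totalGenerations(object), big.mark = ","),
      " generations\n", sep = "")
  for (i in seq_len(nrow(iv)))
    cat(sprintf("  [%6.0f, %6.0f) %-14s point=%.4g indel=%.4g sv=%.4g\n",
                iv$t_start[i], iv$t_end[i], iv$genotype[i],
                iv$point_rate[i], iv$indel_rate[i], iv$sv_rate[i]))
})

.interval_row <- function(t_start, t_end, genotype, point, indel, sv, w) {
  data.frame(t_start = t_start, t_end = t_end, genotype = genotype,
             point_rate = point, indel_rate = indel, sv_rate = sv,
             wAT_CG = w[1], wAT_GC = w[2], wAT_TA = w[3],
             wGC_AT = w[4], wGC_TA = w[5], wGC_CG = w[6],
             stringsAsFactors = FALSE)
}

#' Preset mutator timelines for twelve LTEE-like populations
#'
#' Twelve qualitative presets named after the LTEE populations they emulate
#' (six Ara- and six Ara+). The regimes are qualitative, not fitted:
#' hypermutator onset and reversion times follow the curated repair-allele
#' appearance times, spectra follow the repair pathway lost (mismatch-repair
#' loss elevates A:T->G:C and G:C->A:T point and indel rates; mutT loss
#' elevates A:T->C:G transversions without an indel phenotype; late mutY
#' loss shifts weight onto G:C->T:A), and baseline versus hypermutator rates
#' are set so a nonmutator accrues on the order of 1e2 observed mutations
#' and an MMR hypermutator a few thousand over 60,000 generations.
#' Ara-2 reverts to its pre-hypermutator rates after the mutL phase
#' reversion; Ara-5, Ara-6 and Ara+1 are IS-element (structural) mutators;
#' Ara-3 has three structural-rate slopes.
#'
#' @param T Simulation horizon in generations (default 60000).
#' @return Named list of twelve [MutatorTimeline-class] objects.
#' @export
presetPopulations <- function(T = 60000) {
  w_base <- c(0.10, 0.25, 0.05, 0.40, 0.12, 0.08)  # wild-type-like spectrum
  w_mmr  <- c(0.01, 0.46, 0.01, 0.46, 0.04, 0.02)  # MMR-deficient
  w_mutt <- c(0.92, 0.02, 0.01, 0.02, 0.02, 0.01)  # mutT-deficient
  w_mutt_muty <- c(0.74, 0.02, 0.01, 0.02, 0.20, 0.01)  # + mutY loss
  w_mmr_muty  <- c(0.01, 0.40, 0.01, 0.40, 0.16, 0.02)
  base <- function(t0, t1, sv = 8e-4)
    .interval_row(t0, t1, "wild-type", 1.5e-3, 4e-4, sv, w_base)
  mmr <- function(t0, t1, geno = "MMR-", sv = 8e-4, w = w_mmr)
    .interval_row(t0, t1, geno, 0.06, 0.008, sv, w)
  mutt <- function(t0, t1, geno = "mutT-", w = w_mutt)
    .interval_row(t0, t1, geno, 0.045, 4e-4, 8e-4, w)
  is_hyper <- function(t0, t1) base(t0, t1, sv = 4e-3)
  # regime boundaries are fixed in generations; clip to the horizon T
  tl <- function(pop, ...) {
    iv <- do.call(rbind, list(...))
    iv <- iv[iv$t_start < T, , drop = FALSE]
    iv$t_end <- pmin(iv$t_end, T)
    MutatorTimeline(pop, iv)
  }
  list(
    "Ara-1" = tl("Ara-1", base(0, 26250), mutt(26250, 32250),
                 mutt(32250, T, geno = "mutT- mutY-", w = w_mutt_muty)),
    "Ara-2" = tl("Ara-2", base(0, 2250), mmr(2250, 42250),
                 base(42250, T)),   # mutL phase reversion restores base rates
    "Ara-3" = tl("Ara-3",
                 .interval_row(0, 30000, "IS+", 1.5e-3, 4e-4, 3e-3, w_base),
                 .interval_row(30000, 34750, "IS++", 1.5e-3, 4e-4, 0.01, w_base),
                 .interval_row(34750, 45000, "MMR- IS++", 0.06, 0.008, 0.01, w_mmr),
                 .interval_row(45000, 48250, "MMR- IS+", 0.06, 0.008, 2e-3, w_mmr),
                 .interval_row(48250, T, "MMR- mutY- IS+", 0.06, 0.008, 2e-3,
                               w_mmr_muty)),
    "Ara-4" = tl("Ara-4", base(0, 7250), mmr(7250, T)),
    "Ara-5" = tl("Ara-5", is_hyper(0, T)),
    "Ara-6" = tl("Ara-6", is_hyper(0, T)),
    "Ara+1" = tl("Ara+1", is_hyper(0, T)),
    "Ara+2" = tl("Ara+2", base(0, T)),
    "Ara+3" = tl("Ara+3", base(0, 2750), mmr(2750, T)),
    "Ara+4" = tl("Ara+4", base(0, T)),
    "Ara+5" = tl("Ara+5", base(0, T)),
    "Ara+6" = tl("Ara+6", base(0, 4750), mutt(4750, 31750),
                 mutt(31750, T, geno = "mutT- mutY-", w = w_mutt_muty))
  )
}
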