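#' WaveParams: a symmetric mutation-rate wave over the replication origin
#'
#' A position-dependent rate multiplier that is symmetric about oriC, with
#' troughs at oriC and its antipode and peaks at mid-replichore:
#' \deqn{m(d) = 1 - A \cos(2\pi d / (L/2))}
#' where `d` is the circular distance to oriC and `A` the amplitude. The
#' trough-to-peak ratio is `(1 - A)/(1 + A)`; `A = 0.5` gives a 25:75
#' (1:3) trough-to-peak ratio. The cosine form with period `L/2` is a
#' modelling choice: observed wave patterns are symmetric over oriC but
#' their functional form (and the phase of the trough) is not pinned down
#' by the data, so both are documented assumptions.
#'
#' @slot amplitude Wave amplitude `A` in `[0, 1)`.
#' @name WaveParams-class
#' @exportClass WaveParams
setClass("WaveParams", representation(amplitude = "numeric"))

setValidity("WaveParams", function(object) {
  A <- object@amplitude
  if (length(A) != 1L || is.na(A) || A < 0 || A >= 1)
    "amplitude must be a single value in [0, 1)" else TRUE
})

#' Construct wave parameters
#'
#' @param amplitude Amplitude `A` in `[0, 1)`; `0` means no positional rate
#'   variation, `0.5` a 25:75 trough-to-peak ratio.
#' @return A [WaveParams-class] object.
#' @export
WaveParams <- function(amplitude = 0) new("WaveParams", amplitude = amplitude)

#' @describeIn WaveParams Amplitude accessor.
#' @param wave A [WaveParams-class].
#' @export
waveAmplitude <- function(wave) wave@amplitude

#' @describeIn WaveParams Trough-to-peak rate ratio `(1 - A)/(1 + A)`.
#' @export
troughPeakRatio <- function(wave) {
  (1 - wave@amplitude) / (1 + wave@amplitude)
}

setMethod("show", "WaveParams", function(object) {
  r <- troughPeakRatio(object)
  cat(sprintf("WaveParams: amplitude A = %.3f (trough:peak = %.0f:%.0f)\n",
              object@amplitude, 100 * r / (1 + r), 100 / (1 + r)))
})

#' Evaluate the wave rate multiplier at chromosome positions
#'
#' @param wave A [WaveParams-class].
#' @param pos 1-based positions.
#' @param layout A [GenomeLayout-class].
#' @return Positive rate multipliers `m(d)` with mean ~1 over the
#'   chromosome.
#' @export
waveMultiplier <- function(wave, pos, layout) {
  d <- abs(oricOffset(pos, layout))
  1 - wave@amplitude * cos(2 * pi * d / (genomeLength(layout) / 2))
}

#' Estimate the wave amplitude from binned mutation counts
#'
#' Two estimators are available. `"minmax"` uses the extreme bin densities,
#' `A = (max - min)/(max + min)`, which matches how a trough-to-peak ratio
#' is read off a plot but is biased upward by sampling noise in the extreme
#' bins. `"cosfit"` regresses per-bin counts on the cosine basis of the
#' wave model (counts ~ a + b cos(2 pi d_k/(L/2)) with `A = -b/a`), which is
#' nearly unbiased when the model form is right.
#'
#' @param counts Per-bin mutation counts, in bin order (length
#'   `nBins(layout)`).
#' @param layout A [GenomeLayout-class].
#' @param method `"minmax"` or `"cosfit"`.
#' @return Estimated amplitude (clamped to `[0, 1)` for `"cosfit"`).
#' @export
estimateWaveAmplitude <- function(counts, layout,
                                  method = c("minmax", "cosfit")) {
  method <- match.arg(method)
  if (length(counts) != nBins(layout))
    stop("counts must have one entry per bin")
  if (method == "minmax") {
    (max(counts) - min(counts)) / (max(counts) + min(counts))
  } else {
    L <- genomeLength(layout)
    w <- binWidth(layout)
    xc <- (seq_len(nBins(layout)) - 0.5) * w
    d <- abs(xc - L / 2)   # circular distance of bin center to oriC
    cb <- cos(2 * pi * d / (L / 2))
    fit <- stats::lm(counts ~ cb)
    a <- stats::coef(fit)
    max(0, min(1 - 1e-12, -a[[2]] / a[[1]]))
  }
}
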