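#' TestResult: a statistical test outcome with its null description
#'
#' A uniform container for every hypothesis test in the package, recording
#' the method, the statistic, the p-value, the tail convention, a plain-text
#' description of the null model, the sample sizes involved, and (for
#' randomization methods) the seed that makes the result reproducible.
#'
#' @slot method Test name.
#' @slot statistic Observed statistic.
#' @slot p_value P-value in `[0, 1]`.
#' @slot tails `"two-tailed"`, `"lower"` or `"upper"`.
#' @slot null Description of the null model.
#' @slot n Sample size(s) used.
#' @slot seed RNG seed for randomization tests, `NA` otherwise.
#' @name TestResult-class
#' @exportClass TestResult
setClass("TestResult",
  representation(method = "character", statistic = "numeric",
                 p_value = "numeric", tails = "character",
                 null = "character", n = "numeric", seed = "numeric"))

setValidity("TestResult", function(object) {
  msgs <- character(0)
  p <- object@p_value
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    msgs <- c(msgs, "p_value must be a single value in [0, 1]")
  if (!is.finite(object@statistic))
    msgs <- c(msgs, "statistic must be finite")
  if (length(msgs)) msgs else TRUE
})

.test_result <- function(method, statistic, p_value, tails, null, n,
                         seed = NA_real_) {
  new("TestResult", method = method, statistic = statistic,
      p_value = p_value, tails = tails, null = null, n = as.numeric(n),
      seed = as.numeric(seed))
}

#' @describeIn TestResult P-value accessor.
#' @param x A [TestResult-class].
#' @export
pValue <- function(x) x@p_value

#' @describeIn TestResult Statistic accessor.
#' @export
testStatistic <- function(x) x@statistic

#' @describeIn TestResult Null-model description accessor.
#' @export
nullDescription <- function(x) x@null

setMethod("show", "TestResult", function(object) {
  cat(object@method, " (", object@tails, ")\n",
      "  statistic = ", format(object@statistic, digits = 6),
      ", p = ", format.pval(object@p_value, digits = 4), "\n",
      "  null: ", object@null, "\n",
      "  n = ", paste(object@n, collapse = ", "),
      if (!is.na(object@seed)) paste0(", seed = ", object@seed) else "",
      "\n", sep = "")
})
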