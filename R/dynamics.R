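.check_population <- function(muts, population) {
  pops <- unique(muts$population)
  if (!population %in% pops)
    stop("unknown population '", population, "'; available: ",
         paste(sort(pops), collapse = ", "))
  invisible(TRUE)
}

#' Cumulative observed mutations over time
#'
#' The cumulative number of observed mutations of one class in one
#' population, as a step function keyed on appearance time. Structural
#' variants can be split by IS-element association (`"sv_is"` /
#' `"sv_other"`), mirroring how transposon-driven and other junctions are
#' usually displayed separately.
#'
#' @param muts A validated mutation `data.frame`.
#' @param population Population label.
#' @param mclass One of `"point"`, `"indel"`, `"sv"`, `"sv_is"`,
#'   `"sv_other"`, `"all"`.
#' @return A `data.frame` with sorted unique `time` (generations) and
#'   nondecreasing `count`; attributes `population` and `mclass`.
#' @export
cumulativeCounts <- function(muts, population,
                             mclass = c("point", "indel", "sv", "sv_is",
                                        "sv_other", "all")) {
  mclass <- match.arg(mclass)
  .check_population(muts, population)
  m <- muts[muts$population == population, , drop = FALSE]
  m <- switch(mclass,
    all = m,
    sv_is = m[m$mclass == "sv" & m$is_associated %in% TRUE, , drop = FALSE],
    sv_other = m[m$mclass == "sv" & !m$is_associated %in% TRUE, , drop = FALSE],
    m[m$mclass == mclass, , drop = FALSE])
  t <- sort(unique(m$appearance_time))
  counts <- cumsum(as.integer(table(factor(m$appearance_time, levels = t))))
  out <- data.frame(time = t, count = counts)
  attr(out, "population") <- population
  attr(out, "mclass") <- mclass
  out
}

#' Point-mutation spectrum over time windows
#'
#' Counts point mutations by six-class spectrum in consecutive windows of
#' `window_width` generations tiling `[0, T]`, where `T` is the latest
#' appearance time in the population.
#'
#' @param muts A validated mutation `data.frame`.
#' @param population Population label.
#' @param window_width Window width in generations (default 2500).
#' @param proportions Also add per-window proportion columns.
#' @return A `data.frame` with `window_start`, `window_end`, one count
#'   column per spectrum class (and `prop.*` columns if requested). Window
#'   counts sum to the population's point-mutation total.
#' @export
spectrumOverTime <- function(muts, population, window_width = 2500,
                             proportions = FALSE) {
  if (window_width <= 0) stop("window_width must be > 0")
  .check_population(muts, population)
  m <- muts[muts$population == population & muts$mclass == "point", ,
            drop = FALSE]
  maxT <- if (nrow(m)) max(m$appearance_time) else window_width
  n_win <- max(1L, ceiling(maxT / window_width))
  edges <- (0:n_win) * window_width
  win <- pmin(floor(m$appearance_time / window_width), n_win - 1L)
  cls <- classifySpectrum(m$base_from, m$base_to)
  tab <- table(factor(win, levels = 0:(n_win - 1L)), cls)
  out <- data.frame(window_start = edges[-length(edges)],
                    window_end = edges[-1])
  cnt <- as.data.frame.matrix(tab)
  names(cnt) <- spectrumClasses()
  out <- cbind(out, cnt)
  if (proportions) {
    tot <- rowSums(cnt)
    pr <- cnt / ifelse(tot > 0, tot, NA)
    names(pr) <- paste0("prop.", spectrumClasses())
    out <- cbind(out, pr)
  }
  out
}

#' Least-squares slopes of a cumulative series between breakpoints
#'
#' Fits a least-squares line to the cumulative count within each segment
#' delimited by user-supplied breakpoints (no changepoint detection is
#' attempted: breakpoints are an analyst's hypothesis, e.g. the three
#' structural-rate slopes visible in a population's series). The slope is
#' the observed mutation rate per generation in that segment.
#'
#' @param series Output of [cumulativeCounts()].
#' @param breakpoints Sorted generation values strictly inside the observed
#'   time range.
#' @return A `data.frame` with `t_start`, `t_end`, `n_points`, `slope`
#'   (NA when a segment has fewer than two points) and `ok`.
#' @export
rateChangeSummary <- function(series, breakpoints = numeric(0)) {
  if (!nrow(series)) stop("empty series")
  if (is.unsorted(breakpoints, strictly = TRUE) && length(breakpoints) > 1)
    stop("breakpoints must be strictly sorted")
  rng <- range(series$time)
  if (length(breakpoints) &&
      any(breakpoints <= rng[1] | breakpoints >= rng[2]))
    stop("breakpoints must lie strictly within the observed time range [",
         rng[1], ", ", rng[2], "]")
  edges <- c(rng[1], breakpoints, rng[2])
  out <- data.frame(t_start = edges[-length(edges)], t_end = edges[-1],
                    n_points = NA_integer_, slope = NA_real_, ok = FALSE)
  for (i in seq_len(nrow(out))) {
    sel <- series$time >= out$t_start[i] &
      (series$time < out$t_end[i] | (i == nrow(out) &
                                       series$time <= out$t_end[i]))
    out$n_points[i] <- sum(sel)
    if (sum(sel) >= 2) {
      fit <- stats::lm(count ~ time, data = series[sel, , drop = FALSE])
      out$slope[i] <- stats::coef(fit)[["time"]]
      out$ok[i] <- TRUE
    }
  }
  out
}
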