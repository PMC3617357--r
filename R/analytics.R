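#' Order statistics of clone peak size and lifespan
#'
#' Median, standard deviation (n - 1 denominator), minimum and maximum of
#' the per-clone peak living-cell count and lifespan.  Medians of
#' even-sized samples are the midpoint of the central pair; lifespans are
#' reported in days (1 month = 30 days).
#'
#' @param x a \code{\linkS4class{CohortSummary}}, the data.frame from
#'   \code{\link{cloneTable}}, or a list of
#'   \code{\linkS4class{CloneRecord}} objects.
#' @return data.frame with rows \code{peak} and \code{lifespanDays} and
#'   columns \code{median}, \code{sd}, \code{min}, \code{max}, \code{n}.
#' @examples
#' cloneStats(data.frame(peak = c(1024, 1030, 1040),
#'                       lifespanDays = c(500, 576, 600)))
#' @export
cloneStats <- function(x) {
  if (is(x, "CohortSummary")) x <- x@clones
  if (is.list(x) && !is.data.frame(x))
    x <- data.frame(peak = vapply(x, peakSize, numeric(1)),
                    lifespanDays = vapply(x, lifespanDays, numeric(1)))
  if (nrow(x) < 1L) stop("need at least one clone")
  stat <- function(v) c(median = median(v),
                        sd = if (length(v) > 1L) sd(v) else 0,
                        min = min(v), max = max(v), n = length(v))
  out <- rbind(peak = stat(x$peak), lifespanDays = stat(x$lifespanDays))
  as.data.frame(out)
}

#' Empirical cdf table at fixed breakpoints
#'
#' @param values numeric sample.
#' @param breakpoints strictly increasing evaluation points; the sample
#'   maximum is appended when it exceeds the last breakpoint, so the final
#'   cumulative probability is always 1.
#' @return data.frame (class \code{cdfTable}) with columns
#'   \code{breakpoint} and \code{cumprob}.
#' @export
cdfTable <- function(values, breakpoints) {
  if (!length(values)) stop("empty sample")
  breakpoints <- sort(unique(breakpoints))
  if (max(values) > breakpoints[length(breakpoints)])
    breakpoints <- c(breakpoints, max(values))
  cumprob <- vapply(breakpoints, function(b) mean(values <= b), numeric(1))
  structure(data.frame(breakpoint = breakpoints, cumprob = cumprob),
            class = c("cdfTable", "data.frame"))
}

#' Heterogeneity distributions of a detectable tumor
#'
#' Empirical cumulative distributions, at fixed breakpoints, of the three
#' single-cell malignancy criteria across all living cells of a tumor at
#' detection: division depth \code{d} (immortalization), differentiation
#' coefficient \code{k} (de-differentiation) and proliferation potential
#' \code{alpha}.  Also reports the component-wise medians and the fraction
#' of fully de-differentiated (\eqn{k = 0}) cells.
#'
#' @param snapshot detection-time cell table with columns \code{d},
#'   \code{k}, \code{alpha} (see \code{\link{cellSnapshot}}).
#' @param dBreaks,kBreaks,alphaBreaks cdf evaluation points; defaults are
#'   the standard reporting grids.
#' @return list with elements \code{d}, \code{k}, \code{alpha} (each a
#'   \code{\link{cdfTable}}), \code{medians} (named vector) and
#'   \code{stemFraction}.
#' @export
tumorCdfs <- function(snapshot,
                      dBreaks = c(28, 30, 32, 34, 36, 38, 40:47),
                      kBreaks = seq(0, 1.7, by = 0.1),
                      alphaBreaks = c(-7.5, -5, -2.5, 0, 2, 4:18)) {
  if (!nrow(snapshot)) stop("empty snapshot")
  list(d = cdfTable(snapshot$d, dBreaks),
       k = cdfTable(snapshot$k, kBreaks),
       alpha = cdfTable(snapshot$alpha, alphaBreaks),
       medians = c(d = median(snapshot$d), k = median(snapshot$k),
                   alpha = median(snapshot$alpha)),
       stemFraction = stemFraction(snapshot))
}

#' Cancer-stem-cell fraction
#'
#' Fraction of cells whose differentiation coefficient sits exactly at the
#' zero clamp: completely de-differentiated cells, the cancer-stem-cell
#' portion of the tumor.
#'
#' @param snapshot cell table with a \code{k} column.
#' @return fraction in [0, 1].
#' @examples
#' stemFraction(data.frame(k = c(0, 0, 0.3, 0.5, 1, 1, 0.2, 0.9, 4, 2)))
#' @export
stemFraction <- function(snapshot) {
  if (!nrow(snapshot)) stop("empty snapshot")
  mean(snapshot$k <= 0)
}

#' MRCA phenotype table across tumors
#'
#' For each mass fraction \code{x}, the median, SD, minimum and maximum
#' across tumors of the division depth, proliferation potential and
#' differentiation coefficient of MRCA(\code{x}).
#'
#' @param tumors list of \code{\linkS4class{LineageTree}} objects, or of
#'   data.frames from \code{\link{mrcaPhenotypes}} (useful when trees are
#'   too large to hold simultaneously).
#' @param x mass fractions (rows of the table).
#' @return list of data.frames \code{d}, \code{alpha}, \code{k}, each with
#'   columns \code{x}, \code{median}, \code{sd}, \code{min}, \code{max}.
#' @export
mrcaTable <- function(tumors, x = c(1, 0.999, 0.995, 0.99, 0.95, 0.90,
                                    0.80, 0.70, 0.60, 0.50)) {
  if (!length(tumors)) stop("need at least one tumor")
  phen <- lapply(tumors, function(tt)
    if (is(tt, "LineageTree")) mrcaPhenotypes(tt, x) else tt)
  one <- function(var) {
    rows <- lapply(x, function(xx) {
      v <- vapply(phen, function(p) p[[var]][match(xx, p$x)], numeric(1))
      data.frame(x = xx, median = median(v),
                 sd = if (length(v) > 1L) sd(v) else 0,
                 min = min(v), max = max(v))
    })
    do.call(rbind, rows)
  }
  list(d = one("d"), alpha = one("alpha"), k = one("k"))
}

#' Median cancer cell of a tumor snapshot
#'
#' The component-wise medians of (\code{k}, \code{alpha}, \code{d},
#' \code{g}) across the living cells of a detectable tumor: a synthetic
#' phenotype (the MCC), not an actual cell.  Division depth \code{d} and
#' generation number \code{g} advance together in proliferating lineages
#' (\eqn{g \approx d + 1} at birth), so both are reported.
#'
#' @param snapshot cell table with columns \code{k}, \code{alpha},
#'   \code{d} and (optionally) \code{g}.
#' @return one-row data.frame with columns \code{k}, \code{alpha},
#'   \code{d}, \code{g}.
#' @examples
#' medianCell(data.frame(d = c(40, 44, 45), g = c(41, 45, 46),
#'                       k = c(0, 0.3, 0.6), alpha = c(9, 10.3, 12)))
#' @export
medianCell <- function(snapshot) {
  if (!nrow(snapshot)) stop("empty snapshot")
  data.frame(k = median(snapshot$k), alpha = median(snapshot$alpha),
             d = median(snapshot$d),
             g = if ("g" %in% names(snapshot)) median(snapshot$g)
                 else NA_real_)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum distance between the two empirical
#' distribution functions, \eqn{D = \sup_x |F_a(x) - F_b(x)|}; the
#' two-sided p-value uses the asymptotic Kolmogorov distribution
#' \eqn{Q(\lambda) = 2 \sum_{j \ge 1} (-1)^{j-1} e^{-2 j^2 \lambda^2}}
#' evaluated at \eqn{\lambda = \sqrt{n_a n_b / (n_a + n_b)}\, D}.
#'
#' @param a,b numeric samples of size \eqn{\ge 2}.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @examples
#' ksTwoSample(c(1, 2, 3, 4), c(3, 4, 5, 6))$statistic   # 0.5
#' @export
ksTwoSample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples must have at least 2 observations")
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
  D <- max(abs(Fa - Fb))
  neff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- sqrt(neff) * D
  if (lambda <= 0.2) {            # Q(lambda) = 1 to within 1e-12 here
    p <- 1
  } else {
    j <- seq_len(1000)
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(1, max(0, p))
  }
  list(statistic = D, p.value = p)
}
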