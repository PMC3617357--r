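#' Construct a phenotype
#'
#' @param k differentiation coefficient (1/month), \eqn{\ge 0}.
#' @param alpha proliferation potential (cycles/month).
#' @param g generation number, \eqn{\ge 1}.
#' @param d division depth of the initializing cell within the lineage
#'   that produced it; defaults to \code{g} (see
#'   \code{\linkS4class{Phenotype}}).
#' @return a \code{\linkS4class{Phenotype}}.
#' @examples
#' phenotype(k = 0.18, alpha = 3.66, g = 17)
#' @export
phenotype <- function(k, alpha, g, d = g) {
  new("Phenotype", k = k, alpha = alpha, g = g, d = d)
}

#' Canonical tumor-initiating phenotypes
#'
#' The typical tumor-initiating cancer cell (TICC) carries the median
#' features of the most recent common ancestor of 99.5\% of a detectable
#' mass: \eqn{k = 0.18}, \eqn{\alpha = 3.66}, \eqn{g = 17}.  Its fully
#' de-differentiated stem counterpart (TICSC) has \eqn{k = 0} with the
#' same \eqn{\alpha} and \eqn{g}.
#'
#' @return a \code{\linkS4class{Phenotype}}.
#' @export
ticcPhenotype <- function() phenotype(k = 0.18, alpha = 3.66, g = 17)

#' @rdname ticcPhenotype
#' @export
ticscPhenotype <- function() phenotype(k = 0, alpha = 3.66, g = 17)

phenVec <- function(phen) {
  if (is.null(phen)) return(NULL)
  stopifnot(is(phen, "Phenotype"))
  validObject(phen)
  c(phen@k, phen@alpha, phen@g, phen@d)
}

#' Simulate one clone
#'
#' Runs the event-driven branching process from a single root cell (a
#' normal progenitor by default, or a given \code{phenotype}) until
#' extinction, tumor detection at \code{detectThreshold} living cells
#' (the simulation stops there and the mass is analyzed at that moment),
#' or \code{maxSimTime}.
#'
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @param seed integer master seed.
#' @param phenotype NULL for a normal progenitor, or a
#'   \code{\linkS4class{Phenotype}} initializing the root cell (its
#'   mutation sum is set so that \eqn{k = k_p(g) + \sum m_i} holds).
#' @param cloneIndex substream index; \code{(seed, cloneIndex)} identify
#'   the RNG stream, so cohorts are reproducible clone by clone.
#' @param series record the living-cell count after every event.  Runs
#'   whose event count exceeds \code{seriesBudget} are refused mid-run
#'   unless \code{force = TRUE} (memory guard for near-detection runs).
#' @param lineage record the full lineage tree (a
#'   \code{\linkS4class{LineageTree}} with descendant counts).
#' @param snapshot record the phenotypes of all living cells at detection
#'   (or at the censor time).
#' @param seriesBudget event budget above which series recording is
#'   refused.
#' @param force bypass the series memory guard.
#' @param maxEvents safety cap on processed events; exceeding it censors
#'   the run (signals parameter pathology).
#' @return a \code{\linkS4class{CloneRecord}}.
#' @examples
#' rec <- simulateClone(neutralParameters(), seed = 1)
#' peakSize(rec)   # exactly 2^10 under the neutral model
#' @export
simulateClone <- function(params = modelParameters(), seed,
                          phenotype = NULL, cloneIndex = 1,
                          series = TRUE, lineage = FALSE, snapshot = FALSE,
                          seriesBudget = 1e5, force = FALSE,
                          maxEvents = 1e8) {
  stopifnot(is.finite(seed))
  res <- cpp_simulate_clone(paramList(params), seed, cloneIndex,
                            phenVec(phenotype), series, lineage, snapshot,
                            maxEvents,
                            if (force) Inf else seriesBudget)
  tree <- NULL
  if (lineage) {
    ln <- res$lineage
    cnt <- cpp_descendant_counts(ln$parent, ln$alive)
    tree <- new("LineageTree", parent = ln$parent, d = ln$d,
                gBirth = ln$gBirth, gEvent = ln$gEvent, fate = ln$fate,
                tBirth = ln$tBirth, tEvent = ln$tEvent,
                alphaAtEvent = ln$alphaAtEvent, kAtEvent = ln$kAtEvent,
                alive = ln$alive, descendantCount = cnt,
                finalMass = cnt[1L])
  }
  new("CloneRecord",
      peak = res$peak, lifespanDays = res$lifespanMonths * 30,
      tumor = res$tumor, censored = res$censored,
      timeToDetectionDays = res$timeToDetectionMonths * 30,
      births = res$births, deaths = res$deaths, seed = seed,
      cloneIndex = cloneIndex,
      series = if (series) res$series else data.frame(),
      snapshot = if (!is.null(res$snapshot)) res$snapshot
                 else data.frame(),
      tree = tree, parameters = params)
}

#' Simulate a cohort of independent progenitors
#'
#' Runs \code{n} independent clones (one seeded substream each, so results
#' do not depend on execution order), counts detected tumors and reports
#' the empirical per-progenitor tumor probability with its exact Garwood
#' 95\% confidence interval.
#'
#' @param n number of progenitors.
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @param seed integer master seed.
#' @param phenotype NULL for normal progenitors, or a
#'   \code{\linkS4class{Phenotype}} for every root cell.
#' @param tumorMedians also record, for every detected tumor, the median
#'   \code{k}, \code{alpha}, \code{d} and stem fraction of its
#'   detection-time mass (costs one lineage pass per tumor).
#' @param level confidence level for the interval.
#' @param maxEvents per-clone safety cap on processed events.
#' @return a \code{\linkS4class{CohortSummary}}.
#' @examples
#' cs <- simulateCohort(50, neutralParameters(), seed = 1)
#' nTumors(cs)        # 0: the neutral model never transforms
#' @export
simulateCohort <- function(n, params = modelParameters(), seed,
                           phenotype = NULL, tumorMedians = TRUE,
                           level = 0.95, maxEvents = 1e8) {
  stopifnot(n >= 1, is.finite(seed))
  res <- cpp_simulate_cohort(paramList(params), seed, n,
                             phenVec(phenotype), tumorMedians, maxEvents)
  clones <- data.frame(peak = res$peak,
                       lifespanDays = res$lifespanMonths * 30,
                       tumor = res$tumor, censored = res$censored,
                       timeToDetectionDays = res$timeToDetectionMonths * 30)
  tum <- which(res$tumor)
  tumorMed <- data.frame(k = res$medianK[tum], alpha = res$medianAlpha[tum],
                         d = res$medianD[tum],
                         stemFraction = res$stemFraction[tum])
  x <- length(tum)
  ci <- poissonExactCI(x, n, level = level)
  new("CohortSummary", nProgenitors = n, nTumors = x, probability = x / n,
      ciLower = ci[[1L]], ciUpper = ci[[2L]], clones = clones,
      tumorMedians = tumorMed, phenotype = phenotype, seed = seed,
      parameters = params)
}

#' Simulate the fate of phenotype-initialized cells
#'
#' Initializes \code{n} independent root cells with a given phenotype
#' (e.g. the typical TICC or TICSC) and reports the fraction that spawn a
#' detectable tumor, with its exact confidence interval.  The root's
#' mutation sum is set to \eqn{k - k_p(g)} so the differentiation identity
#' holds, and its division depth defaults to \eqn{g} (the cell carries its
#' lineage history's depth).
#'
#' @param phen a \code{\linkS4class{Phenotype}}.
#' @inheritParams simulateCohort
#' @param tumorMedians see \code{\link{simulateCohort}}; defaults to off
#'   because spawn-probability runs do not need per-tumor phenotypes.
#' @return a \code{\linkS4class{CohortSummary}}; its \code{probability} is
#'   the spawn fraction.
#' @examples
#' \donttest{
#' cs <- simulateFromPhenotype(ticcPhenotype(), n = 20,
#'                             params = modelParameters(), seed = 1)
#' tumorProbability(cs)   # near 0.72 at scale
#' }
#' @export
simulateFromPhenotype <- function(phen, n, params = modelParameters(),
                                  seed, tumorMedians = FALSE,
                                  level = 0.95, maxEvents = 1e8) {
  stopifnot(is(phen, "Phenotype"))
  simulateCohort(n, params, seed, phenotype = phen,
                 tumorMedians = tumorMedians, level = level,
                 maxEvents = maxEvents)
}

#' Exact Poisson (Garwood) confidence interval for a rare probability
#'
#' For \code{x} events in \code{n} trials the exact two-sided interval on
#' the per-trial rate is
#' \deqn{[\tfrac{1}{2}\chi^2_{\alpha/2}(2x),\;
#'        \tfrac{1}{2}\chi^2_{1-\alpha/2}(2x + 2)]\, /\, n,}
#' with lower bound 0 when \code{x = 0}.
#'
#' @param x event count (\eqn{\ge 0}).
#' @param n number of trials (> 0).
#' @param level confidence level in (0, 1).
#' @return named numeric vector \code{c(lower, upper)} of probabilities.
#' @examples
#' poissonExactCI(8, 305505000)   # c(1.13053e-08, 5.15998e-08)
#' @export
poissonExactCI <- function(x, n, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  stopifnot(x >= 0, n > 0)
  a <- 1 - level
  lower <- if (x == 0) 0 else qchisq(a / 2, 2 * x) / 2
  upper <- qchisq(1 - a / 2, 2 * x + 2) / 2
  # the Poisson rate interval can exceed 1 when x is not small relative to
  # n; clamp since the reported quantity is a probability
  c(lower = lower / n, upper = min(1, upper / n))
}

# ----------------------------------------------------------- accessors ----

#' Accessors for simulation results
#'
#' @param object a \code{\linkS4class{CloneRecord}} or
#'   \code{\linkS4class{CohortSummary}}.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peakSize", function(object) standardGeneric("peakSize"))
#' @rdname accessors
#' @export
setMethod("peakSize", "CloneRecord", function(object) object@peak)

#' @rdname accessors
#' @export
setGeneric("lifespanDays", function(object) standardGeneric("lifespanDays"))
#' @rdname accessors
#' @export
setMethod("lifespanDays", "CloneRecord", function(object)
  object@lifespanDays)

#' @rdname accessors
#' @export
setGeneric("isTumor", function(object) standardGeneric("isTumor"))
#' @rdname accessors
#' @export
setMethod("isTumor", "CloneRecord", function(object) object@tumor)

#' @rdname accessors
#' @export
setGeneric("cellSnapshot", function(object) standardGeneric("cellSnapshot"))
#' @rdname accessors
#' @export
setMethod("cellSnapshot", "CloneRecord", function(object) object@snapshot)

#' @rdname accessors
#' @export
setGeneric("countSeries", function(object) standardGeneric("countSeries"))
#' @rdname accessors
#' @export
setMethod("countSeries", "CloneRecord", function(object) object@series)

#' @rdname accessors
#' @export
setGeneric("lineageTree", function(object) standardGeneric("lineageTree"))
#' @rdname accessors
#' @export
setMethod("lineageTree", "CloneRecord", function(object) object@tree)

#' @rdname accessors
#' @export
setGeneric("nTumors", function(object) standardGeneric("nTumors"))
#' @rdname accessors
#' @export
setMethod("nTumors", "CohortSummary", function(object) object@nTumors)

#' @rdname accessors
#' @export
setGeneric("tumorProbability",
           function(object) standardGeneric("tumorProbability"))
#' @rdname accessors
#' @export
setMethod("tumorProbability", "CohortSummary",
          function(object) object@probability)

#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setMethod("confInt", "CohortSummary", function(object)
  c(lower = object@ciLower, upper = object@ciUpper))

#' @rdname accessors
#' @export
setGeneric("cloneTable", function(object) standardGeneric("cloneTable"))
#' @rdname accessors
#' @export
setMethod("cloneTable", "CohortSummary", function(object) object@clones)

#' @rdname accessors
#' @export
setGeneric("tumorMedians", function(object) standardGeneric("tumorMedians"))
#' @rdname accessors
#' @export
setMethod("tumorMedians", "CohortSummary", function(object)
  object@tumorMedians)

#' @describeIn accessors display method for a clone
#' @export
setMethod("show", "CloneRecord", function(object) {
  cat("CloneRecord\n")
  cat(sprintf("  peak %g cells; lifespan %.1f days%s\n", object@peak,
              object@lifespanDays,
              if (object@censored) " (censored)" else ""))
  if (object@tumor)
    cat(sprintf("  TUMOR: detected at %.1f days\n",
                object@timeToDetectionDays))
  cat(sprintf("  %g births, %g deaths; seed %g / stream %g\n",
              object@births, object@deaths, object@seed,
              object@cloneIndex))
  if (nrow(object@snapshot))
    cat(sprintf("  snapshot: %d living cells recorded\n",
                nrow(object@snapshot)))
  if (!is.null(object@tree))
    cat(sprintf("  lineage: %d nodes, final mass %d\n",
                length(object@tree@parent), object@tree@finalMass))
  invisible(NULL)
})

#' @describeIn accessors display method for a cohort
#' @export
setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary\n")
  if (!is.null(object@phenotype))
    cat(sprintf("  phenotype roots: k = %g, alpha = %g, g = %g\n",
                object@phenotype@k, object@phenotype@alpha,
                object@phenotype@g))
  cat(sprintf("  %g progenitors, %g tumors\n", object@nProgenitors,
              object@nTumors))
  cat(sprintf("  probability %.6g  [95%% CI %.6g, %.6g]\n",
              object@probability, object@ciLower, object@ciUpper))
  cat(sprintf("  peak cells: median %g; lifespan: median %.1f days\n",
              median(object@clones$peak),
              median(object@clones$lifespanDays)))
  invisible(NULL)
})
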