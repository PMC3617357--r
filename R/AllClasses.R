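#' Mutation-effect model specification
#'
#' Distribution family for the per-daughter mutational effects \eqn{m_i}
#' (units 1/month) that are added to a cell's differentiation coefficient
#' \eqn{k = k_p(g) + \sum_i m_i}.  Three families are supported:
#' \describe{
#'   \item{\code{pointmass}}{every effect equals \code{value} (the neutral
#'     model is \code{value = 0}).}
#'   \item{\code{gaussian}}{\eqn{m_i \sim N(\code{mean}, \code{sd}^2)}.}
#'   \item{\code{mixture}}{with probability \code{1 - tailProb} a draw
#'     from \eqn{N(\code{gaussMean}, \code{gaussSd}^2)} (near-neutral
#'     bulk); with probability \code{tailProb} a de-differentiating hit
#'     \eqn{-(\code{tailShift} + \mathrm{Exp}(\code{tailScale}))}; with
#'     probability \code{posProb} a re-differentiating hit
#'     \eqn{+\code{posShift} + \mathrm{Exp}(\code{posScale})}.  The
#'     negative hits let rare lineages defy the programmed
#'     differentiation drift (the route to immortalization); the positive
#'     hits prune fully de-differentiated clades and are what leaves even
#'     a cancer stem cell a small chance of clonal failure.}
#' }
#'
#' @slot family character; one of \code{"pointmass"}, \code{"gaussian"},
#'   \code{"mixture"}.
#' @slot params named numeric vector of family parameters (see above).
#'
#' @seealso \code{\link{mutationModel}}, \code{\link{drawMutationEffects}}
#' @export
setClass("MutationModel",
  representation(family = "character", params = "numeric"),
  prototype(family = "mixture",
            params = c(gaussMean = 0.013, gaussSd = 0.055,
                       tailProb = 0.002, tailShift = 0,
                       tailScale = 0.18, posProb = 0.01,
                       posShift = 0.4, posScale = 0.1)))

setValidity("MutationModel", function(object) {
  f <- object@family
  p <- object@params
  if (length(f) != 1L || !f %in% c("pointmass", "gaussian", "mixture"))
    return("family must be one of 'pointmass', 'gaussian', 'mixture'")
  need <- switch(f,
    pointmass = "value",
    gaussian  = c("mean", "sd"),
    mixture   = c("gaussMean", "gaussSd", "tailProb", "tailShift",
                  "tailScale", "posProb", "posShift", "posScale"))
  if (!all(need %in% names(p)))
    return(paste0("params must contain: ", paste(need, collapse = ", ")))
  if (any(!is.finite(p))) return("params must be finite")
  if (f == "gaussian" && p[["sd"]] < 0) return("sd must be >= 0")
  if (f == "mixture") {
    if (p[["tailProb"]] < 0 || p[["tailProb"]] > 1)
      return("tailProb must be in [0, 1]")
    if (p[["gaussSd"]] < 0 || p[["tailScale"]] <= 0 ||
        p[["tailShift"]] < 0)
      return("gaussSd must be >= 0, tailScale > 0 and tailShift >= 0")
    if (p[["posProb"]] < 0 || p[["posProb"]] + p[["tailProb"]] > 1 ||
        p[["posScale"]] <= 0 || p[["posShift"]] < 0)
      return("positive-hit parameters out of range")
  }
  TRUE
})

#' Model parameters for the single-cell clonal dynamics
#'
#' All coefficients of the programmed trajectory, the environment and
#' mutation distributions, the detection threshold and the stop rules.
#' Defaults reproduce the study conditions: postmenopausal hormone level
#' \eqn{\beta \sim N(5, 0.5^2)} cycles/month\eqn{^2}, two mutations per
#' daughter cell per division, a detectable tumor at \eqn{10^6} living
#' cells, programmed proliferation \eqn{\alpha_p(g) = 1.7\,(10 - g)}
#' cycles/month and programmed differentiation
#' \eqn{k_p(g) = 3.78\,(1 - e^{-0.4 g}) + 0.03\,g} 1/month (so that a
#' terminally differentiated cell has \eqn{k \approx 4}).
#'
#' @slot gLimit programmed generation limit (dimensionless).
#' @slot alphaPScale coefficient of the programmed proliferation curve
#'   (cycles/month).
#' @slot kpSaturation,kpRate,kpLinear saturation level (1/month),
#'   exponential rate (per generation) and linear term (1/month per
#'   generation) of the programmed differentiation curve.
#' @slot betaMean,betaSd hormone environment distribution
#'   (cycles/month\eqn{^2}); one value of \eqn{\beta} is drawn per cell at
#'   birth and held for its life.
#' @slot mutationsPerDivision number of new mutational effects acquired by
#'   each daughter cell at birth.
#' @slot mutationModel a \code{\linkS4class{MutationModel}}.
#' @slot inheritanceNoiseSd SD of the Gaussian perturbation applied to a
#'   daughter's inherited \eqn{\alpha} at birth (cycles/month).
#' @slot alphaInitial progenitor \eqn{\alpha} at \eqn{t = 0} (cycles/month).
#' @slot detectThreshold living-cell count defining a clinically detectable
#'   tumor (cells).
#' @slot kFloor lower clamp for \eqn{k} (1/month); fixed at 0, the clamp
#'   creates the fully de-differentiated (stem) class.
#' @slot maxSimTime hard stop (months).
#'
#' @seealso \code{\link{modelParameters}}
#' @export
setClass("ModelParameters",
  representation(
    gLimit = "numeric", alphaPScale = "numeric",
    kpSaturation = "numeric", kpRate = "numeric", kpLinear = "numeric",
    betaMean = "numeric", betaSd = "numeric",
    mutationsPerDivision = "numeric", mutationModel = "MutationModel",
    inheritanceNoiseSd = "numeric", alphaInitial = "numeric",
    detectThreshold = "numeric", kFloor = "numeric",
    maxSimTime = "numeric"))

setValidity("ModelParameters", function(object) {
  sc <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("gLimit", "alphaPScale", "kpSaturation", "kpRate", "kpLinear",
              "betaMean", "betaSd", "mutationsPerDivision",
              "inheritanceNoiseSd", "alphaInitial", "detectThreshold",
              "kFloor", "maxSimTime"))
    if (!sc(slot(object, s))) return(paste0(s, " must be a finite scalar"))
  if (object@betaSd < 0) return("betaSd must be >= 0")
  if (object@inheritanceNoiseSd < 0)
    return("inheritanceNoiseSd must be >= 0")
  if (object@mutationsPerDivision < 0 ||
      object@mutationsPerDivision != round(object@mutationsPerDivision))
    return("mutationsPerDivision must be a non-negative integer")
  if (object@detectThreshold < 1) return("detectThreshold must be >= 1")
  if (object@kFloor != 0) return("kFloor must be 0 (the de-differentiation clamp)")
  if (object@maxSimTime <= 0) return("maxSimTime must be > 0")
  if (object@gLimit < 1) return("gLimit must be >= 1")
  validObject(object@mutationModel)
  TRUE
})

#' Cell phenotype triple
#'
#' Initializer for phenotype-driven runs: differentiation coefficient
#' \eqn{k} (1/month), proliferation potential \eqn{\alpha} (cycles/month)
#' and generation number \eqn{g}.  The optional division depth \code{d}
#' positions the cell within the lineage that produced it; it defaults to
#' \eqn{g}, since generation number and division depth advance together in
#' lineages that never pause (the progenitor's birth counts as division 1).
#'
#' @slot k,alpha,g,d numeric scalars (see above).
#' @seealso \code{\link{phenotype}}, \code{\link{ticcPhenotype}},
#'   \code{\link{simulateFromPhenotype}}
#' @export
setClass("Phenotype",
  representation(k = "numeric", alpha = "numeric", g = "numeric",
                 d = "numeric"))

setValidity("Phenotype", function(object) {
  if (length(object@k) != 1L || !is.finite(object@k) || object@k < 0)
    return("k must be a finite scalar >= 0")
  if (length(object@alpha) != 1L || !is.finite(object@alpha))
    return("alpha must be a finite scalar")
  if (object@g < 1 || object@g != round(object@g))
    return("g must be an integer >= 1")
  if (object@d < 1 || object@d != round(object@d))
    return("d must be an integer >= 1")
  TRUE
})

#' Lineage tree of a simulated clone
#'
#' Compressed columnar ancestry of a clone: one row per cell ever born,
#' children carrying larger indices than their parents.  Node identity
#' follows the binary ID scheme in which a parent with ID \eqn{x} has
#' daughters \eqn{10x + 1} and \eqn{10x + 2}; codes are kept as digit
#' sequences (see \code{\link{lineageCode}}) because the literal integers
#' overflow past ~18 divisions while tumors reach depth ~47.
#'
#' @slot parent integer; index of each node's parent (root has 0).
#' @slot d integer; division depth (root depth from \code{\link{phenotype}}
#'   or 1; the progenitor's birth counts as division 1).
#' @slot gBirth,gEvent integer; generation number at birth and at the fate
#'   event.
#' @slot fate integer; 0 censored, 1 division, 2 death.
#' @slot tBirth,tEvent numeric; birth and fate-event times (months).
#' @slot alphaAtEvent,kAtEvent numeric; phenotype snapshot at the fate
#'   event.
#' @slot alive logical; whether the cell is part of the final mass (living
#'   at detection time, or at the censor time).
#' @slot descendantCount integer; descendants contributed to the final mass
#'   (the node itself counts if alive).
#' @slot finalMass integer scalar; size of the final mass (equals the
#'   root's descendant count).
#'
#' @seealso \code{\link{descendantCounts}}, \code{\link{mrcaFraction}},
#'   \code{\link{asNewick}}
#' @export
setClass("LineageTree",
  representation(
    parent = "integer", d = "integer", gBirth = "integer",
    gEvent = "integer", fate = "integer", tBirth = "numeric",
    tEvent = "numeric", alphaAtEvent = "numeric", kAtEvent = "numeric",
    alive = "logical", descendantCount = "integer",
    finalMass = "integer"))

setValidity("LineageTree", function(object) {
  n <- length(object@parent)
  if (n < 1L) return("tree must contain at least the root")
  if (object@parent[1L] != 0L) return("root must have parent 0")
  if (n > 1L && any(object@parent[-1L] < 1L | object@parent[-1L] >=
                    seq_len(n)[-1L]))
    return("each non-root node's parent must precede it")
  same <- c("d", "gBirth", "gEvent", "fate", "tBirth", "tEvent",
            "alphaAtEvent", "kAtEvent", "alive", "descendantCount")
  for (s in same)
    if (length(slot(object, s)) != n)
      return(paste0("slot ", s, " must have one entry per node"))
  if (length(object@finalMass) != 1L) return("finalMass must be a scalar")
  if (object@descendantCount[1L] != object@finalMass)
    return("root descendant count must equal the final mass size")
  TRUE
})

#' Outcome of a single simulated clone
#'
#' @slot peak maximum simultaneous living-cell count (cells).
#' @slot lifespanDays progenitor birth to death of the last descendant
#'   (days; 1 month = 30 days), or the censor/detection time.
#' @slot tumor logical; did the clone reach the detection threshold?
#' @slot censored logical; was any cell still alive at \code{maxSimTime}?
#' @slot timeToDetectionDays days to reach the threshold (NA if no tumor).
#' @slot births,deaths event counts.
#' @slot seed,cloneIndex the RNG stream identity of this run.
#' @slot series data.frame of the living-cell count after every event
#'   (columns \code{time} in months and \code{cells}); empty if not
#'   recorded.
#' @slot snapshot data.frame of the phenotypes (\code{d}, \code{g},
#'   \code{k}, \code{alpha}) of all living cells at detection (or at the
#'   censor time); empty if not recorded or the clone went extinct.
#' @slot tree a \code{\linkS4class{LineageTree}}, or NULL.
#' @slot parameters the \code{\linkS4class{ModelParameters}} used.
#'
#' @seealso \code{\link{simulateClone}}
#' @export
setClass("CloneRecord",
  representation(
    peak = "numeric", lifespanDays = "numeric", tumor = "logical",
    censored = "logical", timeToDetectionDays = "numeric",
    births = "numeric", deaths = "numeric", seed = "numeric",
    cloneIndex = "numeric", series = "data.frame",
    snapshot = "data.frame", tree = "ANY",
    parameters = "ModelParameters"))

setValidity("CloneRecord", function(object) {
  if (object@peak < 1) return("peak must be >= 1")
  if (!is.na(object@lifespanDays) && object@lifespanDays < 0)
    return("lifespan must be >= 0")
  if (nrow(object@series) &&
      abs(object@peak - max(object@series$cells)) > 0)
    return("peak must equal the maximum of the N(t) series")
  if (!is.null(object@tree) && !is(object@tree, "LineageTree"))
    return("tree must be NULL or a LineageTree")
  TRUE
})

#' Aggregate outcome of a cohort of progenitors
#'
#' @slot nProgenitors,nTumors counts.
#' @slot probability empirical per-progenitor tumor probability.
#' @slot ciLower,ciUpper exact (Garwood) 95\% confidence bounds on the
#'   probability.
#' @slot clones data.frame with one row per clone: \code{peak},
#'   \code{lifespanDays}, \code{tumor}, \code{censored},
#'   \code{timeToDetectionDays}.
#' @slot tumorMedians data.frame with one row per detected tumor: median
#'   \code{k}, \code{alpha}, \code{d} and the \code{stemFraction} of its
#'   detection-time mass (all NA when not recorded).
#' @slot phenotype the initializing \code{\linkS4class{Phenotype}}, or NULL
#'   for normal progenitors.
#' @slot seed master seed of the cohort.
#' @slot parameters the \code{\linkS4class{ModelParameters}} used.
#'
#' @seealso \code{\link{simulateCohort}}, \code{\link{simulateFromPhenotype}}
#' @export
setClass("CohortSummary",
  representation(
    nProgenitors = "numeric", nTumors = "numeric", probability = "numeric",
    ciLower = "numeric", ciUpper = "numeric", clones = "data.frame",
    tumorMedians = "data.frame", phenotype = "ANY", seed = "numeric",
    parameters = "ModelParameters"))

setValidity("CohortSummary", function(object) {
  if (object@nProgenitors < 1) return("nProgenitors must be >= 1")
  if (object@nTumors > object@nProgenitors)
    return("nTumors cannot exceed nProgenitors")
  p <- object@probability
  if (abs(p - object@nTumors / object@nProgenitors) > 1e-12)
    return("probability must equal nTumors / nProgenitors")
  if (object@ciLower > p + 1e-12 || object@ciUpper < p - 1e-12)
    return("probability must lie within the confidence interval")
  if (object@ciLower < 0 || object@ciUpper > 1)
    return("confidence bounds must lie in [0, 1]")
  if (!is.null(object@phenotype) && !is(object@phenotype, "Phenotype"))
    return("phenotype must be NULL or a Phenotype")
  TRUE
})
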