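#' Construct a mutation-effect model
#'
#' @param family one of \code{"pointmass"}, \code{"gaussian"},
#'   \code{"mixture"}.
#' @param value point-mass value (1/month); \code{family = "pointmass"}.
#' @param mean,sd Gaussian location and scale; \code{family = "gaussian"}.
#' @param gaussMean,gaussSd,tailProb,tailShift,tailScale mixture
#'   parameters: mean and SD of the near-neutral Gaussian bulk,
#'   probability of a de-differentiating hit, and its location/scale (a
#'   hit is \eqn{-(\code{tailShift} + \mathrm{Exp}(\code{tailScale}))});
#'   \code{family = "mixture"}.
#' @param posProb,posShift,posScale probability and location/scale of the
#'   opposite, re-differentiating hit
#'   (\eqn{+\code{posShift} + \mathrm{Exp}(\code{posScale})}), which
#'   restores a cell's hold on its programmed schedule;
#'   \code{family = "mixture"}.
#'
#' @details The mixture defaults are the package's calibration of a
#'   quantity the model requires but the study conditions leave free.  The
#'   near-neutral bulk (slightly stabilizing mean, moderate SD) sets both
#'   how firmly senescent cells are pulled into death (clone-lifespan
#'   scale) and how readily a rare lineage random-walks its
#'   differentiation coefficient downward against the programmed drift
#'   (the tumor-initiating cell's chance of spawning a mass).  The rare
#'   de-differentiating exponential tail supplies larger erosion steps,
#'   and the rarer re-differentiating hits prune fully de-differentiated
#'   clades so a detectable tumor is not overrun by them.  See the
#'   methods vignette for the calibration rationale and its residual
#'   misfits.
#'
#' @return a \code{\linkS4class{MutationModel}}.
#' @examples
#' mutationModel("pointmass", value = 0)   # the neutral model
#' mutationModel()                          # calibrated default mixture
#' @export
mutationModel <- function(family = c("mixture", "gaussian", "pointmass"),
                          value = 0, mean = 0, sd = 0.05,
                          gaussMean = 0.013, gaussSd = 0.055,
                          tailProb = 0.002, tailShift = 0,
                          tailScale = 0.18, posProb = 0.01,
                          posShift = 0.4, posScale = 0.1) {
  family <- match.arg(family)
  params <- switch(family,
    pointmass = c(value = value),
    gaussian  = c(mean = mean, sd = sd),
    mixture   = c(gaussMean = gaussMean, gaussSd = gaussSd,
                  tailProb = tailProb, tailShift = tailShift,
                  tailScale = tailScale, posProb = posProb,
                  posShift = posShift, posScale = posScale))
  new("MutationModel", family = family, params = params)
}

#' Construct the model parameters
#'
#' Returns a validated \code{\linkS4class{ModelParameters}} object; all
#' arguments default to the study conditions (see the class documentation).
#'
#' @param gLimit programmed generation limit.
#' @param alphaPScale slope of \eqn{\alpha_p(g) =}
#'   \code{alphaPScale * (gLimit - g)} (cycles/month).
#' @param kpSaturation,kpRate,kpLinear parameters of
#'   \eqn{k_p(g) = kpSaturation\,(1 - e^{-kpRate\, g}) + kpLinear\, g}.
#' @param betaMean,betaSd hormone environment distribution
#'   (cycles/month^2).
#' @param mutationsPerDivision new mutational effects per daughter.
#' @param mutationModel a \code{\linkS4class{MutationModel}}.
#' @param inheritanceNoiseSd SD of daughter-alpha inheritance noise
#'   (cycles/month).
#' @param alphaInitial progenitor alpha at t = 0 (cycles/month).
#' @param detectThreshold living cells defining a detectable tumor.
#' @param kFloor lower clamp for k (must be 0).
#' @param maxSimTime hard stop (months).
#'
#' @return a \code{\linkS4class{ModelParameters}}.
#' @examples
#' p <- modelParameters()
#' programmedDifferentiation(10, p)   # ~4.0: terminally differentiated
#' @export
modelParameters <- function(gLimit = 10, alphaPScale = 1.7,
                            kpSaturation = 3.78, kpRate = 0.4,
                            kpLinear = 0.03, betaMean = 5, betaSd = 0.5,
                            mutationsPerDivision = 2,
                            mutationModel = cloneFate::mutationModel(),
                            inheritanceNoiseSd = 0.1, alphaInitial = 2.95,
                            detectThreshold = 1e6, kFloor = 0,
                            maxSimTime = 120) {
  new("ModelParameters", gLimit = gLimit, alphaPScale = alphaPScale,
      kpSaturation = kpSaturation, kpRate = kpRate, kpLinear = kpLinear,
      betaMean = betaMean, betaSd = betaSd,
      mutationsPerDivision = mutationsPerDivision,
      mutationModel = mutationModel,
      inheritanceNoiseSd = inheritanceNoiseSd, alphaInitial = alphaInitial,
      detectThreshold = detectThreshold, kFloor = kFloor,
      maxSimTime = maxSimTime)
}

#' Neutral (mutation-free) parameter set
#'
#' Convenience wrapper: zero mutational effects, zero inheritance noise and
#' a degenerate environment \eqn{\beta \equiv} \code{betaMean}.  Under these
#' conditions the model is fully deterministic: every cell divides exactly
#' \code{gLimit} times and the clone peaks at exactly \code{2^gLimit} cells.
#'
#' @param ... passed on to \code{\link{modelParameters}}.
#' @return a \code{\linkS4class{ModelParameters}}.
#' @export
neutralParameters <- function(...) {
  modelParameters(mutationModel = mutationModel("pointmass", value = 0),
                  inheritanceNoiseSd = 0, betaSd = 0, ...)
}

# Flatten parameters for the C++ core.
paramList <- function(params) {
  stopifnot(is(params, "ModelParameters"))
  validObject(params)
  mm <- params@mutationModel
  fam <- match(mm@family, c("pointmass", "gaussian", "mixture")) - 1L
  p <- mm@params
  gp <- function(nm, def = 0) if (nm %in% names(p)) unname(p[[nm]]) else def
  list(gLimit = params@gLimit, alphaPScale = params@alphaPScale,
       kpSaturation = params@kpSaturation, kpRate = params@kpRate,
       kpLinear = params@kpLinear, betaMean = params@betaMean,
       betaSd = params@betaSd,
       mutationsPerDivision = as.integer(params@mutationsPerDivision),
       mutFamily = fam, mutValue = gp("value"), mutMean = gp("mean"),
       mutSd = gp("sd"), mixGaussMean = gp("gaussMean"),
       mixGaussSd = gp("gaussSd"), mixTailProb = gp("tailProb"),
       mixTailShift = gp("tailShift"), mixTailScale = gp("tailScale"),
       mixPosProb = gp("posProb"), mixPosShift = gp("posShift"),
       mixPosScale = gp("posScale"),
       inheritanceNoiseSd = params@inheritanceNoiseSd,
       alphaInitial = params@alphaInitial,
       detectThreshold = params@detectThreshold, kFloor = params@kFloor,
       maxSimTime = params@maxSimTime)
}

#' Programmed proliferation potential
#'
#' The generation-indexed intrinsic proliferation schedule
#' \eqn{\alpha_p(g) = \code{alphaPScale} (\code{gLimit} - g)}
#' (cycles/month): strongly positive for young generations, zero at the
#' programmed limit and negative past it, which drives normal cells into
#' senescence and death after about 10-12 divisions.
#'
#' @param g generation number(s); integer, \eqn{\ge 1}.
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @return numeric vector of rates (cycles/month).
#' @examples
#' p <- modelParameters()
#' programmedProliferation(c(1, 10, 11), p)   # 15.3, 0, -1.7
#' @export
programmedProliferation <- function(g, params = modelParameters()) {
  if (any(g < 1) || any(g != round(g)))
    stop("g must be integer >= 1")
  params@alphaPScale * (params@gLimit - g)
}

#' Programmed differentiation coefficient
#'
#' The generation-indexed intrinsic differentiation schedule
#' \eqn{k_p(g) = \code{kpSaturation}(1 - e^{-\code{kpRate}\,g}) +
#' \code{kpLinear}\,g} (1/month): zero at \eqn{g = 0}, saturating near 3.78
#' with a slow linear drift, so that a terminally differentiated cell
#' (\eqn{g \approx 10}) has \eqn{k_p \approx 4.0}.
#'
#' @param g generation number(s); integer, \eqn{\ge 0}.
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @return numeric vector of coefficients (1/month).
#' @examples
#' programmedDifferentiation(0:10, modelParameters())
#' @export
programmedDifferentiation <- function(g, params = modelParameters()) {
  if (any(g < 0) || any(g != round(g)))
    stop("g must be integer >= 0")
  params@kpSaturation * (1 - exp(-params@kpRate * g)) + params@kpLinear * g
}

#' Propagate a single cell to its next fate event
#'
#' Exact event-time propagation of one cell from its current state to its
#' next division (cycle status +1), death (-1) or the time cap.  Between
#' generation increments the dynamics are linear with constant
#' coefficients, so \eqn{\alpha(t)} relaxes exponentially toward
#' \eqn{\alpha^* = \alpha_p + \beta/k} (linearly when \eqn{k = 0}) and the
#' event time is found on the analytic cycle-status integral.
#'
#' @param state named numeric vector or list with entries \code{t} (months),
#'   \code{alpha} (cycles/month), \code{c} (cycle status, in (-1, 1)),
#'   \code{s} (cycle units to the next generation boundary, in (0, 1]) and
#'   \code{g} (generation number).
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @param mutationSum lineage sum of mutational effects (1/month).
#' @param beta the cell's environment coefficient (cycles/month^2).
#' @param tStop absolute time cap (months); defaults to
#'   \code{maxSimTime(params)}.
#' @return list with \code{event} ("division", "death" or "censored"),
#'   \code{t}, \code{alpha}, \code{c}, \code{s}, \code{g} at the event, and
#'   \code{k}, the differentiation coefficient in force at the event.
#' @examples
#' ## constant alpha = 2 (k = 0, beta = 0): division at exactly 1/2 month
#' p <- modelParameters()
#' propagateCell(c(t = 0, alpha = 2, c = 0, s = 1, g = 17),
#'               p, mutationSum = -programmedDifferentiation(17, p),
#'               beta = 0)
#' @export
propagateCell <- function(state, params = modelParameters(),
                          mutationSum = 0, beta = params@betaMean,
                          tStop = params@maxSimTime) {
  st <- unlist(state)[c("t", "alpha", "c", "s", "g")]
  if (any(is.na(st))) stop("state must contain t, alpha, c, s, g")
  if (st[["c"]] <= -1 || st[["c"]] >= 1)
    stop("cell is not alive: c must be in (-1, 1)")
  if (st[["s"]] <= 0) stop("s must be > 0")
  cpp_propagate_cell(paramList(params), unname(st), mutationSum, beta,
                     tStop)
}

#' @describeIn modelParameters display method
#' @param object a \code{ModelParameters} object.
#' @export
setMethod("show", "ModelParameters", function(object) {
  mm <- object@mutationModel
  cat("ModelParameters\n")
  cat(sprintf("  programmed trajectory: alpha_p(g) = %.3g (%g - g); k_p(%g) = %.3f\n",
              object@alphaPScale, object@gLimit, object@gLimit,
              programmedDifferentiation(object@gLimit, object)))
  cat(sprintf("  environment: beta ~ N(%.3g, %.3g^2) per cell\n",
              object@betaMean, object@betaSd))
  cat(sprintf("  mutations: %d per daughter, %s(%s)\n",
              as.integer(object@mutationsPerDivision), mm@family,
              paste(sprintf("%s = %.3g", names(mm@params), mm@params),
                    collapse = ", ")))
  cat(sprintf("  alpha: initial %.3g, inheritance noise SD %.3g\n",
              object@alphaInitial, object@inheritanceNoiseSd))
  cat(sprintf("  detection at %.3g cells; time cap %.3g months\n",
              object@detectThreshold, object@maxSimTime))
  invisible(NULL)
})

#' @describeIn mutationModel display method
#' @param object a \code{MutationModel} object.
#' @export
setMethod("show", "MutationModel", function(object) {
  cat(sprintf("MutationModel: %s(%s)\n", object@family,
              paste(sprintf("%s = %.3g", names(object@params),
                            object@params), collapse = ", ")))
  invisible(NULL)
})
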