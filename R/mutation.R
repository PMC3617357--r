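#' Draw per-cell environment coefficients
#'
#' The hormone environment coefficient \eqn{\beta} (cycles/month^2) is
#' drawn once per cell at birth from
#' \eqn{N(\code{betaMean}, \code{betaSd}^2)} and held for the cell's life.
#' This sampler is the same deterministic generator stream the simulation
#' engine uses, so distributional tests exercise the engine's own draws.
#'
#' @param n number of draws.
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @return numeric vector of length \code{n}.
#' @examples
#' drawEnvironment(5, modelParameters(), seed = 1)
#' @export
drawEnvironment <- function(n, params = modelParameters(), seed) {
  stopifnot(n >= 0, is.finite(seed))
  cpp_draw_environment(n, params@betaMean, params@betaSd, seed)
}

#' Draw mutational effects
#'
#' Draws \code{n} mutational effects \eqn{m_i} (1/month) from the
#' configured family; the engine adds \code{mutationsPerDivision} such
#' draws to each newborn daughter's lineage sum.
#'
#' @param n number of draws.
#' @param spec a \code{\linkS4class{MutationModel}} (or a
#'   \code{\linkS4class{ModelParameters}}, whose model is used).
#' @param seed integer seed.
#' @return numeric vector of length \code{n}.
#' @examples
#' drawMutationEffects(4, mutationModel("pointmass", value = 0), seed = 1)
#' @export
drawMutationEffects <- function(n, spec = mutationModel(), seed) {
  stopifnot(n >= 0, is.finite(seed))
  params <- if (is(spec, "ModelParameters")) spec
            else modelParameters(mutationModel = spec)
  cpp_draw_mutation_effects(n, paramList(params), seed)
}

#' Analytic mean of a mutation-effect distribution
#'
#' Closed-form per-effect expectation of \eqn{m_i}: \code{value} for a
#' point mass, \code{mean} for a Gaussian, and the probability-weighted
#' sum of the bulk mean and the two hit means for the mixture.
#'
#' @param spec a \code{\linkS4class{MutationModel}}.
#' @return numeric scalar (1/month).
#' @export
mutationEffectMean <- function(spec = mutationModel()) {
  stopifnot(is(spec, "MutationModel"))
  p <- spec@params
  switch(spec@family,
         pointmass = unname(p[["value"]]),
         gaussian  = unname(p[["mean"]]),
         mixture   = {
           pt <- unname(p[["tailProb"]]); pp <- unname(p[["posProb"]])
           (1 - pt - pp) * unname(p[["gaussMean"]]) -
             pt * (unname(p[["tailShift"]]) + unname(p[["tailScale"]])) +
             pp * (unname(p[["posShift"]]) + unname(p[["posScale"]]))
         })
}

#' Perturb an inherited proliferation potential
#'
#' At division each daughter inherits its parent's \eqn{\alpha} plus
#' zero-mean Gaussian noise of SD \code{inheritanceNoiseSd}.
#'
#' @param parentAlpha the parent's \eqn{\alpha} at division (cycles/month).
#' @param n number of draws.
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @param seed integer seed.
#' @return numeric vector of length \code{n}.
#' @export
perturbInheritedAlpha <- function(parentAlpha, n = 1,
                                  params = modelParameters(), seed) {
  stopifnot(is.finite(parentAlpha), n >= 0, is.finite(seed))
  cpp_perturb_alpha(parentAlpha, n, params@inheritanceNoiseSd, seed)
}
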