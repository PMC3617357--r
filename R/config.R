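#' Run configuration
#'
#' A validated bundle of model parameters plus an experiment description,
#' loadable from YAML/JSON.  Defaults reproduce the study conditions
#' (\eqn{\beta \sim N(5, 0.5^2)}, two mutations per daughter per division,
#' detection at \eqn{10^6} cells).
#'
#' @slot parameters a \code{\linkS4class{ModelParameters}}.
#' @slot experiment list: \code{mode} ("clone", "cohort" or "phenotype"),
#'   \code{n}, and for phenotype mode \code{k}, \code{alpha}, \code{g}
#'   (optional \code{d}).
#' @slot seed master seed.
#' @slot recording one of "full", "compressed", "counts".
#' @seealso \code{\link{loadConfig}}
#' @export
setClass("RunConfig",
  representation(parameters = "ModelParameters", experiment = "list",
                 seed = "numeric", recording = "character"))

setValidity("RunConfig", function(object) {
  ex <- object@experiment
  if (!ex$mode %in% c("clone", "cohort", "phenotype"))
    return("experiment$mode must be clone, cohort or phenotype")
  if (!is.numeric(ex$n) || ex$n < 1)
    return("experiment$n must be >= 1")
  if (ex$mode == "phenotype" &&
      !all(c("k", "alpha", "g") %in% names(ex)))
    return("phenotype mode needs experiment$k, $alpha, $g")
  if (!object@recording %in% c("full", "compressed", "counts"))
    return("recording must be full, compressed or counts")
  if (length(object@seed) != 1L || !is.finite(object@seed))
    return("seed must be a finite scalar")
  TRUE
})

paramKeys <- c("gLimit", "alphaPScale", "kpSaturation", "kpRate",
               "kpLinear", "betaMean", "betaSd", "mutationsPerDivision",
               "mutationModel", "inheritanceNoiseSd", "alphaInitial",
               "detectThreshold", "kFloor", "maxSimTime")

#' Load a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) configuration, validates it
#' against the schema and fills defaults.  Unknown keys are rejected with
#' a field-path message; an empty file yields the full default
#' configuration.
#'
#' @param path readable configuration file.
#' @return a \code{\linkS4class{RunConfig}}.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("parameters:\n  betaSd: 0.25\nseed: 7", f)
#' loadConfig(f)
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("parameters", "experiment", "seed", "recording")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  pr <- raw$parameters
  if (!is.null(pr)) {
    bad <- setdiff(names(pr), paramKeys)
    if (length(bad)) stop("unknown key(s) under parameters: ",
                          paste0("parameters$", bad, collapse = ", "))
  }
  mm <- pr$mutationModel
  mutmod <- if (is.null(mm)) mutationModel()
  else {
    bad <- setdiff(names(mm),
                   c("family", "value", "mean", "sd", "gaussMean",
                     "gaussSd", "tailProb", "tailShift", "tailScale",
                     "posProb", "posShift", "posScale"))
    if (length(bad)) stop("unknown key(s) under parameters$mutationModel: ",
                          paste0("parameters$mutationModel$", bad,
                                 collapse = ", "))
    do.call(mutationModel, mm)
  }
  pr$mutationModel <- mutmod
  params <- tryCatch(do.call(modelParameters, as.list(pr)),
                     error = function(e)
                       stop("invalid parameters: ", conditionMessage(e)))
  ex <- raw$experiment
  if (is.null(ex)) ex <- list()
  # YAML 1.1 reads a bare `n` key as a boolean; map it back
  names(ex)[names(ex) %in% c("FALSE", "no")] <- "n"
  bad <- setdiff(names(ex), c("mode", "n", "k", "alpha", "g", "d"))
  if (length(bad)) stop("unknown key(s) under experiment: ",
                        paste0("experiment$", bad, collapse = ", "))
  if (is.null(ex$mode)) ex$mode <- "clone"
  if (is.null(ex$n)) ex$n <- 1
  cfg <- new("RunConfig", parameters = params, experiment = ex,
             seed = if (is.null(raw$seed)) 1 else raw$seed,
             recording = if (is.null(raw$recording)) "compressed"
                         else raw$recording)
  validObject(cfg)
  cfg
}

#' Save a run configuration
#'
#' Writes a \code{\linkS4class{RunConfig}} back to YAML;
#' \code{loadConfig(saveConfig(cfg, f))} reproduces \code{cfg}.
#'
#' @param config a \code{\linkS4class{RunConfig}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  p <- config@parameters
  mm <- p@mutationModel
  out <- list(
    parameters = c(
      setNames(lapply(setdiff(paramKeys, "mutationModel"),
                      function(s) slot(p, s)),
               setdiff(paramKeys, "mutationModel")),
      list(mutationModel = c(list(family = mm@family),
                             as.list(mm@params)))),
    experiment = config@experiment,
    seed = config@seed,
    recording = config@recording)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the experiment described by a configuration
#'
#' @param config a \code{\linkS4class{RunConfig}}.
#' @return a \code{\linkS4class{CloneRecord}} (clone mode) or
#'   \code{\linkS4class{CohortSummary}} (cohort/phenotype mode).
#' @export
runConfig <- function(config) {
  stopifnot(is(config, "RunConfig"))
  p <- config@parameters
  ex <- config@experiment
  full <- config@recording == "full"
  switch(ex$mode,
    clone = simulateClone(p, seed = config@seed,
                          series = config@recording != "counts",
                          lineage = full, snapshot = full,
                          force = full),
    cohort = simulateCohort(ex$n, p, seed = config@seed,
                            tumorMedians = config@recording != "counts"),
    phenotype = simulateFromPhenotype(
      phenotype(k = ex$k, alpha = ex$alpha, g = ex$g,
                d = if (is.null(ex$d)) ex$g else ex$d),
      n = ex$n, params = p, seed = config@seed,
      tumorMedians = config@recording != "counts"))
}

#' Deterministic test fixtures
#'
#' Small, fully reproducible objects for tests and examples:
#' \describe{
#'   \item{\code{tiny-clone}}{a neutral-parameter clone (deterministic
#'     full binary expansion; peak exactly \eqn{2^{10}} cells).}
#'   \item{\code{toy-tree}}{a depth-3 annotated
#'     \code{\linkS4class{LineageTree}} with 4 living leaves.}
#'   \item{\code{toy-snapshot}}{a 20-cell phenotype table with
#'     hand-computable medians (k 0.85, alpha 5.25, d 42) and stem
#'     fraction 0.1.}
#' }
#'
#' @param kind fixture name.
#' @param seed integer seed (fixtures are deterministic given the seed).
#' @return the fixture object.
#' @examples
#' peakSize(makeFixture("tiny-clone"))          # 1024
#' medianCell(makeFixture("toy-snapshot"))
#' @export
makeFixture <- function(kind = c("tiny-clone", "toy-tree",
                                 "toy-snapshot"), seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    "tiny-clone" = simulateClone(neutralParameters(), seed = seed),
    "toy-tree" = LineageTree(
      parent = c(0L, 1L, 1L, 2L, 2L, 3L, 3L),
      alive = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
      alphaAtEvent = c(8, 10, 9, 5, 6, 7, 4),
      kAtEvent = c(1.3, 2.1, 2.2, 3.1, 3.0, 2.9, 3.3)),
    "toy-snapshot" = data.frame(
      d = rep(c(40L, 44L), each = 10),
      g = rep(c(41L, 45L), each = 10),
      k = c(0, 0, (1:18) / 10),
      alpha = seq(0.5, 10, by = 0.5)))
}
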