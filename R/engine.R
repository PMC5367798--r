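## The docking loop: wrap the force-field energy in the magnitude transform,
## drive the tensor-train magnitude maximizer over the search space with
## rough Subplex refinement as the in-loop callback, and persist every
## refined candidate to the binary minima store.

#' Magnitude transform of the energy
#'
#' \code{f(E, E*) = exp(100 * arccot(E - E*))} with arccot the continuous
#' decreasing branch onto (0, pi) and \code{E*} the lowest raw energy found
#' so far. Strictly decreasing in \code{E}, range \code{(1, exp(100*pi))}:
#' the global minimization problem becomes magnitude maximization, large
#' clash energies are flattened towards 1, and low minima are sharply
#' separated.
#'
#' @param e raw energy (treated as dimensionless).
#' @param eStar current lowest raw energy.
#' @return Positive scalar (vectorized over \code{e}).
#' @examples
#' energyTransform(0, 0) == exp(50 * pi)
#' @export
energyTransform <- function(e, eStar) {
  exp(100 * (pi / 2 - atan(e - eStar)))
}

#' Rough in-loop local refinement of a search-space point
#'
#' Bounded derivative-free refinement in DOF space by the Subplex algorithm
#' (Nelder-Mead simplex cycling over low-dimensional subspaces), capped at
#' \code{budget} energy evaluations. Deliberately rough: the thorough
#' quasi-Newton polishing belongs to post-processing.
#'
#' @param point numeric d-vector within bounds.
#' @param space a \linkS4class{SearchSpace}.
#' @param system the \linkS4class{MolecularSystem}.
#' @param model an \linkS4class{EnergyModel}.
#' @param budget maximum energy evaluations; 0 returns the input unchanged.
#' @return list with \code{point} (clipped to bounds) and \code{energy};
#'   the returned energy never exceeds the input point's energy.
#' @export
roughRefine <- function(point, space, system, model, budget = 200L) {
  dm <- space@dims
  obj <- function(p) modelEnergy(model, buildCoords(p, space, system))
  e0 <- obj(point)
  if (budget <= 2L) return(list(point = point, energy = e0))
  res <- nloptr::sbplx(x0 = point, fn = obj,
                       lower = dm$lower, upper = dm$upper,
                       control = list(maxeval = as.integer(budget)))
  if (is.finite(res$value) && res$value <= e0)
    list(point = pmin(pmax(res$par, dm$lower), dm$upper),
         energy = res$value)
  else list(point = point, energy = e0)
}

#' Dock a ligand into the receptor
#'
#' Runs the grid-free docking loop: the search space is discretized on a
#' \code{2^m} grid per dimension, the complex energy (computed directly by
#' the energy backend for every visited conformation, no precalculated
#' potential grid) is wrapped in [energyTransform()] with a running
#' \code{E*}, and [ttMagnitudeMaximize()] drives cross interpolation with
#' [roughRefine()] as the step-4 callback. Every refined candidate is
#' appended to a binary \linkS4class{MinimaStore}. Deterministic for a
#' fixed seed and configuration.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param space a \linkS4class{SearchSpace} built for \code{system}.
#' @param model an \linkS4class{EnergyModel}; validated on entry.
#' @param storePath output path for the binary store (default a tempfile).
#' @param rmax maximal TT-rank (paper-tested regimes: 4 with n = 2^16,
#'   8 or 16 with n = 2^12).
#' @param iterations optimizer iterations (default 15).
#' @param seed integer seed for the whole run.
#' @param refineBudget energy evaluations per rough refinement.
#' @param sweeps cross half-sweeps per iteration.
#' @param validate run the energy-model contract checks first.
#' @return A \linkS4class{MinimaStore} pointing at the written file; its
#'   \code{header} carries the run provenance, and attribute
#'   \code{bestEnergy} the final \code{E*}.
#' @export
dock <- function(system, space, model, storePath = tempfile(fileext = ".ttm"),
                 rmax = 4L, iterations = 15L, seed = 1L,
                 refineBudget = 200L, sweeps = 2L, validate = TRUE) {
  if (validate) validateEnergyModel(model, system)
  dm <- space@dims
  d <- nrow(dm)
  lig <- ligandIndices(system)
  mov <- moveableIndices(system)
  env <- new.env(parent = emptyenv())
  env$eStar <- NA_real_
  env$eStarTrace <- numeric(0)
  env$nref <- 0L
  f <- ImplicitTensor(function(idx) {
    e <- modelEnergy(model, buildCoords(gridToPoint(idx, space),
                                        space, system))
    if (is.na(env$eStar)) env$eStar <- e
    energyTransform(e, env$eStar)
  }, dm$n)
  handle <- createMinimaStore(storePath, d = d, nLig = length(lig),
                              nMov = length(mov), seed = seed,
                              configHash = configHash(space, rmax,
                                                      iterations, seed),
                              sysChecksum = systemChecksum(system))
  on.exit(if (!handle$closed) closeStoreHandle(handle), add = TRUE)
  refineCb <- function(idx, value) {
    p0 <- gridToPoint(idx, space)
    rr <- roughRefine(p0, space, system, model, budget = refineBudget)
    env$nref <- env$nref + 1L
    cds <- buildCoords(rr$point, space, system)
    appendMinimaRecord(handle, point = rr$point,
                       ligCoords = cds[lig, , drop = FALSE],
                       movCoords = cds[mov, , drop = FALSE],
                       energy = rr$energy, tag = env$nref)
    if (rr$energy < env$eStar) env$eStar <- rr$energy
    env$eStarTrace <- c(env$eStarTrace, env$eStar)
    pointToGrid(rr$point, space)
  }
  ttMagnitudeMaximize(f, rmax = rmax, iterations = iterations,
                      refine = refineCb, seed = seed, sweeps = sweeps)
  closeStoreHandle(handle)
  store <- MinimaStore(storePath)
  attr(store, "bestEnergy") <- env$eStar
  attr(store, "eStarTrace") <- env$eStarTrace
  attr(store, "evaluations") <- evalCount(f)
  store
}

configHash <- function(space, rmax, iterations, seed) {
  txt <- paste(c(sprintf("%.10g", c(space@cubeCenter, space@cubeEdge,
                                    space@atomCubeEdge)),
                 space@m, rmax, iterations, seed), collapse = "|")
  crc32(charToRaw(txt))
}

systemChecksum <- function(system) {
  txt <- paste(c(system@atoms$element, sprintf("%.6f", system@atoms$charge),
                 sprintf("%.6f", system@coords),
                 system@bonds$i, system@bonds$j), collapse = "|")
  crc32(charToRaw(txt))
}
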