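## Molecular system construction, rotatable-bond perception and torsion
## application. The receptor comes first in the global atom index space,
## then the ligand; bond indices are global.

## Force-field atom types for the reference backend: element-derived small
## integers, with aromatic-ring members shifted by +20 (real force-field
## typing distinguishes aromatic from aliphatic atoms, and the
## chemical-digest machinery needs that granularity to separate, e.g., a
## ring carbon's neighborhood from a methyl carbon's). An MMFF94 adapter
## would overwrite these with types 1..99.
ELEMENT_FF_TYPES <- c(H = 1L, C = 2L, N = 3L, O = 4L, S = 5L, P = 6L,
                      F = 7L, Cl = 8L, Br = 9L, I = 10L)

elementFFType <- function(element, aromatic = FALSE) {
  t <- ELEMENT_FF_TYPES[element]
  t[is.na(t)] <- 99L
  t <- unname(t)
  ifelse(aromatic & t != 99L, t + 20L, t)
}

#' Assemble a molecular system from receptor and ligand tables
#'
#' @param receptorElements,ligandElements character element symbols.
#' @param receptorCoords,ligandCoords numeric n x 3 matrices (Angstrom).
#' @param receptorCharges,ligandCharges partial charges (e); default 0.
#' @param ligandBonds data.frame with ligand-local columns \code{i},
#'   \code{j}, \code{order} (numeric; 1.5 for aromatic).
#' @param receptorBonds optional data.frame, receptor-local indices.
#' @param moveable integer vector of receptor atom indices (global =
#'   receptor-local, receptor atoms come first) confined to small cubes.
#' @param ffTypes optional integer force-field types per atom (receptor
#'   then ligand); defaults to element-derived types.
#' @return A validated \linkS4class{MolecularSystem} with ring flags and
#'   rotatable bonds assigned.
#' @export
makeMolecularSystem <- function(receptorElements, receptorCoords,
                                ligandElements, ligandCoords,
                                ligandBonds,
                                receptorCharges = NULL, ligandCharges = NULL,
                                receptorBonds = NULL, moveable = integer(0),
                                ffTypes = NULL) {
  nr <- length(receptorElements); nl <- length(ligandElements)
  if (is.null(receptorCharges)) receptorCharges <- numeric(nr)
  if (is.null(ligandCharges)) ligandCharges <- numeric(nl)
  allBonds <- list(
    i = c(if (!is.null(receptorBonds)) receptorBonds$i,
          if (nrow(ligandBonds) > 0L) ligandBonds$i + nr),
    j = c(if (!is.null(receptorBonds)) receptorBonds$j,
          if (nrow(ligandBonds) > 0L) ligandBonds$j + nr),
    order = c(if (!is.null(receptorBonds)) receptorBonds$order,
              if (nrow(ligandBonds) > 0L) ligandBonds$order))
  aromatic <- logical(nr + nl)
  ar <- abs(allBonds$order - 1.5) < 1e-9
  aromatic[unique(c(allBonds$i[ar], allBonds$j[ar]))] <- TRUE
  atoms <- data.frame(
    element = c(receptorElements, ligandElements),
    charge = c(receptorCharges, ligandCharges),
    ffType = if (is.null(ffTypes))
      elementFFType(c(receptorElements, ligandElements), aromatic)
    else as.integer(ffTypes),
    isHydrogen = c(receptorElements, ligandElements) == "H",
    owner = rep(c("receptor", "ligand"), c(nr, nl)),
    moveable = FALSE,
    stringsAsFactors = FALSE)
  atoms$moveable[moveable] <- TRUE
  coords <- rbind(as.matrix(receptorCoords), as.matrix(ligandCoords))
  dimnames(coords) <- NULL
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  if (!is.null(receptorBonds) && nrow(receptorBonds) > 0L)
    bonds <- rbind(bonds, data.frame(i = receptorBonds$i,
                                     j = receptorBonds$j,
                                     order = receptorBonds$order))
  if (nrow(ligandBonds) > 0L)
    bonds <- rbind(bonds, data.frame(i = ligandBonds$i + nr,
                                     j = ligandBonds$j + nr,
                                     order = ligandBonds$order))
  bonds$inRing <- ringBondFlags(bonds, nr + nl)
  sys <- new("MolecularSystem", atoms = atoms, coords = coords,
             bonds = bonds, rotatableBonds = integer(0))
  sys@rotatableBonds <- detectRotatableBonds(sys)
  validObject(sys)
  sys
}

## A bond is in a ring iff it is not a bridge of the bond graph.
ringBondFlags <- function(bonds, natoms) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::make_empty_graph(n = natoms, directed = FALSE)
  g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(bonds))
  flags[as.integer(br)] <- FALSE
  flags
}

ligandGraph <- function(system) {
  g <- igraph::make_empty_graph(n = nrow(system@atoms), directed = FALSE)
  b <- ligandBondRows(system)
  if (length(b) > 0L)
    g <- igraph::add_edges(g, rbind(system@bonds$i[b], system@bonds$j[b]))
  g
}

ligandBondRows <- function(system) {
  lig <- ligandIndices(system)
  which(system@bonds$i %in% lig & system@bonds$j %in% lig)
}

#' Detect rotatable ligand bonds
#'
#' A ligand bond is rotatable when it is a single non-ring bond whose
#' removal splits the ligand into two components, each containing at least
#' one moving heavy atom (a non-hydrogen atom other than the bond endpoint
#' on that side). Rotors that move only hydrogens (methyl, hydroxyl) are
#' therefore excluded. Order is ascending bond index and deterministic.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @return Integer vector of rotatable bond rows (into the bond table).
#' @export
detectRotatableBonds <- function(system) {
  b <- system@bonds
  cand <- intersect(ligandBondRows(system),
                    which(b$order == 1 & !b$inRing))
  g <- ligandGraph(system)
  heavy <- !system@atoms$isHydrogen
  keep <- vapply(cand, function(r) {
    sides <- splitAtBond(g, b$i[r], b$j[r])
    all(vapply(seq_along(sides), function(s) {
      axis <- c(b$i[r], b$j[r])[s]
      any(heavy[setdiff(sides[[s]], axis)])
    }, logical(1)))
  }, logical(1))
  sort(cand[keep])
}

## Components of the ligand graph after deleting bond (i, j); element 1 is
## the side containing i, element 2 the side containing j.
splitAtBond <- function(g, i, j) {
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
  comp <- igraph::components(g2)$membership
  list(which(comp == comp[i]), which(comp == comp[j]))
}

rotationMatrixAxis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle); C <- 1 - c
  matrix(c(a[1]^2 * C + c,        a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[1] * a[2] * C + a[3] * s, a[2]^2 * C + c,        a[2] * a[3] * C - a[1] * s,
           a[1] * a[3] * C - a[2] * s, a[2] * a[3] * C + a[1] * s, a[3]^2 * C + c),
         3L, 3L, byrow = TRUE)
}

rotateAbout <- function(coords, origin, axis, angle) {
  rot <- rotationMatrixAxis(axis, angle)
  sweep(sweep(coords, 2L, origin) %*% t(rot), 2L, origin, `+`)
}

#' Rotate a ligand fragment about a rotatable bond
#'
#' Rotates the smaller of the two components obtained by cutting the bond
#' (ties: the side containing the bond's second atom moves) about the bond
#' axis; atoms in the larger component and on the axis stay fixed, so bond
#' lengths and angles within each component are preserved.
#'
#' @param coords full N x 3 coordinate matrix.
#' @param bond row index into the bond table; must be rotatable.
#' @param angle rotation in radians.
#' @param system a \linkS4class{MolecularSystem}.
#' @return The rotated coordinate matrix.
#' @export
applyTorsion <- function(coords, bond, angle, system) {
  if (!(bond %in% system@rotatableBonds))
    stop("bond ", bond, " is not rotatable")
  i <- system@bonds$i[bond]; j <- system@bonds$j[bond]
  sides <- splitAtBond(ligandGraph(system), i, j)
  moving <- if (length(sides[[1L]]) < length(sides[[2L]]))
    setdiff(sides[[1L]], i) else setdiff(sides[[2L]], j)
  axis <- coords[j, ] - coords[i, ]
  coords[moving, ] <- rotateAbout(coords[moving, , drop = FALSE],
                                  coords[i, ], axis, angle)
  coords
}

#' Validate an energy backend against the engine's contract
#'
#' Checks rigid-motion invariance (energy unchanged under random rotations
#' plus translations of the whole complex) and, when the backend claims an
#' analytic gradient, agreement with central finite differences.
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param system the \linkS4class{MolecularSystem} the model will see.
#' @param nChecks number of random geometries tested.
#' @param seed RNG seed for the random motions.
#' @return TRUE invisibly; stops with a message on contract violation.
#' @export
validateEnergyModel <- function(model, system, nChecks = 5L, seed = 1L) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  base <- atomCoords(system)
  e0 <- modelEnergy(model, base)
  if (!is.finite(e0)) stop("energy model: non-finite energy at input coords")
  for (t in seq_len(nChecks)) {
    axis <- stats::rnorm(3); angle <- stats::runif(1, 0, 2 * pi)
    shift <- stats::rnorm(3, sd = 3)
    moved <- sweep(rotateAbout(base, colMeans(base), axis, angle), 2L,
                   shift, `+`)
    if (abs(modelEnergy(model, moved) - e0) > 1e-6 * max(1, abs(e0)))
      stop("energy model violates rigid-motion invariance")
    if (model@hasGradient) {
      jitter <- base + matrix(stats::rnorm(length(base), sd = 0.05),
                              ncol = 3L)
      ga <- modelGradient(model, jitter)
      gn <- numericalGradient(model@energyFn, jitter)
      rel <- max(abs(ga - gn)) / max(1, max(abs(gn)))
      if (rel > 1e-4)
        stop(sprintf(
          "energy model gradient disagrees with finite differences (rel %.2e)",
          rel))
    }
  }
  invisible(TRUE)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}

.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
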