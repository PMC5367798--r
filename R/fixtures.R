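## Deterministic fixtures: analytic optimization landscapes with known
## maxima, and toy receptor-ligand complexes with planted global minima.
## Everything is a pure function of its arguments and seed, so every stage
## of the engine is testable without external data.

#' Analytic test tensor with a known argmax
#'
#' Three families of positive landscapes on the unit cube, sampled at cell
#' centers \code{x_i = (i - 0.5)/n}:
#' \describe{
#'   \item{separable}{product of per-dimension positive vectors; the argmax
#'     is the tuple of per-dimension argmaxes.}
#'   \item{gaussians}{sum of 3 isotropic Gaussian bumps with random centers
#'     — a smooth multimodal landscape.}
#'   \item{rastrigin}{\code{exp(-R(x))} with an oscillatory, many-minima
#'     Rastrigin-style \code{R}; sharply multimodal.}
#' }
#'
#' @param name one of "separable", "gaussians", "rastrigin".
#' @param d dimensions.
#' @param n grid nodes per dimension.
#' @param seed RNG seed; same seed, same tensor.
#' @param denseArgmax also compute the true argmax by dense enumeration;
#'   requires \code{n^d <= 3e5} (refused with guidance otherwise). For
#'   "separable" the argmax comes from separability at any size.
#' @return list with \code{tensor} (an \linkS4class{ImplicitTensor}),
#'   \code{argmax} (integer multi-index or NULL), \code{maxValue}, and
#'   \code{fun} (vectorized index-matrix evaluator used by the dense scan;
#'   does not touch the oracle counter).
#' @export
makeAnalyticTensor <- function(name = c("separable", "gaussians",
                                        "rastrigin"),
                               d, n, seed = 1L, denseArgmax = TRUE) {
  name <- match.arg(name)
  oldSeed <- .Random.seed.save()
  on.exit(.Random.seed.restore(oldSeed))
  set.seed(seed)
  xs <- (seq_len(n) - 0.5) / n
  if (name == "separable") {
    vecs <- lapply(seq_len(d), function(k) stats::runif(n, 0.1, 1))
    fun <- function(idx) {
      idx <- matrix(idx, ncol = d)
      Reduce(`*`, lapply(seq_len(d), function(k) vecs[[k]][idx[, k]]))
    }
    argmax <- vapply(vecs, which.max, integer(1))
  } else if (name == "gaussians") {
    centers <- matrix(stats::runif(3L * d, 0.15, 0.85), 3L, d)
    amp <- c(1, 0.7, 0.5); sig <- c(0.18, 0.12, 0.15)
    fun <- function(idx) {
      x <- matrix(xs[matrix(idx, ncol = d)], ncol = d)
      v <- 0
      for (j in 1:3)
        v <- v + amp[j] * exp(-rowSums(
          sweep(x, 2L, centers[j, ])^2) / (2 * sig[j]^2))
      v
    }
    argmax <- NULL
  } else {
    ctr <- stats::runif(d, 0.2, 0.8)
    fun <- function(idx) {
      x <- sweep(matrix(xs[matrix(idx, ncol = d)], ncol = d), 2L, ctr)
      exp(-rowSums(20 * x^2 + 1 - cos(6 * pi * x)))
    }
    argmax <- NULL
  }
  maxValue <- NULL
  if (is.null(argmax) || denseArgmax) {
    if (denseArgmax) {
      if (as.numeric(n)^d > 3e5)
        stop("dense enumeration refused: n^d = ", as.numeric(n)^d,
             " > 3e5; lower n or d, or set denseArgmax = FALSE")
      grid <- as.matrix(expand.grid(rep(list(seq_len(n)), d)))
      vals <- fun(grid)
      argmax <- grid[which.max(vals), ]
      maxValue <- max(vals)
    }
  }
  if (is.null(maxValue) && !is.null(argmax))
    maxValue <- fun(matrix(argmax, 1L))
  list(tensor = ImplicitTensor(function(idx) fun(matrix(idx, 1L)),
                               rep(n, d)),
       argmax = if (is.null(argmax)) NULL else as.integer(argmax),
       maxValue = maxValue, fun = fun)
}

## Ligand templates: local coordinates (centered), elements and bonds.
## Chains use ideal sp3 zigzag geometry (b0 = 1.526 A, 109.47 deg).
ligandTemplate <- function(name) {
  b0 <- 1.526
  half <- 109.47 / 2 * pi / 180
  zig <- function(n) {
    cds <- matrix(0, n, 3L)
    for (i in 2:n) {
      dir <- c(sin(half), cos(half) * (-1)^i, 0)
      cds[i, ] <- cds[i - 1L, ] + b0 * dir
    }
    sweep(cds, 2L, colMeans(cds))
  }
  chainBonds <- function(n)
    data.frame(i = seq_len(n - 1L), j = 2:n, order = 1)
  switch(name,
    diatomic = list(elements = c("C", "C"),
                    coords = cbind(0, 0, c(-b0 / 2, b0 / 2)),
                    bonds = chainBonds(2L)),
    triatomic = list(elements = rep("C", 3L), coords = zig(3L),
                     bonds = chainBonds(3L)),
    chain4 = list(elements = rep("C", 4L), coords = zig(4L),
                  bonds = chainBonds(4L)),
    chain6 = list(elements = rep("C", 6L), coords = zig(6L),
                  bonds = chainBonds(6L)),
    stop("unknown ligand template '", name, "'"))
}

#' Toy receptor-ligand complex with a planted global minimum
#'
#' The receptor is a cage of carbon atoms: two rings of
#' \code{nPocketAtoms/2} atoms at \code{z = +/- layerZ}, radius
#' \code{pocketRadius}, the upper ring rotated half a step. The ligand
#' (template-built, centered at the cage center) sits in the
#' Lennard-Jones pocket; with the default geometry the input pose is the
#' planted global minimum of the reference force field. With
#' \code{clashAtom = TRUE} an extra receptor atom is placed so that its
#' crystallographic position clashes with the planted pose while a
#' displacement of at most half the atom-cube edge relieves the clash:
#' rigid-receptor docking then finds its optimum away from the planted
#' pose, a moveable-atom run recovers it.
#'
#' @param ligand template name: "diatomic" (default), "triatomic",
#'   "chain4", "chain6".
#' @param nPocketAtoms even number of cage atoms (default 8).
#' @param pocketRadius cage ring radius in Angstrom.
#' @param layerZ half-separation of the two rings (Angstrom).
#' @param clashAtom add the clash-construction receptor atom.
#' @param outDir if given, write \code{receptor.pdb} (charges in the
#'   B-factor column), \code{ligand.mol2} and, for the clash variant,
#'   \code{moveable.txt} there.
#' @param seed reserved for randomized variants; the default geometry is
#'   deterministic.
#' @return list with \code{system} (clash atom already flagged moveable
#'   when present), \code{plantedCoords} (full coordinates of the planted
#'   pose = the input coordinates), \code{clashAtom} (index or NA),
#'   \code{files} (named paths when \code{outDir} given).
#' @export
makeToyComplex <- function(ligand = "diatomic", nPocketAtoms = 8L,
                           pocketRadius = 3.6, layerZ = 1.4,
                           clashAtom = FALSE, outDir = NULL, seed = 1L) {
  if (nPocketAtoms %% 2L != 0L) stop("nPocketAtoms must be even")
  half <- nPocketAtoms %/% 2L
  ang <- 2 * pi * (seq_len(half) - 1L) / half
  ring <- function(z, offset)
    cbind(pocketRadius * cos(ang + offset), pocketRadius * sin(ang + offset),
          z)
  recCoords <- rbind(ring(-layerZ, 0), ring(layerZ, pi / half))
  recElements <- rep("C", nPocketAtoms)
  recCharges <- numeric(nPocketAtoms)
  clashIdx <- NA_integer_
  if (clashAtom) {
    ## Clash construction: one atom 2.45 A above the planted ligand's top
    ## atom on the cage open axis (strong Lennard-Jones overlap with the
    ## planted pose, no cage contact) whose small cube allows a corner
    ## displacement that relieves the clash, plus a floor atom below the
    ## cage that blocks the cheap escape of sliding the ligand down the
    ## open axis. Rigid-receptor relief therefore requires displacing the
    ## ligand well away from the planted pose; a moveable clash atom makes
    ## the planted pose the global minimum again.
    lt <- ligandTemplate(ligand)
    tip <- lt$coords[which.max(lt$coords[, 3L]), ]
    bottom <- lt$coords[which.min(lt$coords[, 3L]), ]
    recCoords <- rbind(recCoords, tip + c(0, 0, 2.45),
                       bottom + c(0, 0, -3.59))
    recElements <- c(recElements, "C", "C")
    recCharges <- c(recCharges, 0, 0)
    clashIdx <- nPocketAtoms + 1L
  }
  lt <- ligandTemplate(ligand)
  sys <- makeMolecularSystem(recElements, recCoords,
                             lt$elements, lt$coords,
                             ligandBonds = lt$bonds,
                             receptorCharges = recCharges,
                             moveable = if (clashAtom) clashIdx
                                        else integer(0))
  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pdb <- file.path(outDir, "receptor.pdb")
    mol2 <- file.path(outDir, "ligand.mol2")
    writeReceptorPdb(pdb, recElements, recCoords, charges = recCharges)
    writeLigandMol2(mol2, lt$elements, lt$coords, bonds = lt$bonds,
                    name = paste0("toy_", ligand))
    files <- list(receptor = pdb, ligand = mol2)
    if (clashAtom) {
      mv <- file.path(outDir, "moveable.txt")
      writeMoveableAtoms(mv, clashIdx)
      files$moveable <- mv
    }
  }
  list(system = sys, plantedCoords = atomCoords(sys), clashAtom = clashIdx,
       files = files)
}

#' DOF-space point of the planted pose
#'
#' The planted pose is the input geometry itself: ligand center at its
#' input position, identity rotation, zero torsions, moveable atoms at
#' their crystallographic positions.
#'
#' @param space a \linkS4class{SearchSpace} built for \code{system}.
#' @param system the \linkS4class{MolecularSystem}.
#' @return Numeric d-vector decodable by [decodeConformation()].
#' @export
plantedPoint <- function(space, system) {
  dm <- space@dims
  lig <- ligandIndices(system)
  pt <- numeric(nrow(dm))
  pt[1:3] <- colMeans(system@coords[lig, , drop = FALSE])
  pt[4:6] <- c(0, 0, 0)   # identity rotation (zero spin)
  ac <- which(dm$kind == "atom_coord")
  if (length(ac) > 0L) pt[ac] <- system@coords[cbind(dm$atom[ac],
                                                     dm$axis[ac])]
  pt
}
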