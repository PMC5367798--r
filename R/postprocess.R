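## Stage-II pipeline: energy-sorted dedup of the raw store (plain ligand
## RMSD), full box-constrained L-BFGS-B polishing in Cartesian coordinates,
## symmetry-aware dedup (chemical digests + Hungarian assignment, moveable
## atoms included), and the INON/EN docking-paradigm analysis.

#' Plain atom-ordered RMSD between two coordinate sets
#'
#' @param a,b matrices of identical dimension (n x 3).
#' @return RMSD in Angstrom, no symmetry accounting.
#' @export
naiveRmsd <- function(a, b) {
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

## Full-complex coordinates for a store record.
recordCoords <- function(rec, system) {
  cds <- system@coords
  cds[ligandIndices(system), ] <- rec$ligCoords
  mov <- moveableIndices(system)
  if (length(mov) > 0L) cds[mov, ] <- rec$movCoords
  cds
}

#' Energy-sorted dedup of the non-optimized minima (Sorter stage)
#'
#' Sorts the store's records ascending by raw energy (ties by discovery
#' order) and keeps a record iff its plain ligand RMSD — atom-to-atom,
#' no chemical symmetry, no moveable atoms — to every already-kept record
#' is at least \code{threshold}; among similar minima only the
#' lowest-energy one survives.
#'
#' @param store a \linkS4class{MinimaStore} or file path.
#' @param system the \linkS4class{MolecularSystem} of the run.
#' @param threshold similarity threshold in Angstrom (default 0.1).
#' @return List of \linkS4class{Conformation}s, ascending energy, with
#'   attribute \code{skipped} (corrupt records).
#' @export
sorterDedup <- function(store, system, threshold = 0.1) {
  dat <- readMinimaStore(store)
  recs <- dat$records
  if (length(recs) == 0L) {
    out <- list()
    attr(out, "skipped") <- attr(dat, "skipped")
    return(out)
  }
  energies <- vapply(recs, `[[`, numeric(1), "energy")
  ord <- order(energies)      # stable: ties keep discovery order
  keptLig <- list()
  kept <- list()
  for (i in ord) {
    lc <- recs[[i]]$ligCoords
    dup <- any(vapply(keptLig, function(k) naiveRmsd(k, lc) < threshold,
                      logical(1)))
    if (!dup) {
      keptLig[[length(keptLig) + 1L]] <- lc
      kept[[length(kept) + 1L]] <-
        Conformation(recs[[i]]$point, recordCoords(recs[[i]], system),
                     energy = recs[[i]]$energy)
    }
  }
  attr(kept, "skipped") <- attr(dat, "skipped")
  kept
}

#' Full local optimization of one minimum (OptmX stage)
#'
#' Limited-memory quasi-Newton (L-BFGS-B) minimization over the Cartesian
#' coordinates of all ligand atoms and all moveable receptor atoms — a
#' change of variables from the docking stage's DOF space. Moveable atoms
#' keep their small-cube box constraints; ligand atoms are unconstrained.
#' Converged when the projected-gradient max-norm drops to \code{gtol} or
#' the iteration cap is reached.
#'
#' @param conf a \linkS4class{Conformation} (or full coordinate matrix).
#' @param system the \linkS4class{MolecularSystem}.
#' @param model an \linkS4class{EnergyModel}; without an analytic gradient
#'   a finite-difference gradient is used with a warning.
#' @param atomCubeEdge small-cube edge for the moveable-atom boxes
#'   (Angstrom, default 1).
#' @param gtol gradient max-norm target (kcal/mol/Angstrom).
#' @param maxit iteration cap.
#' @return An optimized \linkS4class{Conformation}; its energy never
#'   exceeds the input energy. Attributes: \code{converged},
#'   \code{gradNorm}.
#' @export
optimizeFull <- function(conf, system, model, atomCubeEdge = 1,
                         gtol = 1e-4, maxit = 2000L) {
  if (!model@hasGradient)
    warning("energy model has no analytic gradient; using finite differences")
  coords0 <- if (is(conf, "Conformation")) atomCoords(conf) else as.matrix(conf)
  free <- c(ligandIndices(system), moveableIndices(system))
  mov <- moveableIndices(system)
  lower <- rep(-Inf, 3L * length(free))
  upper <- rep(Inf, 3L * length(free))
  if (length(mov) > 0L) {
    pos <- match(mov, free)
    for (k in seq_along(mov)) {
      sl <- (pos[k] - 1L) * 3L + 1:3
      lower[sl] <- system@coords[mov[k], ] - atomCubeEdge / 2
      upper[sl] <- system@coords[mov[k], ] + atomCubeEdge / 2
    }
  }
  assemble <- function(x) {
    cds <- coords0
    cds[free, ] <- matrix(x, ncol = 3L, byrow = TRUE)
    cds
  }
  fn <- function(x) modelEnergy(model, assemble(x))
  gr <- function(x) {
    g <- modelGradient(model, assemble(x))
    as.vector(t(g[free, , drop = FALSE]))
  }
  x0 <- as.vector(t(coords0[free, , drop = FALSE]))
  x0 <- pmin(pmax(x0, lower), upper)
  e0 <- fn(x0)
  best <- list(x = x0, e = e0)
  converged <- FALSE
  for (round in 1:5) {
    res <- tryCatch(
      stats::optim(best$x, fn, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = as.integer(maxit),
                                  factr = 10, pgtol = gtol / 10)),
      error = function(e) NULL)
    if (!is.null(res) && res$value <= best$e)
      best <- list(x = res$par, e = res$value)
    gn <- projGradNorm(gr(best$x), best$x, lower, upper)
    if (gn <= gtol) { converged <- TRUE; break }
    ## line-search stalls near rough Lennard-Jones walls: polish with the
    ## PORT trust-region quasi-Newton, which pushes the gradient further
    pol <- tryCatch(
      stats::nlminb(best$x, fn, gr, lower = lower, upper = upper,
                    control = list(iter.max = as.integer(maxit),
                                   rel.tol = 1e-14, abs.tol = 0)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$objective <= best$e)
      best <- list(x = pol$par, e = pol$objective)
    gn <- projGradNorm(gr(best$x), best$x, lower, upper)
    if (gn <= gtol) { converged <- TRUE; break }
    ## both solvers stalled: take a short backtracking descent step to
    ## move off the stalled iterate, then retry
    g <- gr(best$x)
    step <- 1e-3 / max(max(abs(g)), 1e-12)
    for (ls in 1:30) {
      cand <- pmin(pmax(best$x - step * g, lower), upper)
      eCand <- fn(cand)
      if (eCand < best$e) { best <- list(x = cand, e = eCand); break }
      step <- step / 2
    }
  }
  out <- Conformation(if (is(conf, "Conformation")) conf@point else numeric(0),
                      assemble(best$x), energy = best$e)
  attr(out, "converged") <- converged
  attr(out, "gradNorm") <- projGradNorm(gr(best$x), best$x, lower, upper)
  out
}

## Max-norm of the projected gradient under box constraints.
projGradNorm <- function(g, x, lower, upper) {
  atLo <- x <= lower + 1e-12 & g > 0
  atHi <- x >= upper - 1e-12 & g < 0
  g[atLo | atHi] <- 0
  max(abs(g), 0)
}

#' Chemical digest of a ligand atom
#'
#' Hash of the atom's typed bonded neighborhood: atoms within \code{depth}
#' bonds are ordered by (bond distance ascending, force-field type
#' ascending) — equally distant, equally typed atoms contribute identical
#' bytes, so their mutual order is immaterial — and the type sequence is
#' hashed with CRC32. Atoms related by a type-preserving graph automorphism
#' get equal digests, which is how symmetry-equivalent atoms are grouped.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param atomIndex global index of a ligand atom.
#' @param depth breadth-first search depth in bonds (default 13).
#' @return Numeric unsigned 32-bit digest.
#' @export
chemicalDigest <- function(system, atomIndex, depth = 13L) {
  if (!(atomIndex %in% ligandIndices(system)))
    stop("chemical digests are defined for ligand atoms")
  g <- ligandGraph(system)
  dist <- igraph::distances(g, v = atomIndex)[1L, ]
  sel <- which(is.finite(dist) & dist <= depth)
  ft <- system@atoms$ffType[sel]
  if (any(ft > 255L)) stop("force-field type exceeds one byte")
  ord <- order(dist[sel], ft)
  crc32(as.raw(ft[ord]))
}

#' Digest table for all ligand atoms
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param depth BFS depth (default 13).
#' @return Numeric vector of digests, one per ligand atom (ligand-local
#'   order).
#' @export
digestTable <- function(system, depth = 13L) {
  vapply(ligandIndices(system), function(a) chemicalDigest(system, a, depth),
         numeric(1))
}

#' Symmetry-corrected RMSD between two conformations
#'
#' Ligand atoms with equal chemical digests are grouped; within each group
#' the squared-distance matrix between the two conformations' positions is
#' assigned optimally by the Hungarian method, and costs are summed over
#' groups. With \code{includeMoveable = TRUE}, moveable receptor atoms are
#' appended as identity pairs (no permutation). Always at most the naive
#' ordered RMSD, and at least the true automorphism-constrained RMSD.
#'
#' @param confA,confB \linkS4class{Conformation}s (or full coordinate
#'   matrices) over the same system.
#' @param system the shared \linkS4class{MolecularSystem}.
#' @param includeMoveable include moveable receptor atoms as fixed pairs.
#' @param depth digest BFS depth.
#' @return RMSD in Angstrom.
#' @export
symmetryRmsd <- function(confA, confB, system, includeMoveable = FALSE,
                         depth = 13L) {
  ca <- if (is(confA, "Conformation")) atomCoords(confA) else as.matrix(confA)
  cb <- if (is(confB, "Conformation")) atomCoords(confB) else as.matrix(confB)
  lig <- ligandIndices(system)
  dg <- digestTable(system, depth)
  total <- 0
  count <- 0L
  for (grp in split(seq_along(lig), dg)) {
    ia <- lig[grp]
    pa <- ca[ia, , drop = FALSE]
    pb <- cb[ia, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
    d2 <- pmax(d2, 0)
    if (length(grp) == 1L) total <- total + d2[1L, 1L]
    else {
      asg <- clue::solve_LSAP(d2)
      total <- total + sum(d2[cbind(seq_along(grp), as.integer(asg))])
    }
    count <- count + length(grp)
  }
  if (includeMoveable) {
    mov <- moveableIndices(system)
    if (length(mov) > 0L) {
      total <- total + sum((ca[mov, , drop = FALSE] -
                            cb[mov, , drop = FALSE])^2)
      count <- count + length(mov)
    }
  }
  sqrt(total / count)
}

#' Symmetry-aware dedup of optimized minima (Unique stage)
#'
#' Greedy ascending-energy sweep with the keep-lowest rule of the Sorter
#' stage, but the metric is [symmetryRmsd()] with moveable receptor atoms
#' included, so symmetric ring flips and equivalent-atom swaps collapse.
#'
#' @param confs list of optimized \linkS4class{Conformation}s.
#' @param system the \linkS4class{MolecularSystem}.
#' @param threshold similarity threshold in Angstrom (default 0.1, matching
#'   the Sorter stage).
#' @return A \linkS4class{MinimaSpectrum} with 1-based contiguous indices.
#' @export
uniqueDedup <- function(confs, system, threshold = 0.1) {
  if (length(confs) == 0L)
    return(new("MinimaSpectrum", table = emptySpectrumTable(),
               conformations = list()))
  energies <- vapply(confs, energyOf, numeric(1))
  ord <- order(energies)
  kept <- list()
  for (i in ord) {
    dup <- any(vapply(kept, function(k)
      symmetryRmsd(k, confs[[i]], system, includeMoveable = TRUE) < threshold,
      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- confs[[i]]
  }
  tab <- data.frame(index = seq_along(kept),
                    energy_kcal_mol = vapply(kept, energyOf, numeric(1)),
                    rmsd_to_native_A = NA_real_,
                    center_distance_A = NA_real_)
  new("MinimaSpectrum", table = tab, conformations = kept)
}

emptySpectrumTable <- function() {
  data.frame(index = integer(0), energy_kcal_mol = numeric(0),
             rmsd_to_native_A = numeric(0), center_distance_A = numeric(0))
}

ligandCenter <- function(conf, system) {
  colMeans(atomCoords(conf)[ligandIndices(system), , drop = FALSE])
}

#' Annotate a spectrum with distances to the optimized native pose
#'
#' Fills the \code{rmsd_to_native_A} (ligand-only symmetry RMSD) and
#' \code{center_distance_A} (distance between ligand geometric centers)
#' columns.
#'
#' @param spectrum a \linkS4class{MinimaSpectrum}.
#' @param native the optimized native \linkS4class{Conformation}.
#' @param system the \linkS4class{MolecularSystem}.
#' @return The annotated spectrum.
#' @export
annotateSpectrum <- function(spectrum, native, system) {
  if (nTotal(spectrum) == 0L) return(spectrum)
  natCenter <- ligandCenter(native, system)
  spectrum@table$rmsd_to_native_A <-
    vapply(spectrum@conformations, function(cf)
      symmetryRmsd(cf, native, system, includeMoveable = FALSE), numeric(1))
  spectrum@table$center_distance_A <-
    vapply(spectrum@conformations, function(cf)
      sqrt(sum((ligandCenter(cf, system) - natCenter)^2)), numeric(1))
  spectrum
}

#' INON and EN docking-paradigm indices
#'
#' INON is the smallest spectrum index whose ligand pose lies within
#' \code{rmsdCut} (symmetry RMSD) of the optimized native pose, or Inf if
#' none does; INON = 1 means the docking paradigm is satisfied (the global
#' minimum is near the native pose). EN additionally requires the minimum's
#' energy within \code{energyWindow} of the optimized native energy.
#'
#' @param spectrum a \linkS4class{MinimaSpectrum} (annotated or not).
#' @param native optimized native \linkS4class{Conformation} with energy.
#' @param system the \linkS4class{MolecularSystem}.
#' @param rmsdCut acceptance radius in Angstrom (default 2).
#' @param energyWindow energy window in kcal/mol (default 1).
#' @return list with elements \code{inon} and \code{en} (positive integer
#'   or Inf) plus \code{paradigmSatisfied} (INON == 1).
#' @export
paradigmIndices <- function(spectrum, native, system, rmsdCut = 2,
                            energyWindow = 1) {
  if (nTotal(spectrum) == 0L)
    return(list(inon = Inf, en = Inf, paradigmSatisfied = FALSE))
  if (anyNA(spectrum@table$rmsd_to_native_A))
    spectrum <- annotateSpectrum(spectrum, native, system)
  tb <- spectrum@table
  near <- tb$rmsd_to_native_A < rmsdCut
  inWindow <- abs(tb$energy_kcal_mol - energyOf(native)) <= energyWindow
  inon <- if (any(near)) as.numeric(min(tb$index[near])) else Inf
  en <- if (any(near & inWindow))
    as.numeric(min(tb$index[near & inWindow])) else Inf
  list(inon = inon, en = en, paradigmSatisfied = identical(inon, 1L) ||
         (is.finite(inon) && inon == 1))
}

#' Write the results table (RMSD-PP stage)
#'
#' Tab-separated table with one row per minimum: index, energy, symmetry
#' RMSD to the optimized native pose, and the distance between ligand
#' geometric centers. Header comment lines carry the run provenance,
#' N_tot, INON and EN.
#'
#' @param spectrum an annotated \linkS4class{MinimaSpectrum}.
#' @param indices result of [paradigmIndices()].
#' @param path output file.
#' @param config optional named list echoed into the header.
#' @param seed optional seed echoed into the header.
#' @return \code{path} invisibly.
#' @export
writeReport <- function(spectrum, indices, path, config = list(),
                        seed = NA_integer_) {
  hdr <- c(sprintf("# ttdock minima report"),
           if (length(config) > 0L)
             sprintf("# config: %s",
                     paste(names(config), unlist(config), sep = "=",
                           collapse = " ")),
           sprintf("# seed: %s", seed),
           sprintf("# N_tot: %d", nTotal(spectrum)),
           sprintf("# INON: %s  EN: %s", format(indices$inon),
                   format(indices$en)))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    spectrumTable(spectrum), path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Full post-processing pipeline for a docking run
#'
#' Sorter dedup of the raw store, L-BFGS-B optimization of every unique
#' non-optimized minimum, symmetry-aware Unique dedup, annotation against
#' the optimized native pose and INON/EN computation.
#'
#' @param store a \linkS4class{MinimaStore} or path.
#' @param system the \linkS4class{MolecularSystem}.
#' @param model the \linkS4class{EnergyModel}.
#' @param nativeCoords full coordinates of the native (crystallographic)
#'   complex; default = the system's input coordinates.
#' @param sorterThreshold,uniqueThreshold dedup thresholds (Angstrom).
#' @param atomCubeEdge moveable-atom box edge for the optimizer.
#' @param rmsdCut,energyWindow INON/EN parameters.
#' @return list with \code{spectrum} (annotated), \code{indices},
#'   \code{native} (optimized native conformation).
#' @export
postprocessRun <- function(store, system, model,
                           nativeCoords = atomCoords(system),
                           sorterThreshold = 0.1, uniqueThreshold = 0.1,
                           atomCubeEdge = 1, rmsdCut = 2, energyWindow = 1) {
  unique0 <- sorterDedup(store, system, threshold = sorterThreshold)
  optimized <- lapply(unique0, optimizeFull, system = system, model = model,
                      atomCubeEdge = atomCubeEdge)
  spectrum <- uniqueDedup(optimized, system, threshold = uniqueThreshold)
  native <- optimizeFull(nativeCoords, system, model,
                         atomCubeEdge = atomCubeEdge)
  spectrum <- annotateSpectrum(spectrum, native, system)
  indices <- paradigmIndices(spectrum, native, system, rmsdCut = rmsdCut,
                             energyWindow = energyWindow)
  list(spectrum = spectrum, indices = indices, native = native)
}
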