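## Central S4 data containers. Validity methods enforce the structural
## invariants the algorithms rely on; all downstream code goes through the
## accessors defined here rather than touching slots.

#' Tensor-train decomposition of a d-dimensional array
#'
#' A chain of three-way cores \code{G_i} of shape
#' \code{(r_{i-1}, n_i, r_i)} representing the array element
#' \code{A[i_1, ..., i_d] = G_1[, i_1, ] \%*\% ... \%*\% G_d[, i_d, ]}.
#' Storage is linear in \code{d}, so fine grids in many dimensions remain
#' tractable.
#'
#' @slot cores list of \code{d} numeric 3-way arrays; core \code{i} has
#'   dimensions \code{c(r_{i-1}, n_i, r_i)} with \code{r_0 = r_d = 1}.
#' @seealso [ttElement()], [ttCrossInterpolate()]
#' @export
setClass("TensorTrain", representation(cores = "list"))

setValidity("TensorTrain", function(object) {
  cs <- object@cores
  if (length(cs) < 1L) return("a tensor train needs at least one core")
  for (i in seq_along(cs)) {
    ci <- cs[[i]]
    if (!is.array(ci) || length(dim(ci)) != 3L)
      return(sprintf("core %d is not a 3-way array", i))
    if (!all(is.finite(ci)))
      return(sprintf("core %d contains non-finite entries", i))
  }
  if (dim(cs[[1L]])[1L] != 1L || dim(cs[[length(cs)]])[3L] != 1L)
    return("boundary TT-ranks r_0 and r_d must equal 1")
  for (i in seq_len(length(cs) - 1L))
    if (dim(cs[[i]])[3L] != dim(cs[[i + 1L]])[1L])
      return(sprintf("rank mismatch between cores %d and %d", i, i + 1L))
  TRUE
})

#' Construct a TensorTrain from a list of cores
#'
#' @param cores list of 3-way arrays with chaining rank dimensions.
#' @return A validated \linkS4class{TensorTrain}.
#' @examples
#' tt <- TensorTrain(list(array(1, c(1, 4, 1)), array(1, c(1, 4, 1))))
#' ttElement(tt, c(2, 3))
#' @export
TensorTrain <- function(cores) new("TensorTrain", cores = cores)

#' @describeIn TensorTrain TT-ranks \code{r_0 ... r_d}.
#' @param x a \code{TensorTrain}.
#' @export
setMethod("ttRanks", "TensorTrain", function(x) {
  c(1L, vapply(x@cores, function(ci) dim(ci)[3L], integer(1)))
})

#' @describeIn TensorTrain mode sizes \code{n_1 ... n_d}.
#' @export
setMethod("modeSizes", "TensorTrain", function(x) {
  vapply(x@cores, function(ci) dim(ci)[2L], integer(1))
})

setMethod("show", "TensorTrain", function(object) {
  cat(sprintf("TensorTrain: d = %d, mode sizes [%s], TT-ranks [%s]\n",
              length(object@cores),
              paste(modeSizes(object), collapse = ", "),
              paste(ttRanks(object), collapse = ", ")))
})

#' Implicitly defined tensor (element oracle)
#'
#' Wraps a callable that maps a 1-based multi-index to a scalar. Elements are
#' never stored; every call is counted, which is how the evaluation-budget
#' guarantees of the cross-interpolation optimizer are audited.
#'
#' @slot evaluator function taking an integer multi-index (length d,
#'   1-based) and returning a finite scalar; must be deterministic.
#' @slot modeSizes integer vector \code{n_1 ... n_d}.
#' @slot state environment holding the mutable evaluation counter.
#' @export
setClass("ImplicitTensor",
         representation(evaluator = "function",
                        modeSizes = "integer",
                        state = "environment"))

setValidity("ImplicitTensor", function(object) {
  if (length(object@modeSizes) < 1L || any(object@modeSizes < 1L))
    return("modeSizes must be positive")
  TRUE
})

#' Construct an ImplicitTensor
#'
#' @param evaluator function(idx) -> scalar, idx a 1-based integer
#'   multi-index of length \code{length(modeSizes)}.
#' @param modeSizes integer vector of grid sizes per dimension.
#' @return An \linkS4class{ImplicitTensor} with its call counter at zero.
#' @examples
#' f <- ImplicitTensor(function(idx) prod(idx), c(4, 4, 4))
#' tensorElement(f, c(2, 2, 2))
#' evalCount(f)
#' @export
ImplicitTensor <- function(evaluator, modeSizes) {
  st <- new.env(parent = emptyenv())
  st$count <- 0L
  new("ImplicitTensor", evaluator = evaluator,
      modeSizes = as.integer(modeSizes), state = st)
}

#' @describeIn ImplicitTensor number of oracle calls made so far.
#' @param x an \code{ImplicitTensor}.
#' @export
setMethod("evalCount", "ImplicitTensor", function(x) x@state$count)

#' @describeIn ImplicitTensor mode sizes \code{n_1 ... n_d}.
#' @export
setMethod("modeSizes", "ImplicitTensor", function(x) x@modeSizes)

setMethod("show", "ImplicitTensor", function(object) {
  cat(sprintf("ImplicitTensor: d = %d, mode sizes [%s], %d evaluations\n",
              length(object@modeSizes),
              paste(object@modeSizes, collapse = ", "),
              evalCount(object)))
})

#' Evaluate one element of an implicit tensor (counted)
#'
#' @param f an \linkS4class{ImplicitTensor}.
#' @param idx integer multi-index, 1-based.
#' @return The scalar \code{f[idx]}; the call counter increments by exactly 1.
#' @export
tensorElement <- function(f, idx) {
  if (length(idx) != length(f@modeSizes) ||
      any(idx < 1L) || any(idx > f@modeSizes))
    stop("multi-index out of range for this tensor")
  f@state$count <- f@state$count + 1L
  v <- f@evaluator(as.integer(idx))
  if (!is.finite(v)) stop("evaluator returned a non-finite value at index [",
                          paste(idx, collapse = ","), "]")
  v
}

## Row-wise evaluation of a matrix of multi-indices; one counted call per row.
tensorElements <- function(f, idxmat) {
  apply(idxmat, 1L, function(row) tensorElement(f, row))
}

#' Interpolation-point state of the cross optimizer
#'
#' Carries, per unfolding, the current column (suffix) and row (prefix)
#' multi-index pools, plus the running list of the best points seen. The
#' magnitude-maximization loop threads this state through iterations so that
#' refined and injected points steer where the next cross pass samples.
#'
#' @slot rowPools list of d+1 integer matrices; element k+1 holds prefixes of
#'   length k (one per row).
#' @slot colPools list of d+1 integer matrices; element k+1 holds suffixes of
#'   length d-k (one per row).
#' @slot bestPoints list of \code{list(idx=, value=)} sorted by decreasing
#'   \code{|value|}.
#' @slot iteration integer, completed optimizer iterations.
#' @slot modeSizes integer vector of grid sizes.
#' @export
setClass("CrossState",
         representation(rowPools = "list", colPools = "list",
                        bestPoints = "list", iteration = "integer",
                        modeSizes = "integer"))

setValidity("CrossState", function(object) {
  d <- length(object@modeSizes)
  if (length(object@rowPools) != d + 1L || length(object@colPools) != d + 1L)
    return("pools must have d+1 entries (prefix lengths 0..d)")
  for (k in 0:d) {
    rp <- object@rowPools[[k + 1L]]
    cp <- object@colPools[[k + 1L]]
    if (ncol(rp) != k) return("prefix pool has wrong index length")
    if (ncol(cp) != d - k) return("suffix pool has wrong index length")
    if (k > 0L && nrow(rp) > 0L &&
        (any(rp < 1L) || any(rp > rep(object@modeSizes[1:k], each = nrow(rp)))))
      return("prefix pool index out of range")
    if (k < d && nrow(cp) > 0L &&
        (any(cp < 1L) ||
         any(cp > rep(object@modeSizes[(k + 1L):d], each = nrow(cp)))))
      return("suffix pool index out of range")
  }
  vals <- vapply(object@bestPoints, function(p) abs(p$value), numeric(1))
  if (length(vals) > 1L && any(diff(vals) > 0))
    return("bestPoints must be sorted by decreasing |value|")
  TRUE
})

setMethod("show", "CrossState", function(object) {
  cat(sprintf(
    "CrossState: d = %d, iteration %d, %d best points tracked\n",
    length(object@modeSizes), object@iteration, length(object@bestPoints)))
})

#' Molecular system: receptor + ligand atoms, bonds, typing
#'
#' Receptor and ligand share one global atom index space (receptor first,
#' then ligand). Bond indices are global. Ligand mobility is expressed by
#' search-space degrees of freedom, never by per-atom moveable flags, which
#' are reserved for receptor atoms confined to small cubes.
#'
#' @slot atoms data.frame with columns \code{element} (symbol),
#'   \code{charge} (e), \code{ffType} (positive integer force-field type),
#'   \code{isHydrogen} (logical), \code{owner} ("receptor"/"ligand"),
#'   \code{moveable} (logical, receptor only).
#' @slot coords numeric N x 3 matrix, input (crystallographic) coordinates
#'   in Angstrom.
#' @slot bonds data.frame with columns \code{i}, \code{j} (global atom
#'   indices), \code{order} (numeric; 1.5 = aromatic), \code{inRing}
#'   (logical).
#' @slot rotatableBonds integer vector of row indices into \code{bonds}
#'   (ligand bonds only), ascending.
#' @export
setClass("MolecularSystem",
         representation(atoms = "data.frame", coords = "matrix",
                        bonds = "data.frame", rotatableBonds = "integer"))

setValidity("MolecularSystem", function(object) {
  a <- object@atoms
  need <- c("element", "charge", "ffType", "isHydrogen", "owner", "moveable")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  n <- nrow(a)
  if (nrow(object@coords) != n || ncol(object@coords) != 3L)
    return("coords must be an N x 3 matrix matching the atom table")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (any(a$ffType < 1L)) return("ffType must be >= 1")
  if (!all(a$owner %in% c("receptor", "ligand")))
    return("owner must be 'receptor' or 'ligand'")
  if (any(a$moveable & a$owner == "ligand"))
    return("ligand atoms must not carry moveable flags")
  b <- object@bonds
  if (nrow(b) > 0L && (any(b$i < 1L) || any(b$j < 1L) ||
                       any(b$i > n) || any(b$j > n)))
    return("bond indices out of range")
  lig <- which(a$owner == "ligand")
  if (length(lig) > 1L) {
    lb <- b[b$i %in% lig & b$j %in% lig, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      cbind(match(lb$i, lig), match(lb$j, lig)), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(lig) - igraph::vcount(g)))
    if (igraph::components(g)$no != 1L)
      return("ligand bond graph must be connected")
  }
  TRUE
})

#' @describeIn MolecularSystem global indices of ligand atoms.
#' @param x a \code{MolecularSystem}.
#' @export
setMethod("ligandIndices", "MolecularSystem",
          function(x) which(x@atoms$owner == "ligand"))

#' @describeIn MolecularSystem global indices of receptor atoms.
#' @export
setMethod("receptorIndices", "MolecularSystem",
          function(x) which(x@atoms$owner == "receptor"))

#' @describeIn MolecularSystem global indices of moveable receptor atoms.
#' @export
setMethod("moveableIndices", "MolecularSystem",
          function(x) which(x@atoms$moveable))

#' @describeIn MolecularSystem input (crystallographic) coordinates.
#' @export
setMethod("atomCoords", "MolecularSystem", function(x, ...) x@coords)

setMethod("show", "MolecularSystem", function(object) {
  cat(sprintf(
    "MolecularSystem: %d receptor atoms (%d moveable), %d ligand atoms, %d bonds, %d rotatable\n",
    length(receptorIndices(object)), length(moveableIndices(object)),
    length(ligandIndices(object)), nrow(object@bonds),
    length(object@rotatableBonds)))
})

#' Energy-backend contract
#'
#' The docking engine depends only on this contract: a callable from full
#' Cartesian coordinates of the complex to a total energy in kcal/mol
#' (vacuum), optionally with an analytic gradient. Any backend satisfying
#' rigid-motion invariance (and, when it claims gradients, finite-difference
#' agreement) can be plugged in; the packaged reference force field is one
#' such backend.
#'
#' @slot energyFn function(coords N x 3) -> scalar kcal/mol.
#' @slot gradFn function(coords) -> N x 3 gradient, or NULL wrapped in list.
#' @slot hasGradient logical.
#' @slot label character, backend name for reports.
#' @export
setClass("EnergyModel",
         representation(energyFn = "function", gradFn = "list",
                        hasGradient = "logical", label = "character"))

#' Construct an EnergyModel
#'
#' @param energyFn function(coords) -> energy (kcal/mol).
#' @param gradFn optional function(coords) -> N x 3 analytic gradient
#'   (kcal/mol/Angstrom).
#' @param label backend name.
#' @return An \linkS4class{EnergyModel}.
#' @export
EnergyModel <- function(energyFn, gradFn = NULL, label = "custom") {
  new("EnergyModel", energyFn = energyFn,
      gradFn = if (is.null(gradFn)) list() else list(gradFn),
      hasGradient = !is.null(gradFn), label = label)
}

#' Evaluate an energy model
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @return Energy in kcal/mol.
#' @export
modelEnergy <- function(model, coords) model@energyFn(coords)

#' Evaluate an energy model gradient
#'
#' Analytic when the backend provides one, otherwise central finite
#' differences (step 1e-5 Angstrom).
#'
#' @param model an \linkS4class{EnergyModel}.
#' @param coords N x 3 coordinate matrix.
#' @return N x 3 gradient matrix (kcal/mol/Angstrom).
#' @export
modelGradient <- function(model, coords) {
  if (model@hasGradient) return(model@gradFn[[1L]](coords))
  numericalGradient(model@energyFn, coords)
}

numericalGradient <- function(fn, coords, h = 1e-5) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) for (k in 1:3) {
    cp <- coords; cp[i, k] <- cp[i, k] + h
    cm <- coords; cm[i, k] <- cm[i, k] - h
    g[i, k] <- (fn(cp) - fn(cm)) / (2 * h)
  }
  g
}

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf("EnergyModel '%s' (%s gradient)\n", object@label,
              if (object@hasGradient) "analytic" else "numerical"))
})

#' Search space: ordered degrees of freedom on a 2^m grid
#'
#' Dimensions are ordered: 3 ligand-center translations spanning the docking
#' cube, 3 rigid-rotation parameters, torsions in ascending bond index, then
#' moveable receptor atoms in ascending atom index times (x, y, z), each
#' confined to a small cube about its crystallographic position.
#'
#' @slot dims data.frame with columns \code{kind} (translation / rotation /
#'   torsion / atom_coord), \code{lower}, \code{upper} (Angstrom or radians;
#'   the second rotation parameter is the cosine of the axis polar angle),
#'   \code{n} (grid size, 2^m), \code{periodic} (logical), \code{atom}
#'   (global atom index for atom_coord dims, else NA), \code{axis} (1..3 for
#'   atom_coord dims, else NA), \code{bond} (bond row for torsion dims).
#' @slot cubeCenter numeric length-3, docking-cube center (Angstrom).
#' @slot cubeEdge docking-cube edge (Angstrom).
#' @slot atomCubeEdge small-cube edge for moveable atoms (Angstrom).
#' @slot m integer, grid bits (n = 2^m per dimension).
#' @export
setClass("SearchSpace",
         representation(dims = "data.frame", cubeCenter = "numeric",
                        cubeEdge = "numeric", atomCubeEdge = "numeric",
                        m = "integer"))

setValidity("SearchSpace", function(object) {
  d <- object@dims
  if (nrow(d) < 6L) return("a search space has at least the 6 rigid-body dims")
  if (!all(d$kind[1:6] == c(rep("translation", 3), rep("rotation", 3))))
    return("dims must start with 3 translations then 3 rotations")
  if (any(d$upper <= d$lower)) return("each dim needs upper > lower")
  if (any(d$n < 2L)) return("each dim needs at least 2 grid nodes")
  if (length(object@cubeCenter) != 3L) return("cubeCenter must have length 3")
  TRUE
})

#' @describeIn SearchSpace grid sizes per dimension.
#' @param x a \code{SearchSpace}.
#' @export
setMethod("modeSizes", "SearchSpace", function(x) as.integer(x@dims$n))

setMethod("show", "SearchSpace", function(object) {
  tab <- table(object@dims$kind)
  cat(sprintf(
    "SearchSpace: d = %d (%s); cube edge %.1f A at [%s], atom cube %.1f A, n = 2^%d per dim\n",
    nrow(object@dims),
    paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
    object@cubeEdge, paste(sprintf("%.2f", object@cubeCenter), collapse = ", "),
    object@atomCubeEdge, object@m))
})

#' One conformation of the complex
#'
#' @slot point numeric d-vector of continuous DOF values.
#' @slot coords full N x 3 Cartesian coordinates derived from \code{point}.
#' @slot energy kcal/mol, or NA when not evaluated.
#' @export
setClass("Conformation",
         representation(point = "numeric", coords = "matrix",
                        energy = "numeric"))

#' Construct a Conformation
#'
#' @param point numeric d-vector of DOF values (may be empty for
#'   conformations not derived from a search-space point).
#' @param coords full N x 3 Cartesian coordinates.
#' @param energy kcal/mol or NA.
#' @return A \linkS4class{Conformation}.
#' @export
Conformation <- function(point, coords, energy = NA_real_)
  new("Conformation", point = point, coords = coords, energy = energy)

#' @describeIn Conformation full Cartesian coordinates.
#' @param x a \code{Conformation}.
#' @export
setMethod("atomCoords", "Conformation", function(x, ...) x@coords)

#' @describeIn Conformation stored energy (kcal/mol).
#' @export
setMethod("energyOf", "Conformation", function(x) x@energy)

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation: d = %d, %d atoms, E = %s kcal/mol\n",
              length(object@point), nrow(object@coords),
              if (is.na(object@energy)) "NA" else sprintf("%.4f", object@energy)))
})

#' Energy-sorted spectrum of unique local minima
#'
#' @slot table data.frame with columns \code{index} (1-based, the lowest
#'   energy minimum has index 1), \code{energy_kcal_mol},
#'   \code{rmsd_to_native_A}, \code{center_distance_A}.
#' @slot conformations list of \linkS4class{Conformation}, parallel to rows.
#' @export
setClass("MinimaSpectrum",
         representation(table = "data.frame", conformations = "list"))

setValidity("MinimaSpectrum", function(object) {
  tb <- object@table
  if (nrow(tb) != length(object@conformations))
    return("table and conformation list lengths differ")
  if (nrow(tb) > 0L) {
    if (!identical(tb$index, seq_len(nrow(tb))))
      return("indices must be contiguous from 1")
    if (any(diff(tb$energy_kcal_mol) < 0))
      return("entries must be sorted ascending by energy")
  }
  TRUE
})

#' @describeIn MinimaSpectrum number of unique minima (N_tot).
#' @param x a \code{MinimaSpectrum}.
#' @export
setMethod("nTotal", "MinimaSpectrum", function(x) nrow(x@table))

#' @describeIn MinimaSpectrum the results table.
#' @export
setMethod("spectrumTable", "MinimaSpectrum", function(x) x@table)

setMethod("show", "MinimaSpectrum", function(object) {
  n <- nTotal(object)
  cat(sprintf("MinimaSpectrum: N_tot = %d\n", n))
  if (n > 0L) {
    cat(sprintf("  lowest energy %.4f kcal/mol; showing up to 5 entries:\n",
                object@table$energy_kcal_mol[1L]))
    print(utils::head(object@table, 5L), row.names = FALSE)
  }
})
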