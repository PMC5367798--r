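#' @import methods
NULL

#' TT-ranks of a tensor-train object
#'
#' @param x a \linkS4class{TensorTrain}.
#' @return Integer vector \code{r_0, ..., r_d} (with \code{r_0 = r_d = 1}).
#' @export
setGeneric("ttRanks", function(x) standardGeneric("ttRanks"))

#' Mode sizes of a tensor-like object
#'
#' @param x a \linkS4class{TensorTrain} or \linkS4class{ImplicitTensor}.
#' @return Integer vector \code{n_1, ..., n_d}.
#' @export
setGeneric("modeSizes", function(x) standardGeneric("modeSizes"))

#' Number of evaluator calls made so far
#'
#' @param x an \linkS4class{ImplicitTensor}.
#' @return Nonnegative integer count of oracle evaluations.
#' @export
setGeneric("evalCount", function(x) standardGeneric("evalCount"))

#' Cartesian coordinates of an object
#'
#' @param x a \linkS4class{MolecularSystem} or \linkS4class{Conformation}.
#' @param ... further arguments for methods.
#' @return Numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
setGeneric("atomCoords", function(x, ...) standardGeneric("atomCoords"))

#' Potential energy stored on an object
#'
#' @param x a \linkS4class{Conformation}.
#' @return Energy in kcal/mol, or \code{NA} if not yet evaluated.
#' @export
setGeneric("energyOf", function(x) standardGeneric("energyOf"))

#' Indices of ligand atoms within a molecular system
#'
#' @param x a \linkS4class{MolecularSystem}.
#' @return Integer vector of global atom indices.
#' @export
setGeneric("ligandIndices", function(x) standardGeneric("ligandIndices"))

#' Indices of receptor atoms within a molecular system
#'
#' @param x a \linkS4class{MolecularSystem}.
#' @return Integer vector of global atom indices.
#' @export
setGeneric("receptorIndices", function(x) standardGeneric("receptorIndices"))

#' Indices of moveable receptor atoms
#'
#' @param x a \linkS4class{MolecularSystem}.
#' @return Integer vector of global atom indices flagged moveable.
#' @export
setGeneric("moveableIndices", function(x) standardGeneric("moveableIndices"))

#' Number of unique minima in a spectrum
#'
#' @param x a \linkS4class{MinimaSpectrum}.
#' @return Integer \code{N_tot}.
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' Results table of a minima spectrum
#'
#' @param x a \linkS4class{MinimaSpectrum}.
#' @return \code{data.frame} with one row per minimum, sorted ascending by
#'   energy, columns \code{index}, \code{energy_kcal_mol},
#'   \code{rmsd_to_native_A}, \code{center_distance_A}.
#' @export
setGeneric("spectrumTable", function(x) standardGeneric("spectrumTable"))
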