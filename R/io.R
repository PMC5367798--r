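## Structure I/O through bio3d: PDB for the receptor, TRIPOS MOL2 for the
## ligand and exported minima. The moveable-atom list is a plain text
## sidecar (one 1-based receptor atom index per line, '#' comments).

mol2Element <- function(elety) sub("\\..*$", "", elety)

mol2BondOrder <- function(type) {
  ifelse(type == "ar", 1.5, ifelse(type == "am", 1,
         suppressWarnings(as.numeric(type))))
}

#' Read a ligand from a TRIPOS MOL2 file
#'
#' @param path MOL2 file with \code{@<TRIPOS>MOLECULE}, \code{ATOM} and
#'   \code{BOND} blocks; partial charges from the charge column.
#' @return list with \code{elements}, \code{coords} (n x 3), \code{charges},
#'   \code{bonds} (data.frame i, j, order with ligand-local indices) and
#'   \code{name}.
#' @export
readLigandMol2 <- function(path) {
  m <- bio3d::read.mol2(path)
  list(elements = mol2Element(m$atom$elety),
       coords = cbind(m$atom$x, m$atom$y, m$atom$z),
       charges = if (all(is.na(m$atom$charge))) numeric(nrow(m$atom))
                 else m$atom$charge,
       bonds = data.frame(i = as.integer(m$bond$origin),
                          j = as.integer(m$bond$target),
                          order = mol2BondOrder(m$bond$type)),
       name = m$name)
}

#' Write a ligand (or a docked ligand pose) to MOL2
#'
#' @param path output file.
#' @param elements,coords,charges,bonds as returned by [readLigandMol2()].
#' @param name molecule name.
#' @return \code{path} invisibly.
#' @export
writeLigandMol2 <- function(path, elements, coords, charges = NULL,
                            bonds = NULL, name = "ligand") {
  n <- length(elements)
  if (is.null(charges)) charges <- numeric(n)
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                          order = numeric(0))
  sybyl <- ifelse(elements == "C", "C.3",
           ifelse(elements == "N", "N.3",
           ifelse(elements == "O", "O.3", elements)))
  orderStr <- ifelse(bonds$order == 1.5, "ar",
                     format(as.integer(round(bonds$order))))
  lines <- c("@<TRIPOS>MOLECULE", name,
             sprintf("%d %d 0 0 0", n, nrow(bonds)),
             "SMALL", "USER_CHARGES", "",
             "@<TRIPOS>ATOM",
             sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %3d LIG %9.4f",
                     seq_len(n), paste0(elements, seq_len(n)),
                     coords[, 1L], coords[, 2L], coords[, 3L],
                     sybyl, 1L, charges),
             "@<TRIPOS>BOND",
             if (nrow(bonds) > 0L)
               sprintf("%6d %5d %5d %s", seq_len(nrow(bonds)),
                       bonds$i, bonds$j, orderStr))
  writeLines(lines, path)
  invisible(path)
}

#' Read a receptor from PDB
#'
#' Reads ATOM/HETATM records (first alternate location only). Standard PDB
#' carries no partial charges; \code{chargesFromB = TRUE} reads them from
#' the B-factor column, the convention used by the packaged toy-complex
#' writer.
#'
#' @param path PDB file with hydrogens present.
#' @param chargesFromB interpret the B-factor column as partial charges.
#' @return list with \code{elements}, \code{coords}, \code{charges}.
#' @export
readReceptorPdb <- function(path, chargesFromB = FALSE) {
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  if ("alt" %in% names(at) && any(!is.na(at$alt)))
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- substr(trimws(at$elety), 1L, 1L)
  list(elements = trimws(el),
       coords = cbind(at$x, at$y, at$z),
       charges = if (chargesFromB) at$b else numeric(nrow(at)))
}

#' Write a receptor to PDB
#'
#' @param path output file.
#' @param elements,coords element symbols and n x 3 coordinates.
#' @param charges optional partial charges, stored in the B-factor column.
#' @return \code{path} invisibly.
#' @export
writeReceptorPdb <- function(path, elements, coords, charges = NULL) {
  n <- length(elements)
  if (is.null(charges)) charges <- numeric(n)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords)),
                   type = rep("ATOM", n),
                   resno = seq_len(n), resid = rep("REC", n),
                   eleno = seq_len(n),
                   elety = paste0(elements, seq_len(n)),
                   chain = rep("A", n),
                   o = rep(1, n), b = charges,
                   elesy = elements)
  invisible(path)
}

#' Read a moveable-atom list file
#'
#' @param path text file, one 1-based receptor atom index per line;
#'   \code{#} starts a comment.
#' @return Sorted integer vector.
#' @export
readMoveableAtoms <- function(path) {
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines)
  sort(as.integer(lines[nzchar(lines)]))
}

#' Write a moveable-atom list file
#'
#' @param path output file.
#' @param indices 1-based receptor atom indices.
#' @return \code{path} invisibly.
#' @export
writeMoveableAtoms <- function(path, indices) {
  writeLines(c("# moveable receptor atoms (1-based indices)",
               format(sort(as.integer(indices)))), path)
  invisible(path)
}

#' Assemble a molecular system from structure files
#'
#' @param pdbPath receptor PDB (hydrogens present).
#' @param mol2Path ligand MOL2 with bond table.
#' @param moveable moveable receptor atoms: an integer vector, a path to a
#'   list file, or NULL.
#' @param chargesFromB read receptor charges from the B-factor column.
#' @return A \linkS4class{MolecularSystem}.
#' @export
systemFromFiles <- function(pdbPath, mol2Path, moveable = NULL,
                            chargesFromB = FALSE) {
  rec <- readReceptorPdb(pdbPath, chargesFromB = chargesFromB)
  lig <- readLigandMol2(mol2Path)
  mv <- if (is.null(moveable)) integer(0)
        else if (is.character(moveable)) readMoveableAtoms(moveable)
        else as.integer(moveable)
  makeMolecularSystem(rec$elements, rec$coords, lig$elements, lig$coords,
                      ligandBonds = lig$bonds,
                      receptorCharges = rec$charges,
                      ligandCharges = lig$charges,
                      moveable = mv)
}

#' Export a spectrum's unique minima to molecular files
#'
#' Writes one ligand MOL2 per minimum (\code{minimum_<index>.mol2}) and,
#' when the system has moveable atoms, one receptor PDB with the moveable
#' coordinates substituted (\code{minimum_<index>_receptor.pdb}).
#'
#' @param spectrum a \linkS4class{MinimaSpectrum}.
#' @param system the underlying \linkS4class{MolecularSystem}.
#' @param outDir output directory (created if needed).
#' @return Character vector of written ligand files, invisibly.
#' @export
exportSpectrum <- function(spectrum, system, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lig <- ligandIndices(system)
  nr <- length(receptorIndices(system))
  b <- system@bonds[ligandBondRows(system), , drop = FALSE]
  ligBonds <- data.frame(i = b$i - nr, j = b$j - nr, order = b$order)
  files <- character(0)
  for (r in seq_len(nTotal(spectrum))) {
    cds <- atomCoords(spectrum@conformations[[r]])
    f <- file.path(outDir, sprintf("minimum_%04d.mol2", r))
    writeLigandMol2(f, system@atoms$element[lig], cds[lig, , drop = FALSE],
                    charges = system@atoms$charge[lig], bonds = ligBonds,
                    name = sprintf("minimum_%d", r))
    files <- c(files, f)
    if (length(moveableIndices(system)) > 0L)
      writeReceptorPdb(file.path(outDir,
                                 sprintf("minimum_%04d_receptor.pdb", r)),
                       system@atoms$element[seq_len(nr)],
                       cds[seq_len(nr), , drop = FALSE],
                       charges = system@atoms$charge[seq_len(nr)])
  }
  invisible(files)
}
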