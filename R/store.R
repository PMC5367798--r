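## Binary minima store (.ttm): little-endian, append-only file of refined
## candidate minima. Layout:
##   magic "TTM1" (4 bytes) | int32 version | int32 seed | int32 d |
##   int32 nLig | int32 nMov | int32 configHash | int32 sysChecksum
## then records:
##   int32 tag | doubles: point (d), ligand coords (3*nLig, row-major),
##   moveable coords (3*nMov), energy | int32 CRC32 of the payload bytes.
## Unsigned 32-bit checksums are stored two's-complement in the int32.

STORE_MAGIC <- charToRaw("TTM1")
STORE_VERSION <- 1L

asSigned32 <- function(u) as.integer(ifelse(u > 2^31 - 1, u - 2^32, u))
asUnsigned32 <- function(s) ifelse(s < 0, s + 2^32, s)

#' Handle to a binary store of non-optimized minima
#'
#' @slot path file path of the \code{.ttm} store.
#' @slot header list: version, seed, d, nLig, nMov, configHash, sysChecksum.
#' @export
setClass("MinimaStore", representation(path = "character", header = "list"))

#' Open an existing minima store
#'
#' @param path a \code{.ttm} file written by [dock()].
#' @return A \linkS4class{MinimaStore}.
#' @export
MinimaStore <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readStoreHeader(con)
  new("MinimaStore", path = path, header = hdr)
}

setMethod("show", "MinimaStore", function(object) {
  h <- object@header
  cat(sprintf(
    "MinimaStore '%s': d = %d, %d ligand / %d moveable atoms, seed %d\n",
    basename(object@path), h$d, h$nLig, h$nMov, h$seed))
})

createMinimaStore <- function(path, d, nLig, nMov, seed, configHash,
                              sysChecksum) {
  con <- file(path, "wb")
  writeBin(STORE_MAGIC, con)
  writeBin(c(STORE_VERSION, as.integer(seed), as.integer(d),
             as.integer(nLig), as.integer(nMov),
             asSigned32(configHash), asSigned32(sysChecksum)),
           con, size = 4L, endian = "little")
  h <- new.env(parent = emptyenv())
  h$con <- con; h$closed <- FALSE
  h$d <- d; h$nLig <- nLig; h$nMov <- nMov
  h
}

recordPayload <- function(handle, point, ligCoords, movCoords, energy) {
  vals <- c(point, as.vector(t(ligCoords)),
            if (handle$nMov > 0L) as.vector(t(movCoords)), energy)
  writeBin(vals, raw(), size = 8L, endian = "little")
}

appendMinimaRecord <- function(handle, point, ligCoords, movCoords,
                               energy, tag) {
  payload <- recordPayload(handle, point, ligCoords, movCoords, energy)
  writeBin(as.integer(tag), handle$con, size = 4L, endian = "little")
  writeBin(payload, handle$con)
  writeBin(asSigned32(crc32(payload)), handle$con, size = 4L,
           endian = "little")
  invisible(NULL)
}

closeStoreHandle <- function(handle) {
  close(handle$con)
  handle$closed <- TRUE
  invisible(NULL)
}

readStoreHeader <- function(con) {
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, STORE_MAGIC)) stop("not a TTM minima store")
  ints <- readBin(con, "integer", n = 7L, size = 4L, endian = "little")
  list(version = ints[1L], seed = ints[2L], d = ints[3L], nLig = ints[4L],
       nMov = ints[5L], configHash = asUnsigned32(ints[6L]),
       sysChecksum = asUnsigned32(ints[7L]))
}

#' Read all records of a minima store
#'
#' Each record's CRC is verified; corrupt records are skipped with a
#' warning and counted in attribute \code{skipped}.
#'
#' @param store a \linkS4class{MinimaStore} or a file path.
#' @return list with \code{header} and \code{records}, the latter a list of
#'   \code{list(tag, point, ligCoords, movCoords, energy)} in file order.
#' @export
readMinimaStore <- function(store) {
  path <- if (is(store, "MinimaStore")) store@path else store
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readStoreHeader(con)
  nvals <- hdr$d + 3L * hdr$nLig + 3L * hdr$nMov + 1L
  records <- list()
  skipped <- 0L
  repeat {
    tag <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(tag) == 0L) break
    payload <- readBin(con, "raw", n = 8L * nvals)
    crcStored <- readBin(con, "integer", n = 1L, size = 4L,
                         endian = "little")
    if (length(payload) < 8L * nvals || length(crcStored) == 0L) {
      skipped <- skipped + 1L
      warning("truncated record at end of store; skipped")
      break
    }
    if (asUnsigned32(crcStored) != crc32(payload)) {
      skipped <- skipped + 1L
      warning("CRC mismatch in store record; skipped")
      next
    }
    vals <- readBin(payload, "double", n = nvals, size = 8L,
                    endian = "little")
    point <- vals[seq_len(hdr$d)]
    off <- hdr$d
    ligCoords <- matrix(vals[off + seq_len(3L * hdr$nLig)],
                        ncol = 3L, byrow = TRUE)
    off <- off + 3L * hdr$nLig
    movCoords <- if (hdr$nMov > 0L)
      matrix(vals[off + seq_len(3L * hdr$nMov)], ncol = 3L, byrow = TRUE)
    else matrix(numeric(0), 0L, 3L)
    records[[length(records) + 1L]] <-
      list(tag = tag, point = point, ligCoords = ligCoords,
           movCoords = movCoords, energy = vals[nvals])
  }
  out <- list(header = hdr, records = records)
  attr(out, "skipped") <- skipped
  out
}
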