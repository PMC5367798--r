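#' CRC32 checksum of a byte sequence
#'
#' Standard reflected-polynomial CRC32 (0xEDB88320, init 0xFFFFFFFF, final
#' xor — the zlib convention), computed on raw bytes. Returned as a double
#' because R integers cannot hold unsigned 32-bit values.
#'
#' @param bytes raw vector (or integer vector of byte values 0..255).
#' @return Numeric scalar in \code{[0, 2^32 - 1]}.
#' @examples
#' crc32(charToRaw("123456789")) == 0xCBF43926
#' @export
crc32 <- function(bytes) {
  if (is.numeric(bytes)) {
    if (any(bytes < 0 | bytes > 255 | bytes != floor(bytes)))
      stop("byte values must be integers in 0..255")
    bytes <- as.raw(bytes)
  }
  hex <- digest::digest(bytes, algo = "crc32", serialize = FALSE)
  hexToNum(hex)
}

## Hex string -> nonnegative double (handles values above .Machine$integer.max)
hexToNum <- function(hex) {
  digits <- strtoi(strsplit(tolower(hex), "")[[1L]], base = 16L)
  sum(digits * 16^(rev(seq_along(digits)) - 1))
}
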