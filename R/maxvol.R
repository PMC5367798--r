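#' Dominant (maximal-volume) square submatrix of a tall matrix
#'
#' Greedy row-swap search for an r x r submatrix of a full-column-rank
#' n x r matrix whose determinant is maximal in modulus. On return every
#' entry of \code{a \%*\% solve(a[idx, ])} has magnitude at most
#' \code{1 + tol} (the dominance property), which bounds the selected
#' submatrix's volume within \code{(1 + tol)^r} of the true maximum.
#' Dominant submatrices are the pivoting engine of cross interpolation:
#' rows holding large-volume crosses carry large-magnitude entries.
#'
#' @param a numeric matrix, n x r with n >= r and full column rank.
#' @param tol dominance tolerance; swaps stop once no entry of the
#'   interpolation matrix exceeds \code{1 + tol} in modulus.
#' @param maxSweeps cap on row swaps before giving up.
#' @return Integer vector of r row indices. Attribute \code{converged}
#'   reports whether the dominance bound was certified; if not, the best
#'   selection found is returned with a warning.
#' @examples
#' a <- rbind(diag(2), matrix(0, 4, 2))
#' maxvol(a)  # rows 1 and 2
#' @export
maxvol <- function(a, tol = 1e-2, maxSweeps = 100L) {
  a <- as.matrix(a)
  n <- nrow(a); r <- ncol(a)
  if (n < r) stop("maxvol needs a tall matrix (nrow >= ncol)")
  if (qr(a)$rank < r)
    stop("maxvol: matrix is rank-deficient, no nonsingular submatrix exists")
  idx <- luPivotRows(a)
  sweep <- 0L
  converged <- FALSE
  while (sweep < maxSweeps) {
    sweep <- sweep + 1L
    c <- a %*% solve(a[idx, , drop = FALSE])
    pos <- which.max(abs(c))
    i <- (pos - 1L) %% n + 1L
    j <- (pos - 1L) %/% n + 1L
    if (abs(c[i, j]) <= 1 + tol) { converged <- TRUE; break }
    idx[j] <- i
  }
  if (!converged)
    warning("maxvol did not certify dominance within ", maxSweeps,
            " swaps; returning best selection found")
  idx <- as.integer(idx)
  attr(idx, "converged") <- converged
  idx
}

## Row pivots of a partial-pivot LU factorization: a nonsingular starting
## submatrix for the swap loop.
luPivotRows <- function(a) {
  n <- nrow(a); r <- ncol(a)
  work <- a
  avail <- seq_len(n)
  picked <- integer(r)
  for (k in seq_len(r)) {
    p <- which.max(abs(work[avail, k]))
    row <- avail[p]
    picked[k] <- row
    avail <- avail[-p]
    piv <- work[row, k]
    if (abs(piv) < .Machine$double.eps)
      stop("maxvol: pivot breakdown (rank-deficient matrix)")
    if (length(avail) > 0L && k < r) {
      fac <- work[avail, k] / piv
      work[avail, ] <- work[avail, , drop = FALSE] -
        outer(fac, work[row, ])
    }
  }
  picked
}
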