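## Tensor-train cross interpolation and the magnitude-maximization loop.
##
## The optimizer treats the objective as a d-dimensional tensor given only
## through an element oracle, builds a low-rank TT interpolant from crossed
## index sets chosen by maxvol pivoting, and exploits the fact that
## large-volume crosses concentrate on large-magnitude entries. One sweep
## evaluates a mode-uniform budget of n*r^2 entries per dimension: interior
## modes as r x r crosses expanded along the mode, boundary modes as
## oversampled panels (more columns or a larger prefix pool), so a sweep
## costs exactly d*n*r^2 oracle calls and the oversampling sharpens the
## boundary subspace estimates.

#' Evaluate one element of a tensor train
#'
#' Collapses the chained core products
#' \code{G_1[, i_1, ] \%*\% ... \%*\% G_d[, i_d, ]} to a scalar.
#'
#' @param tt a \linkS4class{TensorTrain}.
#' @param idx integer multi-index (1-based), one entry per mode.
#' @return The scalar tensor element.
#' @examples
#' tt <- TensorTrain(list(array(c(1, 2), c(1, 2, 1)),
#'                        array(c(3, 4), c(1, 2, 1))))
#' ttElement(tt, c(2, 2))  # 2 * 4 = 8
#' @export
ttElement <- function(tt, idx) {
  ms <- modeSizes(tt)
  if (length(idx) != length(ms) || any(idx < 1L) || any(idx > ms))
    stop("multi-index out of range for this tensor train")
  v <- matrix(1, 1L, 1L)
  for (k in seq_along(idx)) {
    ck <- tt@cores[[k]]
    v <- v %*% matrix(ck[, idx[k], ], nrow = dim(ck)[1L])
  }
  drop(v)
}

#' Densify a tensor train (small tensors only)
#'
#' Materializes every element; intended for oracle checks at toy sizes.
#'
#' @param tt a \linkS4class{TensorTrain}.
#' @param maxElements refuse beyond this many entries.
#' @return Numeric array with dimensions \code{modeSizes(tt)}.
#' @export
ttDense <- function(tt, maxElements = 3e6) {
  ms <- modeSizes(tt)
  if (prod(as.numeric(ms)) > maxElements)
    stop("tensor too large to densify (", prod(as.numeric(ms)), " elements)")
  ck <- tt@cores[[1L]]
  m <- matrix(aperm(ck, c(2L, 1L, 3L)), nrow = ms[1L])  # n1 x r1 (r0 = 1)
  for (k in seq_along(ms)[-1L]) {
    ck <- tt@cores[[k]]
    rkm1 <- dim(ck)[1L]; rk <- dim(ck)[3L]
    m <- m %*% matrix(ck, nrow = rkm1)        # (prod n) x (n_k * r_k)
    m <- matrix(aperm(array(m, c(nrow(m), ms[k], rk)), c(1L, 2L, 3L)),
                nrow = nrow(m) * ms[k])
  }
  array(m, dim = ms)
}

#' Fresh interpolation-point state with randomly seeded pools
#'
#' @param modeSizes integer grid sizes per dimension.
#' @param rmax maximal TT-rank.
#' @param poolCap pool size per unfolding (default \code{2 * rmax}).
#' @return A \linkS4class{CrossState}.
#' @export
newCrossState <- function(modeSizes, rmax, poolCap = 2L * rmax) {
  ms <- as.integer(modeSizes)
  d <- length(ms)
  rowPools <- colPools <- vector("list", d + 1L)
  for (k in 0:d) {
    rowPools[[k + 1L]] <- randomIndexMatrix(poolCap, ms[seq_len(k)])
    colPools[[k + 1L]] <- randomIndexMatrix(poolCap, ms[seq_len(d - k) + k])
  }
  new("CrossState", rowPools = rowPools, colPools = colPools,
      bestPoints = list(), iteration = 0L, modeSizes = ms)
}

randomIndexMatrix <- function(nrows, sizes) {
  if (length(sizes) == 0L)
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  total <- prod(as.numeric(sizes))
  nrows <- as.integer(min(nrows, total))
  m <- vapply(sizes, function(n) sample.int(n, nrows, replace = TRUE),
              integer(nrows))
  if (nrows == 1L) m <- matrix(m, nrow = 1L)
  uniqueRows(m)
}

uniqueRows <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m[!duplicated(apply(m, 1L, paste, collapse = ",")), , drop = FALSE]
}

## Draw `target` distinct index rows: about half from the head of `pool`
## (exploitation of injected and previously selected points), the rest
## random (exploration, so the crosses never collapse onto one basin).
takeIndexRows <- function(pool, target, sizes) {
  pool <- uniqueRows(pool)
  total <- if (length(sizes) == 0L) 1 else prod(as.numeric(sizes))
  target <- as.integer(min(target, total))
  nHead <- min(nrow(pool), ceiling(target / 2))
  picked <- pool[seq_len(nHead), , drop = FALSE]
  for (tries in 1:50) {
    if (nrow(picked) >= target) break
    extra <- randomIndexMatrix(target - nrow(picked), sizes)
    picked <- uniqueRows(rbind(picked, extra))
  }
  if (nrow(picked) < target && nrow(pool) > nHead) {
    more <- pool[setdiff(seq_len(nrow(pool)),
                         seq_len(nHead)), , drop = FALSE]
    picked <- uniqueRows(rbind(picked, more))
  }
  picked[seq_len(min(target, nrow(picked))), , drop = FALSE]
}

## Append panel evaluations to the log environment.
logPanel <- function(logEnv, idxmat, values) {
  t <- logEnv$nseg + 1L
  logEnv$idx[[t]] <- idxmat
  logEnv$val[[t]] <- values
  logEnv$nseg <- t
}

newLogEnv <- function() {
  e <- new.env(parent = emptyenv())
  e$idx <- list(); e$val <- list(); e$nseg <- 0L
  e
}

collectLog <- function(logEnv, from = 1L) {
  if (logEnv$nseg < from)
    return(list(indices = NULL, values = numeric(0)))
  segs <- from:logEnv$nseg
  list(indices = do.call(rbind, logEnv$idx[segs]),
       values = unlist(logEnv$val[segs], use.names = FALSE))
}

## One left-to-right sweep. Uses the suffix (column) pools in `state`,
## returns cores plus fresh prefix (row) pools and the maxvol interpolation
## points (selected row x best column per mode: the step-3 harvest).
## `r` is the target rank.
crossSweepLR <- function(f, state, r, logEnv) {
  ms <- modeSizes(f)
  d <- length(ms)
  cores <- vector("list", d)
  rowPools <- vector("list", d + 1L)
  rowPools[[1L]] <- matrix(integer(0), 1L, 0L)
  harvest <- list()                         # maxvol points per mode
  prefixSel <- matrix(integer(0), 1L, 0L)   # nested I_{k-1}, r_{k-1} rows
  prefixPool <- prefixSel                   # oversampled pool for mode d
  for (k in seq_len(d)) {
    n <- ms[k]
    usePool <- k == d && nrow(prefixPool) > nrow(prefixSel)
    pref <- if (usePool) prefixPool else prefixSel
    np <- nrow(pref)
    nCols <- if (k == d) 1L else max(1L, ceiling(r^2 / nrow(prefixSel)))
    sufs <- takeIndexRows(state@colPools[[k + 1L]], nCols,
                          ms[seq_len(d - k) + k])
    nc <- nrow(sufs)
    ## rows of the panel: (prefix p, i_k), prefix-major, i fastest
    rowPref <- pref[rep(seq_len(np), each = n), , drop = FALSE]
    rowI <- rep(seq_len(n), times = np)
    panel <- matrix(0, np * n, nc)
    for (jc in seq_len(nc)) {
      idxmat <- cbind(rowPref, rowI,
                      sufs[rep(jc, np * n), , drop = FALSE])
      vals <- tensorElements(f, idxmat)
      logPanel(logEnv, idxmat, vals)
      panel[, jc] <- vals
    }
    if (k == d) {
      ## final core: rows of the panel belonging to the nested prefix set
      keep <- rowPrefixPositions(pref, prefixSel, n)
      cores[[k]] <- array(t(matrix(panel[keep, 1L], nrow = n)),
                          dim = c(nrow(prefixSel), n, 1L))
      ## full-length index pool: the largest-magnitude rows of this panel
      ord <- order(abs(panel[, 1L]), decreasing = TRUE)
      ord <- ord[seq_len(min(length(ord), r^2))]
      rowPools[[k + 1L]] <- cbind(rowPref, rowI)[ord, , drop = FALSE]
      sel <- ord[seq_len(min(length(ord), r))]
      harvest[[k]] <- list(idx = cbind(rowPref, rowI)[sel, , drop = FALSE],
                           value = panel[sel, 1L])
      break
    }
    sv <- svd(panel)
    tolr <- max(dim(panel)) * .Machine$double.eps * max(sv$d[1L], 1e-300)
    rk <- max(1L, min(r, sum(sv$d > tolr)))
    basis <- sv$u[, seq_len(rk), drop = FALSE]
    sel <- maxvol(basis)
    core <- basis %*% solve(basis[sel, , drop = FALSE])
    cores[[k]] <- aperm(array(core, c(n, np, rk)), c(2L, 1L, 3L))
    ## nested next prefixes, plus an oversampled pool ranked by leverage
    fullRows <- cbind(rowPref, rowI)
    prefixSel <- fullRows[sel, , drop = FALSE]
    ## step-3 harvest: each maxvol row with its largest-magnitude column
    bestCol <- apply(abs(panel[sel, , drop = FALSE]), 1L, which.max)
    harvest[[k]] <- list(
      idx = cbind(prefixSel[rep(seq_along(sel), 1L), , drop = FALSE],
                  sufs[bestCol, , drop = FALSE]),
      value = panel[cbind(sel, bestCol)])
    lev <- rowSums(basis^2)
    ord <- c(sel, setdiff(order(lev, decreasing = TRUE), sel))
    poolSize <- min(nrow(fullRows), r^2)
    prefixPool <- fullRows[ord[seq_len(poolSize)], , drop = FALSE]
    rowPools[[k + 1L]] <- prefixPool
  }
  hIdx <- do.call(rbind, lapply(harvest, `[[`, "idx"))
  hVal <- unlist(lapply(harvest, `[[`, "value"), use.names = FALSE)
  list(cores = cores, rowPools = rowPools,
       harvest = list(idx = hIdx, value = hVal))
}

## Positions (within the prefix-major panel row order) of rows whose prefix
## is in `wanted`; returns them ordered as (wanted prefix, i = 1..n).
rowPrefixPositions <- function(pool, wanted, n) {
  keyPool <- apply(pool, 1L, paste, collapse = ",")
  keyWant <- apply(wanted, 1L, paste, collapse = ",")
  p <- match(keyWant, keyPool)
  if (anyNA(p)) stop("internal error: nested prefix missing from pool")
  as.vector(t(outer(p - 1L, seq_len(n), function(a, b) a * n + b)))
}

reverseImplicit <- function(f) {
  d <- length(f@modeSizes)
  g <- new("ImplicitTensor",
           evaluator = local({
             ev <- f@evaluator
             function(idx) ev(rev(idx))
           }),
           modeSizes = rev(f@modeSizes),
           state = f@state)          # shared counter
  g
}

revCols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

reverseState <- function(state) {
  d <- length(state@modeSizes)
  new("CrossState",
      rowPools = lapply(rev(state@colPools), revCols),
      colPools = lapply(rev(state@rowPools), revCols),
      bestPoints = lapply(state@bestPoints,
                          function(p) list(idx = rev(p$idx), value = p$value)),
      iteration = state@iteration,
      modeSizes = rev(state@modeSizes))
}

reverseLogSegments <- function(logEnv, from) {
  for (t in from:logEnv$nseg)
    logEnv$idx[[t]] <- revCols(logEnv$idx[[t]])
  invisible(NULL)
}

#' Cross interpolation of an implicit tensor
#'
#' Builds a TT interpolant with all ranks at most \code{rmax} by alternating
#' left-to-right and right-to-left maxvol-pivoted sweeps over crossed index
#' sets. Each sweep evaluates about \code{d * n * rmax^2} oracle entries
#' (\code{n} the largest mode size); for tensors whose true TT-ranks are at
#' most \code{rmax} the interpolant reproduces every entry.
#'
#' @param f an \linkS4class{ImplicitTensor}.
#' @param rmax maximal TT-rank (>= 1).
#' @param state a \linkS4class{CrossState}, or NULL to seed pools randomly
#'   from the current RNG state.
#' @param sweeps number of half sweeps (default 2: one left, one right).
#' @param logEnv internal evaluation log (environment); usually left NULL.
#' @return \code{list(tt =, state =)}: the interpolant and the refreshed
#'   interpolation-point state.
#' @export
ttCrossInterpolate <- function(f, rmax, state = NULL, sweeps = 2L,
                               logEnv = NULL) {
  stopifnot(rmax >= 1L)
  ms <- modeSizes(f)
  if (is.null(state)) state <- newCrossState(ms, rmax)
  if (is.null(logEnv)) logEnv <- newLogEnv()
  cores <- NULL
  harvIdx <- NULL; harvVal <- numeric(0)
  for (s in seq_len(max(1L, sweeps))) {
    if (s %% 2L == 1L) {
      sw <- crossSweepLR(f, state, rmax, logEnv)
      state@rowPools <- mergePools(sw$rowPools, state@rowPools)
      cores <- sw$cores
      harvIdx <- rbind(harvIdx, sw$harvest$idx)
    } else {
      segFrom <- logEnv$nseg + 1L
      frev <- reverseImplicit(f)
      strev <- reverseState(state)
      sw <- crossSweepLR(frev, strev, rmax, logEnv)
      reverseLogSegments(logEnv, segFrom)
      newCol <- lapply(rev(sw$rowPools), revCols)
      state@colPools <- mergePools(newCol, state@colPools)
      cores <- lapply(rev(sw$cores), function(ck) aperm(ck, c(3L, 2L, 1L)))
      harvIdx <- rbind(harvIdx, revCols(sw$harvest$idx))
    }
    harvVal <- c(harvVal, sw$harvest$value)
  }
  state@bestPoints <- updateBestPoints(state@bestPoints, logEnv)
  list(tt = TensorTrain(cores), state = state,
       harvest = list(idx = harvIdx, value = harvVal))
}

mergePools <- function(fresh, old, cap = 64L) {
  out <- vector("list", length(fresh))
  for (i in seq_along(fresh)) {
    merged <- uniqueRows(rbind(fresh[[i]], old[[i]]))
    out[[i]] <- merged[seq_len(min(nrow(merged), cap)), , drop = FALSE]
  }
  out
}

updateBestPoints <- function(best, logEnv, keep = 50L) {
  all <- collectLog(logEnv)
  if (is.null(all$indices)) return(best)
  ord <- order(abs(all$values), decreasing = TRUE)
  ord <- ord[!duplicated(apply(all$indices[ord, , drop = FALSE], 1L,
                               paste, collapse = ","))]
  ord <- ord[seq_len(min(keep, length(ord)))]
  pts <- lapply(ord, function(i)
    list(idx = all$indices[i, ], value = all$values[i]))
  merged <- c(pts, best)
  key <- vapply(merged, function(p) paste(p$idx, collapse = ","), "")
  merged <- merged[!duplicated(key)]
  vals <- vapply(merged, function(p) abs(p$value), numeric(1))
  merged[order(vals, decreasing = TRUE)][seq_len(min(keep, length(merged)))]
}

## Inject the suffix/prefix slices of the best points into the pools
## (step-6 injection) and merge neighboring unfoldings' sets (step-5 merge).
injectBestPoints <- function(state, poolCap) {
  d <- length(state@modeSizes)
  if (length(state@bestPoints) == 0L) return(state)
  top <- state@bestPoints[seq_len(min(poolCap, length(state@bestPoints)))]
  idxm <- do.call(rbind, lapply(top, function(p) matrix(p$idx, nrow = 1L)))
  for (k in 0:d) {
    suf <- idxm[, seq_len(d - k) + k, drop = FALSE]
    pre <- idxm[, seq_len(k), drop = FALSE]
    state@colPools[[k + 1L]] <-
      headRows(uniqueRows(rbind(suf, state@colPools[[k + 1L]])), 64L)
    state@rowPools[[k + 1L]] <-
      headRows(uniqueRows(rbind(pre, state@rowPools[[k + 1L]])), 64L)
  }
  ## step-5 neighbor merge: a suffix set for unfolding k gains the tails of
  ## unfolding k-1's suffixes; prefixes gain the heads of unfolding k+1's.
  for (k in 1:d) {
    tails <- state@colPools[[k]][, -1L, drop = FALSE]
    state@colPools[[k + 1L]] <-
      headRows(uniqueRows(rbind(state@colPools[[k + 1L]], tails)), 64L)
  }
  for (k in (d - 1L):0) {
    heads <- state@rowPools[[k + 2L]][, seq_len(k), drop = FALSE]
    state@rowPools[[k + 1L]] <-
      headRows(uniqueRows(rbind(state@rowPools[[k + 1L]], heads)), 64L)
  }
  state
}

headRows <- function(m, nmax) m[seq_len(min(nrow(m), nmax)), , drop = FALSE]

#' Global magnitude maximization over an implicit tensor
#'
#' The iterative cross-maximization loop: (1-2) cross-interpolate the tensor
#' on the current index sets, (3) harvest the large-magnitude interpolation
#' points, (4) optionally refine them through a caller-supplied callback and
#' project the refinements back onto the grid, (5) merge neighboring
#' unfoldings' interpolation sets, (6) inject the best points seen, then
#' repeat. Every oracle evaluation is logged; the best-so-far magnitude is
#' non-decreasing across iterations and the whole run is deterministic for a
#' fixed seed.
#'
#' @param f an \linkS4class{ImplicitTensor}.
#' @param rmax maximal TT-rank.
#' @param iterations number of outer iterations (>= 1).
#' @param refine optional callback \code{function(idx, value)} returning a
#'   grid multi-index near a locally improved point (or NULL to skip);
#'   typically a rough simplex refinement in the caller's continuous space.
#'   Refined points are the maxvol interpolation points of every unfolding
#'   (never the same grid point twice across iterations), giving the
#'   O(d * rmax) local refinements per iteration the method is designed
#'   around.
#' @param seed integer RNG seed; fixes the whole run.
#' @param sweeps half sweeps per iteration.
#' @param nRefine cap on refined points per mode and iteration (default
#'   \code{rmax}; the per-iteration total is \code{nRefine * d}).
#' @param poolCap interpolation-set merge cap (default \code{2 * rmax}).
#' @param rankSchedule if TRUE, ranks start at \code{min(2, rmax)} and grow
#'   by 1 per iteration up to \code{rmax}.
#' @return \code{list(index =, value =, log =, tt =, state =)}: the
#'   largest-magnitude grid point found, its value, the full evaluation log
#'   (\code{log$indices}, \code{log$values}, \code{log$iteration}), the last
#'   interpolant and the final \linkS4class{CrossState}.
#' @export
ttMagnitudeMaximize <- function(f, rmax, iterations, refine = NULL,
                                seed = 1L, sweeps = 2L, nRefine = rmax,
                                poolCap = 2L * rmax, rankSchedule = TRUE) {
  stopifnot(iterations >= 1L)
  set.seed(seed)
  ms <- modeSizes(f)
  state <- newCrossState(ms, rmax, poolCap)
  logEnv <- newLogEnv()
  refinedKeys <- new.env(parent = emptyenv())  # never refine a point twice
  segEnd <- integer(iterations)   # last log segment recorded in iteration t
  for (t in seq_len(iterations)) {
    rT <- if (rankSchedule) min(rmax, min(2L, rmax) + t - 1L) else rmax
    segFrom <- logEnv$nseg + 1L
    res <- ttCrossInterpolate(f, rT, state, sweeps = sweeps, logEnv = logEnv)
    state <- res$state
    if (!is.null(refine)) {
      ## step 4: refine the maxvol interpolation points of every unfolding
      ## (up to nRefine per mode and sweep: O(d * rmax) local refinements)
      hv <- res$harvest
      ord <- order(abs(hv$value), decreasing = TRUE)
      keys <- apply(hv$idx[ord, , drop = FALSE], 1L, paste, collapse = ",")
      fresh <- !duplicated(keys) &
        !vapply(keys, exists, logical(1), envir = refinedKeys)
      ord <- ord[fresh]
      ord <- ord[seq_len(min(length(ord), nRefine * length(ms)))]
      for (i in ord) {
        assign(paste(hv$idx[i, ], collapse = ","), TRUE, refinedKeys)
        newIdx <- refine(hv$idx[i, ], hv$value[i])
        if (!is.null(newIdx)) {
          v <- tensorElement(f, newIdx)
          logPanel(logEnv, matrix(as.integer(newIdx), nrow = 1L), v)
        }
      }
      state@bestPoints <- updateBestPoints(state@bestPoints, logEnv)
    }
    state <- injectBestPoints(state, poolCap)
    state@iteration <- t
    segEnd[t] <- logEnv$nseg
  }
  all <- collectLog(logEnv)
  seglen <- vapply(logEnv$idx, nrow, integer(1))
  segIter <- findInterval(seq_len(logEnv$nseg) - 1L, segEnd) + 1L
  iterTag <- rep.int(segIter, times = seglen)
  best <- which.max(abs(all$values))
  list(index = all$indices[best, ], value = all$values[best],
       log = list(indices = all$indices, values = all$values,
                  iteration = iterTag),
       tt = res$tt, state = state)
}
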