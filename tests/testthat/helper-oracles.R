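## Shared fixtures and independent oracles used across the suite.

## Random tensor train with prescribed ranks; dense oracle via ttDense.
randomTT <- function(d, n, rank, seed) {
  set.seed(seed)
  rk <- c(1L, rep(rank, d - 1L), 1L)
  TensorTrain(lapply(seq_len(d), function(k)
    array(stats::rnorm(rk[k] * n * rk[k + 1L]), c(rk[k], n, rk[k + 1L]))))
}

## Exhaustive |det| maximum over all r-row submatrices (oracle for maxvol).
bruteMaxDet <- function(a, r) {
  combos <- utils::combn(nrow(a), r)
  max(apply(combos, 2L, function(rows)
    abs(det(a[rows, , drop = FALSE]))))
}

## Minimum summed squared distance over all within-group permutations
## (oracle for the Hungarian assignment in symmetryRmsd).
brutePermCost <- function(pa, pb) {
  n <- nrow(pa)
  perms <- allPermutations(n)
  best <- Inf
  for (p in perms)
    best <- min(best, sum((pa - pb[p, , drop = FALSE])^2))
  best
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

## Quadratic-time reference for the greedy keep-lowest dedup sweep.
referenceDedup <- function(coordsList, energies, threshold, rmsdFun) {
  ord <- order(energies)
  kept <- integer(0)
  for (i in ord) {
    ok <- all(vapply(kept, function(k)
      rmsdFun(coordsList[[k]], coordsList[[i]]) >= threshold, logical(1)))
    if (ok) kept <- c(kept, i)
  }
  kept
}

## Ligand-only molecular system (one far-away receptor atom keeps the
## receptor side non-empty without interacting).
ligandOnlySystem <- function(elements, coords, bonds, charges = NULL) {
  makeMolecularSystem("C", matrix(c(500, 500, 500), 1L),
                      elements, coords, ligandBonds = bonds,
                      ligandCharges = charges)
}

## Butane with explicit hydrogens: heavy chain C1-C2-C3-C4 (ideal sp3
## zigzag), hydrogens placed roughly tetrahedrally (geometry does not need
## to be perfect for graph-based tests).
butaneSystem <- function() {
  b0 <- 1.526; bh <- 1.09
  half <- 109.47 / 2 * pi / 180
  cc <- matrix(0, 4L, 3L)
  for (i in 2:4)
    cc[i, ] <- cc[i - 1L, ] + b0 * c(sin(half), cos(half) * (-1)^i, 0)
  hs <- list()
  hb <- list()
  k <- 4L
  for (i in 1:4) {
    nH <- if (i %in% c(1L, 4L)) 3L else 2L
    for (h in seq_len(nH)) {
      k <- k + 1L
      ang <- 2 * pi * h / (nH + 1)
      hs[[length(hs) + 1L]] <- cc[i, ] + bh * c(0, sin(ang), cos(ang))
      hb[[length(hb) + 1L]] <- c(i, k)
    }
  }
  coords <- rbind(cc, do.call(rbind, hs))
  bonds <- rbind(data.frame(i = 1:3, j = 2:4, order = 1),
                 data.frame(i = vapply(hb, `[`, numeric(1), 1L),
                            j = vapply(hb, `[`, numeric(1), 2L), order = 1))
  ligandOnlySystem(c(rep("C", 4L), rep("H", k - 4L)), coords, bonds)
}

## Planar hexagonal carbon ring with one substituent carbon on atom 1
## (toluene-like skeleton, no hydrogens); returns the system plus the
## ring-position labels.
tolueneSystem <- function() {
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  methyl <- c(2.9, 0, 0)
  coords <- rbind(ring, methyl)
  bonds <- rbind(data.frame(i = 1:6, j = c(2:6, 1L), order = 1.5),
                 data.frame(i = 1L, j = 7L, order = 1))
  list(system = ligandOnlySystem(rep("C", 7L), coords, bonds),
       ipso = 1L, ortho = c(2L, 6L), meta = c(3L, 5L), para = 4L,
       methyl = 7L)
}

## Small deterministic docking run on the plain cavity fixture, shared by
## the engine tests (kept tiny: coarse grid, few iterations).
tinyDockRun <- function(seed = 3L, path = tempfile(fileext = ".ttm")) {
  tc <- makeToyComplex()
  model <- referenceEnergyModel(tc$system)
  space <- buildSearchSpace(tc$system, m = 4L)
  store <- dock(tc$system, space, model, storePath = path, rmax = 3L,
                iterations = 3L, seed = seed, refineBudget = 60L,
                validate = FALSE)
  list(tc = tc, model = model, space = space, store = store)
}
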