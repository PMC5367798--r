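## Reference vacuum force field: harmonic bonds and angles, cosine torsions,
## 12-6 Lennard-Jones and Coulomb with 1-2/1-3 exclusions and no cutoff.
## This backend exists so that the engine is fully testable with no external
## parameter sets; any other backend satisfying the EnergyModel contract
## (e.g. an MMFF94 adapter) can replace it.

COULOMB_CONST <- 332.0637  # kcal*A/(mol*e^2)

#' Load the packaged reference force-field parameter table
#'
#' @param path YAML parameter file; defaults to the packaged table. The
#'   schema is documented in the file itself: per-element Lennard-Jones
#'   sigma/epsilon, bond and torsion parameters keyed by element pairs,
#'   angle parameters keyed by the central element, and the Coulomb
#'   dielectric.
#' @return Nested list of parameters.
#' @export
refFFParams <- function(path = system.file("extdata", "ref_ff.yaml",
                                           package = "ttdock")) {
  yaml::read_yaml(path)
}

pairKey <- function(e1, e2) {
  ifelse(e1 <= e2, paste0(e1, "-", e2), paste0(e2, "-", e1))
}

lookupPair <- function(table, e1, e2, what) {
  key <- pairKey(e1, e2)
  hit <- table[key]
  miss <- vapply(hit, is.null, logical(1))
  if (any(miss))
    stop("no ", what, " parameters for element pair ",
         paste(unique(key[miss]), collapse = ", "))
  hit
}

## Precomputed interaction lists for a fixed topology.
buildTopology <- function(system, params) {
  a <- system@atoms
  n <- nrow(a)
  b <- system@bonds
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  ## bonds
  bondPar <- if (nrow(b) > 0L)
    lookupPair(params$bonds, a$element[b$i], a$element[b$j], "bond")
  else list()
  bonds <- list(i = b$i, j = b$j,
                k = vapply(bondPar, function(p) as.numeric(p$k), numeric(1)),
                b0 = vapply(bondPar, function(p) as.numeric(p$b0),
                            numeric(1)))
  ## angles: every bonded pair around a central atom
  ai <- aj <- ak <- integer(0)
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      ai <- c(ai, cmb[1L, ]); aj <- c(aj, rep.int(j, ncol(cmb)))
      ak <- c(ak, cmb[2L, ])
    }
  }
  angPar <- params$angles[a$element[aj]]
  if (length(aj) > 0L && any(vapply(angPar, is.null, logical(1))))
    stop("no angle parameters for central element ",
         paste(unique(a$element[aj][vapply(angPar, is.null, logical(1))]),
               collapse = ", "))
  angles <- list(i = ai, j = aj, k = ak,
                 kth = vapply(angPar, function(p) as.numeric(p$k),
                              numeric(1)),
                 th0 = vapply(angPar, function(p) as.numeric(p$theta0),
                              numeric(1)) * pi / 180)
  ## torsions: i-j-k-l over every central bond
  ti <- tj <- tk <- tl <- integer(0)
  for (r in seq_len(nrow(b))) {
    j <- b$i[r]; k <- b$j[r]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      if (i != l) {
        ti <- c(ti, i); tj <- c(tj, j); tk <- c(tk, k); tl <- c(tl, l)
      }
  }
  torPar <- if (length(tj) > 0L)
    lookupPair(params$torsions, a$element[tj], a$element[tk], "torsion")
  else list()
  torsions <- list(i = ti, j = tj, k = tk, l = tl,
                   v = vapply(torPar, function(p) as.numeric(p$v),
                              numeric(1)),
                   nper = vapply(torPar, function(p) as.numeric(p$mult),
                                 numeric(1)),
                   phi0 = vapply(torPar, function(p) as.numeric(p$phi0),
                                 numeric(1)) * pi / 180)
  ## nonbonded pairs: all pairs minus 1-2 and 1-3
  excl <- new.env(parent = emptyenv())
  markExcl <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, excl)
  for (r in seq_len(nrow(b))) markExcl(b$i[r], b$j[r])
  for (t in seq_along(ai)) markExcl(ai[t], ak[t])
  pi_ <- pj_ <- integer(0)
  if (n >= 2L) {
    cmb <- utils::combn(seq_len(n), 2L)
    keep <- !vapply(seq_len(ncol(cmb)), function(c)
      exists(paste(cmb[1L, c], cmb[2L, c]), excl), logical(1))
    pi_ <- cmb[1L, keep]; pj_ <- cmb[2L, keep]
  }
  ljTab <- params$lj
  getLJ <- function(el, field) {
    p <- ljTab[el]
    miss <- vapply(p, is.null, logical(1))
    if (any(miss))
      stop("no Lennard-Jones parameters for element ",
           paste(unique(el[miss]), collapse = ", "))
    vapply(p, function(e) as.numeric(e[[field]]), numeric(1))
  }
  sig <- (getLJ(a$element[pi_], "sigma") + getLJ(a$element[pj_], "sigma")) / 2
  eps <- sqrt(getLJ(a$element[pi_], "epsilon") *
              getLJ(a$element[pj_], "epsilon"))
  qq <- COULOMB_CONST * a$charge[pi_] * a$charge[pj_] /
    params$coulomb$dielectric
  pairs <- list(i = pi_, j = pj_, sig = sig, eps = eps, qq = qq)
  list(bonds = bonds, angles = angles, torsions = torsions, pairs = pairs,
       natoms = n)
}

ffEnergy <- function(coords, top) {
  e <- 0
  b <- top$bonds
  if (length(b$i) > 0L) {
    d <- coords[b$j, , drop = FALSE] - coords[b$i, , drop = FALSE]
    bl <- sqrt(rowSums(d^2))
    e <- e + sum(b$k * (bl - b$b0)^2)
  }
  a <- top$angles
  if (length(a$j) > 0L) {
    th <- angleValues(coords, a)
    e <- e + sum(a$kth * (th - a$th0)^2)
  }
  t <- top$torsions
  if (length(t$j) > 0L) {
    phi <- dihedralValues(coords, t)
    e <- e + sum(t$v * (1 + cos(t$nper * phi - t$phi0)))
  }
  p <- top$pairs
  if (length(p$i) > 0L) {
    d <- coords[p$j, , drop = FALSE] - coords[p$i, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    sr6 <- (p$sig / r)^6
    e <- e + sum(4 * p$eps * (sr6^2 - sr6)) + sum(p$qq / r)
  }
  e
}

angleValues <- function(coords, a) {
  u <- coords[a$i, , drop = FALSE] - coords[a$j, , drop = FALSE]
  v <- coords[a$k, , drop = FALSE] - coords[a$j, , drop = FALSE]
  cosv <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(1, pmax(-1, cosv)))
}

crossRows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

dihedralValues <- function(coords, t) {
  b1 <- coords[t$j, , drop = FALSE] - coords[t$i, , drop = FALSE]
  b2 <- coords[t$k, , drop = FALSE] - coords[t$j, , drop = FALSE]
  b3 <- coords[t$l, , drop = FALSE] - coords[t$k, , drop = FALSE]
  n1 <- crossRows(b1, b2)
  n2 <- crossRows(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  atan2(rowSums(crossRows(n1, n2) * b2) / b2n, rowSums(n1 * n2))
}

addAt <- function(g, idx, contrib) {
  s <- rowsum(contrib, idx)
  rows <- as.integer(rownames(s))
  g[rows, ] <- g[rows, ] + s
  g
}

ffGradient <- function(coords, top) {
  g <- matrix(0, top$natoms, 3L)
  b <- top$bonds
  if (length(b$i) > 0L) {
    d <- coords[b$j, , drop = FALSE] - coords[b$i, , drop = FALSE]
    bl <- sqrt(rowSums(d^2))
    fac <- 2 * b$k * (bl - b$b0) / bl
    g <- addAt(g, b$j, d * fac)
    g <- addAt(g, b$i, -d * fac)
  }
  a <- top$angles
  if (length(a$j) > 0L) {
    u <- coords[a$i, , drop = FALSE] - coords[a$j, , drop = FALSE]
    v <- coords[a$k, , drop = FALSE] - coords[a$j, , drop = FALSE]
    un <- sqrt(rowSums(u^2)); vn <- sqrt(rowSums(v^2))
    uh <- u / un; vh <- v / vn
    cosv <- pmin(1, pmax(-1, rowSums(uh * vh)))
    sinv <- pmax(sqrt(1 - cosv^2), 1e-8)
    th <- acos(cosv)
    pref <- 2 * a$kth * (th - a$th0)
    dthdi <- (uh * cosv - vh) / (un * sinv)
    dthdk <- (vh * cosv - uh) / (vn * sinv)
    g <- addAt(g, a$i, pref * dthdi)
    g <- addAt(g, a$k, pref * dthdk)
    g <- addAt(g, a$j, -pref * (dthdi + dthdk))
  }
  t <- top$torsions
  if (length(t$j) > 0L) {
    b1 <- coords[t$j, , drop = FALSE] - coords[t$i, , drop = FALSE]
    b2 <- coords[t$k, , drop = FALSE] - coords[t$j, , drop = FALSE]
    b3 <- coords[t$l, , drop = FALSE] - coords[t$k, , drop = FALSE]
    n1 <- crossRows(b1, b2)
    n2 <- crossRows(b2, b3)
    b2n <- sqrt(rowSums(b2^2))
    phi <- atan2(rowSums(crossRows(n1, n2) * b2) / b2n, rowSums(n1 * n2))
    dEdphi <- -t$v * t$nper * sin(t$nper * phi - t$phi0)
    n1sq <- pmax(rowSums(n1^2), 1e-12)
    n2sq <- pmax(rowSums(n2^2), 1e-12)
    dphidi <- -n1 * (b2n / n1sq)
    dphidl <- n2 * (b2n / n2sq)
    f12 <- rowSums(b1 * b2) / b2n^2
    f32 <- rowSums(b3 * b2) / b2n^2
    dphidj <- -dphidi * (1 + f12) + dphidl * f32
    dphidk <- dphidi * f12 - dphidl * (1 + f32)
    g <- addAt(g, t$i, dEdphi * dphidi)
    g <- addAt(g, t$j, dEdphi * dphidj)
    g <- addAt(g, t$k, dEdphi * dphidk)
    g <- addAt(g, t$l, dEdphi * dphidl)
  }
  p <- top$pairs
  if (length(p$i) > 0L) {
    d <- coords[p$j, , drop = FALSE] - coords[p$i, , drop = FALSE]
    r2 <- rowSums(d^2)
    r <- sqrt(r2)
    sr6 <- (p$sig^2 / r2)^3
    dEdr <- (-24 * p$eps * (2 * sr6^2 - sr6) - p$qq / r) / r
    fv <- d * (dEdr / r)
    g <- addAt(g, p$j, fv)
    g <- addAt(g, p$i, -fv)
  }
  g
}

#' Reference energy backend for a molecular system
#'
#' Builds an \linkS4class{EnergyModel} for the fixed topology of
#' \code{system}: harmonic bond and angle terms, periodic torsion terms,
#' and 12-6 Lennard-Jones plus Coulomb over all pairs except 1-2 and 1-3
#' (no cutoff). Parameters come from the packaged element-keyed YAML table;
#' a missing entry raises an error naming the element pair. The gradient is
#' analytic.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param params parameter list from [refFFParams()].
#' @return An \linkS4class{EnergyModel} with \code{hasGradient = TRUE}.
#' @examples
#' sys <- makeToyComplex()$system
#' model <- referenceEnergyModel(sys)
#' modelEnergy(model, atomCoords(sys))
#' @export
referenceEnergyModel <- function(system, params = refFFParams()) {
  top <- buildTopology(system, params)
  EnergyModel(energyFn = function(coords) ffEnergy(coords, top),
              gradFn = function(coords) ffGradient(coords, top),
              label = "reference-vacuum-ff")
}
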