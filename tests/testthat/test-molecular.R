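test_that("Lennard-Jones pair energy hits -epsilon at the minimum distance", {
  sig <- 3.4; eps <- 0.086                       # packaged C-C parameters
  rmin <- 2^(1 / 6) * sig
  sys <- makeMolecularSystem("C", matrix(c(0, 0, 0), 1),
                             "C", matrix(c(rmin, 0, 0), 1),
                             ligandBonds = data.frame(i = integer(0),
                                                      j = integer(0),
                                                      order = numeric(0)))
  model <- referenceEnergyModel(sys)
  expect_equal(modelEnergy(model, atomCoords(sys)), -eps, tolerance = 1e-12)
})

test_that("reference energy is rigid-motion invariant", {
  tc <- makeToyComplex(ligand = "chain4")
  model <- referenceEnergyModel(tc$system)
  cds <- atomCoords(tc$system)
  e0 <- modelEnergy(model, cds)
  shifted <- sweep(cds, 2, c(5, 5, 5), `+`)
  expect_lt(abs(modelEnergy(model, shifted) - e0), 1e-9)
  expect_silent(validateEnergyModel(model, tc$system))
})

test_that("analytic gradient matches central finite differences", {
  tc <- makeToyComplex(ligand = "chain4")   # bonds, angles, torsion, pairs
  model <- referenceEnergyModel(tc$system)
  set.seed(8)
  for (t in 1:3) {
    cds <- atomCoords(tc$system) +
      matrix(rnorm(3 * nrow(atomCoords(tc$system)), sd = 0.08), ncol = 3)
    ga <- modelGradient(model, cds)
    gn <- ttdock:::numericalGradient(model@energyFn, cds)
    expect_lt(max(abs(ga - gn)) / max(1, max(abs(gn))), 1e-4)
  }
})

test_that("missing force-field parameters name the offending pair", {
  sys <- makeMolecularSystem(character(0), matrix(numeric(0), 0, 3),
                             c("C", "I"), cbind(c(0, 2.1), 0, 0),
                             ligandBonds = data.frame(i = 1, j = 2,
                                                      order = 1))
  expect_error(referenceEnergyModel(sys), "C-I")
})

test_that("rotatable-bond perception follows the moving-heavy-atom rule", {
  ## ethane: the C-C rotor moves only hydrogens -> excluded
  b <- 1.526
  h <- rbind(c(-0.5, 0.9, 0), c(-0.5, -0.45, 0.78), c(-0.5, -0.45, -0.78))
  coords <- rbind(c(0, 0, 0), c(b, 0, 0), h, sweep(-h, 2, c(b, 0, 0), `+`))
  bonds <- data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                      j = c(2, 3, 4, 5, 6, 7, 8), order = 1)
  eth <- ligandOnlySystem(c("C", "C", rep("H", 6)), coords, bonds)
  expect_identical(detectRotatableBonds(eth), integer(0))

  ## benzene: every ring bond is in a ring -> none rotatable
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  benz <- ligandOnlySystem(rep("C", 6), ring,
                           data.frame(i = 1:6, j = c(2:6, 1), order = 1.5))
  expect_identical(detectRotatableBonds(benz), integer(0))

  ## butane: exactly the central C2-C3 bond
  but <- butaneSystem()
  rot <- detectRotatableBonds(but)
  expect_length(rot, 1)
  ## ligand atoms sit after the single receptor atom: C2 = 3, C3 = 4
  expect_setequal(c(but@bonds$i[rot], but@bonds$j[rot]), c(3, 4))
})

test_that("rotatable bonds are invariant under atom relabeling", {
  but <- butaneSystem()
  lig <- ligandIndices(but)
  nl <- length(lig)
  rotPairs <- function(sys, toOldLocal) {
    rows <- detectRotatableBonds(sys)
    off <- length(receptorIndices(sys))
    sort(vapply(rows, function(r) {
      a <- toOldLocal[sys@bonds$i[r] - off]
      b <- toOldLocal[sys@bonds$j[r] - off]
      paste(min(a, b), max(a, b))
    }, ""))
  }
  expect_identical(rotPairs(but, seq_len(nl)), "2 3")  # heavy C2-C3
  perm <- rev(seq_len(nl))                     # ligand-local relabeling
  lb <- but@bonds[ttdock:::ligandBondRows(but), ]
  sys2 <- makeMolecularSystem(
    "C", matrix(c(500, 500, 500), 1),
    but@atoms$element[lig][perm], but@coords[lig, ][perm, ],
    ligandBonds = data.frame(i = match(lb$i - 1L, perm),
                             j = match(lb$j - 1L, perm),
                             order = lb$order))
  expect_identical(rotPairs(sys2, perm), "2 3")
})

test_that("applyTorsion preserves geometry and composes", {
  but <- butaneSystem()
  rot <- detectRotatableBonds(but)[1]
  cds <- atomCoords(but)
  expect_identical(applyTorsion(cds, rot, 0, but), cds)
  expect_lt(max(abs(applyTorsion(cds, rot, 2 * pi, but) - cds)), 1e-9)
  ab <- applyTorsion(applyTorsion(cds, rot, 0.7, but), rot, 0.5, but)
  expect_lt(max(abs(ab - applyTorsion(cds, rot, 1.2, but))), 1e-9)
  ## internal geometry: all bond lengths preserved
  r1 <- applyTorsion(cds, rot, 1.1, but)
  bl <- function(c_) sqrt(rowSums((c_[but@bonds$i, ] - c_[but@bonds$j, ])^2))
  expect_lt(max(abs(bl(r1) - bl(cds))), 1e-9)
  expect_error(applyTorsion(cds, 1L, 0.3, but), "not rotatable")
})

test_that("anti-butane C1-C4 distance matches the trigonometric construction", {
  but <- butaneSystem()
  rot <- detectRotatableBonds(but)[1]
  cds <- atomCoords(but)
  ## input zigzag is already anti (phi = 180 deg); rotating to syn (by pi)
  ## and back by pi must reproduce it, and the anti C1-C4 distance follows
  ## from ideal geometry: d = b*sqrt(
  ##   (1 + 2*sin(half))^2 * ... ) computed here by explicit construction
  b <- 1.526; half <- 109.47 / 2 * pi / 180
  p1 <- c(0, 0, 0); p2 <- p1 + b * c(sin(half), cos(half), 0)
  p3 <- p2 + b * c(sin(half), -cos(half), 0)
  p4 <- p3 + b * c(sin(half), cos(half), 0)
  dAnti <- sqrt(sum((p4 - p1)^2))
  ## ligand C1 and C4 are global atoms 2 and 5 (one receptor atom first)
  expect_equal(sqrt(sum((cds[5, ] - cds[2, ])^2)), dAnti, tolerance = 1e-9)
  ## syn conformer: C1-C4 distance from explicit rotation of p4 about the
  ## C2-C3 axis by pi
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  v <- p4 - p2
  vrot <- v * cos(pi) + pracmaCross(axis, v) * sin(pi) +
    axis * sum(axis * v) * (1 - cos(pi))
  dSyn <- sqrt(sum((p2 + vrot - p1)^2))
  syn <- applyTorsion(cds, rot, pi, but)
  expect_equal(sqrt(sum((syn[5, ] - syn[2, ]) ^ 2)), dSyn, tolerance = 1e-9)
})
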