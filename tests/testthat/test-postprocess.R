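test_that("CRC32 matches the zlib reference vector", {
  expect_identical(crc32(charToRaw("123456789")), 0xCBF43926)
  expect_identical(crc32(as.integer(charToRaw("abc"))),
                   crc32(charToRaw("abc")))
  expect_error(crc32(c(-1, 5)), "0..255")
})

test_that("sorter dedup keeps the lowest-energy representative", {
  tc <- makeToyComplex()
  sys <- tc$system
  lig <- atomCoords(sys)[ligandIndices(sys), ]
  mk <- function(records) {
    h <- ttdock:::createMinimaStore(tempfile(fileext = ".ttm"), d = 6L,
                                    nLig = 2L, nMov = 0L, seed = 1L,
                                    configHash = 0, sysChecksum = 0)
    for (i in seq_along(records))
      ttdock:::appendMinimaRecord(h, numeric(6), records[[i]]$lig,
                                  matrix(numeric(0), 0, 3),
                                  records[[i]]$e, tag = i)
    path <- summary(h$con)$description
    ttdock:::closeStoreHandle(h)
    path
  }
  ## identical poses at energies -5 and -4: single survivor at -5
  p <- mk(list(list(lig = lig, e = -4), list(lig = lig, e = -5)))
  out <- sorterDedup(p, sys)
  expect_length(out, 1L)
  expect_identical(energyOf(out[[1]]), -5)
  ## empty store -> empty output
  expect_length(sorterDedup(mk(list()), sys), 0L)
  ## 50 random records: survivors pairwise >= threshold, set matches the
  ## quadratic-time reference sweep
  set.seed(23)
  recs <- lapply(1:50, function(i)
    list(lig = lig + matrix(rnorm(6, sd = 0.12), 2), e = rnorm(1)))
  out <- sorterDedup(mk(recs), sys, threshold = 0.1)
  expect_gt(length(out), 1L)
  ligs <- lapply(out, function(cf)
    atomCoords(cf)[ligandIndices(sys), , drop = FALSE])
  for (i in seq_along(ligs)) for (j in seq_len(i - 1L))
    expect_gte(naiveRmsd(ligs[[i]], ligs[[j]]), 0.1)
  ref <- referenceDedup(lapply(recs, `[[`, "lig"),
                        vapply(recs, `[[`, numeric(1), "e"),
                        0.1, naiveRmsd)
  expect_identical(vapply(out, energyOf, numeric(1)),
                   vapply(recs, `[[`, numeric(1), "e")[ref])
})

test_that("full optimization reaches tight gradients and never raises energy", {
  ## stretched diatomic relaxes to the equilibrium bond length
  b0 <- 1.526
  sys <- makeMolecularSystem(character(0), matrix(numeric(0), 0, 3),
                             c("C", "C"),
                             cbind(c(0, b0 + 0.3), 0, 0),
                             ligandBonds = data.frame(i = 1, j = 2,
                                                      order = 1))
  model <- referenceEnergyModel(sys)
  opt <- optimizeFull(atomCoords(sys), sys, model)
  blen <- sqrt(sum((atomCoords(opt)[2, ] - atomCoords(opt)[1, ])^2))
  expect_equal(blen, b0, tolerance = 1e-5)
  expect_lte(attr(opt, "gradNorm"), 1e-4)
  ## starting at the stationary point: unchanged to numerical precision
  opt2 <- optimizeFull(opt, sys, model)
  expect_lt(max(abs(atomCoords(opt2) - atomCoords(opt))), 1e-6)
  ## random toy-complex starts: gradient target met, energy non-increasing
  tc <- makeToyComplex(ligand = "chain4")
  model <- referenceEnergyModel(tc$system)
  set.seed(24)
  sp <- buildSearchSpace(tc$system, m = 4)
  for (t in 1:3) {
    pt <- sp@dims$lower + runif(nrow(sp@dims)) *
      (sp@dims$upper - sp@dims$lower)
    conf <- decodeConformation(pt, sp, tc$system)
    e0 <- modelEnergy(model, atomCoords(conf))
    opt <- optimizeFull(conf, tc$system, model)
    expect_lte(energyOf(opt), e0 + 1e-12)
    expect_lte(attr(opt, "gradNorm"), 1e-4)
  }
})

test_that("chemical digests group symmetry-equivalent atoms", {
  ## benzene: all six carbons share one digest
  ang <- 2 * pi * (0:5) / 6
  benz <- ligandOnlySystem(rep("C", 6), cbind(1.4 * cos(ang),
                                              1.4 * sin(ang), 0),
                           data.frame(i = 1:6, j = c(2:6, 1), order = 1.5))
  dg <- digestTable(benz)
  expect_length(unique(dg), 1L)
  ## toluene skeleton: ortho pair equal, meta pair equal, para distinct
  tol <- tolueneSystem()
  dgt <- digestTable(tol$system)
  expect_identical(dgt[tol$ortho[1]], dgt[tol$ortho[2]])
  expect_identical(dgt[tol$meta[1]], dgt[tol$meta[2]])
  expect_false(dgt[tol$para] == dgt[tol$ortho[1]])
  ## digests do not depend on the input atom ordering
  perm <- c(4L, 2L, 7L, 1L, 6L, 3L, 5L)
  lb <- tol$system@bonds[ttdock:::ligandBondRows(tol$system), ]
  lig <- ligandIndices(tol$system)
  sys2 <- ligandOnlySystem(rep("C", 7),
                           tol$system@coords[lig, ][perm, ],
                           data.frame(i = match(lb$i - 1L, perm),
                                      j = match(lb$j - 1L, perm),
                                      order = lb$order))
  dg2 <- digestTable(sys2)
  expect_identical(unname(dg2), unname(dgt[perm]))
  ## a depth-0 neighborhood is the atom's own type alone (aromatic C = 22)
  expect_identical(chemicalDigest(benz, ligandIndices(benz)[1], depth = 0),
                   crc32(as.raw(22L)))
})

test_that("symmetry RMSD equals the permutation-enumeration oracle", {
  expect_equal(symmetryRmsd(atomCoords(tolueneSystem()$system),
                            atomCoords(tolueneSystem()$system),
                            tolueneSystem()$system), 0)
  set.seed(25)
  for (t in 1:100) {
    ## random chain molecule, <= 10 atoms, random elements
    n <- sample(4:10, 1)
    el <- sample(c("C", "N", "O"), n, replace = TRUE)
    bonds <- data.frame(i = 1:(n - 1), j = 2:n, order = 1)
    sys <- ligandOnlySystem(el, matrix(rnorm(3 * n, sd = 2), n), bonds)
    a <- matrix(rnorm(3 * n, sd = 2), n)
    b <- matrix(rnorm(3 * n, sd = 2), n)
    fullA <- rbind(c(500, 500, 500), a)
    fullB <- rbind(c(500, 500, 500), b)
    dg <- digestTable(sys)
    groups <- split(seq_len(n), dg)
    skip <- any(vapply(groups, length, integer(1)) > 4L)
    if (skip) next
    cost <- 0
    for (g in groups) cost <- cost + brutePermCost(a[g, , drop = FALSE],
                                                   b[g, , drop = FALSE])
    oracle <- sqrt(cost / n)
    got <- symmetryRmsd(fullA, fullB, sys)
    expect_equal(got, oracle, tolerance = 1e-10)
    expect_lte(got, naiveRmsd(a, b) + 1e-12)
    ## pseudometric symmetry
    expect_equal(got, symmetryRmsd(fullB, fullA, sys), tolerance = 1e-10)
  }
})

test_that("a phenyl-type ring flip has zero symmetry RMSD", {
  tol <- tolueneSystem()
  cds <- atomCoords(tol$system)
  flipped <- cds
  flipped[, 2] <- -flipped[, 2]   # 180-degree flip about the ipso-para axis
  expect_lt(symmetryRmsd(flipped, cds, tol$system), 1e-6)
  expect_gt(naiveRmsd(flipped[ligandIndices(tol$system), ],
                      cds[ligandIndices(tol$system), ]), 1)
})

test_that("unique dedup removes symmetric duplicates and is idempotent", {
  tol <- tolueneSystem()
  sys <- tol$system
  cds <- atomCoords(sys)
  flipped <- cds; flipped[, 2] <- -flipped[, 2]
  shifted <- cds; shifted[ligandIndices(sys), 1] <-
    shifted[ligandIndices(sys), 1] + 5
  confs <- list(Conformation(numeric(0), cds, energy = -3),
                Conformation(numeric(0), flipped, energy = -2.5),
                Conformation(numeric(0), shifted, energy = -1))
  spec <- uniqueDedup(confs, sys)
  expect_identical(nTotal(spec), 2L)           # flip collapses
  expect_identical(spectrumTable(spec)$energy_kcal_mol, c(-3, -1))
  ## idempotence
  spec2 <- uniqueDedup(spec@conformations, sys)
  expect_identical(spectrumTable(spec2), spectrumTable(spec))
  ## survivors pairwise above threshold under the same metric
  for (i in seq_len(nTotal(spec))) for (j in seq_len(i - 1L))
    expect_gte(symmetryRmsd(spec@conformations[[i]],
                            spec@conformations[[j]], sys,
                            includeMoveable = TRUE), 0.1)
})

test_that("INON/EN indices follow their definitions", {
  tol <- tolueneSystem()
  sys <- tol$system
  cds <- atomCoords(sys)
  mkconf <- function(dx, e) {
    c2 <- cds
    c2[ligandIndices(sys), 1] <- c2[ligandIndices(sys), 1] + dx
    Conformation(numeric(0), c2, energy = e)
  }
  native <- Conformation(numeric(0), cds, energy = -5)
  ## index-1 entry is the native pose itself
  spec <- uniqueDedup(list(mkconf(0, -5), mkconf(6, -4)), sys)
  idx <- paradigmIndices(spec, native, sys)
  expect_identical(idx$inon, 1)
  expect_identical(idx$en, 1)
  expect_true(idx$paradigmSatisfied)
  ## nothing within 2 A
  spec2 <- uniqueDedup(list(mkconf(6, -4), mkconf(9, -3)), sys)
  idx2 <- paradigmIndices(spec2, native, sys)
  expect_identical(idx2$inon, Inf)
  expect_identical(idx2$en, Inf)
  ## near pose outside the energy window: INON finite, EN = Inf
  spec3 <- uniqueDedup(list(mkconf(6, -4), mkconf(1.5, -2)), sys)
  idx3 <- paradigmIndices(spec3, native, sys)
  expect_identical(idx3$inon, 2)
  expect_identical(idx3$en, Inf)
  ## empty spectrum
  idx0 <- paradigmIndices(uniqueDedup(list(), sys), native, sys)
  expect_identical(idx0$inon, Inf)
})

test_that("the report carries N_tot rows and recomputable center distances", {
  run <- tinyDockRun(seed = 6L)
  pp <- postprocessRun(run$store, run$tc$system, run$model)
  path <- tempfile(fileext = ".tsv")
  writeReport(pp$spectrum, pp$indices, path,
              config = list(rmax = 3, m = 4), seed = 6L)
  lines <- readLines(path)
  body <- utils::read.delim(path, comment.char = "#")
  expect_identical(nrow(body), nTotal(pp$spectrum))
  expect_true(any(grepl(sprintf("N_tot: %d", nTotal(pp$spectrum)), lines)))
  ## center distance recomputed independently
  sys <- run$tc$system
  natCtr <- colMeans(atomCoords(pp$native)[ligandIndices(sys), ])
  for (r in seq_len(nrow(body))) {
    ctr <- colMeans(atomCoords(pp$spectrum@conformations[[r]])[
      ligandIndices(sys), ])
    expect_equal(body$center_distance_A[r], sqrt(sum((ctr - natCtr)^2)),
                 tolerance = 1e-9)
  }
  ## empty spectrum: header-only file with N_tot = 0
  p0 <- tempfile(fileext = ".tsv")
  writeReport(uniqueDedup(list(), sys),
              list(inon = Inf, en = Inf), p0)
  expect_true(any(grepl("N_tot: 0", readLines(p0))))
})
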