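test_that("energy transform has the exact closed form and limits", {
  expect_identical(energyTransform(-3.7, -3.7), exp(50 * pi))
  expect_equal(energyTransform(1e12, 0), 1, tolerance = 1e-9)
  set.seed(17)
  e1 <- rnorm(200, sd = 50); e2 <- e1 + abs(rnorm(200, sd = 20)) + 1e-6
  expect_true(all(energyTransform(e1, -10) > energyTransform(e2, -10)))
  expect_true(all(is.finite(energyTransform(c(-1e6, 0, 1e6), 0))))
})

test_that("rough refinement never increases energy and respects bounds", {
  tc <- makeToyComplex()
  model <- referenceEnergyModel(tc$system)
  sp <- buildSearchSpace(tc$system, m = 5)
  set.seed(18)
  for (t in 1:3) {
    p0 <- sp@dims$lower + runif(6) * (sp@dims$upper - sp@dims$lower)
    e0 <- modelEnergy(model, ttdock:::buildCoords(p0, sp, tc$system))
    rr <- roughRefine(p0, sp, tc$system, model, budget = 150)
    expect_lte(rr$energy, e0 + 1e-12)
    expect_true(all(rr$point >= sp@dims$lower - 1e-12 &
                    rr$point <= sp@dims$upper + 1e-12))
    ## budget 0: input returned unchanged
    same <- roughRefine(p0, sp, tc$system, model, budget = 0)
    expect_identical(same$point, p0)
    expect_equal(same$energy, e0)
  }
})

test_that("rough refinement locates a quadratic-bowl minimum", {
  ## stand-alone 2-D bowl expressed through a custom energy model on a
  ## 2-atom system whose x-coordinates act as the free variables
  tc <- makeToyComplex()
  sp <- buildSearchSpace(tc$system, m = 5)
  target <- sp@cubeCenter[1:2] + c(0.3, -0.8)
  bowl <- EnergyModel(function(coords) {
    ctr <- colMeans(coords[ligandIndices(tc$system), , drop = FALSE])
    sum((ctr[1:2] - target)^2)
  }, label = "bowl")
  p0 <- c(sp@cubeCenter + c(2, 2, 0), 0, 0, 0)
  rr <- roughRefine(p0, sp, tc$system, bowl, budget = 500)
  expect_lt(max(abs(rr$point[1:2] - target)), 1e-3)
})

test_that("the minima store round-trips records bit-exactly", {
  d <- 4L
  h <- ttdock:::createMinimaStore(tempfile(fileext = ".ttm"), d = d,
                                  nLig = 2L, nMov = 1L, seed = 9L,
                                  configHash = crc32(as.raw(1:4)),
                                  sysChecksum = crc32(as.raw(5:9)))
  set.seed(19)
  recs <- lapply(1:5, function(i)
    list(point = rnorm(d), lig = matrix(rnorm(6), 2), mov = matrix(rnorm(3), 1),
         energy = rnorm(1)))
  for (i in seq_along(recs))
    ttdock:::appendMinimaRecord(h, recs[[i]]$point, recs[[i]]$lig,
                                recs[[i]]$mov, recs[[i]]$energy, tag = i)
  path <- summary(h$con)$description
  ttdock:::closeStoreHandle(h)
  back <- readMinimaStore(path)
  expect_identical(back$header$seed, 9L)
  expect_length(back$records, 5L)
  for (i in 1:5) {
    expect_identical(back$records[[i]]$point, recs[[i]]$point)
    expect_identical(back$records[[i]]$ligCoords, unname(recs[[i]]$lig))
    expect_identical(back$records[[i]]$energy, recs[[i]]$energy)
  }
  ## corrupt one record: flip a payload byte -> skipped with warning
  raw <- readBin(path, "raw", file.size(path))
  off <- length(raw) - 20L
  raw[off] <- as.raw(bitwXor(as.integer(raw[off]), 255L))
  writeBin(raw, path)
  expect_warning(bad <- readMinimaStore(path), "CRC")
  expect_length(bad$records, 4L)
  expect_identical(attr(bad, "skipped"), 1L)
})

test_that("docking is deterministic and the store is self-consistent", {
  p1 <- tempfile(fileext = ".ttm"); p2 <- tempfile(fileext = ".ttm")
  r1 <- tinyDockRun(seed = 3L, path = p1)
  r2 <- tinyDockRun(seed = 3L, path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  ## E* trace is monotone non-increasing
  expect_true(all(diff(attr(r1$store, "eStarTrace")) <= 0))
  ## every stored energy equals re-evaluating the stored coordinates
  recs <- readMinimaStore(r1$store)$records
  expect_gt(length(recs), 0L)
  for (rec in recs) {
    cds <- atomCoords(r1$tc$system)
    cds[ligandIndices(r1$tc$system), ] <- rec$ligCoords
    expect_equal(modelEnergy(r1$model, cds), rec$energy, tolerance = 1e-9)
  }
})
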