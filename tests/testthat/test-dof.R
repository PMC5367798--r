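test_that("search-space dimensionality is 6 + torsions + 3*moveable", {
  tc <- makeToyComplex()                      # rigid ligand, rigid receptor
  expect_identical(nrow(buildSearchSpace(tc$system, m = 5)@dims), 6L)
  sys <- setMoveable(tc$system, 1:3)
  expect_identical(nrow(buildSearchSpace(sys, m = 5)@dims), 6L + 9L)
  tc4 <- makeToyComplex(ligand = "chain4")    # one torsion
  sys4 <- setMoveable(tc4$system, 1:2)
  sp4 <- buildSearchSpace(sys4, m = 4)
  expect_identical(nrow(sp4@dims), 6L + 1L + 6L)
  expect_true(all(sp4@dims$n == 2^4))
  expect_identical(sp4@dims$kind,
                   c(rep("translation", 3), rep("rotation", 3), "torsion",
                     rep("atom_coord", 6)))
})

test_that("grid mapping uses cell centers and round-trips on nodes", {
  tc <- makeToyComplex()
  sp <- buildSearchSpace(tc$system, m = 5)
  n <- 32L
  ## node n/2 decodes to center minus half a cell on translations
  idx <- rep(n / 2, 6L)
  pt <- gridToPoint(as.integer(idx), sp)
  h <- sp@cubeEdge / n
  expect_equal(pt[1:3], sp@cubeCenter - h / 2, tolerance = 1e-12)
  set.seed(14)
  for (t in 1:1000) {
    ix <- as.integer(sapply(sp@dims$n, sample, size = 1))
    expect_identical(pointToGrid(gridToPoint(ix, sp), sp), ix)
  }
})

test_that("decode matches an independent geometric construction", {
  tc <- makeToyComplex(ligand = "chain6")     # 3 torsions
  sys <- tc$system
  sp <- buildSearchSpace(sys, m = 5)
  expect_identical(nrow(sp@dims), 9L)
  lig <- ligandIndices(sys)
  set.seed(15)
  fr <- attr(sp, "ligandFrame")
  for (t in 1:5) {
    pt <- sp@dims$lower + runif(9) * (sp@dims$upper - sp@dims$lower)
    conf <- decodeConformation(pt, sp, sys)
    ## independent construction: torsion-tree replay in the local frame
    ## (explicit Rodrigues rotations), recenter, rigid rotation, translate
    loc <- sweep(sys@coords[lig, ], 2, colMeans(sys@coords[lig, ]))
    rodrigues <- function(v, axis, ang) {
      a <- axis / sqrt(sum(axis^2))
      v * cos(ang) + pracmaCross(a, v) * sin(ang) +
        a * sum(a * v) * (1 - cos(ang))
    }
    for (k in seq_along(fr$tree)) {
      tw <- fr$tree[[k]]
      axv <- loc[tw$axisTo, ] - loc[tw$axisFrom, ]
      for (mv in tw$moving)
        loc[mv, ] <- loc[tw$axisFrom, ] +
          rodrigues(loc[mv, ] - loc[tw$axisFrom, ], axv, pt[6 + k])
    }
    loc <- sweep(loc, 2, colMeans(loc))
    th <- pt[4]; z <- pt[5]; psi <- pt[6]
    ax <- c(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
    ref <- t(apply(loc, 1, rodrigues, axis = ax, ang = psi))
    ref <- sweep(ref, 2, pt[1:3], `+`)
    expect_lt(max(abs(atomCoords(conf)[lig, ] - ref)), 1e-9)
    ## the decoded geometric center is exactly the decoded translation
    expect_lt(max(abs(colMeans(atomCoords(conf)[lig, ]) - pt[1:3])), 1e-9)
  }
})

test_that("decode preserves ligand internal geometry and fixed atoms", {
  tc <- makeToyComplex(ligand = "chain4", clashAtom = TRUE)
  sys <- tc$system
  sp <- buildSearchSpace(sys, m = 5)
  lb <- ttdock:::ligandBondRows(sys)
  bl0 <- sqrt(rowSums((sys@coords[sys@bonds$i[lb], ] -
                       sys@coords[sys@bonds$j[lb], ])^2))
  fixedRec <- setdiff(receptorIndices(sys), moveableIndices(sys))
  set.seed(16)
  for (t in 1:20) {
    ix <- as.integer(sapply(sp@dims$n, sample, size = 1))
    cds <- atomCoords(decodeConformation(ix, sp, sys))
    bl <- sqrt(rowSums((cds[sys@bonds$i[lb], ] - cds[sys@bonds$j[lb], ])^2))
    expect_lt(max(abs(bl - bl0)), 1e-9)
    ## non-moveable receptor atoms bit-identical
    expect_identical(cds[fixedRec, ], sys@coords[fixedRec, ])
    ## moveable atoms inside their small cubes
    mv <- moveableIndices(sys)
    expect_true(all(abs(cds[mv, ] - sys@coords[mv, ]) <=
                    sp@atomCubeEdge / 2 + 1e-12))
    ## ligand geometric center inside the docking cube
    ctr <- colMeans(cds[ligandIndices(sys), ])
    expect_true(all(abs(ctr - sp@cubeCenter) <= sp@cubeEdge / 2 + 1e-9))
  }
})

test_that("moveable-atom marking thresholds behave monotonically", {
  tc <- makeToyComplex()
  sys <- tc$system
  lig <- atomCoords(sys)[ligandIndices(sys), ]
  expect_identical(markMoveableAtoms(sys, list(lig), 0), integer(0))
  ## nearest cage atom sits 3.656 A from the closest ligand atom
  d <- as.matrix(stats::dist(rbind(atomCoords(sys)[1:8, ], lig)))[1:8, 9:10]
  expect_identical(markMoveableAtoms(sys, list(lig), 3.7),
                   unname(which(apply(d, 1, min) <= 3.7)))
  expect_identical(markMoveableAtoms(sys, list(lig), 3.5), integer(0))
  m1 <- markMoveableAtoms(sys, list(lig), 3.7)
  m3 <- markMoveableAtoms(sys, list(lig), 4.2)
  expect_true(all(m1 %in% m3))
  expect_true(length(m1) > 0)
  ## a pose moved next to atom 1 pulls it in at small thresholds
  near1 <- sweep(lig, 2, atomCoords(sys)[1, ] - colMeans(lig) +
                   c(2.5, 0, 0), `+`)
  expect_true(1L %in% markMoveableAtoms(sys, list(lig, near1), 3))
  expect_error(markMoveableAtoms(sys, list(), 3), "at least one")
})
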