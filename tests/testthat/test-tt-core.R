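test_that("ttElement collapses chained core products correctly", {
  ones <- TensorTrain(list(array(1, c(1, 4, 1)), array(1, c(1, 4, 1)),
                           array(1, c(1, 4, 1))))
  for (idx in list(c(1, 1, 1), c(4, 2, 3)))
    expect_identical(ttElement(ones, idx), 1)
  ab <- TensorTrain(list(array(c(1, 2), c(1, 2, 1)),
                         array(c(3, 4), c(1, 2, 1))))
  expect_identical(ttElement(ab, c(2, 2)), 8)      # separable product 2*4
  expect_error(ttElement(ab, c(3, 1)), "out of range")
  tt <- randomTT(3, 5, 3, seed = 11)
  dense <- ttDense(tt)
  for (t in 1:20) {
    idx <- c(sample(5, 1), sample(5, 1), sample(5, 1))
    expect_lt(abs(ttElement(tt, idx) - dense[idx[1], idx[2], idx[3]]),
              1e-10)
  }
})

test_that("TensorTrain validity rejects inconsistent cores", {
  expect_error(TensorTrain(list(array(1, c(1, 3, 2)),
                                array(1, c(3, 3, 1)))), "rank mismatch")
  expect_error(TensorTrain(list(array(1, c(2, 3, 1)))), "boundary")
})

test_that("maxvol returns the dominant submatrix", {
  a <- rbind(diag(2), matrix(0, 6, 2))
  expect_setequal(as.integer(maxvol(a)), 1:2)   # only nonsingular choice
  set.seed(21)
  for (t in 1:10) {
    a <- matrix(rnorm(16), 8, 2)
    idx <- maxvol(a, tol = 1e-2)
    c <- a %*% solve(a[idx, ])
    expect_lte(max(abs(c)), 1 + 1e-2 + 1e-12)
    expect_gte(abs(det(a[idx, ])),
               bruteMaxDet(a, 2) / (1 + 1e-2)^2 - 1e-12)
  }
  expect_error(maxvol(cbind(1:5, 2 * (1:5))), "rank-deficient")
})

test_that("cross interpolation is exact on low-rank tensors", {
  u <- runif(8) + 0.5; v <- runif(8) + 0.5; w <- runif(8) + 0.5
  f <- ImplicitTensor(function(idx) u[idx[1]] * v[idx[2]] * w[idx[3]],
                      c(8, 8, 8))
  set.seed(1)
  res <- ttCrossInterpolate(f, rmax = 1)
  dense <- ttDense(res$tt)
  truth <- outer(outer(u, v), w)
  expect_lt(max(abs(dense - truth)) / max(abs(truth)), 1e-8)

  tt0 <- randomTT(4, 8, 3, seed = 5)
  a0 <- ttDense(tt0)
  f2 <- ImplicitTensor(function(idx) a0[matrix(idx, 1)], rep(8, 4))
  set.seed(2)
  res2 <- ttCrossInterpolate(f2, rmax = 4, sweeps = 4)
  expect_lt(max(abs(ttDense(res2$tt) - a0)) / max(abs(a0)), 1e-8)
})

test_that("one interpolation pass respects the d*n*rmax^2 budget", {
  f <- ImplicitTensor(function(idx) sum(sin(idx)) + 7, rep(16, 6))
  set.seed(3)
  ttCrossInterpolate(f, rmax = 4)
  expect_lte(evalCount(f), 10 * 6 * 16 * 4^2)
})

test_that("magnitude maximization finds planted maxima", {
  ## quadratic bowl: argmax of -||x - x0||^2 is the grid node nearest x0
  d <- 3; n <- 16
  x0 <- c(0.31, 0.62, 0.48)
  xs <- (seq_len(n) - 0.5) / n
  g <- function(idx) exp(-sum((xs[idx] - x0)^2))   # positive, max at x0
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), d)))
  vals <- apply(grid, 1, g)
  trueIdx <- grid[which.max(vals), ]
  f <- ImplicitTensor(g, rep(n, d))
  res <- ttMagnitudeMaximize(f, rmax = 3, iterations = 5, seed = 4)
  expect_identical(as.integer(res$index), as.integer(trueIdx))

  ## constant tensor: any index, the constant value
  fc <- ImplicitTensor(function(idx) 2.5, rep(6, 3))
  resc <- ttMagnitudeMaximize(fc, rmax = 2, iterations = 2, seed = 1)
  expect_identical(resc$value, 2.5)
})

test_that("maximization is deterministic and best-so-far is monotone", {
  mk <- function() {
    at <- makeAnalyticTensor("gaussians", d = 4, n = 8, seed = 9)
    at$tensor
  }
  r1 <- ttMagnitudeMaximize(mk(), rmax = 3, iterations = 6, seed = 13)
  r2 <- ttMagnitudeMaximize(mk(), rmax = 3, iterations = 6, seed = 13)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$index, r2$index)
  perIter <- tapply(abs(r1$log$values), r1$log$iteration, max)
  expect_true(all(diff(cummax(perIter)) >= 0))
})
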