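randPoints <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 4), n, 3)
}

rigidCopy <- function(x, seed) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3)
  rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  x %*% (rx %*% rz) + matrix(runif(3, -5, 5), nrow(x), 3, byrow = TRUE)
}

test_that("superposition recovers rigid transforms exactly", {
  x <- randPoints(12, 1)
  same <- kabschSuperpose(x, x)
  expect_lt(same$rmsd, 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)
  y <- rigidCopy(x, 2)
  fit <- kabschSuperpose(x, y)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabschSuperpose(x[1:2, ], x[1:2, ]), "size")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabschSuperpose(line, line + 1), "collinear")
})

test_that("superposition RMSD agrees with the quaternion oracle", {
  for (seed in 1:25) {
    a <- randPoints(20, seed)
    b <- rigidCopy(a, seed + 100) + matrix(rnorm(60, sd = 0.5), 20, 3)
    expect_equal(kabschSuperpose(a, b)$rmsd, quaternionRmsd(a, b),
                 tolerance = 1e-9)
  }
})

test_that("RMSD series is zero for static frames and blind to translation", {
  rec <- makeAcidicPocketReceptor(1)$structure
  tr <- makeTrajectory(rec, "static", noiseSd = 0, nFrames = 12,
                       seed = 1)$trajectory
  helix <- selectIndices(rec, chain = "B", resSeq = 50:86, atomName = "CA")
  expect_equal(max(rmsdSeries(tr, helix)), 0, tolerance = 1e-10)
  shifted <- tr
  shifted@xyz[5, , ] <- shifted@xyz[5, , ] +
    matrix(c(3, -2, 1), dim(tr@xyz)[2], 3, byrow = TRUE)
  expect_equal(max(rmsdSeries(shifted, helix)), 0, tolerance = 1e-8)
  expect_error(rmsdSeries(tr, integer(0)), "empty")
})

test_that("an opening trajectory shows the generated RMSD trend", {
  rec <- makeAcidicPocketReceptor(2)$structure
  gen <- makeTrajectory(rec, "opening", noiseSd = 0.05, nFrames = 60, seed = 3)
  helix <- selectIndices(rec, chain = "B", resSeq = 50:86, atomName = "CA")
  rms <- rmsdSeries(gen$trajectory, helix)
  firstMean <- mean(rms[1:24])
  lastMean <- mean(rms[37:60])
  expect_gt(lastMean, firstMean)
})

test_that("CA-CA distances are Euclidean and resolve the default pairs", {
  rec <- makeAcidicPocketReceptor(1)$structure
  tr <- makeTrajectory(rec, "static", noiseSd = 0, nFrames = 10,
                       seed = 1)$trajectory
  # 3-4-5 sanity on a hand-built pair
  i <- selectIndices(rec, chain = "A", resSeq = 76, atomName = "CA")
  j <- selectIndices(rec, chain = "B", resSeq = 50, atomName = "CA")
  manual <- sqrt(sum((coords(rec)[i, ] - coords(rec)[j, ])^2))
  d <- caDistanceSeries(tr)
  expect_equal(unname(d[1, "D1"]), manual, tolerance = 1e-9)
  expect_equal(colnames(d), paste0("D", 1:5))
  expect_equal(max(apply(d, 2, sd)), 0)
  badPairs <- defaultPocketPairs()
  badPairs$res1[1] <- 999L
  expect_error(caDistanceSeries(tr, badPairs), "999")
})

test_that("closing mode narrows D3-D5 and leaves D1-D2 unchanged", {
  rec <- makeAcidicPocketReceptor(4)$structure
  gen <- makeTrajectory(rec, "closing_D3toD5", noiseSd = 0, nFrames = 50,
                        seed = 2)
  d <- caDistanceSeries(gen$trajectory)
  for (lb in c("D3", "D4", "D5")) {
    expect_lt(mean(d[31:50, lb]), mean(d[1:20, lb]))
    expect_equal(unname(gen$truth$pairTrend[lb]), "down")
  }
  for (lb in c("D1", "D2"))
    expect_equal(sd(d[, lb]), 0, tolerance = 1e-12)
})

test_that("window statistics match hand arithmetic and a brute-force pass", {
  ws <- windowStats(c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2), 0.4)
  expect_equal(ws$n, 4L)
  expect_equal(ws$mean, 2)
  expect_equal(ws$sd, 0)
  expect_equal(ws$twoSd, 0)
  set.seed(5)
  for (len in c(10, 37, 100)) {
    x <- rnorm(len)
    got <- windowStats(x, 0.4)
    ref <- bruteWindow(x, 0.4)
    expect_equal(got$mean, ref$mean, tolerance = 1e-12)
    expect_equal(got$sd, ref$sd, tolerance = 1e-12)
    expect_identical(got$twoSd, 2 * got$sd)
  }
  expect_error(windowStats(c(1, 2), 0.4), "at least 2")
  expect_equal(groupAggregate(c(3, 5, 7), "median"), 5)
  expect_equal(groupAggregate(c(3, 5, 7), "mean"), 5)
  expect_equal(groupAggregate(c(3, 5, 10), "mean"), 6)
})
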