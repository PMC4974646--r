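p0 <- methodParams()

test_that("velocity is distance over elapsed time", {
  expect_equal(velocityFromDistance(0, 90), 0)
  expect_equal(velocityFromDistance(90, 90), 1)
  expect_equal(velocityFromDistance(c(45, 90), 90), c(0.5, 1))
  expect_error(velocityFromDistance(10, 0), "elapsedTime")
})

test_that("MCE worked examples: one cost-2 pixel gives 2.5 degC, two give 5.0, one cost-3 gives 5.0", {
  fx <- makeRidgeValley(valleyWidth = 1)
  res <- runForward(fx$current, fx$future)
  mce <- exposureLayer(res, "mce")[, fx$truth$sourceCols]
  expect_equal(unique(as.vector(mce)), 2.5)

  fx2 <- makeRidgeValley(valleyWidth = 2)
  res2 <- runForward(fx2$current, fx2$future)
  expect_equal(unique(as.vector(
    exposureLayer(res2, "mce")[, fx2$truth$sourceCols])), 5.0)

  # one pixel two bands out (+-1.0 degC, cost 3) is also 5.0
  fx3 <- makeRidgeValley(valleyWidth = 1, valleyDissim = 1.0)
  res3 <- runForward(fx3$current, fx3$future)
  expect_equal(unique(as.vector(
    exposureLayer(res3, "mce")[, fx3$truth$sourceCols])), 5.0)

  # ridge pixels: high MCE despite short trajectories
  med <- exposureLayer(res, "med")[, fx$truth$sourceCols]
  expect_true(all(med <= 4 * 5))
})

test_that("computeMCE matches the accounting identity and scales inversely with p", {
  fx <- makeRidgeValley(valleyWidth = 1)
  s <- interpolateSeries(fx$current, fx$future)
  cs <- buildFinalCost(5.3, s, params = p0, pixelSize = 5)
  acc <- accumulatedCost(cs, c(4, 3), p0)
  ana <- oracleAnalogues(5.3, fx$future@values)
  dest <- selectDestination(acc, ana)$destination
  tr <- extractPath(acc, dest, increment = 5.3)
  expect_equal(computeMCE(tr, p0), 2.5)
  # doubling p halves MCE for the fixed trajectory
  expect_equal(computeMCE(tr, methodParams(penalty = 4)), 1.25)
  # all-analogue trajectory has exactly zero MCE
  accFlat <- accumulatedCost(matrix(1, 4, 4), c(1, 1), p0, pixelSize = 5)
  expect_identical(computeMCE(extractPath(accFlat, c(4, 4)), p0), 0)
})

test_that("MCE is invariant to extra analogue stretches on the path", {
  fx <- makeRidgeValley(ridgeWidth = 4, valleyWidth = 1)
  res <- runForward(fx$current, fx$future)
  mce <- exposureLayer(res, "mce")
  med <- exposureLayer(res, "med")
  # sources deeper into ridge A travel further but accumulate no more exposure
  expect_gt(med[4, 1], med[4, 4])
  expect_equal(mce[4, 1], mce[4, 4])
})

test_that("flat uniform-warming terrain: MCE = 0 everywhere and the velocities agree", {
  fx <- makeFlatGradient(nrow = 30, ncol = 8)
  res <- runForward(fx$current, fx$future)
  mce <- exposureLayer(res, "mce")
  routed <- !is.na(mce)
  expect_true(any(routed))
  expect_true(all(mce[routed] == 0))
  v1 <- exposureLayer(res, "velocityMED")
  v2 <- exposureLayer(res, "velocityED")
  expect_equal(v1[routed], v2[routed])
  expect_true(all(exposureLayer(res, "ratio")[routed] == 1))
  # routed destination = brute-force nearest analogue on the rounded fields
  ana <- oracleAnalogues(fx$current@values[25, 4], fx$future@values)
  want <- oracleNearest(c(25, 4), ana, 5)
  expect_equal(exposureLayer(res, "destRow")[25, 4], want$destination[1])
  expect_equal(exposureLayer(res, "ed")[25, 4], want$ed)
  expect_equal(v2[25, 4], want$ed / 90)
})

test_that("zero warming gives zero velocities and reverse equals forward as the identity", {
  fx <- makeFlatGradient(nrow = 12, ncol = 6, warming = 0)
  fwd <- runForward(fx$current, fx$future)
  rev <- runReverse(fx$current, fx$future)
  for (res in list(fwd, rev)) {
    v <- exposureLayer(res, "velocityMED")
    expect_true(all(v[!is.na(v)] == 0))
    dr <- exposureLayer(res, "destRow")
    ok <- !is.na(dr)
    expect_equal(dr[ok], row(dr)[ok]) # every pixel is its own analogue
  }
})

test_that("reverse mode mirrors forward displacement on a symmetric flat gradient", {
  # gradient 0.1 degC/px: every value is a 0.1 multiple, so no rounding ties
  fx <- makeFlatGradient(nrow = 30, ncol = 6, gradient = 0.1)
  fwd <- runForward(fx$current, fx$future)
  rev <- runReverse(fx$current, fx$future)
  # forward moves poleward (to smaller rows), reverse equatorward
  fr <- exposureLayer(fwd, "destRow"); rr <- exposureLayer(rev, "destRow")
  wantF <- oracleNearest(c(25, 3), oracleAnalogues(
    fx$current@values[25, 3], fx$future@values), 5)
  expect_equal(fr[25, 3], wantF$destination[1])
  wantR <- oracleNearest(c(5, 3), oracleAnalogues(
    fx$future@values[5, 3], fx$current@values), 5)
  expect_equal(rr[5, 3], wantR$destination[1])
  # the displacements mirror each other
  expect_equal(25 - fr[25, 3], rr[5, 3] - 5)
  okF <- !is.na(fr); okR <- !is.na(rr)
  expect_true(all(fr[okF] <= row(fr)[okF]))
  expect_true(all(rr[okR] >= row(rr)[okR]))
})

test_that("velocity_MED >= velocity_ED and MED >= ED on every fixture", {
  fixtures <- list(
    makeFlatGradient(nrow = 20, ncol = 6),
    makeRidgeValley(valleyWidth = 2),
    makePeninsula()
  )
  for (fx in fixtures) {
    res <- runForward(fx$current, fx$future)
    med <- exposureLayer(res, "med"); ed <- exposureLayer(res, "ed")
    ok <- !is.na(med) & !is.na(ed)
    expect_true(any(ok))
    expect_true(all(med[ok] >= ed[ok] - 1e-9))
    expect_true(all(exposureLayer(res, "ratio")[ok] >= 1 - 1e-9))
    mce <- exposureLayer(res, "mce")
    expect_true(all(mce[!is.na(mce)] >= -1e-12))
  }
})

test_that("peninsula tips route south through dissimilar climate; land bridges relieve them", {
  fx <- makePeninsula()
  res <- runForward(fx$current, fx$future)
  tip <- fx$truth$tip
  dest <- c(exposureLayer(res, "destRow")[tip[1], tip[2]],
            exposureLayer(res, "destCol")[tip[1], tip[2]])
  expect_equal(dest, fx$truth$summit)
  expect_gt(dest[1], tip[1]) # destination south of the source
  tipMCE <- exposureLayer(res, "mce")[tip[1], tip[2]]
  expect_gt(tipMCE, 0)
  # oracle check of the tip's accumulated cost over the same composite
  s <- interpolateSeries(fx$current, fx$future)
  T <- fx$current@values[tip[1], tip[2]]
  water <- fx$current@waterMask
  cs <- buildFinalCost(T, s, waterMask = water, params = p0, pixelSize = 5)
  csv <- cs@costs
  ora <- oracleDijkstra(csv, 5, tip)
  med <- exposureLayer(res, "med")[tip[1], tip[2]]
  expect_equal(tipMCE, (ora[dest[1], dest[2]] - med) / p0@penalty)
  # all-land control: a shorter, cooler corridor lowers the tip's exposure
  ctrl <- makePeninsula(allLand = TRUE)
  resC <- runForward(ctrl$current, ctrl$future)
  expect_lt(exposureLayer(resC, "mce")[tip[1], tip[2]], tipMCE)
})

test_that("sources with no analogue anywhere are flagged with NA metrics", {
  # uniform cooling-free landscape where warming removes all analogues
  cur <- temperatureGrid(matrix(5.0, 4, 4), pixelSize = 5)
  fut <- temperatureGrid(matrix(6.0, 4, 4), pixelSize = 5)
  res <- runForward(cur, fut)
  expect_true(all(exposureFlag(res, "noAnalogue")))
  expect_true(all(is.na(exposureLayer(res, "med"))))
})

test_that("the tidy exposure table carries one row per source pixel with metrics and flags", {
  fx <- makeRidgeValley()
  res <- runForward(fx$current, fx$future)
  tab <- exposureTable(res)
  expect_true(all(c("row", "col", "ed", "med", "velocityED", "velocityMED",
                    "mce", "ratio", "destRow", "destCol", "noAnalogue") %in%
                    names(tab)))
  routed <- tab[!tab$noAnalogue, ]
  expect_equal(nrow(routed), sum(!is.na(exposureLayer(res, "med"))))
  expect_true(all(routed$mce >= 0))
})

test_that("result layers and the table export losslessly", {
  fx <- makeRidgeValley()
  res <- runForward(fx$current, fx$future)
  tmp <- withr::local_tempdir()
  files <- writeExposureResult(res, tmp)
  mce <- climExposure:::.readAsc(file.path(tmp, "forward_mce.asc"))$values
  expect_identical(mce, exposureLayer(res, "mce"))
  tab <- utils::read.csv(file.path(tmp, "forward_table.csv"))
  expect_equal(nrow(tab), nrow(exposureTable(res)))
})
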