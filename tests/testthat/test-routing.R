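p0 <- methodParams()

test_that("unit-resistance accumulated cost equals travelled distance", {
  costs <- matrix(1, 5, 5)
  acc <- accumulatedCost(costs, c(3, 3), p0, pixelSize = 5)
  expect_equal(acc@acc[3, 4], 5)            # cardinal neighbour
  expect_equal(acc@acc[4, 4], sqrt(2) * 5)  # diagonal neighbour
  expect_equal(acc@acc[3, 3], 0)
  # full field equals the 8-connected shortest-length field from the oracle
  expect_equal(acc@acc, oracleDijkstra(costs, 5, c(3, 3)))
})

test_that("accumulated cost matches the brute-force Dijkstra oracle on random surfaces", {
  for (seed in 1:100) {
    set.seed(seed)
    costs <- randomCosts(8, 8, maxCost = 5, naFrac = 0.1)
    src <- which(!is.na(costs), arr.ind = TRUE)
    src <- src[sample.int(nrow(src), 1), ]
    nb <- if (seed %% 2) 8 else 4
    pars <- methodParams(neighbourhood = nb)
    acc <- accumulatedCost(costs, src, pars, pixelSize = 5)
    expect_equal(acc@acc, oracleDijkstra(costs, 5, src, nb),
                 tolerance = 1e-12, info = sprintf("seed %d", seed))
  }
  for (seed in 1:3) {
    set.seed(1000 + seed)
    costs <- randomCosts(20, 20, maxCost = 9)
    acc <- accumulatedCost(costs, c(1, 1), p0, pixelSize = 2.5)
    expect_equal(acc@acc, oracleDijkstra(costs, 2.5, c(1, 1)))
  }
})

test_that("paths detour around expensive walls when the detour is cheaper", {
  costs <- matrix(1, 7, 7)
  costs[2:7, 4] <- 50 # wall with a gap at the top
  acc <- accumulatedCost(costs, c(6, 2), p0, pixelSize = 1)
  expect_equal(acc@acc, oracleDijkstra(costs, 1, c(6, 2)))
  tr <- extractPath(acc, c(6, 6))
  expect_true(all(tr@costs == 1)) # the path threads the gap, never the wall
  expect_true(any(tr@path[, 1] == 1))
})

test_that("per-pixel half-edge lengths reproduce MED and the accounting identity", {
  # straight 3-pixel cardinal path at 5 km
  costs <- matrix(1, 1, 3)
  acc <- accumulatedCost(costs, c(1, 1), p0, pixelSize = 5)
  tr <- extractPath(acc, c(1, 3))
  expect_equal(tr@lengths, c(2.5, 5, 2.5))
  expect_equal(tr@MED, 10)
  # single diagonal step
  acc2 <- accumulatedCost(matrix(1, 2, 2), c(1, 1), p0, pixelSize = 5)
  tr2 <- extractPath(acc2, c(2, 2))
  expect_equal(tr2@MED, sqrt(2) * 5)
  expect_equal(tr2@lengths, rep(sqrt(2) * 5 / 2, 2))
  # identity sum(cost_i * l_i) = accumulated cost on random surfaces
  for (seed in 1:25) {
    set.seed(seed)
    costs <- randomCosts(10, 10, maxCost = 6)
    acc <- accumulatedCost(costs, c(1, 1), p0, pixelSize = 5)
    dest <- c(sample.int(10, 1), sample.int(10, 1))
    tr <- extractPath(acc, dest)
    expect_equal(sum(tr@costs * tr@lengths), acc@acc[dest[1], dest[2]],
                 tolerance = 1e-9)
    expect_equal(sum(tr@lengths), tr@MED)
  }
})

test_that("destination selection takes the least accumulated cost with deterministic tie-breaks", {
  costs <- matrix(1, 5, 5)
  acc <- accumulatedCost(costs, c(3, 3), p0, pixelSize = 5)
  # nearer analogue wins on cost
  sel <- selectDestination(acc, rbind(c(3, 5), c(3, 4)))
  expect_equal(sel$destination, c(3, 4))
  # two equal-cost, equal-ED analogues: row-major order decides
  sel2 <- selectDestination(acc, rbind(c(5, 3), c(1, 3)))
  expect_equal(sel2$destination, c(1, 3))
  # equal accumulated cost, different ED: smaller ED wins
  cc <- matrix(1, 2, 3); cc[2, 1] <- 3
  accc <- accumulatedCost(cc, c(1, 1), p0, pixelSize = 5)
  expect_equal(accc@acc[2, 1], accc@acc[1, 3]) # both 10
  tie <- selectDestination(accc, rbind(c(1, 3), c(2, 1)))
  expect_equal(tie$destination, c(2, 1))
  # source is its own analogue
  self <- selectDestination(accc, rbind(c(1, 1), c(2, 2)))
  expect_equal(self$destination, c(1, 1))
  expect_equal(self$cost, 0)
  # empty set flagged, not fatal
  none <- selectDestination(acc, matrix(integer(0), 0, 2))
  expect_true(none$noAnalogue)
  expect_null(none$destination)
})

test_that("water and nodata sources are rejected; unreachable destinations flagged", {
  costs <- matrix(1, 3, 3)
  costs[2, ] <- NA # impassable band
  expect_error(accumulatedCost(costs, c(2, 2), p0, pixelSize = 5), "nodata")
  w <- matrix(FALSE, 3, 3); w[1, 1] <- TRUE
  expect_error(accumulatedCost(matrix(1, 3, 3), c(1, 1), p0, pixelSize = 5,
                               isWater = w), "water")
  acc <- accumulatedCost(costs, c(1, 1), p0, pixelSize = 5)
  expect_error(extractPath(acc, c(3, 3)), "unreachable")
  sel <- selectDestination(acc, rbind(c(3, 3)))
  expect_true(sel$noAnalogue)
})

test_that("nearest-Euclidean matches a brute-force scan and ignores cost", {
  set.seed(5)
  fut <- matrix(roundTemperature(runif(144, 4, 6)), 12, 12)
  for (i in 1:10) {
    src <- c(sample.int(12, 1), sample.int(12, 1))
    T <- fut[src[1], src[2]]
    ana <- oracleAnalogues(T, fut)
    got <- nearestEuclidean(src, ana, 5)
    want <- oracleNearest(src, ana, 5)
    expect_equal(got$ed, want$ed)
    expect_equal(got$destination, want$destination)
  }
  expect_true(is.na(nearestEuclidean(c(1, 1), matrix(0L, 0, 2), 5)$ed))
  expect_equal(nearestEuclidean(c(2, 2), rbind(c(2, 2)), 5)$ed, 0)
})

test_that("raising the water cost never decreases an accumulated cost", {
  fx <- makePeninsula()
  s <- interpolateSeries(fx$current, fx$future)
  tip <- fx$truth$tip
  T <- fx$current@values[tip[1], tip[2]]
  w <- fx$current@waterMask
  lo <- buildFinalCost(T, s, waterMask = w,
                       params = methodParams(waterCost = 50))@costs
  hi <- buildFinalCost(T, s, waterMask = w,
                       params = methodParams(waterCost = 5000))@costs
  accLo <- accumulatedCost(lo, tip, p0, pixelSize = 5)
  accHi <- accumulatedCost(hi, tip, p0, pixelSize = 5)
  expect_true(all(accHi@acc >= accLo@acc - 1e-9, na.rm = TRUE))
})
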