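p0 <- methodParams()

test_that("integer cost bands match a brute-force band enumeration", {
  # independent oracle: walk the band edges outward from the analogue bin
  bandOracle <- function(d, hw) {
    k <- 1
    upper <- hw
    while (d > upper + 1e-9) {
      k <- k + 1
      upper <- upper + 2 * hw
    }
    k
  }
  for (d in seq(0, 3, by = 0.01)) {
    expect_equal(dissimilarityCost(5.3, 5.3 + d, p0), bandOracle(d, 0.25),
                 info = sprintf("d = %.2f", d))
    expect_equal(dissimilarityCost(5.3, 5.3 - d, p0), bandOracle(d, 0.25))
  }
})

test_that("the stated example bands hold: analogue 1, then 2, then 3", {
  expect_equal(dissimilarityCost(5.3, 5.3, p0), 1)
  expect_equal(dissimilarityCost(5.3, 5.55, p0), 1)   # on the +-0.25 edge
  expect_equal(dissimilarityCost(5.3, 5.6, p0), 2)    # (0.25, 0.75]
  expect_equal(dissimilarityCost(5.3, 6.05, p0), 2)   # upper edge inclusive
  expect_equal(dissimilarityCost(5.3, 6.1, p0), 3)    # (0.75, 1.25]
  expect_equal(dissimilarityCost(5.3, 4.3, p0), 3)
})

test_that("the linear cost form equals P * |dT| + 1 outside the analogue bin", {
  p <- methodParams(costForm = "linear")
  expect_equal(dissimilarityCost(5.0, 6.0, p), 3)   # 2 * 1 + 1
  expect_equal(dissimilarityCost(5.0, 5.1, p), 1)   # analogue
})

test_that("intermediate cost surfaces apply the cost elementwise with nodata", {
  u <- matrix(5.3, 3, 3)
  expect_equal(buildIntermediateCost(5.3, u, p0), matrix(1, 3, 3))
  expect_equal(buildIntermediateCost(5.3, u + 0.5, p0), matrix(2, 3, 3))
  chk <- matrix(5.3, 4, 4); chk[(row(chk) + col(chk)) %% 2 == 0] <- 6.3
  out <- buildIntermediateCost(5.3, chk, p0)
  expect_equal(out[chk == 5.3], rep(1, 8))
  expect_equal(out[chk == 6.3], rep(3, 8))
  u[2, 2] <- NA
  expect_true(is.na(buildIntermediateCost(5.3, u, p0)[2, 2]))
})

test_that("the composite takes the minimum over time, so warming-through pixels cost 1", {
  # pixel warms from T-1 through T to T+1: dissimilar at both endpoints,
  # analogue somewhere in between
  cur <- temperatureGrid(matrix(4.3, 2, 2), pixelSize = 5)
  fut <- temperatureGrid(matrix(6.3, 2, 2), pixelSize = 5)
  s <- interpolateSeries(cur, fut, nSteps = 31)
  cs <- buildFinalCost(5.3, s, params = p0)
  expect_equal(cs@costs, matrix(1, 2, 2))
  expect_equal(buildIntermediateCost(5.3, cur@values, p0), matrix(3, 2, 2))

  # static pixel never near T keeps its endpoint cost
  s2 <- interpolateSeries(cur, cur, nSteps = 5)
  expect_equal(buildFinalCost(5.3, s2, params = p0)@costs, matrix(3, 2, 2))

  # water override wins even where the temperature matches the increment
  w <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  cs3 <- buildFinalCost(5.3, s, waterMask = w, params = p0)
  expect_equal(cs3@costs[1, 1], 5000)
  expect_equal(cs3@costs[2, 1], 1)
})

test_that("composite cost is <= every intermediate cost, elementwise", {
  set.seed(11)
  for (i in 1:20) {
    cur <- temperatureGrid(matrix(roundTemperature(runif(48, 0, 8)), 6, 8),
                           pixelSize = 5)
    fut <- temperatureGrid(cur@values + roundTemperature(runif(48, 0, 2)),
                           pixelSize = 5)
    s <- interpolateSeries(cur, fut, nSteps = 7)
    T <- sample(cur@values, 1)
    cs <- buildFinalCost(T, s, params = p0)
    for (g in s@grids)
      expect_true(all(cs@costs <= buildIntermediateCost(T, g, p0) + 1e-12))
  }
})

test_that("widening the analogue half-width never increases a cost", {
  set.seed(12)
  temps <- matrix(roundTemperature(runif(100, 0, 10)), 10, 10)
  for (hw in c(0.25, 0.5, 1)) {
    narrow <- dissimilarityCost(5.0, temps, methodParams(halfWidth = hw))
    wide <- dissimilarityCost(5.0, temps, methodParams(halfWidth = 2 * hw))
    expect_true(all(wide <= narrow))
  }
})

test_that("increments enumerate the distinct rounded land temperatures, ascending", {
  g <- temperatureGrid(matrix(c(4.9, 5.0, 5.1, 5.0, 4.9, NA), 2, 3),
                       pixelSize = 5)
  expect_equal(enumerateIncrements(g), c(4.9, 5.0, 5.1))
  u <- temperatureGrid(matrix(7.2, 3, 3), pixelSize = 5)
  expect_equal(enumerateIncrements(u), 7.2)
  # count equals the number of distinct values; sources map to their own value
  set.seed(3)
  m <- temperatureGrid(matrix(roundTemperature(runif(200, -3, 3)), 10, 20),
                       pixelSize = 5)
  inc <- enumerateIncrements(m)
  expect_equal(length(inc), length(unique(as.vector(m@values))))
  expect_true(all(as.vector(m@values) %in% inc))
  allNA <- temperatureGrid(matrix(NA_real_, 2, 2), pixelSize = 5)
  expect_error(enumerateIncrements(allNA), "empty land mask|no land")
})
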