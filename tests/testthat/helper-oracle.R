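# Independent oracles, deliberately naive and separate from the package's
# igraph-backed implementation.

# O(V^2) single-source Dijkstra over the lattice with the declared edge
# weight: mean(endpoint costs) * length (pixel size cardinal, sqrt(2) *
# pixel size diagonal). NA cells are impassable.
oracleDijkstra <- function(costs, pixelSize, source, neighbourhood = 8) {
  nr <- nrow(costs); nc <- ncol(costs)
  offs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (neighbourhood == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  dist <- matrix(Inf, nr, nc)
  dist[is.na(costs)] <- NA
  visited <- matrix(FALSE, nr, nc)
  dist[source[1], source[2]] <- 0
  repeat {
    d <- dist
    d[visited] <- NA
    if (all(is.na(d) | !is.finite(d))) break
    u <- which(d == min(d, na.rm = TRUE))[1]
    ur <- (u - 1) %% nr + 1; uc <- (u - 1) %/% nr + 1
    visited[ur, uc] <- TRUE
    for (o in offs) {
      vr <- ur + o[1]; vc <- uc + o[2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      if (is.na(costs[vr, vc]) || visited[vr, vc]) next
      len <- if (o[1] != 0 && o[2] != 0) sqrt(2) * pixelSize else pixelSize
      w <- (costs[ur, uc] + costs[vr, vc]) / 2 * len
      if (dist[ur, uc] + w < dist[vr, vc]) dist[vr, vc] <- dist[ur, uc] + w
    }
  }
  dist
}

# Brute-force analogue scan: row/col matrix of pixels whose target-period
# temperature is within the half-width of the increment.
oracleAnalogues <- function(increment, targetValues, halfWidth = 0.25) {
  which(!is.na(targetValues) &
          abs(targetValues - increment) <= halfWidth + 1e-9, arr.ind = TRUE)
}

# Brute-force nearest-ED scan returning the distance and the (row, col)
# of the closest analogue under the row-major tie-break.
oracleNearest <- function(source, analoguesRC, pixelSize) {
  d <- pixelSize * sqrt((analoguesRC[, 1] - source[1])^2 +
                          (analoguesRC[, 2] - source[2])^2)
  best <- which(d <= min(d) + 1e-12)
  cand <- analoguesRC[best, , drop = FALSE]
  o <- order(cand[, 1], cand[, 2])[1]
  list(ed = min(d), destination = as.integer(cand[o, ]))
}

# Random strictly positive cost surface for property tests.
randomCosts <- function(nr, nc, maxCost = 5, naFrac = 0) {
  m <- matrix(sample.int(maxCost, nr * nc, replace = TRUE), nr, nc)
  if (naFrac > 0) {
    drop <- sample.int(nr * nc, round(naFrac * nr * nc))
    m[drop] <- NA
  }
  m
}
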