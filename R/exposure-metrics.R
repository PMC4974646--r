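# Per-pixel exposure metrics from least-cost climate trajectories.
#
# Forward mode: every land pixel of the current grid is a source; its
# increment is its own rounded temperature; analogues are future-grid
# pixels within the half-width; the composite cost surface for the
# increment is minimised over the current->future interpolated series.
# Reverse mode swaps the roles (sources on the future grid, analogues on
# the current grid, series reversed) and measures climatic accessibility.

#' Distance-based climate velocity
#'
#' @param distance distance (km); ED or MED.
#' @param elapsedTime elapsed time (years) between period midpoints.
#' @return velocity (km per year).
#' @examples
#' velocityFromDistance(90, 90) # 1
#' @export
velocityFromDistance <- function(distance, elapsedTime) {
  if (any(elapsedTime <= 0)) stop("elapsedTime must be > 0")
  distance / elapsedTime
}

#' Minimum cumulative exposure of a trajectory
#'
#' MCE = (accumulated cost - MED) / p, in degC: the cumulative tally of
#' climate dissimilarity encountered along the least-exposure trajectory.
#' MED is subtracted because the cost of 1 assigned to analogue pixels
#' means the accumulated cost implicitly contains the path distance;
#' dividing by the penalty converts cost units back to degC. Exactly zero
#' for a path that traverses only analogue (cost 1) pixels.
#'
#' @param trajectory a [Trajectory].
#' @param params a [MethodParams] (penalty p).
#' @return MCE in degC (>= 0).
#' @export
computeMCE <- function(trajectory, params = methodParams()) {
  (trajectory@accumulatedCost - trajectory@MED) / params@penalty
}

# Shared engine. src/dst are TemperatureGrids in source/destination roles.
.runEngine <- function(src, dst, params, direction,
                       returnTrajectories = FALSE) {
  checkCoRegistered(src, dst)
  nr <- nrow(src@values); nc <- ncol(src@values)
  water <- src@waterMask | dst@waterMask
  nodata <- src@nodataMask | dst@nodataMask
  land <- !nodata & !water
  islandMask <- matrix(FALSE, nr, nc)
  if (params@islandPolicy == "exclude") {
    islandMask <- excludeIslands(land, connectivity = params@neighbourhood,
                                 minArea = params@islandMinArea)
  }
  eligible <- land & !islandMask

  series <- interpolateSeries(src, dst, params@nSteps)
  srcV <- src@values
  dstV <- dst@values
  ps <- src@pixelSize

  lay <- function() matrix(NA_real_, nr, nc)
  layers <- list(ed = lay(), med = lay(), velocityED = lay(),
                 velocityMED = lay(), mce = lay(), ratio = lay(),
                 destRow = lay(), destCol = lay())
  flags <- list(noAnalogue = matrix(FALSE, nr, nc),
                islandExcluded = islandMask,
                isWater = water)
  trajs <- list()

  increments <- enumerateIncrements(src, params, eligible = eligible)
  for (T in increments) {
    srcMask <- eligible & !is.na(srcV) & abs(srcV - T) < params@incrementStep / 2
    if (!any(srcMask)) next
    ana <- analogueMask(T, dstV, params, eligible = eligible)
    srcRC <- which(srcMask, arr.ind = TRUE)
    anaRC <- which(ana, arr.ind = TRUE)
    if (!nrow(anaRC)) {
      flags$noAnalogue[srcMask] <- TRUE
      next
    }
    cs <- buildFinalCost(T, series, waterMask = water, params = params,
                         pixelSize = ps)
    cs@costs[nodata] <- NA_real_
    bg <- .buildCostGraph(cs@costs, ps, params@neighbourhood)
    sVids <- bg$vid[cbind(srcRC[, 1], srcRC[, 2])]
    aVids <- bg$vid[cbind(anaRC[, 1], anaRC[, 2])]
    dmat <- igraph::distances(bg$graph, v = sVids, to = aVids,
                              algorithm = "dijkstra")
    for (i in seq_len(nrow(srcRC))) {
      s <- as.integer(srcRC[i, ])
      accRow <- dmat[i, ]
      finite <- is.finite(accRow)
      if (!any(finite)) {
        flags$noAnalogue[s[1], s[2]] <- TRUE
        next
      }
      amin <- min(accRow[finite])
      tied <- which(finite & accRow <= amin + .eps * max(1, amin))
      cand <- anaRC[tied, , drop = FALSE]
      if (nrow(cand) > 1L) {
        dd <- sqrt((cand[, 1] - s[1])^2 + (cand[, 2] - s[2])^2)
        cand <- cand[dd <= min(dd) + .eps, , drop = FALSE]
        cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      }
      dest <- as.integer(cand[1, ])

      ne <- nearestEuclidean(s, anaRC, ps)
      ed <- ne$ed

      # delineate the trajectory for MED and MCE
      sVid <- bg$vid[s[1], s[2]]
      dVid <- bg$vid[dest[1], dest[2]]
      if (sVid == dVid) {
        pathRC <- matrix(s, 1, 2)
      } else {
        sp <- igraph::shortest_paths(bg$graph, from = sVid, to = dVid,
                                     output = "vpath",
                                     algorithm = "dijkstra")
        pathRC <- .cellRC(bg$vid, as.integer(sp$vpath[[1]]))
      }
      pa <- .pathAccounting(pathRC, cs@costs, ps)
      med <- pa$MED
      mce <- (pa$acc - med) / params@penalty
      layers$ed[s[1], s[2]] <- ed
      layers$med[s[1], s[2]] <- med
      layers$velocityED[s[1], s[2]] <- ed / params@elapsedTime
      layers$velocityMED[s[1], s[2]] <- med / params@elapsedTime
      layers$mce[s[1], s[2]] <- mce
      layers$ratio[s[1], s[2]] <-
        if (ed > 0) med / ed else if (med == 0) 1 else NA_real_
      layers$destRow[s[1], s[2]] <- dest[1]
      layers$destCol[s[1], s[2]] <- dest[2]
      if (returnTrajectories) {
        trajs[[sprintf("r%dc%d", s[1], s[2])]] <-
          new("Trajectory", source = s, destination = dest, path = pathRC,
              lengths = pa$lengths, costs = pa$costs,
              accumulatedCost = pa$acc, MED = med, increment = T)
      }
    }
  }
  new("ExposureResult", layers = layers, flags = flags,
      direction = direction, params = params, pixelSize = ps,
      xll = src@xll, yll = src@yll, trajectories = trajs)
}

#' Forward exposure analysis
#'
#' For every land source pixel of the current grid: build the composite
#' cost surface of its 0.1 degC increment, route to the least-accumulated-
#' cost future analogue, and derive ED, MED, the two velocities, MCE, the
#' velocity ratio, destination location and flags. Characterises the
#' potential exposure of organisms at each site under the warming interval.
#'
#' @param current,future co-registered [TemperatureGrid] pair.
#' @param params a [MethodParams].
#' @param returnTrajectories keep the per-source [Trajectory] objects
#'   (memory-heavy on large grids; default `FALSE`).
#' @return an [ExposureResult] with `direction = "forward"`.
#' @export
runForward <- function(current, future, params = methodParams(),
                       returnTrajectories = FALSE) {
  .runEngine(current, future, params, "forward", returnTrajectories)
}

#' Reverse accessibility analysis
#'
#' Role swap of [runForward()]: sources are future-grid pixels, analogue
#' sets are drawn from the current grid, and the interpolated series runs
#' future -> current. Characterises how climatically accessible each site
#' is — whether organisms living under the site's future climate can reach
#' it from where that climate occurs today.
#'
#' @inheritParams runForward
#' @return an [ExposureResult] with `direction = "reverse"`.
#' @export
runReverse <- function(current, future, params = methodParams(),
                       returnTrajectories = FALSE) {
  .runEngine(future, current, params, "reverse", returnTrajectories)
}

#' @describeIn ExposureResult-class extract a metric layer by name
#'   (`ed`, `med`, `velocityED`, `velocityMED`, `mce`, `ratio`, `destRow`,
#'   `destCol`).
#' @param x object.
#' @param name layer/flag name.
#' @export
setMethod("exposureLayer", "ExposureResult", function(x, name) {
  if (!name %in% names(x@layers))
    stop("unknown layer '", name, "'; available: ",
         paste(names(x@layers), collapse = ", "))
  x@layers[[name]]
})

#' @describeIn ExposureResult-class extract a flag layer (`noAnalogue`,
#'   `islandExcluded`, `isWater`).
#' @export
setMethod("exposureFlag", "ExposureResult", function(x, name) {
  if (!name %in% names(x@flags))
    stop("unknown flag '", name, "'")
  x@flags[[name]]
})

#' @describeIn ExposureResult-class tidy per-pixel table (one row per
#'   source pixel) of all metrics and flags.
#' @export
setMethod("exposureTable", "ExposureResult", function(x) {
  nr <- nrow(x@layers$med); nc <- ncol(x@layers$med)
  df <- data.frame(
    row = rep(seq_len(nr), nc),
    col = rep(seq_len(nc), each = nr),
    ed = as.vector(x@layers$ed),
    med = as.vector(x@layers$med),
    velocityED = as.vector(x@layers$velocityED),
    velocityMED = as.vector(x@layers$velocityMED),
    mce = as.vector(x@layers$mce),
    ratio = as.vector(x@layers$ratio),
    destRow = as.vector(x@layers$destRow),
    destCol = as.vector(x@layers$destCol),
    noAnalogue = as.vector(x@flags$noAnalogue),
    islandExcluded = as.vector(x@flags$islandExcluded),
    isWater = as.vector(x@flags$isWater)
  )
  df[!df$isWater & !(is.na(df$med) & !df$noAnalogue & !df$islandExcluded), ]
})

setMethod("show", "ExposureResult", function(object) {
  v <- object@layers$velocityMED
  m <- object@layers$mce
  ok <- !is.na(v)
  cat(sprintf("ExposureResult (%s): %d x %d px @ %g km\n", object@direction,
              nrow(v), ncol(v), object@pixelSize))
  if (any(ok)) {
    cat(sprintf("  velocity_MED: median %.3f km/yr   MCE = 0 on %.1f%% of routed pixels\n",
                stats::median(v[ok]), 100 * mean(m[!is.na(m)] == 0)))
  }
  cat(sprintf("  flags: %d no-analogue, %d island-excluded, %d water\n",
              sum(object@flags$noAnalogue), sum(object@flags$islandExcluded),
              sum(object@flags$isWater)))
})

#' Write all result layers as ESRI ASCII grids
#'
#' Metric layers are written as floating-point bands, flags as 0/1 integer
#' bands, alongside a tidy CSV of [exposureTable()].
#'
#' @param result an [ExposureResult].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default the direction).
#' @return invisibly the vector of files written.
#' @export
writeExposureResult <- function(result, dir, prefix = result@direction) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  geo <- function(m, f) writeGridLayer(m, f, pixelSize = result@pixelSize,
                                       xll = result@xll, yll = result@yll)
  for (nm in names(result@layers)) {
    f <- file.path(dir, sprintf("%s_%s.asc", prefix, nm))
    geo(result@layers[[nm]], f); paths <- c(paths, f)
  }
  for (nm in names(result@flags)) {
    f <- file.path(dir, sprintf("%s_flag_%s.asc", prefix, nm))
    geo(result@flags[[nm]] * 1L, f); paths <- c(paths, f)
  }
  f <- file.path(dir, sprintf("%s_table.csv", prefix))
  utils::write.csv(exposureTable(result), f, row.names = FALSE)
  paths <- c(paths, f)
  invisible(paths)
}
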