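# Bivariate exposure classification and island handling.

#' Identify island pixels
#'
#' Labels connected components of the land mask (default 8-connectivity,
#' matching routing); every component except the largest is an island.
#' With `minArea` set, any component smaller than `minArea` pixels is an
#' island instead. Exposure metrics are not interpretable for island
#' sources or destinations because the heavy water cost dominates their
#' trajectories.
#'
#' @param land logical matrix, `TRUE` on routable land.
#' @param connectivity 4 or 8.
#' @param minArea minimum mainland component area in pixels, or `NA` for
#'   the largest-component rule.
#' @return logical matrix, `TRUE` on island pixels.
#' @export
excludeIslands <- function(land, connectivity = 8, minArea = NA) {
  land <- as.matrix(land)
  if (!any(land)) return(matrix(FALSE, nrow(land), ncol(land)))
  costs <- matrix(NA_real_, nrow(land), ncol(land))
  costs[land] <- 1
  bg <- .buildCostGraph(costs, pixelSize = 1, neighbourhood = connectivity)
  comp <- igraph::components(bg$graph)
  lab <- matrix(NA_integer_, nrow(land), ncol(land))
  lab[land] <- comp$membership[bg$vid[land]]
  island <- matrix(FALSE, nrow(land), ncol(land))
  if (is.na(minArea)) {
    main <- which.max(comp$csize)
    island[land] <- lab[land] != main
  } else {
    small <- which(comp$csize < minArea)
    island[land] <- lab[land] %in% small
  }
  island
}

#' Flag sources whose source or destination pixel sits on an island
#'
#' Applies the exclusion rule to a result computed with
#' `islandPolicy = "keep"`: a source pixel is flagged when it lies on an
#' island or when its recorded destination does. Flagged pixels should be
#' omitted from maps and statistics.
#'
#' @param result an [ExposureResult].
#' @param islandMask logical matrix from [excludeIslands()].
#' @return the result with its `islandExcluded` flag updated and metric
#'   layers blanked (`NA`) on flagged pixels.
#' @export
flagIslands <- function(result, islandMask) {
  dr <- result@layers$destRow
  dc <- result@layers$destCol
  destIsland <- matrix(FALSE, nrow(dr), ncol(dr))
  ok <- !is.na(dr)
  destIsland[ok] <- islandMask[cbind(dr[ok], dc[ok])]
  flag <- islandMask | destIsland
  result@flags$islandExcluded <- result@flags$islandExcluded | flag
  for (nm in names(result@layers)) result@layers[[nm]][flag] <- NA_real_
  result
}

#' Bivariate velocity/MCE exposure classification
#'
#' Four classes from crossing velocity_MED with MCE: MCE = 0 is "low"
#' exposure and MCE > 0 "high" (MCE distributions are strongly
#' right-skewed and zero-inflated); the velocity boundary is the median of
#' the valid velocity_MED values (flagged pixels excluded before the
#' median is taken). Classes: 1 = low velocity / low MCE, 2 = low / high,
#' 3 = high / low, 4 = high / high; velocity at or below the median counts
#' as low.
#'
#' @param velocityMED numeric matrix, or an [ExposureResult] (in which case
#'   `mce` is taken from it too and flagged pixels are excluded).
#' @param mce numeric matrix of MCE values (degC).
#' @param exclude optional logical matrix of pixels to exclude.
#' @return list with `classes` (integer matrix, `NA` where excluded or
#'   unrouted), `velocityThreshold` and `mceThreshold` (always 0).
#' @export
classifyBivariate <- function(velocityMED, mce = NULL, exclude = NULL) {
  if (is(velocityMED, "ExposureResult")) {
    res <- velocityMED
    velocityMED <- res@layers$velocityMED
    mce <- res@layers$mce
    exclude <- res@flags$noAnalogue | res@flags$islandExcluded |
      res@flags$isWater
  }
  if (is.null(mce)) stop("mce layer required")
  valid <- !is.na(velocityMED) & !is.na(mce)
  if (!is.null(exclude)) valid <- valid & !exclude
  if (!any(valid)) stop("no valid pixels to classify (all NA or excluded)")
  vmed <- stats::median(velocityMED[valid])
  highV <- velocityMED > vmed
  highM <- mce > 0
  cls <- matrix(NA_integer_, nrow(velocityMED), ncol(velocityMED))
  cls[valid] <- 1L + 2L * highV[valid] + 1L * highM[valid]
  list(classes = cls, velocityThreshold = vmed, mceThreshold = 0)
}

#' Write a classification raster with a JSON threshold sidecar
#'
#' @param classification result of [classifyBivariate()].
#' @param path output `.asc` path (integer band); thresholds go to
#'   `<path>.json`.
#' @param pixelSize,xll,yll georeferencing.
#' @return invisibly `path`.
#' @export
writeClassification <- function(classification, path, pixelSize,
                                xll = 0, yll = 0) {
  writeGridLayer(classification$classes, path, pixelSize = pixelSize,
                 xll = xll, yll = yll)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(velocityThreshold = classification$velocityThreshold,
           mceThreshold = classification$mceThreshold),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
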