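# Parameterised benchmark landscapes with known ground truth.
#
# Three families cover the geometries the method must handle: a flat
# latitudinal gradient (analytic poleward displacement, MCE = 0), a
# two-ridge mountain field built from an elevation profile and a lapse
# rate (trajectories forced across a warm valley with a known
# dissimilarity band, hence a closed-form MCE), and a north-pointing
# peninsula with water on three sides (routes forced south, water penalty
# engaged). All generators are deterministic; optional Gaussian noise is
# off by default so worked-example fixtures are exactly constructible.

.mkPair <- function(curVals, warming, pixelSize, waterMask = NULL,
                    noiseSD = 0, seed = NULL) {
  if (noiseSD > 0) {
    if (!is.null(seed)) set.seed(seed)
    curVals <- curVals + matrix(stats::rnorm(length(curVals), 0, noiseSD),
                                nrow(curVals))
  }
  cur <- temperatureGrid(curVals, pixelSize = pixelSize,
                         waterMask = waterMask)
  fut <- temperatureGrid(cur@values + warming, pixelSize = pixelSize,
                         waterMask = waterMask)
  list(current = cur, future = fut)
}

#' Flat latitudinal temperature gradient under uniform warming
#'
#' Temperature increases away from the pole (row 1 is the poleward edge)
#' at `gradient` degC per pixel; the future grid is the current grid plus
#' a uniform `warming`. Every pixel's exact-match future analogue lies
#' `warming/gradient` pixels poleward; with the analogue half-width the
#' nearest member of the analogue set is `(warming - halfWidth)/gradient`
#' pixels poleward. On this terrain least-exposure trajectories traverse
#' only analogue climate, so MCE = 0 and velocity_MED = velocity_ED.
#'
#' @param nrow,ncol grid dimensions.
#' @param pixelSize pixel edge length (km).
#' @param gradient north-south gradient (degC per pixel, > 0 = warmer
#'   southward); must be nonzero.
#' @param warming uniform warming (degC).
#' @param baseTemp temperature of row 1 (degC).
#' @param noiseSD optional Gaussian noise SD (degC; default 0).
#' @param seed RNG seed used when `noiseSD > 0`.
#' @return list with `current`, `future` ([TemperatureGrid]) and `truth`
#'   (analytic displacements, in pixels and km).
#' @export
makeFlatGradient <- function(nrow = 50, ncol = 50, pixelSize = 5,
                             gradient = 0.05, warming = 1.0, baseTemp = 5,
                             noiseSD = 0, seed = NULL) {
  if (gradient == 0)
    stop("gradient must be nonzero: a flat field has no analogue direction")
  vals <- matrix(baseTemp + gradient * (seq_len(nrow) - 1), nrow, ncol)
  pair <- .mkPair(vals, warming, pixelSize, noiseSD = noiseSD, seed = seed)
  pair$truth <- list(
    exactOffsetPixels = warming / gradient,
    exactOffsetKm = warming / gradient * pixelSize,
    expectedMCE = 0
  )
  pair
}

#' Two-ridge mountain field with a warm valley
#'
#' Builds temperature from an elevation profile times a lapse rate:
#' `T = baseTemp + baseGradient * (row - 1) - lapseRate * elevation[col]`.
#' Two flat-topped ridges flank a valley `valleyWidth` pixels wide whose
#' floor is `valleyDissim` degC warmer than the first ridge top. The
#' second ridge is `warming` degC colder than the first, so after uniform
#' warming the only analogues of first-ridge sources sit on the second
#' ridge, and every least-exposure trajectory from the first ridge crosses
#' the valley's dissimilarity band. With the defaults (valleyDissim 0.5,
#' one-pixel valley, 5-km pixels, penalty 2) the crossing traverses one
#' cost-2 pixel and MCE = 2.5 degC; a two-pixel valley doubles it.
#'
#' @param nrow number of rows.
#' @param ridgeWidth width (columns) of each ridge top.
#' @param valleyWidth width (columns) of the valley floor.
#' @param pixelSize pixel edge length (km).
#' @param topTemp current temperature of the first ridge top (degC).
#' @param valleyDissim valley floor dissimilarity above `topTemp` (degC);
#'   0.5 places the valley in the second cost band.
#' @param warming uniform warming (degC); also the ridge-to-ridge offset.
#' @param baseGradient optional north-south gradient (degC per pixel).
#' @param lapseRate lapse rate (degC per m) used to derive the elevation
#'   profile.
#' @param noiseSD,seed optional noise as in [makeFlatGradient()].
#' @return list with `current`, `future`, `truth` (valley cost band and the
#'   closed-form expected MCE at penalty 2) and `elevation` (profile, m).
#' @export
makeRidgeValley <- function(nrow = 7, ridgeWidth = 3, valleyWidth = 1,
                            pixelSize = 5, topTemp = 5.3, valleyDissim = 0.5,
                            warming = 1.0, baseGradient = 0,
                            lapseRate = 0.0065, noiseSD = 0, seed = NULL) {
  if (valleyDissim <= 0)
    warning("degenerate profile: valley is not warmer than the ridge tops")
  ncol <- 2 * ridgeWidth + valleyWidth
  # elevations that reproduce the target temperatures under the lapse rate
  elevA <- valleyDissim / lapseRate
  elevB <- (valleyDissim + warming) / lapseRate
  elev <- c(rep(elevA, ridgeWidth), rep(0, valleyWidth),
            rep(elevB, ridgeWidth))
  baseTemp <- topTemp + valleyDissim # valley floor (elevation 0)
  vals <- outer(baseGradient * (seq_len(nrow) - 1),
                baseTemp - lapseRate * elev, "+")
  pair <- .mkPair(vals, warming, pixelSize, noiseSD = noiseSD, seed = seed)
  params <- methodParams()
  valleyCost <- dissimilarityCost(topTemp, topTemp + valleyDissim, params)
  pair$truth <- list(
    valleyCostBand = valleyCost,
    expectedMCE = (valleyCost - 1) * valleyWidth * pixelSize / params@penalty,
    sourceCols = seq_len(ridgeWidth),
    valleyCols = ridgeWidth + seq_len(valleyWidth),
    destCols = ridgeWidth + valleyWidth + seq_len(ridgeWidth)
  )
  pair$elevation <- elev
  pair
}

#' North-pointing peninsula with water on three sides
#'
#' A land tongue points north (row 1 end) into open water, attached to a
#' mainland band in the south; temperature follows a latitudinal gradient
#' under uniform warming, and a single high-elevation summit pixel on the
#' mainland is the only place whose future temperature matches the
#' peninsula tip's current climate. Trajectories from the tip must run
#' south down the tongue (or cross water at the water cost), accumulating
#' exposure through the warmer mainland rows, so the tip's destination
#' lies south of it and its MCE is positive. The all-land control
#' (`allLand = TRUE`) keeps the temperatures but removes the water,
#' opening a shorter diagonal corridor and reducing the tip's MCE. An
#' optional one-pixel island sits in the western bay.
#'
#' @param nrow,ncol grid dimensions.
#' @param pixelSize pixel edge length (km).
#' @param baseTemp temperature of row 1 (degC).
#' @param gradient north-south gradient (degC per pixel southward).
#' @param warming uniform warming (degC).
#' @param tongueRows,tongueCols rows/columns occupied by the tongue.
#' @param summit `c(row, col)` of the cold summit pixel (mainland).
#' @param island `c(row, col)` of a one-pixel island in the bay, or `NULL`.
#' @param allLand drop the water mask (control scenario).
#' @return list with `current`, `future`, `truth` (tip and summit
#'   locations).
#' @export
makePeninsula <- function(nrow = 15, ncol = 15, pixelSize = 5, baseTemp = 5,
                          gradient = 0.2, warming = 1.0,
                          tongueRows = 1:8, tongueCols = 7:9,
                          summit = c(13, 3), island = c(3, 3),
                          allLand = FALSE) {
  vals <- matrix(baseTemp + gradient * (seq_len(nrow) - 1), nrow, ncol)
  # summit: the only pixel whose future temperature equals the tip's current
  vals[summit[1], summit[2]] <- baseTemp - warming
  water <- matrix(FALSE, nrow, ncol)
  if (!allLand) {
    water[tongueRows, ] <- TRUE
    water[tongueRows, tongueCols] <- FALSE
    if (!is.null(island)) water[island[1], island[2]] <- FALSE
  }
  pair <- .mkPair(vals, warming, pixelSize, waterMask = water)
  pair$truth <- list(
    tip = c(min(tongueRows), tongueCols[ceiling(length(tongueCols) / 2)]),
    summit = summit,
    island = if (allLand) NULL else island
  )
  pair
}

#' Ground-truth sidecar for a generated fixture
#'
#' Serialises the `truth` entry of a generator's return value as JSON next
#' to exported fixture rasters.
#'
#' @param fixture a generator return value.
#' @param path output JSON path.
#' @return invisibly `path`.
#' @export
writeFixtureTruth <- function(fixture, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write fixture truth")
  jsonlite::write_json(fixture$truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
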