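#' @import methods
NULL

#' Temperature raster with georeferencing and masks
#'
#' A single-band mean annual temperature raster on an equal-area projected
#' grid with square pixels. Values are stored in degrees Celsius, rounded to
#' the nearest 0.1 degree on ingest (half away from zero) so that analogue-bin
#' membership is reproducible. Two logical masks ride along: `nodataMask`
#' marks pixels that never participate in routing or analogue search, and
#' `waterMask` marks open water, which is excluded from sources and analogue
#' sets but remains routable at the (heavy) water cost.
#'
#' @slot values numeric matrix of temperatures (degrees C); `NA` at nodata.
#' @slot pixelSize positive scalar, pixel edge length in km (pixels square).
#' @slot xll,yll numeric, coordinates of the lower-left corner of the grid in
#'   the projected system, same units as `pixelSize`.
#' @slot nodataMask logical matrix, `TRUE` where no data.
#' @slot waterMask logical matrix, `TRUE` over open water.
#' @name TemperatureGrid-class
#' @aliases TemperatureGrid
#' @exportClass TemperatureGrid
setClass("TemperatureGrid",
  representation(
    values = "matrix",
    pixelSize = "numeric",
    xll = "numeric",
    yll = "numeric",
    nodataMask = "matrix",
    waterMask = "matrix"
  )
)

setValidity("TemperatureGrid", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a single positive number (km)")
  if (!identical(dim(v), dim(object@nodataMask)) ||
      !identical(dim(v), dim(object@waterMask)))
    msgs <- c(msgs, "values, nodataMask and waterMask must share dimensions")
  if (!is.logical(object@nodataMask) || !is.logical(object@waterMask))
    msgs <- c(msgs, "masks must be logical matrices")
  if (any(is.na(v) & !object@nodataMask))
    msgs <- c(msgs, "NA values outside the nodata mask")
  ok <- !object@nodataMask
  if (any(!is.finite(v[ok])))
    msgs <- c(msgs, "non-finite temperatures outside the nodata mask")
  # ingest rounding contract: multiples of 0.1
  if (any(abs(v[ok] * 10 - round(v[ok] * 10)) > 1e-6))
    msgs <- c(msgs, "temperatures must be multiples of 0.1 degC (ingest rounding)")
  if (length(msgs)) msgs else TRUE
})

#' Method parameters for trajectory-based exposure analysis
#'
#' Bundles every tunable of the analysis. Defaults follow the published
#' method: analogue half-width 0.25 degC (bin width 0.5 degC), temperature
#' increments of 0.1 degC, dissimilarity penalty P = 2 dimensionless units per
#' degC (one cost unit per 0.5 degC band), water cost 5000, 31 linearly
#' interpolated temperature grids, 90 years elapsed time, 8-connected moves.
#'
#' @slot halfWidth analogue half-width (degC); a future pixel is an analogue
#'   of increment T when |T_future - T| <= halfWidth.
#' @slot incrementStep spacing of the temperature increments (degC).
#' @slot penalty dissimilarity penalty P (dimensionless units per degC).
#' @slot waterCost cost assigned to open-water pixels in final cost surfaces.
#' @slot nSteps number of interpolated temperature grids (>= 2).
#' @slot elapsedTime years between the current and future period midpoints.
#' @slot neighbourhood 4 or 8, lattice connectivity for routing.
#' @slot costForm "integer" (banded, canonical) or "linear" (P*|dT|+1).
#' @slot islandPolicy "exclude" (islands dropped from sources and analogue
#'   sets, flagged) or "keep".
#' @slot islandMinArea minimum component area (pixels) to count as mainland;
#'   `NA` means only the single largest component is mainland.
#' @name MethodParams-class
#' @aliases MethodParams
#' @exportClass MethodParams
setClass("MethodParams",
  representation(
    halfWidth = "numeric",
    incrementStep = "numeric",
    penalty = "numeric",
    waterCost = "numeric",
    nSteps = "numeric",
    elapsedTime = "numeric",
    neighbourhood = "numeric",
    costForm = "character",
    islandPolicy = "character",
    islandMinArea = "numeric"
  ),
  prototype(
    halfWidth = 0.25, incrementStep = 0.1, penalty = 2, waterCost = 5000,
    nSteps = 31, elapsedTime = 90, neighbourhood = 8, costForm = "integer",
    islandPolicy = "exclude", islandMinArea = NA_real_
  )
)

setValidity("MethodParams", function(object) {
  msgs <- character()
  scalar <- function(x) length(x) == 1L && is.finite(x)
  if (!scalar(object@halfWidth) || object@halfWidth <= 0)
    msgs <- c(msgs, "halfWidth must be > 0")
  if (!scalar(object@incrementStep) || object@incrementStep <= 0)
    msgs <- c(msgs, "incrementStep must be > 0")
  if (!scalar(object@penalty) || object@penalty <= 0)
    msgs <- c(msgs, "penalty must be > 0")
  if (!scalar(object@nSteps) || object@nSteps < 2 ||
      object@nSteps != round(object@nSteps))
    msgs <- c(msgs, "nSteps must be an integer >= 2")
  if (!scalar(object@elapsedTime) || object@elapsedTime <= 0)
    msgs <- c(msgs, "elapsedTime must be > 0 (years)")
  if (!scalar(object@neighbourhood) || !object@neighbourhood %in% c(4, 8))
    msgs <- c(msgs, "neighbourhood must be 4 or 8")
  if (!object@costForm %in% c("integer", "linear"))
    msgs <- c(msgs, "costForm must be 'integer' or 'linear'")
  if (!object@islandPolicy %in% c("exclude", "keep"))
    msgs <- c(msgs, "islandPolicy must be 'exclude' or 'keep'")
  if (scalar(object@waterCost)) {
    # water must dominate any achievable land cost so trajectories avoid it
    if (object@waterCost <= 1)
      msgs <- c(msgs, "waterCost must exceed the analogue cost of 1")
  } else msgs <- c(msgs, "waterCost must be a single finite number")
  if (length(msgs)) msgs else TRUE
})

#' Linearly interpolated temperature series
#'
#' Ordered temperature fields between the current and future periods, used to
#' let trajectories follow isotherms as the climate warms. The first grid is
#' exactly the current field and the last exactly the future field;
#' intermediate grids are convex combinations and are deliberately not
#' re-rounded to 0.1 degC.
#'
#' @slot grids list of numeric matrices, length `nSteps`.
#' @slot years numeric vector of nominal years, strictly increasing.
#' @name InterpolatedSeries-class
#' @aliases InterpolatedSeries
#' @exportClass InterpolatedSeries
setClass("InterpolatedSeries",
  representation(grids = "list", years = "numeric")
)

setValidity("InterpolatedSeries", function(object) {
  msgs <- character()
  if (length(object@grids) < 2L)
    msgs <- c(msgs, "series needs at least two grids")
  if (length(object@years) != length(object@grids))
    msgs <- c(msgs, "years and grids lengths differ")
  if (length(object@years) > 1L && any(diff(object@years) <= 0))
    msgs <- c(msgs, "years must be strictly increasing")
  d <- dim(object@grids[[1L]])
  if (!all(vapply(object@grids, function(g) identical(dim(g), d), logical(1))))
    msgs <- c(msgs, "all grids must share dimensions")
  if (length(msgs)) msgs else TRUE
})

#' Composite cost surface for one temperature increment
#'
#' Integer dissimilarity costs for routing the isotherm `increment`:
#' the elementwise minimum, over all interpolated temperature grids, of the
#' banded dissimilarity cost, with water pixels overridden to the water cost.
#' Land costs are >= 1; a pixel that at any time lies within the analogue
#' half-width of the increment has cost exactly 1.
#'
#' @slot increment the 0.1-degC temperature increment (degC).
#' @slot costs numeric matrix of costs; `NA` at nodata.
#' @slot nSteps number of interpolated grids the composite minimised over.
#' @name CostSurface-class
#' @aliases CostSurface
#' @exportClass CostSurface
setClass("CostSurface",
  representation(increment = "numeric", costs = "matrix", nSteps = "numeric",
                 pixelSize = "numeric")
)

setValidity("CostSurface", function(object) {
  msgs <- character()
  ok <- !is.na(object@costs)
  if (any(object@costs[ok] < 1))
    msgs <- c(msgs, "costs must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Single-source accumulated-cost field
#'
#' Result of a single-source least-cost (Dijkstra) run from a source pixel
#' over the lattice graph of a cost surface. Edge weights are the arithmetic
#' mean of the endpoint costs times the edge length (pixel size for cardinal
#' moves, sqrt(2) times pixel size for diagonal moves), so on an all-analogue
#' surface accumulated cost equals travelled distance. Keeps the graph so
#' least-cost paths can be delineated afterwards.
#'
#' @slot acc numeric matrix of accumulated costs (`Inf` unreachable, `NA`
#'   nodata).
#' @slot source integer c(row, col) of the source pixel.
#' @slot graph the igraph lattice graph used.
#' @slot vid integer matrix mapping cells to graph vertex ids (`NA` nodata).
#' @slot costs the cost matrix routed over.
#' @slot pixelSize pixel edge length (km).
#' @slot neighbourhood 4 or 8.
#' @name AccumulatedCost-class
#' @aliases AccumulatedCost
#' @exportClass AccumulatedCost
setClass("AccumulatedCost",
  representation(acc = "matrix", source = "integer", graph = "ANY",
                 vid = "matrix", costs = "matrix", pixelSize = "numeric",
                 neighbourhood = "numeric")
)

#' A least-exposure climate trajectory
#'
#' Ordered pixel path from a source to its least-accumulated-cost future
#' analogue. Per-pixel traversal lengths `lengths` assign each pixel half of
#' each incident path edge (endpoints get a single half-edge), which makes the
#' accounting identity sum(cost_i * l_i) = accumulated cost exact and
#' sum(l_i) = MED the minimum exposure distance.
#'
#' @slot source,destination integer c(row, col).
#' @slot path integer matrix, one row per pixel, columns row/col.
#' @slot lengths per-pixel traversal lengths l_i (km).
#' @slot costs per-pixel costs along the path.
#' @slot accumulatedCost dimensionless accumulated cost.
#' @slot MED minimum exposure distance (km), sum of `lengths`.
#' @slot increment temperature increment routed (degC).
#' @name Trajectory-class
#' @aliases Trajectory
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    source = "integer", destination = "integer", path = "matrix",
    lengths = "numeric", costs = "numeric", accumulatedCost = "numeric",
    MED = "numeric", increment = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  n <- nrow(object@path)
  if (length(object@lengths) != n || length(object@costs) != n)
    msgs <- c(msgs, "lengths/costs must match path length")
  if (n > 0 && abs(sum(object@lengths) - object@MED) > 1e-6 * max(1, object@MED))
    msgs <- c(msgs, "MED must equal sum of per-pixel lengths")
  if (length(msgs)) msgs else TRUE
})

#' Per-pixel exposure result layers
#'
#' Raster stack of the exposure metrics for one direction of analysis.
#' Layers: `ed` and `med` (km), `velocityED` and `velocityMED` (km/yr),
#' `mce` (degC), `ratio` (velocityMED/velocityED, dimensionless), and the
#' destination location (`destRow`, `destCol`). Flags mark pixels with no
#' analogue (or unreachable analogues), island-excluded pixels, and water.
#' Flagged pixels hold `NA` in the metric layers.
#'
#' @slot layers named list of numeric matrices.
#' @slot flags named list of logical matrices
#'   (`noAnalogue`, `islandExcluded`, `isWater`).
#' @slot direction "forward" (exposure) or "reverse" (accessibility).
#' @slot params the [MethodParams] used.
#' @slot pixelSize pixel edge length (km).
#' @slot xll,yll georeferencing inherited from the inputs.
#' @slot trajectories list of [Trajectory] objects (possibly empty), named by
#'   cell index.
#' @name ExposureResult-class
#' @aliases ExposureResult
#' @exportClass ExposureResult
setClass("ExposureResult",
  representation(
    layers = "list", flags = "list", direction = "character",
    params = "MethodParams", pixelSize = "numeric",
    xll = "numeric", yll = "numeric", trajectories = "list"
  )
)

setValidity("ExposureResult", function(object) {
  need <- c("ed", "med", "velocityED", "velocityMED", "mce", "ratio",
            "destRow", "destCol")
  if (!all(need %in% names(object@layers)))
    return(paste("missing layers:",
                 paste(setdiff(need, names(object@layers)), collapse = ", ")))
  if (!all(c("noAnalogue", "islandExcluded", "isWater") %in%
           names(object@flags)))
    return("missing flag layers")
  if (!object@direction %in% c("forward", "reverse"))
    return("direction must be 'forward' or 'reverse'")
  TRUE
})
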