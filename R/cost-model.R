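# Dissimilarity cost surfaces, one per 0.1 degC temperature increment.
#
# Costs are integer bands of climate dissimilarity: analogues (within the
# half-width of the increment) cost 1 so that cost equals distance along
# analogue terrain, and each further band of one bin width adds 1 (the
# banded form of cost = P * |dT| + 1 with P = 2 per degC and 0.5 degC bins).
# The final surface for an increment is the elementwise minimum over the
# interpolated series — a pixel is charged the cheapest it ever is during
# the interval — with open water then overridden to the water cost.

.eps <- 1e-9

#' Integer dissimilarity cost of a pixel temperature against an increment
#'
#' Banded form (default): cost 1 when `|T - t|` is within the analogue
#' half-width, then `1 + ceiling((|T - t| - halfWidth)/(2*halfWidth))`:
#' successive bands one bin width (0.5 degC at defaults) wide, upper edge
#' inclusive, e.g. dissimilarity in (0.25, 0.75] costs 2. With
#' `costForm = "linear"` the continuous form `P * |T - t| + 1` is used
#' instead (for sensitivity analysis).
#'
#' @param increment temperature increment of interest T (degC).
#' @param temp pixel temperature(s) t_i (degC); vectorised.
#' @param params a [MethodParams].
#' @return numeric cost(s) >= 1; `NA` propagated.
#' @examples
#' p <- methodParams()
#' dissimilarityCost(5.3, 5.3, p)  # 1
#' dissimilarityCost(5.3, 5.8, p)  # 2
#' dissimilarityCost(5.3, 6.3, p)  # 3
#' @export
dissimilarityCost <- function(increment, temp, params = methodParams()) {
  d <- abs(temp - increment)
  hw <- params@halfWidth
  if (params@costForm == "linear") {
    cost <- params@penalty * d + 1
    cost[d <= hw + .eps] <- 1
    return(cost)
  }
  band <- ceiling((d - hw) / (2 * hw) - .eps)
  cost <- 1 + pmax(band, 0)
  cost[d <= hw + .eps] <- 1
  cost
}

#' Intermediate cost surface for one interpolated temperature grid
#'
#' Elementwise [dissimilarityCost()] of a single temperature field against
#' the increment; nodata (`NA`) propagates.
#'
#' @param increment temperature increment T (degC).
#' @param tempValues numeric matrix of temperatures for one time step.
#' @param params a [MethodParams].
#' @return numeric cost matrix.
#' @export
buildIntermediateCost <- function(increment, tempValues,
                                  params = methodParams()) {
  m <- dissimilarityCost(increment, tempValues, params)
  dim(m) <- dim(tempValues)
  m
}

#' Final composite cost surface for one increment
#'
#' The elementwise minimum of the intermediate cost surfaces across all
#' interpolated time steps (a pixel that at any time lies within the
#' analogue half-width of the increment costs 1 — trajectories can follow
#' the climate as it warms, and destination analogues always cost 1 because
#' the last grid is the future field), with water pixels then overridden to
#' the water cost.
#'
#' @param increment temperature increment T (degC).
#' @param series an [InterpolatedSeries].
#' @param waterMask logical matrix of open-water pixels (or `NULL`).
#' @param params a [MethodParams].
#' @return a [CostSurface].
#' @param pixelSize pixel edge length (km), recorded on the surface.
#' @export
buildFinalCost <- function(increment, series, waterMask = NULL,
                           params = methodParams(), pixelSize = NA_real_) {
  costs <- buildIntermediateCost(increment, series@grids[[1L]], params)
  for (k in seq_along(series@grids)[-1L]) {
    costs <- pmin(costs,
                  buildIntermediateCost(increment, series@grids[[k]], params))
  }
  if (!is.null(waterMask)) costs[waterMask] <- params@waterCost
  new("CostSurface", increment = increment, costs = costs,
      nSteps = length(series@grids), pixelSize = as.numeric(pixelSize))
}

setMethod("show", "CostSurface", function(object) {
  rng <- suppressWarnings(range(object@costs, na.rm = TRUE))
  cat(sprintf("CostSurface: increment %.1f degC, %d x %d, costs %g .. %g (min over %d steps)\n",
              object@increment, nrow(object@costs), ncol(object@costs),
              rng[1], rng[2], as.integer(object@nSteps)))
})

#' Enumerate the temperature increments present in a grid
#'
#' One routing problem is solved per 0.1 degC increment; the increments are
#' the distinct rounded temperatures among land source pixels, ascending.
#' Each source pixel belongs to exactly one increment: its own rounded
#' value.
#'
#' @param grid a [TemperatureGrid] (the source-period grid).
#' @param params a [MethodParams].
#' @param eligible optional logical matrix restricting source pixels
#'   (default: the grid's land mask).
#' @return ascending numeric vector of increments (degC).
#' @export
enumerateIncrements <- function(grid, params = methodParams(),
                                eligible = NULL) {
  if (is.null(eligible)) eligible <- landMask(grid)
  v <- grid@values[eligible & !grid@nodataMask]
  if (!length(v)) stop("no land source pixels: empty land mask")
  sort(unique(roundTemperature(v)))
}

#' Analogue set of an increment on a target grid
#'
#' Logical matrix of pixels whose target-period temperature lies within the
#' analogue half-width of the increment, restricted to eligible land.
#'
#' @param increment temperature increment T (degC).
#' @param targetValues numeric matrix of target-period temperatures.
#' @param params a [MethodParams].
#' @param eligible logical matrix of pixels allowed as analogues.
#' @return logical matrix.
#' @export
analogueMask <- function(increment, targetValues, params = methodParams(),
                         eligible = NULL) {
  m <- !is.na(targetValues) &
    abs(targetValues - increment) <= params@halfWidth + .eps
  if (!is.null(eligible)) m <- m & eligible
  m
}
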