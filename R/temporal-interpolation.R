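# Linear interpolation of the temperature field through time.
#
# Trajectories must be able to follow an isotherm as it moves: a pixel that
# is dissimilar today but warms through the increment during the interval
# should cost 1 somewhere along the series, and the destination analogue
# (defined on the future grid) must cost 1 in the last grid. Hence the cost
# composite in cost-model.R minimises over this series.

#' Interpolate temperature grids between the current and future periods
#'
#' Produces `nSteps` temperature fields assuming a linear per-pixel trend:
#' grid k (k = 0..nSteps-1) is the convex combination
#' `(1 - f) * current + f * future` with `f = k/(nSteps-1)`, so the first
#' grid is exactly the current field and the last exactly the future field.
#' Intermediate grids are not re-rounded to 0.1 degC (only ingested inputs
#' are); the banded cost function handles arbitrary precision, and
#' re-rounding would create avoidable bin-boundary artefacts.
#'
#' @param current,future co-registered [TemperatureGrid] pair.
#' @param nSteps number of grids (>= 2); the default 31 spans 90 years in
#'   roughly three-year increments.
#' @param startYear,endYear nominal years carried for reporting only.
#' @return an [InterpolatedSeries].
#' @examples
#' cur <- temperatureGrid(matrix(5, 2, 2), pixelSize = 5)
#' fut <- temperatureGrid(matrix(9.5, 2, 2), pixelSize = 5)
#' s <- interpolateSeries(cur, fut, nSteps = 31)
#' s@grids[[16]][1, 1] # midpoint: 7.25
#' @export
interpolateSeries <- function(current, future, nSteps = 31,
                              startYear = 1995, endYear = 2085) {
  checkCoRegistered(current, future)
  nSteps <- as.integer(nSteps)
  if (nSteps < 2) stop("nSteps must be >= 2")
  cv <- current@values
  fv <- future@values
  f <- seq(0, 1, length.out = nSteps)
  grids <- lapply(f, function(fk) (1 - fk) * cv + fk * fv)
  new("InterpolatedSeries", grids = grids,
      years = seq(startYear, endYear, length.out = nSteps))
}

setMethod("show", "InterpolatedSeries", function(object) {
  cat(sprintf("InterpolatedSeries: %d grids, nominal years %g .. %g\n",
              length(object@grids), object@years[1],
              object@years[length(object@years)]))
})

#' Export an interpolated series for inspection
#'
#' Writes one ESRI ASCII grid per step, suffixed with the step index.
#'
#' @param series an [InterpolatedSeries].
#' @param prefix output path prefix; files are `<prefix>_<k>.asc`.
#' @param pixelSize,xll,yll georeferencing for the written layers.
#' @return invisibly the vector of paths written.
#' @export
writeSeries <- function(series, prefix, pixelSize, xll = 0, yll = 0) {
  paths <- character(length(series@grids))
  for (k in seq_along(series@grids)) {
    paths[k] <- sprintf("%s_%02d.asc", prefix, k)
    writeGridLayer(series@grids[[k]], paths[k], pixelSize = pixelSize,
                   xll = xll, yll = yll)
  }
  invisible(paths)
}
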