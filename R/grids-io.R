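# Raster ingest/export and the TemperatureGrid data model.
#
# Grids are exchanged as ESRI ASCII grids (.asc): a plain-text header
# (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
# the matrix in row-major order, north row first. The format carries square
# pixels by construction; projected units are metres or kilometres and are
# converted to km on ingest. Geographic (degree) grids are rejected: the
# method needs planar distances on an equal-area grid.

#' Round temperatures to the nearest 0.1 degC, half away from zero
#'
#' Ingest normalisation: analogue-bin membership depends on temperatures
#' being exact multiples of the 0.1 degC increment, so all inputs are
#' rounded identically (half away from zero, not banker's rounding).
#' Idempotent.
#'
#' @param x numeric vector/matrix of temperatures (degC).
#' @return `x` rounded to multiples of 0.1.
#' @examples
#' roundTemperature(c(5.34, 5.35, -5.35)) # 5.3 5.4 -5.4
#' @export
roundTemperature <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Construct a TemperatureGrid
#'
#' @param values numeric matrix of temperatures (degC); `NA` marks nodata.
#' @param pixelSize pixel edge length in km (square pixels).
#' @param xll,yll lower-left corner coordinates (km).
#' @param waterMask optional logical matrix of open-water pixels.
#' @param round round values to 0.1 degC on ingest (default `TRUE`).
#' @return a [TemperatureGrid] object.
#' @export
temperatureGrid <- function(values, pixelSize, xll = 0, yll = 0,
                            waterMask = NULL, round = TRUE) {
  values <- as.matrix(values)
  if (round) values <- roundTemperature(values)
  nodata <- is.na(values)
  if (is.null(waterMask)) {
    waterMask <- matrix(FALSE, nrow(values), ncol(values))
  } else {
    waterMask <- as.matrix(waterMask)
    storage.mode(waterMask) <- "logical"
    waterMask[is.na(waterMask)] <- FALSE
  }
  new("TemperatureGrid", values = values, pixelSize = as.numeric(pixelSize),
      xll = as.numeric(xll), yll = as.numeric(yll),
      nodataMask = nodata, waterMask = waterMask)
}

#' Construct method parameters
#'
#' All arguments default to the published study values; see
#' [MethodParams-class] for meanings and units.
#'
#' @param halfWidth analogue half-width (degC).
#' @param incrementStep increment spacing (degC).
#' @param penalty dissimilarity penalty P (units per degC).
#' @param waterCost open-water cost.
#' @param nSteps number of interpolated temperature grids.
#' @param elapsedTime elapsed time (years).
#' @param neighbourhood 4 or 8.
#' @param costForm "integer" (banded) or "linear".
#' @param islandPolicy "exclude" or "keep".
#' @param islandMinArea minimum mainland component area (pixels), or `NA`.
#' @return a [MethodParams] object.
#' @export
methodParams <- function(halfWidth = 0.25, incrementStep = 0.1, penalty = 2,
                         waterCost = 5000, nSteps = 31, elapsedTime = 90,
                         neighbourhood = 8, costForm = "integer",
                         islandPolicy = "exclude", islandMinArea = NA_real_) {
  new("MethodParams", halfWidth = halfWidth, incrementStep = incrementStep,
      penalty = penalty, waterCost = waterCost, nSteps = nSteps,
      elapsedTime = elapsedTime, neighbourhood = neighbourhood,
      costForm = costForm, islandPolicy = islandPolicy,
      islandMinArea = as.numeric(islandMinArea))
}

#' @describeIn TemperatureGrid-class temperature matrix accessor
#' @param x object.
#' @export
setMethod("gridValues", "TemperatureGrid", function(x) x@values)

#' @describeIn TemperatureGrid-class pixel size (km) accessor
#' @export
setMethod("pixelSize", "TemperatureGrid", function(x) x@pixelSize)

#' @describeIn TemperatureGrid-class nodata mask accessor
#' @export
setMethod("nodataMask", "TemperatureGrid", function(x) x@nodataMask)

#' @describeIn TemperatureGrid-class water mask accessor
#' @export
setMethod("waterMask", "TemperatureGrid", function(x) x@waterMask)

#' @describeIn TemperatureGrid-class routable land (not nodata, not water)
#' @export
setMethod("landMask", "TemperatureGrid",
          function(x) !x@nodataMask & !x@waterMask)

setMethod("dim", "TemperatureGrid", function(x) dim(x@values))

setMethod("show", "TemperatureGrid", function(object) {
  d <- dim(object@values)
  rng <- suppressWarnings(range(object@values, na.rm = TRUE))
  cat(sprintf("TemperatureGrid: %d x %d pixels @ %g km\n", d[1], d[2],
              object@pixelSize))
  cat(sprintf("  values : %.1f .. %.1f degC\n", rng[1], rng[2]))
  cat(sprintf("  nodata : %d px   water: %d px\n",
              sum(object@nodataMask), sum(object@waterMask)))
  cat(sprintf("  origin : (%g, %g) km, lower-left\n", object@xll, object@yll))
})

setMethod("show", "MethodParams", function(object) {
  cat("MethodParams:\n")
  cat(sprintf("  analogue half-width : %g degC (bin %g degC)\n",
              object@halfWidth, 2 * object@halfWidth))
  cat(sprintf("  increment step      : %g degC\n", object@incrementStep))
  cat(sprintf("  penalty P           : %g per degC\n", object@penalty))
  cat(sprintf("  water cost          : %g\n", object@waterCost))
  cat(sprintf("  interpolation steps : %g\n", object@nSteps))
  cat(sprintf("  elapsed time        : %g yr\n", object@elapsedTime))
  cat(sprintf("  neighbourhood       : %g-connected (%s costs)\n",
              object@neighbourhood, object@costForm))
  cat(sprintf("  island policy       : %s\n", object@islandPolicy))
})

.parseAscHeader <- function(lines) {
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L || !grepl("^[A-Za-z]", parts[1]) ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  list(header = hdr, nskip = i)
}

.readAsc <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 8L)
  ph <- .parseAscHeader(lines)
  hdr <- ph$header
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("ASCII grid header missing ncols/nrows")
  if (is.null(hdr$cellsize) && is.null(hdr$dx))
    stop("ASCII grid header missing cellsize")
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    # dx/dy header variant: the method requires square pixels
    if (is.null(hdr$dx) || is.null(hdr$dy) || hdr$dx != hdr$dy)
      stop("non-square pixels (dx != dy): the method requires a square-pixel",
           " equal-area grid")
    hdr$cellsize <- hdr$dx
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = numeric(), skip = ph$nskip, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m,
       cellsize = hdr$cellsize,
       xll = if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0,
       yll = if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0)
}

#' Read a temperature raster (ESRI ASCII grid)
#'
#' Reads a single-band temperature raster, rounds values to 0.1 degC, and
#' optionally attaches a co-registered water mask raster (nonzero = water).
#' Grids must be projected and equal-area with square pixels; `units` states
#' the projected unit of `cellsize` and the corner coordinates. Geographic
#' grids in degrees are rejected because the method measures planar
#' distances in km.
#'
#' @param path path to the `.asc` temperature raster.
#' @param waterPath optional path to a co-registered water mask raster.
#' @param units "km" or "m"; unit of the file's cellsize/corner coordinates.
#' @return a [TemperatureGrid].
#' @export
readTemperatureRaster <- function(path, waterPath = NULL,
                                  units = c("km", "m")) {
  units <- match.arg(units[1], c("km", "m", "deg", "degree", "degrees"))
  if (units %in% c("deg", "degree", "degrees"))
    stop("unprojected (degree) grids are not supported: supply an equal-area",
         " projected grid with cellsize in km or m")
  a <- .readAsc(path)
  scale <- if (units == "m") 1e-3 else 1
  water <- NULL
  if (!is.null(waterPath)) {
    w <- .readAsc(waterPath)
    if (!identical(dim(w$values), dim(a$values)) ||
        abs(w$cellsize - a$cellsize) > 1e-9)
      stop("water mask is not co-registered with the temperature raster",
           " (shape or cellsize differs)")
    water <- !is.na(w$values) & w$values != 0
  }
  temperatureGrid(a$values, pixelSize = a$cellsize * scale,
                  xll = a$xll * scale, yll = a$yll * scale,
                  waterMask = water, round = TRUE)
}

#' Check that two grids are co-registered
#'
#' @param a,b [TemperatureGrid] objects (current/future pair).
#' @return invisibly `TRUE`; errors otherwise.
#' @export
checkCoRegistered <- function(a, b) {
  if (!identical(dim(a@values), dim(b@values)))
    stop("grids are not co-registered: shapes ",
         paste(dim(a@values), collapse = "x"), " vs ",
         paste(dim(b@values), collapse = "x"))
  if (abs(a@pixelSize - b@pixelSize) > 1e-9)
    stop("grids are not co-registered: pixel sizes differ")
  if (abs(a@xll - b@xll) > 1e-6 || abs(a@yll - b@yll) > 1e-6)
    stop("grids are not co-registered: origins differ")
  invisible(TRUE)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Writes any 2D result layer (temperatures, km, degC, integer classes or
#' flags) with full double precision, so that write/read round-trips are
#' lossless. `NA` pixels are encoded as the declared nodata value. Integer
#' layers are written without decimals.
#'
#' @param x numeric/integer/logical matrix, or a [TemperatureGrid].
#' @param path output path.
#' @param pixelSize,xll,yll georeferencing (km); taken from `x` when it is a
#'   [TemperatureGrid].
#' @param nodata nodata encoding value (default -9999).
#' @return invisibly `path`.
#' @export
writeGridLayer <- function(x, path, pixelSize = NULL, xll = 0, yll = 0,
                           nodata = -9999) {
  if (is(x, "TemperatureGrid")) {
    pixelSize <- x@pixelSize; xll <- x@xll; yll <- x@yll
    x <- x@values
  }
  if (is.null(pixelSize)) stop("pixelSize required when writing a bare matrix")
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  isInt <- all(is.na(m) | m == round(m))
  fmt <- function(v) {
    out <- if (isInt) sprintf("%.0f", v) else sprintf("%.17g", v)
    out[is.na(v)] <- sprintf(if (isInt) "%.0f" else "%.17g", nodata)
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols        %d", ncol(m)),
    sprintf("nrows        %d", nrow(m)),
    sprintf("xllcorner    %.17g", xll),
    sprintf("yllcorner    %.17g", yll),
    sprintf("cellsize     %.17g", pixelSize),
    sprintf("NODATA_value %s", if (isInt) sprintf("%.0f", nodata)
            else sprintf("%.17g", nodata))
  ), con)
  writeLines(apply(m, 1L, function(r) paste(fmt(r), collapse = " ")), con)
  invisible(path)
}

#' Write a TemperatureGrid (values + optional water mask)
#'
#' @param grid a [TemperatureGrid].
#' @param path output `.asc` path for the temperature band.
#' @param waterPath optional output path for the 0/1 water mask band.
#' @return invisibly `path`.
#' @export
writeTemperatureRaster <- function(grid, path, waterPath = NULL) {
  writeGridLayer(grid, path)
  if (!is.null(waterPath))
    writeGridLayer(grid@waterMask * 1L, waterPath, pixelSize = grid@pixelSize,
                   xll = grid@xll, yll = grid@yll)
  invisible(path)
}

#' Read a plain key: value configuration file into parameters
#'
#' Parses a Debian-control-style `key: value` text file whose keys are the
#' [methodParams()] argument names; unknown keys error. CLI flags override
#' file values.
#'
#' @param path config file path.
#' @param overrides named list of values overriding the file.
#' @return a [MethodParams].
#' @export
readParamsConfig <- function(path, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    d <- read.dcf(path)
    vals <- as.list(d[1, ])
    names(vals) <- tolower(names(vals))
  }
  canon <- names(formals(methodParams))
  names(overrides) <- tolower(names(overrides))
  vals[names(overrides)] <- overrides
  bad <- setdiff(names(vals), tolower(canon))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  args <- list()
  for (nm in names(vals)) {
    target <- canon[tolower(canon) == nm]
    v <- vals[[nm]]
    args[[target]] <- if (target %in% c("costForm", "islandPolicy"))
      as.character(v) else as.numeric(v)
  }
  do.call(methodParams, args)
}

#' @importFrom utils read.csv write.csv
NULL
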