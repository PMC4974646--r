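# Sensitivity of the exposure metrics to resolution, analogue bin width
# and dissimilarity penalty.

#' Coarsen a temperature grid by block aggregation
#'
#' Mean-aggregates `factor` x `factor` pixel blocks (the resampling
#' statistic is exposed because the appropriate choice is data-dependent;
#' only the mean is currently offered), scaling the pixel size. Partial
#' edge blocks are dropped. Block values average the non-nodata pixels; a
#' block is nodata only when all its pixels are. A block is water when
#' more than half of its pixels are.
#'
#' @param grid a [TemperatureGrid].
#' @param factor integer >= 2 aggregation factor.
#' @param stat aggregation statistic; only `"mean"`.
#' @return a coarsened [TemperatureGrid].
#' @export
coarsenGrid <- function(grid, factor, stat = c("mean")) {
  stat <- match.arg(stat)
  factor <- as.integer(factor)
  if (factor < 2) stop("factor must be an integer >= 2")
  v <- grid@values
  nr <- (nrow(v) %/% factor) * factor
  nc <- (ncol(v) %/% factor) * factor
  if (nr < factor || nc < factor)
    stop("factor ", factor, " larger than the grid")
  block <- function(m, f) {
    m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
    a <- array(m, dim = c(factor, nr / factor, factor, nc / factor))
    apply(a, c(2, 4), f)
  }
  vals <- block(v, function(x) if (all(is.na(x))) NA_real_
                               else mean(x, na.rm = TRUE))
  water <- block(grid@waterMask, function(x) mean(x) > 0.5)
  temperatureGrid(vals, pixelSize = grid@pixelSize * factor,
                  xll = grid@xll, yll = grid@yll, waterMask = water,
                  round = TRUE)
}

#' Geometric mean over strictly positive values
#'
#' Zeros are excluded (their count is reported by the sweep); all-zero or
#' empty input yields `NA`.
#'
#' @param x numeric vector; `NA` dropped.
#' @return geometric mean of the positive entries.
#' @export
geometricMean <- function(x) {
  x <- x[!is.na(x) & x > 0]
  if (!length(x)) return(NA_real_)
  exp(mean(log(x)))
}

.summarise <- function(x) {
  x <- x[!is.na(x)]
  q <- if (length(x)) stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
       else rep(NA_real_, 3)
  c(gmean = geometricMean(x), p5 = q[1], p50 = q[2], p95 = q[3],
    nZero = sum(x == 0), n = length(x))
}

#' Sensitivity sweep over resolution, bin width and penalty
#'
#' Re-runs the forward analysis for every combination of coarsening
#' factor, analogue bin width (full width, degC) and dissimilarity
#' penalty, and summarises velocity_MED, velocity_ED, their ratio and MCE
#' with the geometric mean and the 5th/50th/95th percentiles (one row per
#' combination and metric, mirroring a supplementary-table layout).
#' Percentiles of MCE are reported over all routed pixels, its geometric
#' mean over the MCE > 0 subset; `mceZeroFraction` gives the MCE = 0
#' share. Zero velocities are excluded from geometric means and counted in
#' `nZero`.
#'
#' @param current,future co-registered [TemperatureGrid] pair (finest
#'   resolution).
#' @param factors integer vector of coarsening factors (1 = native).
#' @param binWidths numeric vector of analogue bin widths (degC; half-width
#'   is half of each).
#' @param penalties numeric vector of dissimilarity penalties P.
#' @param params baseline [MethodParams]; each combination overrides its
#'   half-width and penalty.
#' @return data.frame with columns factor, pixelSize, binWidth, penalty,
#'   metric, gmean, p5, p50, p95, nZero, n, mceZeroFraction.
#' @export
sensitivitySweep <- function(current, future, factors = 1,
                             binWidths = 0.5, penalties = 2,
                             params = methodParams()) {
  rows <- list()
  for (f in factors) {
    cur <- if (f == 1) current else coarsenGrid(current, f)
    fut <- if (f == 1) future else coarsenGrid(future, f)
    for (bw in binWidths) for (p in penalties) {
      pars <- params
      pars@halfWidth <- bw / 2
      pars@penalty <- p
      res <- runForward(cur, fut, pars)
      valid <- !res@flags$noAnalogue & !res@flags$islandExcluded &
        !res@flags$isWater
      met <- list(velocityMED = res@layers$velocityMED[valid],
                  velocityED = res@layers$velocityED[valid],
                  ratio = res@layers$ratio[valid],
                  mce = res@layers$mce[valid])
      mceAll <- met$mce[!is.na(met$mce)]
      zeroFrac <- if (length(mceAll)) mean(mceAll == 0) else NA_real_
      for (nm in names(met)) {
        s <- .summarise(met[[nm]])
        rows[[length(rows) + 1L]] <- data.frame(
          factor = f, pixelSize = cur@pixelSize, binWidth = bw, penalty = p,
          metric = nm, gmean = s[["gmean"]], p5 = s[["p5"]], p50 = s[["p50"]],
          p95 = s[["p95"]], nZero = s[["nZero"]], n = s[["n"]],
          mceZeroFraction = if (nm == "mce") zeroFrac else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
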