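# Least-cost routing over the lattice graph of a cost surface.
#
# Graph: one vertex per non-nodata pixel; edges join 4- or 8-neighbours.
# Edge weight = mean(endpoint costs) * edge length, with edge length equal
# to the pixel size for cardinal moves and sqrt(2) * pixel size for
# diagonal moves. This transition rule makes accumulated cost equal
# travelled distance on all-analogue (cost 1) terrain and makes the
# accounting identity sum(cost_i * l_i) = accumulated cost exact under the
# half-edge length assignment used in extractPath(). Shortest paths are
# exact Dijkstra (igraph); weights are positive by construction.

.offsets <- function(neighbourhood) {
  card <- list(c(0L, 1L), c(1L, 0L))
  diag <- list(c(1L, 1L), c(1L, -1L))
  if (neighbourhood == 4) card else c(card, diag)
}

# Build the lattice graph of a cost matrix. Returns the igraph object plus
# the cell -> vertex-id map (NA at nodata).
.buildCostGraph <- function(costs, pixelSize, neighbourhood = 8) {
  nr <- nrow(costs); nc <- ncol(costs)
  ok <- !is.na(costs)
  vid <- matrix(NA_integer_, nr, nc)
  vid[ok] <- seq_len(sum(ok))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in .offsets(neighbourhood)) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- vid[r1, c1, drop = FALSE]
    b <- vid[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    ca <- costs[r1, c1, drop = FALSE][keep]
    cb <- costs[r1 + dr, c1 + dc, drop = FALSE][keep]
    len <- if (dr != 0 && dc != 0) sqrt(2) * pixelSize else pixelSize
    from <- c(from, a[keep]); to <- c(to, b[keep])
    w <- c(w, (ca + cb) / 2 * len)
  }
  g <- igraph::make_empty_graph(n = sum(ok), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  list(graph = g, vid = vid)
}

.cellRC <- function(vid, ids) {
  idx <- match(ids, vid)
  cbind(row = (idx - 1L) %% nrow(vid) + 1L, col = (idx - 1L) %/% nrow(vid) + 1L)
}

#' Single-source accumulated least cost over a cost surface
#'
#' Exact Dijkstra accumulated cost from a source pixel to every reachable
#' pixel of the lattice graph (see the class docs for the edge-weight
#' definition). The source must be a routable land pixel; by construction
#' of the per-increment cost surfaces it is an analogue of its own
#' increment (cost 1).
#'
#' @param costSurface a [CostSurface], or a bare cost matrix.
#' @param source integer `c(row, col)` of the source pixel.
#' @param params a [MethodParams] (neighbourhood).
#' @param pixelSize pixel edge length (km); required when `costSurface` is a
#'   bare matrix and the surface carries none.
#' @param isWater optional logical matrix; used only to reject water sources.
#' @return an [AccumulatedCost] object.
#' @export
accumulatedCost <- function(costSurface, source, params = methodParams(),
                            pixelSize = NULL, isWater = NULL) {
  costs <- if (is(costSurface, "CostSurface")) costSurface@costs
           else as.matrix(costSurface)
  if (is.null(pixelSize)) {
    pixelSize <- if (is(costSurface, "CostSurface")) costSurface@pixelSize
                 else NA_real_
  }
  if (!length(pixelSize) || is.na(pixelSize))
    stop("pixelSize required (km)")
  source <- as.integer(source)
  if (is.na(costs[source[1], source[2]]))
    stop("source pixel is nodata: cannot route from it")
  if (!is.null(isWater) && isWater[source[1], source[2]])
    stop("source pixel is water: sources must be land")
  bg <- .buildCostGraph(costs, pixelSize, params@neighbourhood)
  sVid <- bg$vid[source[1], source[2]]
  d <- igraph::distances(bg$graph, v = sVid, algorithm = "dijkstra")
  acc <- matrix(NA_real_, nrow(costs), ncol(costs))
  acc[!is.na(bg$vid)] <- d[1, bg$vid[!is.na(bg$vid)]]
  new("AccumulatedCost", acc = acc, source = source, graph = bg$graph,
      vid = bg$vid, costs = costs, pixelSize = as.numeric(pixelSize),
      neighbourhood = params@neighbourhood)
}

setMethod("show", "AccumulatedCost", function(object) {
  cat(sprintf("AccumulatedCost from (%d, %d): %d x %d, %g-connected\n",
              object@source[1], object@source[2], nrow(object@acc),
              ncol(object@acc), object@neighbourhood))
})

#' Straight-line nearest analogue (ED)
#'
#' Centre-to-centre planar distance from the source to the closest pixel of
#' the analogue set. Tie-break: smallest distance, then row-major pixel
#' order (row, then column) — fully deterministic.
#'
#' @param source integer `c(row, col)`.
#' @param analogues logical matrix (analogue set) or two-column row/col
#'   matrix of analogue pixels.
#' @param pixelSize pixel edge length (km).
#' @return list with `destination` (row, col) and `ed` (km); `ed = NA` and
#'   `destination = NULL` when the set is empty.
#' @export
nearestEuclidean <- function(source, analogues, pixelSize) {
  rc <- if (is.logical(analogues)) which(analogues, arr.ind = TRUE)
        else as.matrix(analogues)
  if (!nrow(rc)) return(list(destination = NULL, ed = NA_real_))
  d <- pixelSize * sqrt((rc[, 1] - source[1])^2 + (rc[, 2] - source[2])^2)
  best <- d <= min(d) + .eps * max(1, min(d))
  cand <- rc[best, , drop = FALSE]
  o <- order(cand[, 1], cand[, 2])[1]
  list(destination = as.integer(cand[o, ]), ed = min(d))
}

#' Select the least-accumulated-cost destination among analogues
#'
#' Argmin of accumulated cost over the analogue set. Ties are broken by
#' smallest Euclidean distance to the source, then row-major pixel order.
#' Returns a no-analogue result when the set is empty or entirely
#' unreachable.
#'
#' @param acc an [AccumulatedCost] (or bare accumulated-cost matrix plus
#'   `source`/`pixelSize`).
#' @param analogues logical matrix or two-column row/col matrix.
#' @param source,pixelSize needed only when `acc` is a bare matrix.
#' @return list with `destination` (row, col or `NULL`), `cost`
#'   (accumulated cost, `NA` if none) and `noAnalogue` flag.
#' @export
selectDestination <- function(acc, analogues, source = NULL,
                              pixelSize = NULL) {
  if (is(acc, "AccumulatedCost")) {
    source <- acc@source; pixelSize <- acc@pixelSize; accM <- acc@acc
  } else accM <- acc
  rc <- if (is.logical(analogues)) which(analogues, arr.ind = TRUE)
        else as.matrix(analogues)
  if (!nrow(rc))
    return(list(destination = NULL, cost = NA_real_, noAnalogue = TRUE))
  a <- accM[cbind(rc[, 1], rc[, 2])]
  finite <- is.finite(a)
  if (!any(finite))
    return(list(destination = NULL, cost = NA_real_, noAnalogue = TRUE))
  rc <- rc[finite, , drop = FALSE]; a <- a[finite]
  amin <- min(a)
  tied <- a <= amin + .eps * max(1, amin)
  cand <- rc[tied, , drop = FALSE]
  if (nrow(cand) > 1L) {
    d <- sqrt((cand[, 1] - source[1])^2 + (cand[, 2] - source[2])^2)
    near <- d <= min(d) + .eps
    cand <- cand[near, , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  }
  list(destination = as.integer(cand[1, ]), cost = amin, noAnalogue = FALSE)
}

# Half-edge length assignment: each pixel of the path receives half of each
# incident path edge; endpoints carry a single half-edge. Makes
# sum(l_i) = MED and sum(cost_i * l_i) = accumulated cost exact.
.pathAccounting <- function(pathRC, costs, pixelSize) {
  n <- nrow(pathRC)
  l <- numeric(n)
  if (n > 1L) {
    dr <- diff(pathRC[, 1]); dc <- diff(pathRC[, 2])
    elen <- ifelse(dr != 0 & dc != 0, sqrt(2) * pixelSize, pixelSize)
    l[seq_len(n - 1L)] <- l[seq_len(n - 1L)] + elen / 2
    l[seq_len(n - 1L) + 1L] <- l[seq_len(n - 1L) + 1L] + elen / 2
  }
  cvec <- costs[cbind(pathRC[, 1], pathRC[, 2])]
  list(lengths = l, costs = cvec, MED = sum(l), acc = sum(cvec * l))
}

#' Delineate the least-cost trajectory to a destination
#'
#' Extracts the least-cost pixel path from the source of an accumulated-cost
#' run to a destination, with per-pixel traversal lengths l_i (half-edge
#' assignment), the minimum exposure distance MED = sum(l_i), and the
#' accumulated cost recomputed as sum(cost_i * l_i) (identical, to floating
#' tolerance, to the Dijkstra distance).
#'
#' @param acc an [AccumulatedCost].
#' @param destination integer `c(row, col)`.
#' @param increment increment recorded on the trajectory (degC; optional).
#' @return a [Trajectory]; errors if the destination is unreachable.
#' @export
extractPath <- function(acc, destination, increment = NA_real_) {
  destination <- as.integer(destination)
  dVid <- acc@vid[destination[1], destination[2]]
  if (is.na(dVid)) stop("destination pixel is nodata")
  if (!is.finite(acc@acc[destination[1], destination[2]]))
    stop("destination unreachable from source (fully masked off)")
  sVid <- acc@vid[acc@source[1], acc@source[2]]
  if (sVid == dVid) {
    pathRC <- matrix(acc@source, 1, 2,
                     dimnames = list(NULL, c("row", "col")))
  } else {
    sp <- igraph::shortest_paths(acc@graph, from = sVid, to = dVid,
                                 output = "vpath", algorithm = "dijkstra")
    ids <- as.integer(sp$vpath[[1]])
    pathRC <- .cellRC(acc@vid, ids)
  }
  pa <- .pathAccounting(pathRC, acc@costs, acc@pixelSize)
  new("Trajectory", source = acc@source, destination = destination,
      path = pathRC, lengths = pa$lengths, costs = pa$costs,
      accumulatedCost = pa$acc, MED = pa$MED,
      increment = as.numeric(increment))
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory (%d,%d) -> (%d,%d): %d px, MED %.2f km, accumulated cost %.2f\n",
              object@source[1], object@source[2], object@destination[1],
              object@destination[2], nrow(object@path), object@MED,
              object@accumulatedCost))
})

#' Export trajectories as GeoJSON LineStrings
#'
#' One feature per trajectory; coordinates are pixel-centre map coordinates
#' (km) from the grid georeferencing; properties carry MED, ED, MCE and
#' accumulated cost where supplied.
#'
#' @param trajectories list of [Trajectory] objects.
#' @param path output file.
#' @param pixelSize,xll,yll,nrow georeferencing of the grid.
#' @param properties optional data.frame (one row per trajectory) of extra
#'   properties.
#' @return invisibly `path`.
#' @export
trajectoryGeoJSON <- function(trajectories, path, pixelSize, xll = 0, yll = 0,
                              nrow, properties = NULL) {
  feat <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    x <- xll + (tr@path[, 2] - 0.5) * pixelSize
    y <- yll + (nrow - tr@path[, 1] + 0.5) * pixelSize
    props <- list(MED = tr@MED, accumulated_cost = tr@accumulatedCost,
                  increment = tr@increment)
    if (!is.null(properties)) props <- c(props, as.list(properties[i, ]))
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_along(x),
                                              function(j) c(x[j], y[j]))),
         properties = props)
  })
  json <- list(type = "FeatureCollection", features = feat)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write GeoJSON")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
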