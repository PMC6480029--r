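#' Construct a regular sensor grid
#'
#' Builds the `nRows x nCols` sensor lattice on which all processes are
#' observed.  Vector index `i` and coordinates `(p, q)` are linked by
#' column-major order: `i = (q - 1) * nRows + p`, so `p` varies fastest.
#'
#' @param nRows,nCols positive integers, the lattice dimensions.
#' @param spacing positive distance between adjacent sensors (default 1).
#' @return a [SensorGrid-class].
#' @examples
#' g <- sensorGrid(5, 5)
#' nLocations(g)
#' head(gridCoords(g))
#' @export
sensorGrid <- function(nRows, nCols, spacing = 1) {
  nRows <- as.integer(nRows)
  nCols <- as.integer(nCols)
  if (is.na(nRows) || is.na(nCols) || nRows < 1L || nCols < 1L)
    stop("nRows and nCols must be positive integers")
  co <- as.matrix(expand.grid(p = seq_len(nRows), q = seq_len(nCols)))
  storage.mode(co) <- "double"
  co <- co * spacing
  dimnames(co) <- list(NULL, c("p", "q"))
  new("SensorGrid", nRows = nRows, nCols = nCols,
      spacing = as.numeric(spacing), coords = co)
}

#' @rdname nLocations
#' @export
setMethod("nLocations", "SensorGrid", function(x) x@nRows * x@nCols)

#' @rdname gridCoords
#' @export
setMethod("gridCoords", "SensorGrid", function(x) x@coords)

#' Pairwise distances between grid locations
#'
#' @param grid a [SensorGrid-class].
#' @return symmetric `n x n` matrix of Euclidean distances.
#' @export
gridDistances <- function(grid) {
  stopifnot(is(grid, "SensorGrid"))
  as.matrix(stats::dist(grid@coords))
}

setMethod("show", "SensorGrid", function(object) {
  cat(sprintf("SensorGrid: %d x %d lattice (%d locations), spacing %g\n",
              object@nRows, object@nCols, nLocations(object),
              object@spacing))
  invisible(object)
})

setMethod("show", "FieldPanel", function(object) {
  v <- object@changePoint
  cat(sprintf("FieldPanel: %d time steps on %d locations; %s\n",
              nrow(object@values), ncol(object@values),
              if (is.na(v)) "in control throughout"
              else sprintf("shift %g on %d locations from t = %d",
                           object@shiftMagnitude, sum(object@clusterMask), v)))
  invisible(object)
})

#' @rdname panelValues
#' @export
setMethod("panelValues", "FieldPanel", function(x) x@values)

#' @rdname horizon
#' @export
setMethod("horizon", "FieldPanel", function(x) nrow(x@values))

#' @rdname processCount
#' @export
setMethod("processCount", "ObservationPanel", function(x) dim(x@values)[1L])

#' @rdname horizon
#' @export
setMethod("horizon", "ObservationPanel", function(x) dim(x@values)[2L])

#' @rdname observedMask
#' @export
setMethod("observedMask", "ObservationPanel", function(x) x@observed)

#' @rdname panelValues
#' @export
setMethod("panelValues", "ObservationPanel", function(x) x@values)

#' @rdname nLocations
#' @export
setMethod("nLocations", "ObservationPanel", function(x) dim(x@values)[3L])

setMethod("show", "ObservationPanel", function(object) {
  d <- dim(object@values)
  frac <- 1 - mean(object@observed)
  cat(sprintf(
    "ObservationPanel: %d process(es) x %d time steps x %d locations (%.1f%% missing)\n",
    d[1L], d[2L], d[3L], 100 * frac))
  invisible(object)
})
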