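#' Number of sensor locations
#'
#' @param x a [SensorGrid-class] or an object carrying one.
#' @return integer count of locations `n = nRows * nCols`.
#' @export
setGeneric("nLocations", function(x) standardGeneric("nLocations"))

#' Location coordinates
#'
#' @param x a [SensorGrid-class] or an object carrying one.
#' @return `n x 2` numeric matrix of `(p, q)` coordinates, ordered by
#'   vector index.
#' @export
setGeneric("gridCoords", function(x) standardGeneric("gridCoords"))

#' Number of related processes in a panel
#'
#' @param x an [ObservationPanel-class].
#' @return integer process count `L`.
#' @export
setGeneric("processCount", function(x) standardGeneric("processCount"))

#' Number of time steps
#'
#' @param x a panel-like object.
#' @return integer horizon `T`.
#' @export
setGeneric("horizon", function(x) standardGeneric("horizon"))

#' Observation mask of a panel
#'
#' @param x an [ObservationPanel-class].
#' @return logical `L x T x n` array, `TRUE` at observed entries.
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' Raw values of a panel or field
#'
#' @param x an [ObservationPanel-class] or [FieldPanel-class].
#' @return the numeric value array/matrix (with `NA` at missing entries
#'   for observation panels).
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' Number of scan clusters
#'
#' @param x a [ClusterSet-class] or [ScanChart-class].
#' @return integer number of deduplicated clusters.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Completed values of an imputed slice
#'
#' @param x a [CompletedSlice-class].
#' @return length-`n` numeric vector.
#' @export
setGeneric("completedValues", function(x) standardGeneric("completedValues"))

#' Imputation flags of a completed slice
#'
#' @param x a [CompletedSlice-class].
#' @return logical vector, `TRUE` where the value was imputed.
#' @export
setGeneric("imputedMask", function(x) standardGeneric("imputedMask"))

#' Control limit of a calibration or report
#'
#' @param x a [CalibrationResult-class] or [AlarmReport-class].
#' @return the control limit `h`.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' Alarm time of a monitored run
#'
#' @param x an [AlarmReport-class].
#' @return integer first exceedance time, or `NA_integer_`.
#' @export
setGeneric("alarmTime", function(x) standardGeneric("alarmTime"))
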