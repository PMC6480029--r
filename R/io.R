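# data.table is used with reference semantics throughout the I/O layer
.datatable.aware <- TRUE

#' Write an observation panel to long-format CSV
#'
#' One record per (time, process, location) with header
#' `time,process,p,q,value`; missing entries get an empty value field.
#' Rows are ordered by time, process, then coordinates, and values are
#' written with 12 significant digits, so regeneration under a fixed seed
#' is byte-identical.
#'
#' @param panel an [ObservationPanel-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "ObservationPanel"))
  d <- dim(panel@values)
  co <- gridCoords(panel@grid)
  dt <- data.table::CJ(time = seq_len(d[2L]), process = seq_len(d[1L]),
                       loc = seq_len(d[3L]), sorted = TRUE)
  dt[, `:=`(p = co[loc, 1L], q = co[loc, 2L])]
  vals <- panel@values[cbind(dt$process, dt$time, dt$loc)]
  dt[, value := ifelse(is.na(vals), "",
                       formatC(signif(vals, 12), format = "g",
                               digits = 12))]
  dt[, loc := NULL]
  data.table::setcolorder(dt, c("time", "process", "p", "q", "value"))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read an observation panel from long-format CSV
#'
#' Expects the header `time,process,p,q,value`; an empty value field
#' marks a missing entry.  Times and processes need not be contiguous,
#' but each (time, process) slice must cover the full grid exactly once;
#' duplicated keys and off-grid coordinates are format errors.
#'
#' @param path input file path.
#' @param grid optional [SensorGrid-class]; by default a unit-spacing
#'   grid is inferred from the maximum coordinates.
#' @return an [ObservationPanel-class].
#' @export
readPanel <- function(path, grid = NULL) {
  dt <- data.table::fread(path, colClasses = list(
    numeric = c("p", "q", "value"), integer = c("time", "process")),
    na.strings = "")
  need <- c("time", "process", "p", "q", "value")
  if (!all(need %in% names(dt)))
    stop("panel file must have columns time,process,p,q,value")
  if (anyDuplicated(dt, by = c("time", "process", "p", "q"))) {
    key <- dt[duplicated(dt, by = c("time", "process", "p", "q"))][1L]
    stop(sprintf(
      "duplicated panel key: time=%d process=%d p=%g q=%g",
      key$time, key$process, key$p, key$q))
  }
  if (is.null(grid))
    grid <- sensorGrid(max(dt$p), max(dt$q))
  co <- gridCoords(grid)
  n <- nLocations(grid)
  loc <- match(paste(dt$p, dt$q), paste(co[, 1L], co[, 2L]))
  if (anyNA(loc)) {
    bad <- dt[is.na(loc)][1L]
    stop(sprintf("coordinates off grid: p=%g q=%g", bad$p, bad$q))
  }
  times <- sort(unique(dt$time))
  procs <- sort(unique(dt$process))
  cnt <- dt[, .N, by = c("time", "process")]
  if (any(cnt$N != n) || nrow(cnt) != length(times) * length(procs))
    stop("every (time, process) slice must cover the full grid exactly once")
  vals <- array(NA_real_, c(length(procs), length(times), n))
  vals[cbind(match(dt$process, procs), match(dt$time, times), loc)] <-
    dt$value
  observationPanel(vals, !is.na(vals), grid)
}

#' Write a simulation configuration to YAML
#'
#' Every field is materialized explicitly, so the file round-trips
#' losslessly through [readRunConfig()].
#'
#' @param config a [SimulationConfig-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  lst <- list(
    grid = list(nRows = config@grid@nRows, nCols = config@grid@nCols,
                spacing = config@grid@spacing),
    covarianceScale = config@covarianceScale,
    horizon = config@horizon,
    changePoint = if (is.na(config@changePoint)) "none"
                  else config@changePoint,
    clusterLocations = which(config@clusterMask),
    shiftMagnitude = config@shiftMagnitude,
    processCount = config@processCount,
    noiseSd = config@noiseSd,
    missingRatio = config@missingRatio,
    seed = if (is.na(config@seed)) "none" else config@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path input file path.
#' @return a [SimulationConfig-class].
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  grid <- sensorGrid(lst$grid$nRows, lst$grid$nCols, lst$grid$spacing)
  simConfig(grid = grid, covarianceScale = lst$covarianceScale,
            horizon = lst$horizon,
            changePoint = if (identical(lst$changePoint, "none"))
              NA_integer_ else lst$changePoint,
            clusterPattern = as.integer(lst$clusterLocations),
            shiftMagnitude = lst$shiftMagnitude,
            processCount = lst$processCount, noiseSd = lst$noiseSd,
            missingRatio = lst$missingRatio,
            seed = if (identical(lst$seed, "none")) NA_integer_
                   else lst$seed)
}

#' Generate an on-disk example bundle
#'
#' Writes a configuration file (`config.yaml`) and a matching simulated
#' panel (`panel.csv`) into `dir`.  The `tiny` bundle (3 x 3 grid, two
#' processes, 20 steps) is meant for fast pipeline smoke tests; the
#' `study` bundle regenerates the reference simulation design (5 x 5
#' grid, 300 steps, change point 51, three processes, noise 0.1) with a
#' selectable missing ratio, cluster pattern and shift.
#'
#' @param kind `"tiny"` or `"study"`.
#' @param dir output directory (created if needed).
#' @param seed master seed (default 1).
#' @param ratio,pattern,shift study-bundle knobs (defaults 0.2,
#'   `"medium"`, 1).
#' @return named character vector of the written paths, invisibly.
#' @export
makeFixture <- function(kind = c("tiny", "study"), dir, seed = 1,
                        ratio = 0.2, pattern = "medium", shift = 1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- if (kind == "tiny") {
    simConfig(grid = sensorGrid(3, 3), horizon = 20, changePoint = 11,
              clusterPattern = 5L, shiftMagnitude = 1, processCount = 2,
              noiseSd = 0.1, missingRatio = 0.2, seed = seed)
  } else {
    simConfig(clusterPattern = pattern, shiftMagnitude = shift,
              missingRatio = ratio, seed = seed)
  }
  cfgPath <- file.path(dir, "config.yaml")
  panPath <- file.path(dir, "panel.csv")
  writeRunConfig(config, cfgPath)
  writePanel(simulatePanel(config, seed = seed), panPath)
  invisible(c(config = cfgPath, panel = panPath))
}
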