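#' Construct a SweepLadder
#'
#' @param cellId cell identifier.
#' @param currents injected current per sweep, pA.
#' @param voltage sweeps x samples matrix, mV. Sweeps are reordered by
#'   increasing current if needed.
#' @param dt sampling interval, ms.
#' @param stepOnset,stepDuration current-step timing, ms.
#' @param capacitancePf amplifier-reported capacitance, pF.
#' @param ageGroup \code{"juvenile"} or \code{"adult"}.
#' @param location optional named list.
#' @return a validated \linkS4class{SweepLadder}.
#' @export
SweepLadder <- function(cellId, currents, voltage, dt = 0.1,
                        stepOnset = 100, stepDuration = 800,
                        capacitancePf = NA_real_, ageGroup = "juvenile",
                        location = list()) {
  if (length(currents) == 0L || is.null(voltage) || nrow(voltage) == 0L)
    .stopf("ladder must contain at least one sweep")
  ord <- order(currents)
  new("SweepLadder", cellId = as.character(cellId),
      currents = as.numeric(currents[ord]),
      voltage = voltage[ord, , drop = FALSE], dt = dt,
      stepOnset = stepOnset, stepDuration = stepDuration,
      capacitancePf = capacitancePf, ageGroup = ageGroup,
      location = location)
}

#' Read a current-clamp sweep ladder from disk
#'
#' The canonical plain-text container is the CSV long dialect with columns
#' \code{cell_id, sweep_index, current_pa, time_ms, voltage_mv} and
#' attribute rows (dt, step timing, capacitance, age group) stored in a
#' sidecar header block of \code{#key=value} comment lines. An RDS dialect
#' is offered for lossless in-session round trips. HDF5 and Axon Binary
#' dialects are declared but require readers that this package does not
#' bundle; requesting them raises an informative error.
#'
#' @param path file path.
#' @param dialect one of \code{"csv"}, \code{"rds"}, \code{"hdf5"},
#'   \code{"abf"}.
#' @return a \linkS4class{SweepLadder}; sweeps sorted by current.
#' @export
readSweepLadder <- function(path, dialect = c("csv", "rds", "hdf5", "abf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (dialect %in% c("hdf5", "abf"))
    .stopf("dialect '%s' needs an external reader that is not bundled; %s",
           dialect, "export the recording to the CSV long dialect instead")
  if (dialect == "rds") {
    obj <- readRDS(path)
    if (!is(obj, "SweepLadder")) .stopf("%s does not contain a SweepLadder",
                                        path)
    validObject(obj)
    return(obj)
  }
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, sub("^#", "", ln))
  }
  kv <- strsplit(hdr, "=", fixed = TRUE)
  attrs <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  dat <- utils::read.csv(path, comment.char = "#")
  need <- c("cell_id", "sweep_index", "current_pa", "time_ms", "voltage_mv")
  if (!all(need %in% names(dat)))
    .stopf("CSV long dialect requires columns %s", paste(need, collapse = ", "))
  sw <- split(dat, dat$sweep_index)
  currents <- vapply(sw, function(s) s$current_pa[1], 0)
  volt <- do.call(rbind, lapply(sw, function(s)
    s$voltage_mv[order(s$time_ms)]))
  num <- function(key, default) {
    if (key %in% names(attrs)) as.numeric(attrs[[key]]) else default
  }
  SweepLadder(
    cellId = as.character(dat$cell_id[1]), currents = currents,
    voltage = volt, dt = num("dt_ms", 0.1),
    stepOnset = num("step_onset_ms", 100),
    stepDuration = num("step_duration_ms", 800),
    capacitancePf = num("capacitance_pf", NA_real_),
    ageGroup = if ("age_group" %in% names(attrs)) attrs[["age_group"]]
               else "juvenile")
}

#' Write a sweep ladder to disk
#'
#' CSV voltages are written with six decimals (round trips to 1e-6 mV);
#' the RDS dialect round trips bit-exactly.
#'
#' @param ladder a valid \linkS4class{SweepLadder}.
#' @param path output path.
#' @param dialect \code{"csv"} or \code{"rds"}.
#' @export
writeSweepLadder <- function(ladder, path, dialect = c("csv", "rds")) {
  dialect <- match.arg(dialect)
  validObject(ladder)
  if (dialect == "rds") {
    saveRDS(ladder, path)
    return(invisible(NULL))
  }
  hdr <- c(
    sprintf("#dt_ms=%.10g", ladder@dt),
    sprintf("#step_onset_ms=%.10g", ladder@stepOnset),
    sprintf("#step_duration_ms=%.10g", ladder@stepDuration),
    if (!is.na(ladder@capacitancePf))
      sprintf("#capacitance_pf=%.10g", ladder@capacitancePf),
    sprintf("#age_group=%s", ladder@ageGroup))
  ns <- ncol(ladder@voltage)
  tms <- (seq_len(ns) - 1L) * ladder@dt
  rows <- do.call(rbind, lapply(seq_along(ladder@currents), function(i)
    data.frame(cell_id = ladder@cellId, sweep_index = i,
               current_pa = ladder@currents[i], time_ms = tms,
               voltage_mv = round(ladder@voltage[i, ], 6))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Resting-membrane-potential quality control for a ladder
#'
#' The per-sweep baseline is the mean voltage over the pre-step segment.
#' A cell fails with reason \code{"rmp_depolarized"} when the mean
#' baseline exceeds \code{maxRmp} (default -50 mV, strict) and with
#' \code{"rmp_unstable"} when the baseline SD exceeds \code{maxRmpSd}
#' (default 6 mV, strict).
#'
#' @param ladder a \linkS4class{SweepLadder}.
#' @param maxRmp depolarization threshold, mV.
#' @param maxRmpSd stability threshold, mV.
#' @return a \linkS4class{LadderQC} report (always returned, never an
#'   error).
#' @export
validateLadder <- function(ladder, maxRmp = -50, maxRmpSd = 6) {
  base <- .sweepBaselines(ladder)
  m <- mean(base)
  s <- if (length(base) > 1L) sd(base) else 0
  reasons <- character()
  if (m > maxRmp) reasons <- c(reasons, "rmp_depolarized")
  if (s > maxRmpSd) reasons <- c(reasons, "rmp_unstable")
  new("LadderQC", cellId = ladder@cellId, rmpMean = m, rmpSd = s,
      passed = length(reasons) == 0L, reasons = reasons)
}
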