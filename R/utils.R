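# internal helpers shared across modules

# baseline (pre-step) window indices for a ladder
.baselineIdx <- function(ladder) {
  n <- max(1L, floor(ladder@stepOnset / ladder@dt))
  seq_len(n)
}

# per-sweep mean baseline voltage, mV
.sweepBaselines <- function(ladder) {
  rowMeans(ladder@voltage[, .baselineIdx(ladder), drop = FALSE])
}

# indices covering the last `ms` milliseconds of the current step
.stepTailIdx <- function(ladder, ms = 50) {
  endS <- floor((ladder@stepOnset + ladder@stepDuration) / ladder@dt)
  endS <- min(endS, ncol(ladder@voltage))
  seq.int(endS - floor(ms / ladder@dt) + 1L, endS)
}

# indices covering the whole current step
.stepIdx <- function(ladder) {
  on <- floor(ladder@stepOnset / ladder@dt) + 1L
  off <- min(floor((ladder@stepOnset + ladder@stepDuration) / ladder@dt),
             ncol(ladder@voltage))
  seq.int(on, off)
}

# truncated-normal draw by rejection (vectorised), bounds may be +/-Inf
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 1000L) {  # pathological spec; clamp rather than spin
      out[bad] <- pmin(pmax(out[bad], lower), upper)
      break
    }
  }
  out
}

# label 4-connected components of a logical matrix; 0 = background
.labelComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
            q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
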