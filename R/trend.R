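#' Append an observation to a smoothed trend series
#'
#' Appends a raw value and updates the exponential moving average with
#' \code{ema_new = alpha * x + (1 - alpha) * ema_prev}; the first value
#' passes through unchanged. Timestamps must be strictly increasing.
#'
#' @param series a \linkS4class{TrendSeries}.
#' @param t acquisition time in hours.
#' @param x raw statistic value (finite).
#' @return The extended \code{TrendSeries}.
#' @examples
#' s <- TrendSeries(alpha = 0.5)
#' s <- emaAppend(s, 0, 10); s <- emaAppend(s, 0.5, 20); s <- emaAppend(s, 1, 30)
#' s@ema   # 10, 15, 22.5
#' @rdname emaAppend
#' @export
setMethod("emaAppend", "TrendSeries", function(series, t, x) {
  if (length(t) != 1 || !is.finite(t))
    stopValidationError("'t' must be a finite scalar time in hours")
  if (length(x) != 1 || !is.finite(x))
    stopValidationError("trend value must be finite")
  n <- length(series@times)
  if (n > 0 && t <= series@times[n])
    stopOrderingError(sprintf(
      "non-increasing time: %.6g h after %.6g h", t, series@times[n]))
  emaNew <- if (n == 0) x else series@alpha * x + (1 - series@alpha) * series@ema[n]
  series@times <- c(series@times, t)
  series@raw <- c(series@raw, x)
  series@ema <- c(series@ema, emaNew)
  series
})

#' Least-squares slope over the last k smoothed values
#'
#' Ordinary least-squares slope of the last \code{k} values of the smoothed
#' (or, if configured, raw) series against their acquisition times, in value
#' units per hour. Returns \code{NA} while fewer than \code{k} points exist:
#' an undefined slope is a value, not an error, and triggers no control
#' action. Unequal sampling intervals are handled by regressing on the
#' actual times.
#'
#' @param series a \linkS4class{TrendSeries}.
#' @return The slope (units/hour), or \code{NA} if fewer than \code{k} points.
#' @examples
#' s <- TrendSeries(alpha = 1)
#' for (i in 1:3) s <- emaAppend(s, (i - 1) * 0.5, i)
#' slopeLastK(s)  # 2 per hour
#' @rdname slopeLastK
#' @export
setMethod("slopeLastK", "TrendSeries", function(series) {
  n <- length(series@times)
  k <- series@k
  if (n < k) return(NA_real_)
  idx <- seq.int(n - k + 1L, n)
  tt <- series@times[idx]
  vv <- if (series@slopeOn == "ema") series@ema[idx] else series@raw[idx]
  tc <- tt - mean(tt)
  sum(tc * (vv - mean(vv))) / sum(tc * tc)
})

#' Rebuild a trend series from persisted values
#'
#' Reconstructs a \linkS4class{TrendSeries} from time, raw and EMA columns as
#' persisted in the statistics CSV, so a restarted controller resumes the
#' smoother exactly where it stopped rather than re-smoothing from scratch.
#'
#' @param times,raw,ema equal-length numeric vectors.
#' @param alpha,k,slopeOn series parameters (see \linkS4class{TrendSeries}).
#' @return A \code{TrendSeries}.
#' @export
trendFromValues <- function(times, raw, ema, alpha = 0.5, k = 3L,
                            slopeOn = "ema") {
  new("TrendSeries", times = as.numeric(times), raw = as.numeric(raw),
      ema = as.numeric(ema), alpha = alpha, k = as.integer(k),
      slopeOn = slopeOn)
}

## Mean of the last k raw values (the alternative safeguard average).
.lastKMean <- function(series) {
  n <- length(series@raw)
  if (n < 1) return(NA_real_)
  k <- min(series@k, n)
  mean(series@raw[seq.int(n - k + 1L, n)])
}
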