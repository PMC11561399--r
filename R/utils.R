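#' Local maxima of a series with a prominence filter
#'
#' Finds interior local maxima and keeps those whose height exceeds the
#' deeper of the two flanking valleys (toward the neighbouring peaks or the
#' series ends) by at least \code{minProminence}. Used to count induction
#' peaks in smoothed MFI trajectories.
#'
#' @param x numeric vector.
#' @param minProminence minimum prominence to keep a peak.
#' @return Integer indices of the peaks, in order.
#' @export
localMaxima <- function(x, minProminence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    ## valley floors toward the nearest higher point (or the series ends)
    left <- which(x[seq_len(i - 1L)] > x[i])
    lo <- if (length(left)) max(left) + 1L else 1L
    right <- which(x[seq.int(i + 1L, n)] > x[i]) + i
    hi <- if (length(right)) min(right) - 1L else n
    x[i] - max(min(x[lo:i]), min(x[i:hi]))
  }, numeric(1))
  ## a double-top from noise yields two candidates; keep the higher one
  keep <- prom >= minProminence
  cand[keep]
}

## JSON-lines status logger (wall-clock ISO timestamps; distinct from the
## deterministic audit log).
.logLine <- function(level, msg, ..., con = stderr()) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                level = level, msg = msg), list(...))
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                           na = "null")), con)
}
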