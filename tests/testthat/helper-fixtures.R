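## Shared fixtures and independent oracles.

## Random event table spanning the dynamic range around typical thresholds.
randomEventTable <- function(n, seed, t = 0) {
  set.seed(seed)
  ev <- cbind(
    `FSC-H` = rlnorm(n, log(2000), 1.2),
    `SSC-H` = rlnorm(n, log(1000), 1.0),
    `FL1-H` = rlnorm(n, log(200), 1.5),
    `FL3-H` = rlnorm(n, log(100), 1.8))
  EventTable(ev, sampleId = sprintf("rand%04d", seed), acquiredAt = t)
}

## Independent straight-line gating oracle: one event at a time, no shared
## code with the package classifier.
oracleClassify <- function(events, fscMin, fl3Threshold, fl1Threshold) {
  out <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    fsc <- events[i, "FSC-H"]
    fl3 <- events[i, "FL3-H"]
    fl1 <- events[i, "FL1-H"]
    if (fsc < fscMin) {
      out[i] <- "debris"
    } else if (fl3 >= fl3Threshold) {
      out[i] <- "damaged"
    } else if (fl1 >= fl1Threshold) {
      out[i] <- "intact_gfp_pos"
    } else {
      out[i] <- "intact_gfp_neg"
    }
  }
  out
}

## Independent minimal FCS writer (integer datatype, little-endian), built
## directly from the format definition; used to create read fixtures that do
## not share code with writeFCS.
miniWriteFcs <- function(path, events, channelNames,
                         datatype = "I", extraKeywords = character(0)) {
  nTot <- nrow(events)
  nPar <- ncol(events)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = datatype, "$MODE" = "L",
          "$NEXTDATA" = "0", "$TOT" = as.character(nTot),
          "$PAR" = as.character(nPar))
  for (i in seq_len(nPar)) {
    kw[sprintf("$P%dN", i)] <- channelNames[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "16777216"
  }
  kw <- c(kw, extraKeywords)
  text <- paste0("/", paste0(names(kw), "/", kw, collapse = "/"), "/")
  textStart <- 58L
  textEnd <- textStart + nchar(text, type = "bytes") - 1L
  dataStart <- textEnd + 1L
  dataEnd <- dataStart + nTot * nPar * 4L - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", textStart, textEnd,
                    if (nTot) dataStart else 0L, if (nTot) dataEnd else 0L,
                    0L, 0L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (nTot)
    writeBin(as.integer(t(events)), con, size = 4L, endian = "little")
  path
}

## Stats stream (data.frame) from vectors.
statsFrame <- function(t, mfi, pct, usable = TRUE) {
  data.frame(t = t, mfi_gfp = mfi, pct_pi = pct,
             usable = rep_len(usable, length(t)))
}
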