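## FCS 3.1 listmode I/O, restricted to the dialect the control loop needs:
## single dataset, $MODE L, $DATATYPE F (written) or I with linear scaling
## (read), little- or big-endian. Custom keywords CYTOLOOP$DILUTION,
## CYTOLOOP$SAMPLEID and CYTOLOOP$ACQHOURS carry sampling metadata.

.FCS_HEADER_LEN <- 58L
.MONTHS <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
             "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")

.formatFcsDate <- function(posix) {
  lt <- as.POSIXlt(posix, tz = "UTC")
  sprintf("%02d-%s-%04d", lt$mday, .MONTHS[lt$mon + 1L], lt$year + 1900L)
}

.parseFcsDate <- function(s) {
  parts <- strsplit(toupper(trimws(s)), "-", fixed = TRUE)[[1]]
  if (length(parts) != 3) return(NULL)
  mon <- match(parts[2], .MONTHS)
  if (is.na(mon)) return(NULL)
  tryCatch(
    as.POSIXct(sprintf("%s-%02d-%s 00:00:00", parts[3], mon, parts[1]),
               tz = "UTC"),
    error = function(e) NULL)
}

.parseBtimHours <- function(s) {
  parts <- strsplit(trimws(s), ":", fixed = TRUE)[[1]]
  if (length(parts) < 3) return(NULL)
  h <- suppressWarnings(as.numeric(parts[1]))
  m <- suppressWarnings(as.numeric(parts[2]))
  sec <- suppressWarnings(as.numeric(parts[3]))
  if (anyNA(c(h, m, sec))) return(NULL)
  h + m / 60 + sec / 3600
}

#' Write an EventTable as an FCS 3.1 file
#'
#' Emits a single-dataset listmode file: $DATATYPE F (32-bit IEEE float),
#' $BYTEORD 1,2,3,4 (little-endian), one 32-bit value per channel per event.
#' $BTIM/$DATE are derived from the acquisition time relative to \code{t0},
#' and custom keywords carry the dilution factor, sample id and the exact
#' decimal-hour acquisition time (so a round trip preserves the clock
#' exactly; floats are rounded to single precision by the format).
#'
#' @param table an \linkS4class{EventTable}; zero events is legal.
#' @param path output file path.
#' @param t0 POSIXct instant corresponding to feed start (t = 0 h); used only
#'   to render $BTIM/$DATE.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readFCS}}
#' @export
writeFCS <- function(table, path,
                     t0 = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  stopifnot(is(table, "EventTable"))
  ev <- table@events
  if (length(ev) && (any(!is.finite(ev)) || any(ev < 0)))
    stopValidationError("event intensities must be finite and non-negative")
  if (ncol(ev) < 1) stopValidationError("at least one channel is required")
  chn <- colnames(ev)
  if (any(grepl("/", chn, fixed = TRUE)) ||
      grepl("/", table@sampleId, fixed = TRUE))
    stopValidationError("channel names and sample id must not contain '/'")

  nTot <- nrow(ev)
  nPar <- ncol(ev)
  acq <- as.POSIXct(t0, tz = "UTC") + table@acquiredAt * 3600
  lt <- as.POSIXlt(acq, tz = "UTC")
  btim <- sprintf("%02d:%02d:%02d", lt$hour, lt$min, floor(lt$sec))

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = as.character(nTot), "$PAR" = as.character(nPar),
    "$BTIM" = btim, "$DATE" = .formatFcsDate(acq),
    "CYTOLOOP$DILUTION" = sprintf("%.10g", table@dilutionFactor),
    "CYTOLOOP$SAMPLEID" = table@sampleId,
    "CYTOLOOP$ACQHOURS" = sprintf("%.12g", table@acquiredAt)
  )
  for (i in seq_len(nPar)) {
    kw[sprintf("$P%dN", i)] <- chn[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <-
      as.character(max(1, ceiling(if (nTot) max(ev[, i]) else 1)))
  }

  ## zero-padded 10-char data offsets: filling in the real values after
  ## measuring the segment cannot change the text length
  buildText <- function(bd, ed) {
    kw[["$BEGINDATA"]] <- sprintf("%010.0f", bd)
    kw[["$ENDDATA"]] <- sprintf("%010.0f", ed)
    paste0("/", paste0(names(kw), "/", kw, collapse = "/"), "/")
  }
  dataBytes <- as.numeric(nTot) * nPar * 4
  dataStart <- .FCS_HEADER_LEN + nchar(buildText(0, 0), type = "bytes")
  text <- if (dataBytes > 0) buildText(dataStart, dataStart + dataBytes - 1)
          else buildText(0, 0)

  hdrNum <- function(x) {
    s <- sprintf("%8d", x)
    if (nchar(s) > 8) "       0" else s   # too large for the header: use TEXT
  }
  textEnd <- dataStart - 1L
  header <- paste0("FCS3.1    ",
                   hdrNum(.FCS_HEADER_LEN), hdrNum(textEnd),
                   if (dataBytes > 0) hdrNum(dataStart) else hdrNum(0L),
                   if (dataBytes > 0) hdrNum(dataStart + dataBytes - 1L)
                   else hdrNum(0L),
                   hdrNum(0L), hdrNum(0L))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (dataBytes > 0)
    writeBin(as.vector(t(ev)), con, size = 4L, endian = "little")
  invisible(path)
}

## Parse the TEXT segment of an FCS file into a named character vector
## ($-keywords normalised to upper case).
.parseFcsText <- function(bytes) {
  txt <- rawToChar(bytes)
  delim <- substr(txt, 1, 1)
  body <- substr(txt, 2, nchar(txt))
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) {
    if (!nzchar(parts[length(parts)])) parts <- parts[-length(parts)]
    else stopFormatError("malformed TEXT segment: odd key/value count")
  }
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  names(vals) <- toupper(trimws(keys))
  vals
}

.fcsSegments <- function(bytes, path) {
  if (length(bytes) < .FCS_HEADER_LEN)
    stopIntegrityError(sprintf("'%s': file shorter than an FCS header", path))
  version <- rawToChar(bytes[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stopFormatError(sprintf("'%s': unsupported FCS version '%s'", path, version))
  off <- function(a, b) {
    v <- suppressWarnings(as.integer(trimws(rawToChar(bytes[a:b]))))
    if (is.na(v)) stopIntegrityError(sprintf("'%s': unreadable header offset", path))
    v
  }
  list(textStart = off(11L, 18L), textEnd = off(19L, 26L),
       dataStart = off(27L, 34L), dataEnd = off(35L, 42L))
}

#' Read an FCS listmode file
#'
#' Reads a single-dataset FCS 3.0/3.1 file with $DATATYPE F (32-bit float)
#' or $DATATYPE I with linear scaling ($PnE 0,0; 16- or 32-bit), either byte
#' order. Channel names are renamed through \code{channelMap} and the result
#' must contain every channel in \code{required}. The acquisition time is
#' taken, in order of precedence, from the CYTOLOOP$ACQHOURS custom keyword
#' (exact decimal hours), from $BTIM/$DATE, or from the file modification
#' time; the chosen source is recorded in the returned object's
#' \code{timeSource} slot (and ends up in the audit log).
#'
#' @param path FCS file path.
#' @param channelMap named character vector mapping detector labels in the
#'   file to canonical names, e.g. \code{c("BL1-H" = "FL1-H")}; default
#'   identity.
#' @param required channels that must be present after mapping; default the
#'   canonical four. Use \code{character(0)} to accept any panel.
#' @param t0 optional POSIXct feed-start instant: when the time must be
#'   derived from $BTIM/$DATE or mtime, hours are computed relative to it
#'   (otherwise relative to midnight of the acquisition date).
#' @return An \linkS4class{EventTable}.
#' @examples
#' p <- tempfile(fileext = ".fcs")
#' m <- matrix(c(100, 5000, 9000, 10, 10, 10, 1, 2, 3, 0, 0, 0), nrow = 3,
#'             dimnames = list(NULL, canonicalChannels))
#' writeFCS(EventTable(m, acquiredAt = 1.5, dilutionFactor = 100), p)
#' readFCS(p)
#' @export
readFCS <- function(path, channelMap = NULL, required = canonicalChannels,
                    t0 = NULL) {
  if (!file.exists(path)) stopIOError(sprintf("no such file: '%s'", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  seg <- .fcsSegments(bytes, path)
  if (seg$textEnd > length(bytes) || seg$textStart >= seg$textEnd)
    stopIntegrityError(sprintf("'%s': TEXT segment out of bounds", path))
  kw <- .parseFcsText(bytes[(seg$textStart + 1L):(seg$textEnd + 1L)])

  need <- function(key) {
    if (is.na(kw[key]) || !nzchar(kw[key]))
      stopFormatError(sprintf("'%s': required keyword %s missing", path, key))
    kw[[key]]
  }
  if (!is.na(kw["$MODE"]) && toupper(kw[["$MODE"]]) != "L")
    stopFormatError(sprintf("'%s': only listmode ($MODE L) is supported", path))
  if (!is.na(kw["$NEXTDATA"]) && as.integer(kw[["$NEXTDATA"]]) != 0)
    stopFormatError(sprintf("'%s': multi-dataset files are not supported", path))

  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "I"))
    stopFormatError(sprintf("'%s': unsupported $DATATYPE '%s'", path, dtype))
  byteord <- gsub(" ", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stopFormatError(sprintf("'%s': unsupported $BYTEORD '%s'",
                                         path, byteord))

  nTot <- as.integer(need("$TOT"))
  nPar <- as.integer(need("$PAR"))
  if (is.na(nTot) || is.na(nPar) || nPar < 1)
    stopFormatError(sprintf("'%s': invalid $TOT/$PAR", path))

  chn <- vapply(seq_len(nPar),
                function(i) need(sprintf("$P%dN", i)), character(1))
  bits <- vapply(seq_len(nPar),
                 function(i) as.integer(need(sprintf("$P%dB", i))), integer(1))
  if (dtype == "F" && any(bits != 32L))
    stopFormatError(sprintf("'%s': $DATATYPE F requires $PnB 32", path))
  if (dtype == "I") {
    if (length(unique(bits)) != 1L || !bits[1] %in% c(16L, 32L))
      stopFormatError(sprintf("'%s': $DATATYPE I needs uniform $PnB 16 or 32",
                              path))
    for (i in seq_len(nPar)) {
      pe <- gsub(" ", "", kw[sprintf("$P%dE", i)])
      if (!is.na(pe) && !pe %in% c("0,0", "0.0,0.0", "0,0.0", "0.0,0"))
        stopFormatError(sprintf(
          "'%s': log-amplified integer data ($P%dE = %s) is not supported",
          path, i, pe))
    }
  }

  if (nTot > 0) {
    dataStart <- seg$dataStart
    dataEnd <- seg$dataEnd
    if (dataStart == 0L) {
      dataStart <- as.integer(need("$BEGINDATA"))
      dataEnd <- as.integer(need("$ENDDATA"))
    }
    bytesPer <- bits[1] %/% 8L
    expected <- as.numeric(nTot) * nPar * bytesPer
    avail <- length(bytes) - dataStart
    if (dataStart <= 0L || avail < expected)
      stopIntegrityError(sprintf(
        "'%s': truncated data segment (need %.0f bytes, have %d)",
        path, expected, max(avail, 0)))
    dat <- bytes[(dataStart + 1L):(dataStart + expected)]
    vals <- if (dtype == "F") {
      readBin(dat, "numeric", n = nTot * nPar, size = 4L, endian = endian)
    } else if (bytesPer == 2L) {
      as.numeric(readBin(dat, "integer", n = nTot * nPar, size = 2L,
                         signed = FALSE, endian = endian))
    } else {
      v <- as.numeric(readBin(dat, "integer", n = nTot * nPar, size = 4L,
                              endian = endian))
      ifelse(v < 0, v + 2^32, v)
    }
    if (any(!is.finite(vals)))
      stopIntegrityError(sprintf("'%s': non-finite values in data segment", path))
    ev <- matrix(vals, nrow = nTot, ncol = nPar, byrow = TRUE)
  } else {
    ev <- matrix(numeric(0), nrow = 0, ncol = nPar)
  }

  mapped <- chn
  if (!is.null(channelMap)) {
    hit <- chn %in% names(channelMap)
    mapped[hit] <- unname(channelMap[chn[hit]])
  }
  colnames(ev) <- mapped
  for (ch in required) if (!ch %in% mapped) stopChannelError(ch)

  tm <- .acquisitionTime(kw, path, t0)
  dil <- suppressWarnings(as.numeric(kw["CYTOLOOP$DILUTION"]))
  sid <- kw["CYTOLOOP$SAMPLEID"]
  if (is.na(sid)) sid <- kw["$FIL"]
  if (is.na(sid)) sid <- basename(path)
  EventTable(ev, sampleId = unname(sid), acquiredAt = tm$hours,
             dilutionFactor = if (is.na(dil)) 1 else dil,
             timeSource = tm$source)
}

## Acquisition time precedence: custom keyword > $BTIM(+$DATE) > file mtime.
.acquisitionTime <- function(kw, path, t0 = NULL) {
  hrs <- suppressWarnings(as.numeric(kw["CYTOLOOP$ACQHOURS"]))
  if (!is.na(hrs)) return(list(hours = hrs, source = "keyword"))
  if (!is.na(kw["$BTIM"])) {
    dayHours <- .parseBtimHours(kw[["$BTIM"]])
    if (!is.null(dayHours)) {
      date <- if (!is.na(kw["$DATE"])) .parseFcsDate(kw[["$DATE"]]) else NULL
      if (!is.null(date) && !is.null(t0)) {
        abs <- date + dayHours * 3600
        return(list(hours = as.numeric(difftime(abs, t0, units = "hours")),
                    source = "btim"))
      }
      return(list(hours = dayHours, source = "btim"))
    }
  }
  mt <- file.info(path)$mtime
  h <- if (!is.null(t0)) as.numeric(difftime(mt, t0, units = "hours"))
       else {
         lt <- as.POSIXlt(mt, tz = "UTC")
         lt$hour + lt$min / 60 + lt$sec / 3600
       }
  list(hours = h, source = "mtime")
}

#' Keyword/value pairs of an FCS file's TEXT segment
#'
#' @param path FCS file path.
#' @return Named character vector of keywords ($-keys upper-cased).
#' @export
fcsKeywords <- function(path) {
  if (!file.exists(path)) stopIOError(sprintf("no such file: '%s'", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  seg <- .fcsSegments(bytes, path)
  .parseFcsText(bytes[(seg$textStart + 1L):(seg$textEnd + 1L)])
}

#' Find new FCS samples in a watched directory
#'
#' Lists FCS files not in \code{alreadySeen}, ordered by acquisition time
#' (same precedence as \code{\link{readFCS}}; unparseable files fall back to
#' modification time) with the file name as a deterministic tiebreak.
#' Concatenating the results of repeated calls over a growing directory
#' yields each file exactly once.
#'
#' @param directory directory to scan.
#' @param alreadySeen character vector of paths already processed.
#' @param pattern file-name regexp, default \code{"\\\\.fcs$"} (case
#'   insensitive).
#' @param t0 optional POSIXct feed-start instant for time conversion.
#' @return Character vector of unseen paths in acquisition-time order.
#' @export
discoverNewSamples <- function(directory, alreadySeen = character(),
                               pattern = "\\.fcs$", t0 = NULL) {
  if (!dir.exists(directory))
    stopIOError(sprintf("cannot read directory '%s'", directory))
  paths <- list.files(directory, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  paths <- setdiff(normalizePath(paths, mustWork = FALSE),
                   normalizePath(alreadySeen, mustWork = FALSE))
  if (!length(paths)) return(character(0))
  times <- vapply(paths, function(p) {
    tryCatch(.acquisitionTime(fcsKeywords(p), p, t0)$hours,
             error = function(e) {
               mt <- file.info(p)$mtime
               if (!is.null(t0)) as.numeric(difftime(mt, t0, units = "hours"))
               else as.numeric(mt) / 3600
             })
  }, numeric(1))
  paths[order(times, basename(paths), method = "radix")]
}
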