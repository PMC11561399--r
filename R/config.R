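## Plain-text run configuration: sectioned "key = value" files.
## Sections: [run], [paths], [gate], [trend], [controller], [sim],
## [actuator]. Lines starting with '#' or ';' are comments. Numeric values,
## TRUE/FALSE, and comma-separated numeric vectors are auto-converted.

.parseIni <- function(path) {
  if (!file.exists(path)) stopConfigError(sprintf("config file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- "global"
  for (ln in lines) {
    ln <- trimws(sub("[#;].*$", "", ln))
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3)
      stopConfigError(sprintf("cannot parse config line: '%s'", ln))
    key <- tolower(trimws(kv[2]))
    val <- trimws(kv[3])
    out[[section]][[key]] <- .coerceConfigValue(val)
  }
  out
}

.coerceConfigValue <- function(val) {
  if (toupper(val) %in% c("TRUE", "YES", "ON")) return(TRUE)
  if (toupper(val) %in% c("FALSE", "NO", "OFF")) return(FALSE)
  if (grepl(",", val, fixed = TRUE)) {
    parts <- suppressWarnings(as.numeric(trimws(strsplit(val, ",")[[1]])))
    if (!anyNA(parts)) return(parts)
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

.GATE_KEYS <- c(fsc_min = "fscMin", fl3_threshold = "fl3Threshold",
                fl1_threshold = "fl1Threshold", min_events = "minEvents",
                mfi_population = "mfiPopulation", mfi_scale = "mfiScale")

.CTRL_KEYS <- c(rate_ladder = "rateLadder", pi_max = "piMax",
                dwell_samples = "dwellSamples",
                safeguard_latching = "safeguardLatching",
                pi_average = "piAverage")

.SIM_KEYS <- c(mu_max = "muMax", ks_glc = "KsGlc", ks_xyl = "KsXyl",
               mu_xyl_frac = "muXylFrac", yxs = "Yxs",
               glc_switch = "glcSwitch", q_detox = "qDetox", kf = "Kf",
               k_ind = "kInd", k_relax = "kRelax", f0 = "F0",
               k_adapt = "kAdapt", k_dam = "kDam", gamma_dam = "gammaDam",
               k_rec = "kRec",
               primary_rate = "primaryRate", feed_glc = "feedGlc",
               feed_xyl = "feedXyl", feed_fur = "feedFur",
               secondary_fur = "secondaryFur", v0 = "V0", x0 = "X0",
               sg0 = "Sg0", sx0 = "Sx0", cv_fl1 = "cvFl1", cv_fl3 = "cvFl3",
               cv_fsc = "cvFsc", cv_ssc = "cvSsc",
               debris_frac = "debrisFrac",
               events_per_sample = "eventsPerSample",
               dilution_ladder = "dilutionLadder",
               events_per_proxy_unit = "eventsPerProxyUnit",
               dilution_band = "dilutionBand", dt = "dt", seed = "seed")

.mapKeys <- function(section, keymap, what) {
  if (is.null(section)) return(list())
  unknown <- setdiff(names(section), names(keymap))
  if (length(unknown))
    stopConfigError(sprintf("unknown %s key(s): %s", what,
                            paste(unknown, collapse = ", ")))
  stats::setNames(section, keymap[names(section)])
}

#' Read a run configuration file
#'
#' Parses a sectioned key = value file into the objects the workflows need:
#' a \linkS4class{GateConfig} (section \code{[gate]}), a
#' \linkS4class{ControllerConfig} (\code{[controller]}), trend parameters
#' (\code{[trend]}: \code{alpha}, \code{k}, \code{slope_on}), a
#' \linkS4class{SimParams} (\code{[sim]}), file-system paths
#' (\code{[paths]}: \code{watch_dir}, \code{out_dir}, \code{stats_csv},
#' \code{audit_log}), actuator settings (\code{[actuator]}: \code{type} =
#' mock|serial, \code{port}, \code{timeout}) and run options (\code{[run]}:
#' \code{mode}, \code{poll_interval}, \code{log_level}). Channel mapping
#' entries live in \code{[channels]} as \code{<detector label> =
#' <canonical name>}. Every section is optional; omitted values take the
#' package defaults.
#'
#' @param path configuration file path.
#' @return A list with elements \code{mode}, \code{gate}, \code{controller},
#'   \code{trend}, \code{sim}, \code{paths}, \code{actuator},
#'   \code{channelMap}, \code{pollInterval}, \code{logLevel}.
#' @examples
#' cfgFile <- system.file("extdata", "example.cfg", package = "cytoloop")
#' conf <- readRunConfig(cfgFile)
#' conf$controller
#' @export
readRunConfig <- function(path) {
  ini <- .parseIni(path)
  gate <- do.call(GateConfig, .mapKeys(ini$gate, .GATE_KEYS, "gate"))
  ctrl <- do.call(ControllerConfig,
                  .mapKeys(ini$controller, .CTRL_KEYS, "controller"))
  sim <- do.call(SimParams, .mapKeys(ini$sim, .SIM_KEYS, "sim"))
  trend <- list(alpha = ini$trend$alpha %||% 0.5,
                k = as.integer(ini$trend$k %||% 3L),
                slopeOn = ini$trend$slope_on %||% "ema")
  channelMap <- if (!is.null(ini$channels))
    unlist(ini$channels) else NULL
  if (!is.null(channelMap)) {
    ## detector labels are case-sensitive instrument strings; the ini parser
    ## lower-cases keys, so channel maps use upper case on both sides
    names(channelMap) <- toupper(names(channelMap))
  }
  list(
    mode = ini$run$mode %||% "analyze",
    pollInterval = ini$run$poll_interval %||% 60,
    logLevel = ini$run$log_level %||% "info",
    gate = gate, controller = ctrl, trend = trend, sim = sim,
    channelMap = channelMap,
    paths = list(watchDir = ini$paths$watch_dir %||% ".",
                 outDir = ini$paths$out_dir %||% "cytoloop_out",
                 statsCsv = ini$paths$stats_csv %||% "stats.csv",
                 auditLog = ini$paths$audit_log %||% "audit.jsonl"),
    actuator = list(type = ini$actuator$type %||% "mock",
                    port = ini$actuator$port %||% "",
                    timeout = ini$actuator$timeout %||% 2)
  )
}
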