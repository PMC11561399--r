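quietLog <- function(...) invisible(NULL)

## A directory of synthetic acquisitions with a known decline, so the
## controller fires predictably when run over the files.
makeSampleDir <- function(d, mfiProfile, piProfile = NULL, n = 400L,
                          seed = 50L) {
  p <- SimParams(eventsPerSample = n, seed = seed, debrisFrac = 0.05)
  if (is.null(piProfile)) piProfile <- rep(0.05, length(mfiProfile))
  for (i in seq_along(mfiProfile)) {
    st <- initialSimState(p)
    st@t <- i * 0.5
    st@Fl <- mfiProfile[i]
    st@D <- piProfile[i]
    tab <- synthesizeSample(st, p, sampleIndex = i, runId = "dirtest")
    writeFCS(tab, file.path(d, sprintf("s%03d.fcs", i)))
  }
  invisible(d)
}

mfiTen <- c(150, 220, 300, 380, 420, 430, 410, 360, 300, 250)

test_that("runAnalyze reproduces the time series deterministically", {
  d <- withr::local_tempdir()
  makeSampleDir(d, mfiTen)
  csv1 <- withr::local_tempfile(fileext = ".csv")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  hist1 <- withr::local_tempfile(fileext = ".csv")
  stats <- runAnalyze(d, statsCsv = csv1, histCsv = hist1, logFun = quietLog)
  runAnalyze(d, statsCsv = csv2, logFun = quietLog)
  expect_identical(nrow(stats), 10L)
  expect_identical(readLines(csv1), readLines(csv2))
  expect_true(all(diff(stats$t) > 0))
  ## MFI tracks the programmed fluorescence profile
  expect_gt(cor(stats$mfi_gfp, mfiTen), 0.99)
  h <- read.csv(hist1)
  expect_setequal(names(h), c("sample_id", "t", "bin_lo", "bin_hi", "count"))
  expect_identical(length(unique(h$sample_id)), 10L)
})

test_that("runAnalyze on an empty directory writes a header-only CSV", {
  d <- withr::local_tempdir()
  csv <- withr::local_tempfile(fileext = ".csv")
  stats <- runAnalyze(d, statsCsv = csv, logFun = quietLog)
  expect_identical(nrow(stats), 0L)
  got <- read.csv(csv)
  expect_identical(nrow(got), 0L)
  expect_true(all(c("sample_id", "t", "mfi_gfp", "pct_pi") %in% names(got)))
})

test_that("control over a static directory matches runSession on the same stats", {
  d <- withr::local_tempdir()
  makeSampleDir(d, mfiTen)
  pump <- MockPump()
  csv <- file.path(d, "stats.csv")
  audit <- file.path(d, "audit.jsonl")
  res <- runControl(d, pump = pump, statsCsv = csv, auditPath = audit,
                    pollInterval = 0, maxPolls = 1, logFun = quietLog)
  stats <- read.csv(csv)
  expect_identical(nrow(stats), 10L)

  offline <- runSession(stats, ControllerConfig())
  expect_equal(res$commands$rate, offline$commands$rate)
  expect_identical(res$commands$cause, offline$commands$cause)
  ## the pump saw every command plus the shutdown stop
  expect_identical(commandedRates(pump),
                   c(offline$commands$rate, 0))
  ## the audit log replays to the same command sequence
  replay <- readAuditLog(audit)
  n <- nrow(offline$commands)
  expect_equal(replay$commands$rate[seq_len(n)], offline$commands$rate)
  ## final audit record is the rate-0 shutdown contract
  last <- replay$records[[length(replay$records)]]
  expect_identical(last$cause, "shutdown")
  expect_identical(last$rate, 0L)
})

test_that("a corrupt file is quarantined and the loop continues", {
  d <- withr::local_tempdir()
  makeSampleDir(d, mfiTen[1:5])
  writeLines("this is not an FCS file", file.path(d, "s000.fcs"))
  csv <- file.path(d, "stats.csv")
  res <- runControl(d, statsCsv = csv,
                    auditPath = file.path(d, "audit.jsonl"),
                    pollInterval = 0, maxPolls = 1, logFun = quietLog)
  expect_identical(nrow(read.csv(csv)), 5L)
  expect_true(file.exists(file.path(d, "quarantine", "s000.fcs")))
  expect_false(file.exists(file.path(d, "s000.fcs")))
})

test_that("a restarted control session resumes trend state exactly", {
  d <- withr::local_tempdir()
  makeSampleDir(d, mfiTen)
  csvA <- file.path(d, "a.csv"); audA <- file.path(d, "a.jsonl")
  one <- runControl(d, statsCsv = csvA, auditPath = audA,
                    pollInterval = 0, maxPolls = 1, logFun = quietLog)

  ## same data split across two sessions into fresh artifacts
  d2 <- withr::local_tempdir()
  files <- list.files(d, pattern = "^s.*fcs$", full.names = TRUE)
  csvB <- file.path(d2, "b.csv"); audB <- file.path(d2, "b.jsonl")
  file.copy(files[1:6], d2)
  runControl(d2, statsCsv = csvB, auditPath = audB,
             pollInterval = 0, maxPolls = 1, logFun = quietLog)
  file.copy(files[7:10], d2)
  two <- runControl(d2, statsCsv = csvB, auditPath = audB,
                    pollInterval = 0, maxPolls = 1, logFun = quietLog)

  a <- read.csv(csvA); b <- read.csv(csvB)
  expect_equal(b$mfi_ema, a$mfi_ema)
  expect_equal(b$pi_ema, a$pi_ema)
  ## and the second half's commands agree with the single-session run
  expect_equal(two$commands$rate, one$commands$rate[7:10])
  expect_identical(two$commands$cause, one$commands$cause[7:10])
})

test_that("runSimulate writes coherent artifacts in both modes", {
  d <- withr::local_tempdir()
  p <- SimParams(eventsPerSample = 300L)
  trajF <- file.path(d, "traj_f.csv")
  resF <- runSimulate(p, duration = 3, mode = "fixed", seed = 41,
                      trajectoryCsv = trajF,
                      statsCsv = file.path(d, "stats_f.csv"))
  resC <- runSimulate(p, duration = 3, mode = "controlled", seed = 41,
                      statsCsv = file.path(d, "stats_c.csv"),
                      auditPath = file.path(d, "audit_c.jsonl"))
  expect_identical(nrow(read.csv(trajF)), 6L)
  expect_identical(nrow(read.csv(file.path(d, "stats_c.csv"))), 6L)
  ## below three usable samples nothing can trigger; and the sensor-
  ## controlled arm never adds less furfural than the fixed arm
  expect_true(all(resC$commands$rate[1:2] == 0))
  expect_gte(tail(resC$trajectory$cum_fur_in, 1),
             tail(resF$trajectory$cum_fur_in, 1))
  ## identical config and seed: identical artifacts
  resC2 <- runSimulate(p, duration = 3, mode = "controlled", seed = 41)
  expect_identical(resC2$trajectory, resC$trajectory)
})

test_that("the example configuration file parses into the expected objects", {
  cfgFile <- system.file("extdata", "example.cfg", package = "cytoloop")
  conf <- readRunConfig(cfgFile)
  expect_identical(conf$mode, "simulate")
  expect_s4_class(conf$gate, "GateConfig")
  expect_s4_class(conf$controller, "ControllerConfig")
  expect_s4_class(conf$sim, "SimParams")
  expect_identical(conf$controller@rateLadder, c(1, 1.5, 3, 5))
  expect_identical(conf$controller@piMax, 35)
  expect_identical(conf$sim@primaryRate, 6.24)
  expect_identical(conf$sim@feedFur, 6.9)
  expect_identical(conf$sim@secondaryFur, 50)
  expect_identical(conf$trend$alpha, 0.5)
  expect_identical(conf$actuator$type, "mock")
})

test_that("unknown configuration keys are rejected", {
  f <- withr::local_tempfile(lines = c("[gate]", "fsc_minimum = 5"))
  expect_error(readRunConfig(f), class = "cytoloop_config_error")
})
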