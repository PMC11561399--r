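## alpha = 1 makes the smoothed series equal the raw series, so decision
## signals can be engineered exactly from the raw values fed in.
mkState <- function(mfiHist, piHist, tHist = NULL, pumpOn = FALSE,
                    ladderIndex = 0L, samplesAtRate = 0L) {
  n <- length(mfiHist)
  if (is.null(tHist)) tHist <- seq_len(n) * 0.5
  st <- ControllerState(alpha = 1)
  st@mfiTrend <- trendFromValues(tHist, mfiHist, mfiHist, alpha = 1)
  st@piTrend <- trendFromValues(tHist, piHist, piHist, alpha = 1)
  st@pumpOn <- pumpOn
  st@ladderIndex <- as.integer(ladderIndex)
  st@samplesAtRate <- as.integer(samplesAtRate)
  st
}

nextStats <- function(state, mfi, pct) {
  tPrev <- max(c(0, state@mfiTrend@times, state@piTrend@times))
  PopulationStats(t = tPrev + 0.5, mfiGfp = mfi, pctPi = pct)
}

cfgD <- ControllerConfig()

test_that("a negative MFI slope starts the pump at the bottom of the ladder", {
  st <- mkState(mfiHist = c(300, 260), piHist = c(12, 11))
  res <- evaluateController(st, nextStats(st, 220, 10), cfgD)
  expect_identical(res$command$cause, "induction_decline_start")
  expect_identical(res$command$rate, 1)
  expect_true(res$state@pumpOn)
  expect_identical(res$state@ladderIndex, 1L)
  expect_identical(res$state@samplesAtRate, 0L)
})

test_that("no action is taken before three usable samples exist", {
  st <- mkState(mfiHist = c(300), piHist = c(10))
  res <- evaluateController(st, nextStats(st, 200, 10), cfgD)
  expect_identical(res$command$cause, "hold")
  expect_identical(res$command$rate, 0)
})

test_that("a slope of exactly zero never triggers", {
  st <- mkState(mfiHist = c(250, 250), piHist = c(10, 10))
  res <- evaluateController(st, nextStats(st, 250, 10), cfgD)
  expect_identical(res$command$cause, "hold")
})

test_that("escalation walks the ladder one step at a time after the dwell", {
  st <- mkState(mfiHist = c(300, 260), piHist = c(10, 9),
                pumpOn = TRUE, ladderIndex = 1L, samplesAtRate = 3L)
  res <- evaluateController(st, nextStats(st, 220, 8), cfgD)
  expect_identical(res$command$cause, "escalate")
  expect_identical(res$command$rate, 1.5)

  ## dwell not yet met: hold at the current rate
  st2 <- mkState(mfiHist = c(300, 260), piHist = c(10, 9),
                 pumpOn = TRUE, ladderIndex = 1L, samplesAtRate = 2L)
  res2 <- evaluateController(st2, nextStats(st2, 220, 8), cfgD)
  expect_identical(res2$command$cause, "hold")
  expect_identical(res2$command$rate, 1)
  expect_identical(res2$state@samplesAtRate, 3L)

  ## the top rate is absorbing (no escalation beyond 5 mL/hr)
  st3 <- mkState(mfiHist = c(300, 260), piHist = c(10, 9),
                 pumpOn = TRUE, ladderIndex = 4L, samplesAtRate = 5L)
  res3 <- evaluateController(st3, nextStats(st3, 220, 8), cfgD)
  expect_identical(res3$command$cause, "hold")
  expect_identical(res3$command$rate, 5)
})

test_that("the safeguard overrides any start or escalation", {
  ## percent PI above the ceiling: stop, regardless of a falling MFI
  st <- mkState(mfiHist = c(300, 260), piHist = c(38, 39),
                pumpOn = TRUE, ladderIndex = 3L, samplesAtRate = 4L)
  res <- evaluateController(st, nextStats(st, 220, 43), cfgD)
  expect_identical(res$command$cause, "safeguard_stop")
  expect_identical(res$command$rate, 0)
  expect_false(res$state@pumpOn)

  ## rising PI slope alone is enough, even below the ceiling
  st2 <- mkState(mfiHist = c(300, 260), piHist = c(8, 10),
                 pumpOn = TRUE, ladderIndex = 1L, samplesAtRate = 1L)
  res2 <- evaluateController(st2, nextStats(st2, 220, 12), cfgD)
  expect_identical(res2$command$cause, "safeguard_stop")

  ## engineered to satisfy start and safeguard at once: safeguard wins
  st3 <- mkState(mfiHist = c(300, 260), piHist = c(36, 37))
  res3 <- evaluateController(st3, nextStats(st3, 220, 39), cfgD)
  expect_identical(res3$command$cause, "safeguard_stop")
  expect_false(res3$state@pumpOn)
})

test_that("after a safeguard stop the pump restarts from the ladder bottom", {
  st <- mkState(mfiHist = c(300, 260, 220, 210), piHist = c(40, 38, 30, 25),
                pumpOn = FALSE, ladderIndex = 3L, samplesAtRate = 1L)
  st@safeguardActive <- TRUE
  res <- evaluateController(st, nextStats(st, 190, 20), cfgD)
  expect_identical(res$command$cause, "induction_decline_start")
  expect_identical(res$command$rate, 1)

  ## latching mode: the pump stays off even after PI conditions clear
  cfgLatch <- ControllerConfig(safeguardLatching = TRUE)
  st2 <- mkState(mfiHist = c(300, 260, 220, 210), piHist = c(40, 38, 30, 25),
                 pumpOn = FALSE, ladderIndex = 3L, samplesAtRate = 1L)
  st2@safeguardActive <- TRUE
  res2 <- evaluateController(st2, nextStats(st2, 190, 20), cfgLatch)
  expect_identical(res2$command$rate, 0)
  expect_true(res2$state@safeguardActive)
})

test_that("the last-k-mean safeguard average is available as an option", {
  cfgMean <- ControllerConfig(piAverage = "last_k_mean")
  ## raw values average above the ceiling while each is non-monotone
  st <- mkState(mfiHist = c(250, 260), piHist = c(40, 36))
  res <- evaluateController(st, nextStats(st, 270, 36), cfgMean)
  expect_identical(res$command$cause, "safeguard_stop")
})

test_that("runSession reproduces hand-simulated command sequences", {
  ## monotone rising MFI: the trigger never fires
  up <- statsFrame(t = (1:8) / 2, mfi = seq(100, 450, 50), pct = rep(5, 8))
  resUp <- runSession(up, cfgD, alpha = 1)
  expect_true(all(resUp$commands$cause == "hold"))
  expect_true(all(resUp$commands$rate == 0))

  ## six rising then three falling samples: exactly one start, at the first
  ## evaluation where the three-point slope turns negative (sample 8)
  mfi <- c(100, 150, 220, 300, 360, 400, 390, 340, 280)
  stream <- statsFrame(t = (1:9) / 2, mfi = mfi, pct = rep(5, 9))
  res <- runSession(stream, cfgD, alpha = 1)
  starts <- which(res$commands$cause == "induction_decline_start")
  expect_identical(starts, 8L)
  expect_identical(res$commands$rate[8], 1)

  ## empty stream
  resE <- runSession(list(), cfgD)
  expect_identical(nrow(resE$commands), 0L)
})

test_that("runSession enforces time ordering and logs unusable samples", {
  bad <- statsFrame(t = c(1, 1), mfi = c(10, 10), pct = c(1, 1))
  expect_error(runSession(bad, cfgD), class = "cytoloop_ordering_error")

  mix <- statsFrame(t = (1:5) / 2, mfi = c(300, 280, 260, 240, 220),
                    pct = rep(5, 5), usable = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  res <- runSession(mix, cfgD, alpha = 1)
  causes <- vapply(res$audit, function(r) r$cause, character(1))
  expect_identical(sum(causes == "skip_unusable"), 1L)
  ## the skipped sample is absent from the command sequence
  expect_identical(nrow(res$commands), 4L)
})

test_that("audit logs are byte-identical across runs and replay to the same commands", {
  set.seed(16)
  stream <- statsFrame(t = (1:20) / 2,
                       mfi = 300 + cumsum(rnorm(20, -5, 20)),
                       pct = pmax(0, 10 + cumsum(rnorm(20, 0, 1))))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  r1 <- runSession(stream, cfgD, auditPath = f1)
  r2 <- runSession(stream, cfgD, auditPath = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  replay <- readAuditLog(f1)
  expect_equal(replay$commands$rate, r1$commands$rate)
  expect_identical(replay$commands$cause, r1$commands$cause)
})
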