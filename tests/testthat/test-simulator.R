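test_that("zero feed with no furfural is an absorbing state", {
  p <- SimParams(primaryRate = 0, dt = 0.01)
  st <- initialSimState(p)
  st@Fl <- 500   # start above basal: must relax back down
  for (i in 1:1500) st <- simStep(st, p, 0)
  expect_identical(st@Cf, 0)
  expect_identical(st@cumFurIn, 0)
  expect_lt(abs(st@Fl - p@F0), 5)   # relaxed back after 15 h >> 1/kRelax
  expect_identical(st@A, 0)          # adaptation needs furfural exposure
})

test_that("with detoxification off, furfural in broth equals the fed mass", {
  p <- SimParams(qDetox = 0, muMax = 0, kDam = 0, dt = 0.01)
  st <- initialSimState(p)
  for (i in 1:1000) st <- simStep(st, p, 2)   # 10 h, constant rates
  fed <- (p@primaryRate * p@feedFur + 2 * p@secondaryFur) * 10
  expect_equal(st@cumFurIn, fed, tolerance = 1e-10)
  expect_equal(st@Cf * st@V * 1000, fed, tolerance = 1e-6)
})

test_that("furfural mass balance closes within 0.5% at dt = 0.01", {
  p <- SimParams(dt = 0.01)
  st <- initialSimState(p)
  for (i in 1:3000) st <- simStep(st, p, 0.5)
  mb <- furfuralMassBalance(st)
  expect_gt(mb$added, 100)
  expect_lt(abs(mb$relative), 0.005)
})

test_that("fluorescence reaches the analytic fixed point without adaptation", {
  ## constant Cf (no feed, no detox, no growth), kAdapt = 0:
  ## Fl* = F0 + kInd * Cf / kRelax
  p <- SimParams(kAdapt = 0, qDetox = 0, primaryRate = 0, muMax = 0,
                 kDam = 0, dt = 0.01)
  st <- initialSimState(p)
  st@Cf <- 0.5
  for (i in 1:2000) st <- simStep(st, p, 0)   # 20 h >> 1 / kRelax
  pred <- p@F0 + p@kInd * 0.5 / p@kRelax
  expect_lt(abs(st@Fl - pred) / pred, 0.01)
})

test_that("steady-state fluorescence responds monotonically to furfural dose", {
  p <- SimParams(kAdapt = 0, qDetox = 0, primaryRate = 0, muMax = 0,
                 kDam = 0, dt = 0.01)
  final <- vapply(c(0.1, 0.3, 0.6, 1.2), function(cf) {
    st <- initialSimState(p)
    st@Cf <- cf
    for (i in 1:1500) st <- simStep(st, p, 0)
    st@Fl
  }, numeric(1))
  expect_true(all(diff(final) > 0))
})

test_that("the integrator shows fourth-order convergence on a smooth problem", {
  runTo <- function(h) {
    p <- SimParams(dt = h, glcSwitch = 0)   # no diauxic-switch kink
    st <- initialSimState(p)
    st@Cf <- 0.3
    for (i in seq_len(round(1 / h))) st <- simStep(st, p, 1)
    st
  }
  ref <- runTo(0.000125)
  err <- function(s) abs(s@Fl - ref@Fl) + 1000 * abs(s@Cf - ref@Cf)
  e <- vapply(c(0.04, 0.02, 0.01), function(h) err(runTo(h)), numeric(1))
  orders <- log2(e[-3] / e[-1])
  expect_true(all(orders > 3))
})

test_that("the trajectory agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- SimParams(glcSwitch = 0, dt = 0.01)
  st0 <- initialSimState(p)
  st0@Cf <- 0.2
  rhs <- function(t, y, parms) list(simDerivs(y, p, 1.5))
  y0 <- c(V = st0@V, X = st0@X, Sg = st0@Sg, Sx = st0@Sx, Cf = st0@Cf,
          A = st0@A, Fl = st0@Fl, D = st0@D, cumFurIn = 0, cumFurDetox = 0)
  sol <- deSolve::ode(y0, seq(0, 5, 0.5), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  st <- st0
  for (i in 1:500) st <- simStep(st, p, 1.5)
  final <- sol[nrow(sol), ]
  expect_equal(st@Fl, unname(final[["Fl"]]), tolerance = 1e-6)
  expect_equal(st@Cf, unname(final[["Cf"]]), tolerance = 1e-6)
  expect_equal(st@X, unname(final[["X"]]), tolerance = 1e-6)
})

test_that("synthesized samples have exact counts and are seed-reproducible", {
  p <- SimParams(eventsPerSample = 5000L, seed = 21L)
  st <- initialSimState(p)
  st@Fl <- 300; st@D <- 0.2
  tab1 <- synthesizeSample(st, p, sampleIndex = 3L)
  tab2 <- synthesizeSample(st, p, sampleIndex = 3L)
  expect_identical(nEvents(tab1), 5000L)
  expect_identical(eventMatrix(tab1), eventMatrix(tab2))
  ## different substream, different draws
  tab3 <- synthesizeSample(st, p, sampleIndex = 4L)
  expect_false(identical(eventMatrix(tab1), eventMatrix(tab3)))
})

test_that("without damage or debris, no events cross the PI threshold", {
  p <- SimParams(eventsPerSample = 5000L, debrisFrac = 0, seed = 22L)
  st <- initialSimState(p)
  st@D <- 0
  tab <- synthesizeSample(st, p, sampleIndex = 1L)
  gate <- GateConfig()
  labs <- classifyEvents(tab, gate)
  ## intact FL3 median 40 vs threshold 400 is > 5 sd of the lognormal away
  expect_identical(sum(labs == "damaged"), 0L)
  expect_identical(sum(labs == "debris"), 0L)
})

test_that("synthesis class fractions track the broth state", {
  p <- SimParams(eventsPerSample = 20000L, debrisFrac = 0.05, seed = 23L)
  st <- initialSimState(p)
  st@Fl <- 400; st@D <- 0.3
  tab <- synthesizeSample(st, p, sampleIndex = 1L)
  stt <- summarizeSample(tab, classifyEvents(tab, GateConfig()), GateConfig())
  expect_equal(stt@nDebris / stt@nTotal, 0.05, tolerance = 0.25)
  expect_equal(stt@pctPi, 30, tolerance = 0.05)
  ## MFI of intact cells follows Fl up to the lognormal mean factor
  expect_equal(stt@mfiGfp, 400 * sqrt(1 + p@cvFl1^2), tolerance = 0.02)
})

test_that("chooseDilution saturates, steps at band edges, and matches its predictor", {
  ladder <- c(10, 100, 1000)
  expect_identical(chooseDilution(1e-6, 5000, ladder), 10)
  expect_identical(chooseDilution(1e6, 5000, ladder), 1000)
  ## exactly at the band edge: the larger factor wins (documented tiebreak)
  ## predicted(10) = band * target exactly when proxy = band*target*10/coef
  ## (values chosen to be exactly representable in binary)
  coef <- 1e5; band <- 1.5; target <- 5000
  edge <- band * target * 10 / coef
  expect_identical(chooseDilution(edge, target, ladder, coef, band), 100)
  expect_identical(chooseDilution(edge * 0.999, target, ladder, coef, band), 10)
  ## exhaustive check against the predictor over a density sweep
  for (proxy in seq(0.01, 3, length.out = 47)) {
    got <- chooseDilution(proxy, target, ladder, coef, band)
    want <- ladder[which(coef * proxy / ladder < band * target)]
    want <- if (length(want)) want[1] else ladder[length(ladder)]
    expect_identical(got, want)
  }
})

test_that("closed-loop runs are deterministic given the master seed", {
  p <- SimParams(eventsPerSample = 400L, seed = 31L)
  r1 <- runClosedLoop(p, duration = 6, mode = "controlled")
  r2 <- runClosedLoop(p, duration = 6, mode = "controlled")
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$stats, r2$stats)
  expect_identical(
    jsonlite::toJSON(r1$audit, auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(r2$audit, auto_unbox = TRUE, digits = NA))
})

test_that("closed-loop FCS output is consumed through the file interface", {
  d <- withr::local_tempdir()
  p <- SimParams(eventsPerSample = 300L, seed = 32L)
  res <- runClosedLoop(p, duration = 2, mode = "fixed", outDir = d)
  expect_length(res$files, 4)
  expect_true(all(file.exists(res$files)))
  tab <- readFCS(res$files[1])
  expect_identical(nEvents(tab), 300L)
  expect_equal(acquiredAt(tab), 0.5)
})
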