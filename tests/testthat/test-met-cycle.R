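test_that("all fluxes vanish at the zero state and negative states are rejected", {
  hep <- enzymeProfile("hepatic")
  v <- reactionFluxes(metCycleState(0, 0, 0, 0), hep)
  expect_equal(unname(v), rep(0, 9))
  expect_error(reactionFluxes(c(met = -1, sam = 1, sah = 1, hcy = 1), hep),
               "negative")
})

test_that("absent enzyme is exactly equivalent to vmax = 0", {
  s <- metCycleState(40, 40, 2, 10)
  pAbsent <- knockoutEnzymes(enzymeProfile("hepatic"), "BHMT")
  pZero <- enzymeProfile("hepatic", enzymes = list(BHMT = list(vmax = 0)))
  expect_identical(reactionFluxes(s, pAbsent), reactionFluxes(s, pZero))
  inp <- sinusoidInput(100, 0.3, 2)
  trA <- simulateMetCycle(pAbsent, inp, s, 4, 0.1)
  trZ <- simulateMetCycle(pZero, inp, s, 4, 0.1)
  expect_identical(trA@states, trZ@states)
})

test_that("flux vector matches an independent term-by-term evaluation", {
  # each rate law evaluated directly from the default constants
  hep <- enzymeProfile("hepatic")
  met <- 41; sam <- 43; sah <- 1.7; hcy <- 17
  expected <- c(
    MATI = 400 * met / (41 + met) * 50 / (50 + sam),
    MATII = 0,
    MATIII = 300 * met / (300 + met) * (1 + 7 * sam^2 / (360^2 + sam^2)),
    GNMT = 600 * sam^2 / (100^2 + sam^2) * 18 / (18 + sah),
    DNMT = 150 * sam / (50 + sam) * 20 / (20 + sah),
    AHCY = 100 * sah - 1 * hcy * 1,
    CBS = 30 * hcy * (sam + sah)^2 / (90^2 + (sam + sah)^2),
    MTR = 80 * hcy / (1 + hcy) * 5.2 / (25 + 5.2),
    BHMT = 180 * hcy / (12 + hcy) * 50 / (100 + 50))
  got <- reactionFluxes(metCycleState(met, sam, sah, hcy), hep)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("one-carbon backbone is conserved: derivative sum is input minus CBS", {
  hep <- enzymeProfile("hepatic")
  inp <- sinusoidInput(120, 0.4, 3)
  set.seed(1)
  for (i in 1:20) {
    s <- metCycleState(runif(1, 0, 100), runif(1, 0, 100),
                       runif(1, 0, 10), runif(1, 0, 30))
    t <- runif(1, 0, 10)
    d <- metCycleRHS(s, t, hep, inp)
    v <- reactionFluxes(s, hep)
    expect_equal(sum(d), inputRate(inp, t) - v[["CBS"]], tolerance = 1e-10)
  }
})

test_that("removing BHMT changes dHcy/dt by exactly its flux", {
  hep <- enzymeProfile("hepatic")
  ko <- knockoutEnzymes(hep, "BHMT")
  s <- metCycleState(40, 40, 2, 10)
  inp <- constantInput(100)
  dHep <- metCycleRHS(s, 0, hep, inp)
  dKo <- metCycleRHS(s, 0, ko, inp)
  expect_equal(dKo[["hcy"]] - dHep[["hcy"]],
               reactionFluxes(s, hep)[["BHMT"]], tolerance = 1e-10)
})

test_that("steady state satisfies root and flux-balance conditions", {
  for (ct in c("hepatic", "follicular")) {
    p <- enzymeProfile(ct)
    ss <- steadyState(p, 100)
    d <- metCycleRHS(ss, 0, p, constantInput(100))
    expect_lt(max(abs(d)), 1e-10)
    v <- reactionFluxes(ss, p)
    matTotal <- v[["MATI"]] + v[["MATII"]] + v[["MATIII"]]
    transmeth <- v[["GNMT"]] + v[["DNMT"]]
    expect_equal(matTotal, transmeth, tolerance = 1e-8)
    expect_equal(transmeth, v[["AHCY"]], tolerance = 1e-8)
    expect_equal(v[["AHCY"]], v[["MTR"]] + v[["BHMT"]] + v[["CBS"]],
                 tolerance = 1e-8)
    expect_equal(v[["CBS"]], 100, tolerance = 1e-8)  # conservation at ss
  }
})

test_that("zero input gives the empty steady state and a null trajectory", {
  hep <- enzymeProfile("hepatic")
  expect_equal(unname(steadyState(hep, 0)), rep(0, 4), tolerance = 1e-8)
  tr <- simulateMetCycle(hep, constantInput(0), metCycleState(0, 0, 0, 0), 5, 0.5)
  expect_true(all(abs(tr@states) < 1e-12))
})

test_that("long integration converges to the root-finder steady state", {
  hep <- enzymeProfile("hepatic")
  ss <- steadyState(hep, 100)
  tr <- simulateMetCycle(hep, constantInput(100), metCycleState(10, 10, 1, 1),
                         tEnd = 3000, dtReport = 50)
  terminal <- tr@states[nrow(tr@states), ]
  expect_lt(max(abs(terminal - ss)), 1e-6)
})

test_that("trajectories are non-negative and respect the mass-balance audit", {
  hep <- enzymeProfile("hepatic")
  inp <- sinusoidInput(100, 0.5, 2)
  ss <- steadyState(hep, 100)
  tr <- simulateMetCycle(hep, inp, ss, 16, 0.005)
  expect_gt(min(tr@states), -1e-9)
  total <- rowSums(tr@states)
  net <- inputRate(inp, tr@times) - tr@fluxes[, "CBS"]
  dt <- diff(tr@times)
  integral <- sum((net[-1] + net[-length(net)]) / 2 * dt)  # trapezoid
  change <- total[length(total)] - total[1]
  expect_lt(abs(integral - change), 0.001 * max(abs(change), sum(abs(net) * c(dt, 0))))
})

test_that("volatility is near zero without forcing and grows with amplitude", {
  hep <- enzymeProfile("hepatic")
  v0 <- transmethylationVolatility(hep, sinusoidInput(100, 0, 2))
  expect_lt(v0$relAmplitude, 1e-6)
  v1 <- transmethylationVolatility(hep, sinusoidInput(100, 0.15, 2))
  v2 <- transmethylationVolatility(hep, sinusoidInput(100, 0.3, 2))
  expect_lt(v1$relAmplitude, v2$relAmplitude)
  expect_gt(v1$relAmplitude, 0)
})

test_that("knockout experiment reports remethylation partition and errors", {
  hep <- enzymeProfile("hepatic")
  inp <- sinusoidInput(100, 0.3, 2)
  res <- knockoutExperiment(hep, "BHMT", inp)
  expect_equal(res$knockout$mtrFraction, 1)
  expect_lt(res$baseline$mtrFraction, 1)
  same <- knockoutExperiment(hep, character(0), inp)
  expect_equal(same$knockout$volatility$relAmplitude,
               same$baseline$volatility$relAmplitude)
  expect_error(steadyState(knockoutEnzymes(hep, c("MTR", "BHMT", "CBS")), 100),
               "non-physiological")
})

test_that("GNMT knockout raises steady-state SAM (regression value)", {
  hep <- enzymeProfile("hepatic")
  ssBase <- steadyState(hep, 100)
  ssKo <- steadyState(knockoutEnzymes(hep, "GNMT"), 100)
  expect_gt(ssKo[["sam"]], ssBase[["sam"]])
})

test_that("enzyme profiles round-trip through the YAML parameter file", {
  p <- enzymeProfile("follicular", enzymes = list(DNMT = list(vmax = 123)))
  f <- tempfile(fileext = ".yaml")
  writeEnzymeProfile(p, f)
  q <- readEnzymeProfile(f)
  expect_equal(p@enzymes, q@enzymes)
  expect_equal(p@pools, q@pools)
  s <- metCycleState(30, 30, 2, 8)
  expect_equal(reactionFluxes(s, p), reactionFluxes(s, q))
})

test_that("trajectory export writes the declared TSV layout", {
  hep <- enzymeProfile("hepatic")
  tr <- simulateMetCycle(hep, constantInput(100), metCycleState(10, 10, 1, 1),
                         1, 0.25)
  f <- tempfile(fileext = ".tsv")
  trajectoryFrame(tr, f)
  df <- read.delim(f)
  expect_equal(names(df)[1:5], c("time", "met", "sam", "sah", "hcy"))
  expect_equal(nrow(df), length(tr@times))
  expect_equal(df$sam, unname(tr@states[, "sam"]), tolerance = 1e-12)
})
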