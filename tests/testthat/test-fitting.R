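test_that("noiseless amino-acid measurements recover the TOY1 split", {
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  meas <- generateMeasurements(net, truth)
  fit <- fitFluxes(net, meas, config = list(starts = 4, seed = 2))
  expect_lt(objective(fit), 1e-8)
  expect_equal(unname(fluxes(fit)["v3"]), 0.6, tolerance = 1e-3)
  ## fitted MDVs reproduce the best profile through the simulator
  resim <- simulateMdvs(net, fit@profile, targets = emuTarget("P", 1:2))
  expect_equal(as.numeric(fittedMdvs(fit)$P),
               as.numeric(resim[[1]]), tolerance = 1e-9)
})

test_that("peptide-mode fitting recovers the same fluxes through the convolution", {
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  meas <- generateMeasurements(net, truth, panel = c("PP"))
  expect_equal(as.numeric(observedMdv(meas, "PP")),
               c(0.16, 0.48, 0.36, 0, 0), tolerance = 1e-12)
  fit <- fitFluxes(net, meas, config = list(starts = 4, seed = 2))
  expect_equal(unname(fluxes(fit)["v3"]), 0.6, tolerance = 1e-3)
  expect_lt(objective(fit), 1e-8)
})

test_that("inconsistent targets yield a reported lack of fit", {
  net <- fixtures()$toy1
  net@fluxes$lb[net@fluxes$id == "v3"] <- 0.5  # force v3 >= 0.5
  meas <- readMeasurements("P,0,1,0.01\nP,1,0,0.01\nP,2,0,0.01")
  fit <- fitFluxes(net, meas, config = list(starts = 4, seed = 1))
  expect_gt(objective(fit), 1)
  expect_gte(unname(fit@profile["v3"]), 0.5 - 1e-9)
})

test_that("random TOY1 profiles are recovered from noiseless data", {
  net <- fixtures()$toy1
  profiles <- sampleFluxProfile(net, seed = 9, n = 20)
  for (v in profiles) {
    meas <- generateMeasurements(net, v)
    fit <- fitFluxes(net, meas, config = list(starts = 3, seed = 1))
    expect_equal(unname(fluxes(fit)["v2"]), unname(v["v2"]),
                 tolerance = 1e-3)
  }
})

test_that("flux ranges match the 1-D grid-scan oracle on TOY1", {
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  meas <- generateMeasurements(net, truth)
  fit <- fitFluxes(net, meas, config = list(starts = 4, seed = 2))
  e <- meas@entries; e$sigma <- 0.05
  meas05 <- new("MeasurementSet", entries = e, mode = "amino_acid")
  ## independent oracle: scan the single free flux; MDV(1) of P equals v3
  ## exactly here, so |v3 - 0.6| <= 0.05
  b <- fluxBounds(net, meas05, fit, config = list(method = "nlp"))
  r <- fluxRanges(b)
  expect_equal(r$vmin[r$reaction == "v3"], 0.55, tolerance = 2e-3)
  expect_equal(r$vmax[r$reaction == "v3"], 0.65, tolerance = 2e-3)
  bg <- fluxBounds(net, meas05, fit,
                   config = list(method = "grid", gridN = 401))
  rg <- fluxRanges(bg)
  expect_equal(rg$vmin[rg$reaction == "v3"], 0.55, tolerance = 5e-3)
  expect_equal(rg$vmax[rg$reaction == "v3"], 0.65, tolerance = 5e-3)
})

test_that("zero error bounds collapse ranges to the best fit", {
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  meas <- generateMeasurements(net, truth)
  fit <- fitFluxes(net, meas, config = list(starts = 4, seed = 2))
  b <- fluxBounds(net, meas, fit,
                  config = list(method = "nlp", errBound = 1e-9))
  expect_lt(max(fluxRanges(b)$width), 1e-4)
})

test_that("a fully measured network has zero-width ranges", {
  net <- fixtures()$toy1
  net@measuredFluxes <- data.frame(
    reaction = c("v_upt", "v1", "v2"), value = c(1, 0.6, 0.4),
    error = 0.001)
  meas <- generateMeasurements(net, toy1Truth(0.4))
  fit <- fitFluxes(net, meas, config = list(starts = 2, seed = 1))
  b <- fluxBounds(net, meas, fit, config = list(method = "nlp"))
  expect_lt(max(fluxRanges(b)$width), 1e-6)
})

test_that("adding measurements never widens a flux range", {
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  m1 <- generateMeasurements(net, truth, panel = c("PP"))
  m2 <- generateMeasurements(net, truth, panel = c("PP", "P"))
  e1 <- m1@entries; e1$sigma <- 0.05
  e2 <- m2@entries; e2$sigma <- 0.05
  m1 <- new("MeasurementSet", entries = e1, mode = "peptide")
  m2 <- new("MeasurementSet", entries = e2, mode = "peptide")
  fit <- fitFluxes(net, m1, config = list(starts = 3, seed = 1))
  b1 <- fluxBounds(net, m1, fit, config = list(method = "grid", gridN = 201))
  b2 <- fluxBounds(net, m2, fit, config = list(method = "grid", gridN = 201))
  expect_true(all(fluxRanges(b2)$width <= fluxRanges(b1)$width + 1e-9))
})
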