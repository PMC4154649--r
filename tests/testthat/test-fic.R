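test_that("FIC closed forms are exact", {
  mkBounds <- function(widths)
    new("FluxBounds", ranges = data.frame(
      reaction = paste0("r", seq_along(widths)), vmin = 0, vmax = widths,
      width = widths, status = "ok"), method = "grid")
  ## all J ranges at the epsilon floor: FIC = -J ln(0.01) = J ln(100)
  expect_equal(ficValue(computeFic(mkBounds(rep(0, 6)))), 6 * log(100),
               tolerance = 1e-12)
  ## one free range 0.5, the rest at the floor
  expect_equal(ficValue(computeFic(mkBounds(c(0.5, rep(0, 5))))),
               -log(0.5) - 5 * log(0.01), tolerance = 1e-12)
  ## k scales linearly; omega is the box volume
  r <- computeFic(mkBounds(c(0.5, 0.2)), k = 2)
  expect_equal(ficValue(r), -2 * log(0.5 * 0.2), tolerance = 1e-12)
  expect_equal(r@omega, 0.1, tolerance = 1e-12)
  ## missing ranges error
  b <- mkBounds(c(0.5, NA))
  expect_error(computeFic(b), "missing flux range")
})

test_that("FIC against a brute-force feasible-range scan on TOY1", {
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  meas <- generateMeasurements(net, truth)
  fit <- fitFluxes(net, meas, config = list(starts = 3, seed = 1))
  b <- fluxBounds(net, meas, fit,
                  config = list(method = "nlp", errBound = 0.05))
  ## brute force: scan the single free flux; P's MDV(1) = v3, so the
  ## feasible interval is v3 in [0.55, 0.65], v2 = 1 - v3, others fixed
  widths <- c(v_upt = 0, v1 = 0.1, v2 = 0.1, v3 = 0.1, v4 = 0, v5 = 0)
  expected <- -sum(log(pmax(widths, 0.01)))
  expect_equal(ficValue(computeFic(b)), expected, tolerance = 0.05)
})

test_that("FIC curve: no constraints, monotonicity, single-residue equality", {
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  cfgAbs <- list(errModel = "absolute", errBound = 0.01, gridN = 101)
  curve <- ficCurve(net, truth, c("PPP", "PP", "P"), config = cfgAbs)
  aaFic <- ficValue(attr(curve, "aaFic"))
  ## prefix 0: stoichiometric variability only, the minimal FIC
  expect_equal(curve$fic[1], min(curve$fic))
  expect_lt(curve$fic[1], aaFic)
  ## nested panels: FIC never decreases
  expect_true(all(diff(curve$fic) >= -1e-9))
  ## the full amino-acid set as single-residue "peptides" gives the
  ## amino-acid FIC exactly (identical constraints)
  single <- ficCurve(net, truth, c("P"), config = cfgAbs)
  expect_equal(single$fic[2], ficValue(attr(single, "aaFic")),
               tolerance = 1e-9)
  ## FIC(3 peptides) >= FIC(1 peptide)
  expect_gte(curve$fic[4], curve$fic[2])
})

test_that("peptide information loss and recovery on the reduced fixture", {
  net <- fixtures()$ecc1
  d <- digestProteome(fixtures()$proteome)
  truth <- sampleFluxProfile(net, seed = 1)
  msub <- c("ALA", "SER", "GLY", "ASP", "GLU", "VAL")
  p5 <- selectPanel(d, 12, lengths = 5, seed = 1)
  ## shared grid for both error models (simulations are model-independent)
  fp <- pepMFA:::.freeParam(net)
  aaAll <- pepMFA:::.aaTargetMdvs(net, truth)
  msAll <- pepMFA:::.measSim(
    net, pepMFA:::.mdvsToMeasurements(aaAll$mdvs, 0.01, "amino_acid"),
    defaultAaMap())
  alphaT <- as.vector(t(fp$N) %*%
                        (pepMFA:::.alignFluxes(net, truth) - fp$v0))
  gs <- pepMFA:::.gridSims(net, fp, msAll, list(gridN = 31),
                           extra = alphaT)
  ## absolute bounds: convolution can only lose information, so the
  ## peptide FIC stays at or below the amino-acid reference
  cAbs <- ficCurve(net, truth, p5, counts = c(0, 3, 6, 12),
                   config = list(errModel = "absolute", errBound = 0.01,
                                 targets = msub, gridCache = gs))
  expect_true(all(cAbs$fic <= ficValue(attr(cAbs, "aaFic")) + 1e-9))
  expect_true(all(diff(cAbs$fic) >= -1e-9))
  ## relative (multiplicative-noise) bounds: the loss is countered and
  ## the amino-acid FIC is reached at a finite panel size
  cRel <- ficCurve(net, truth, p5, counts = 0:12,
                   config = list(targets = msub, gridCache = gs))
  expect_false(is.na(attr(cRel, "matchSize")))
  expect_lte(attr(cRel, "matchSize"), 12)
  ## shorter peptides carry more information at equal count (means over
  ## random panels, flat bounds)
  meanFic <- function(L) mean(vapply(1:3, function(s) {
    p <- selectPanel(d, 10, lengths = L, seed = s)
    cv <- ficCurve(net, truth, p, counts = 10,
                   config = list(errModel = "absolute", errBound = 0.01,
                                 targets = msub, gridCache = gs))
    cv$fic[1]
  }, 0))
  expect_gte(meanFic(5), meanFic(15))
})
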