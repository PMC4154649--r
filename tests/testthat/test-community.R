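test_that("mixture labeling is the convex combination of species labeling", {
  l1 <- list(T1 = mdv(c(1, 0)))
  l2 <- list(T1 = mdv(c(0, 1)))
  mix <- mixtureLabeling(list(l1, l2), c(0.5, 0.5))
  expect_equal(as.numeric(mix$T1), c(0.5, 0.5))
  ## degenerate mixture returns the first species unchanged
  mix1 <- mixtureLabeling(list(l1, l2), c(1, 0))
  expect_equal(as.numeric(mix1$T1), c(1, 0))
  expect_error(mixtureLabeling(list(l1, l2), c(0.6, 0.5)), "sum to 1")
  expect_error(mixtureLabeling(list(l1, list(T2 = mdv(c(1, 0)))), c(.5, .5)),
               "congruent")
})

test_that("fluxes fitted to averaged labeling are not the averaged fluxes", {
  ## two TOY1 "species" with different splits: fitting the 50/50 mixture
  ## labeling gives fluxes different from the 50/50 flux average
  net <- fixtures()$toy1
  v1 <- toy1Truth(0.1); v2 <- toy1Truth(0.6)
  m1 <- generateMeasurements(net, v1, panel = c("PP", "PPP"))
  m2 <- generateMeasurements(net, v2, panel = c("PP", "PPP"))
  mixEntries <- m1@entries
  mixEntries$value <- 0.5 * m1@entries$value + 0.5 * m2@entries$value
  mix <- new("MeasurementSet", entries = mixEntries, mode = "peptide")
  fitMix <- fitFluxes(net, mix, config = list(starts = 4, seed = 1))
  avgFlux <- 0.5 * netFluxes(net, v1) + 0.5 * netFluxes(net, v2)
  ## the convolution is nonlinear in the split, so the two differ
  expect_gt(abs(fluxes(fitMix)[["v2"]] - avgFlux[["v2"]]), 0.01)
})

test_that("the two-species chain is solved species by species", {
  demo <- communityChainDemo(seed = 5)
  sol <- solveCommunity(demo$model, config = list(starts = 4, seed = 1))
  expect_equal(sol$order, c("ferm", "meth"))
  for (s in names(demo$truth)) {
    truthNet <- netFluxes(demo$model@species[[s]]$network, demo$truth[[s]])
    expect_equal(fluxes(sol$fits[[s]]), truthNet, tolerance = 1e-3,
                 info = s)
  }
  ## predicted exchange labeling is reported at EMU resolution
  expect_true(all(c("1", "2", "1,2") %in% names(sol$exchangeLabeling$AC$emus)))
  ## downstream species reproduces its peptide data under the predicted
  ## upstream labeling
  expect_lt(objective(sol$fits$meth), 1e-8)
})

test_that("carbon labeling is conserved end to end at the solution", {
  demo <- communityChainDemo(seed = 3)
  sol <- solveCommunity(demo$model, config = list(starts = 4, seed = 1))
  netA <- demo$model@species$ferm$network
  vA <- sol$fits$ferm@profile
  keysA <- c(emuTarget("LAC", 1:3), emuTarget("ALA", 1:3),
             emuTarget("GLY", 1:2), emuTarget("AC", 1:2),
             emuTarget("CO2A", 1))
  sA <- simulateMdvs(netA, vA, targets = keysA)
  mm <- function(k) mdvMeanMass(sA[[k]])
  inA <- vA[["u_lac"]] * mm(emuTarget("LAC", 1:3))
  outA <- vA[["aa1"]] * mm(emuTarget("ALA", 1:3)) +
    vA[["aa2"]] * mm(emuTarget("GLY", 1:2)) +
    vA[["ex_ac"]] * mm(emuTarget("AC", 1:2)) +
    vA[["co2a_x"]] * mm(emuTarget("CO2A", 1))
  expect_equal(outA, inA, tolerance = 1e-6)
  ## species B consumes what A exports, down to its own sinks
  netB <- sol$fits$meth@cache$ms$graph  # fitted against predicted labeling
  vB <- sol$fits$meth@profile
  netBn <- demo$model@species$meth$network
  netBn@substrateLabeling$AC <- list(type = "emu",
                                     mdvs = sol$exchangeLabeling$AC$emus)
  keysB <- c(emuTarget("AC", 1:2), emuTarget("GLY", 1),
             emuTarget("CO2B", 1))
  sB <- simulateMdvs(netBn, vB, targets = keysB)
  inB <- vB[["u_ac"]] * mdvMeanMass(sB[[emuTarget("AC", 1:2)]])
  outB <- vB[["aa3"]] * mdvMeanMass(sB[[emuTarget("GLY", 1)]]) +
    vB[["co2b_x"]] * mdvMeanMass(sB[[emuTarget("CO2B", 1)]])
  expect_equal(outB, inB, tolerance = 1e-6)
})

test_that("degenerate and invalid communities are handled", {
  ## single-species community reduces to fitFluxes
  net <- fixtures()$toy1
  truth <- toy1Truth(0.4)
  meas <- generateMeasurements(net, truth, panel = c("PP"))
  cm <- communityModel(species = list(
    only = list(network = net, measurements = meas)))
  sol <- solveCommunity(cm, config = list(starts = 3, seed = 1))
  direct <- fitFluxes(net, meas, config = list(starts = 3, seed = 1))
  expect_equal(fluxes(sol$fits$only), fluxes(direct), tolerance = 1e-6)
  ## a peptide shared between species' panels errors before solving
  demo <- communityChainDemo(seed = 2)
  bad <- demo$model
  bad@species$meth$measurements@entries$target <-
    sub("^G$", "AAG", bad@species$meth$measurements@entries$target)
  pb <- bad@species$meth$panel@peptides
  pb$peptide[pb$peptide == "G"] <- "AAG"
  bad@species$meth$panel@peptides <- pb
  expect_error(solveCommunity(bad), "shared between species")
  ## cyclic exchange topologies are refused
  cyc <- demo$model
  cyc@exchanges <- rbind(cyc@exchanges,
                         data.frame(from = "meth", metabolite = "AC",
                                    to = "ferm"))
  expect_error(solveCommunity(cyc), "acyclic|cyclic")
})

test_that("community configuration files load and solve", {
  d <- file.path(tempdir(), "commcfg")
  dir.create(d, showWarnings = FALSE)
  demo <- communityChainDemo(seed = 5)
  writeLines(writeNetworkModel(demo$model@species$ferm$network),
             file.path(d, "ferm.tsv"))
  writeLines(writeNetworkModel(demo$model@species$meth$network),
             file.path(d, "meth.tsv"))
  writeMeasurements(demo$model@species$ferm$measurements,
                    file.path(d, "ferm.csv"))
  writeMeasurements(demo$model@species$meth$measurements,
                    file.path(d, "meth.csv"))
  writeLines(c("[species]",
               "name\tmodel\tmeasurements\tmode",
               "ferm\tferm.tsv\tferm.csv\tpeptide",
               "meth\tmeth.tsv\tmeth.csv\tpeptide",
               "[exchanges]",
               "from\tmetabolite\tto",
               "ferm\tAC\tmeth"), file.path(d, "community.cfg"))
  cm <- readCommunityConfig(file.path(d, "community.cfg"))
  expect_s4_class(cm, "CommunityModel")
  sol <- solveCommunity(cm, config = list(starts = 3, seed = 1))
  expect_equal(fluxes(sol$fits$ferm),
               netFluxes(demo$model@species$ferm$network, demo$truth$ferm),
               tolerance = 1e-3)
  unlink(d, recursive = TRUE)
})
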