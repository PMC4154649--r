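test_that("backward decomposition finds exactly the reachable EMUs", {
  net <- fixtures()$toy1
  g <- emuDecompose(net, emuTarget("P", 1:2))
  expect_setequal(g@nodes$key,
                  c("P:1,2", "C:1,2", "B:1,2", "A:1,2", "A:2,3"))
  expect_setequal(g@nodes$key[g@nodes$kind == "source"],
                  c("A:1,2", "A:2,3"))
  ## a substrate EMU is a single leaf with no edges
  g2 <- emuDecompose(net, emuTarget("A", 1:3))
  expect_equal(nrow(g2@nodes), 1L)
  expect_equal(g2@nodes$kind, "source")
  ## condensation creates one combined node with the right constituents
  g3 <- emuDecompose(fixtures()$toy1c, emuTarget("E", 1:3))
  cmb <- g3@nodes[g3@nodes$kind == "combined", ]
  expect_equal(nrow(cmb), 1L)
  expect_setequal(g3@producers[[cmb$key]], c("C:1,2", "D:1"))
  ## unreachable target errors
  expect_error(emuDecompose(net, "NOPE:1"), "unknown metabolite")
})

test_that("EMU graph is acyclic across size strata", {
  for (net in list(fixtures()$toy1c, fixtures()$ecc1)) {
    targets <- vapply(net@metabolites$id[net@metabolites$role == "sink"],
                      function(m) emuTarget(m, net = net), "")
    g <- emuDecompose(net, unname(targets))
    nd <- g@nodes
    for (key in nd$key[nd$kind == "internal"]) {
      for (e in g@producers[[key]]) {
        srcSize <- nd$size[match(e$src, nd$key)]
        expect_lte(srcSize, nd$size[match(key, nd$key)])
      }
    }
    for (key in nd$key[nd$kind == "combined"]) {
      sizes <- nd$size[match(g@producers[[key]], nd$key)]
      expect_equal(sum(sizes), nd$size[match(key, nd$key)])
    }
  }
})

test_that("TOY1 labeling matches the hand atom-trace", {
  net <- fixtures()$toy1
  sims <- simulateMdvs(net, toy1Truth(0.4), targets = emuTarget("P", 1:2))
  expect_equal(as.numeric(sims[["P:1,2"]]), c(0.4, 0.6, 0), tolerance = 1e-12)
  ## unlabeled substrate: every MDV is [1, 0, ..., 0]
  net0 <- net
  net0@substrateLabeling$A$components[[1]]$purity <- c(0, 0, 0)
  all0 <- simulateMdvs(net0, toy1Truth(0.4),
                       targets = emuTarget("P", 1:2), all = TRUE)
  for (x in all0) expect_equal(as.numeric(x)[1], 1, tolerance = 1e-12)
})

test_that("labeling is invariant under uniform flux scaling", {
  net <- fixtures()$toy1
  v <- toy1Truth(0.27)
  a <- simulateMdvs(net, v, targets = emuTarget("P", 1:2))
  ## relax uptake measurement so the scaled profile is still admissible
  net2 <- net
  net2@measuredFluxes <- net2@measuredFluxes[0, ]
  b <- simulateMdvs(net2, 3.7 * v, targets = emuTarget("P", 1:2))
  expect_equal(as.numeric(a[[1]]), as.numeric(b[[1]]), tolerance = 1e-12)
})

test_that("non-steady and degenerate profiles are rejected with diagnostics", {
  net <- fixtures()$toy1
  v <- toy1Truth(0.4); v["v1"] <- 0.9   # breaks the B balance
  expect_error(simulateMdvs(net, v, targets = emuTarget("P", 1:2)),
               "steady state")
  vdead <- c(v_upt = 1, v1 = 0, v2 = 1, v3 = 0, v4 = 1, v5 = 1)
  expect_error(simulateMdvs(net, vdead, targets = emuTarget("B", 1:3)),
               "dead EMU")
})

test_that("simulated MDVs agree with the full-isotopomer oracle", {
  ## spot equivalence across fixtures and random feasible profiles (the
  ## large-replicate sweep lives in the acceptance suite)
  set.seed(42)
  for (fx in c("toy1", "toy1c", "chainA")) {
    net <- fixtures()[[fx]]
    sinks <- net@metabolites$id[net@metabolites$role == "sink"]
    keys <- vapply(sinks, function(m) emuTarget(m, net = net), "")
    profiles <- sampleFluxProfile(net, seed = 7, n = 5)
    for (v in profiles) {
      sims <- simulateMdvs(net, v, targets = unname(keys))
      orc <- isotopomerOracle(net, v)
      for (m in sinks)
        expect_equal(as.numeric(sims[[keys[[m]]]]), as.numeric(orc[[m]]),
                     tolerance = 1e-8, info = paste(fx, m))
    }
  }
})

test_that("oracle handles substrate mixtures exactly", {
  ## 50/50 mixture of U-13C and unlabeled substrate: hand mixture arithmetic
  net <- fixtures()$toy1
  net@substrateLabeling$A <- list(type = "positional", components = list(
    list(weight = 0.5, purity = c(1, 1, 1)),
    list(weight = 0.5, purity = c(0, 0, 0))))
  v <- toy1Truth(0.4)
  orc <- isotopomerOracle(net, v)
  ## P inherits 2 substrate carbons: 50% fully labeled, 50% unlabeled
  expect_equal(as.numeric(orc$P), c(0.5, 0, 0.5), tolerance = 1e-10)
  sims <- simulateMdvs(net, v, targets = emuTarget("P", 1:2))
  expect_equal(as.numeric(sims[[1]]), c(0.5, 0, 0.5), tolerance = 1e-10)
})

test_that("linear pathways conserve the substrate MDV", {
  txt <- paste(c("[reactions]", "id\tequation\treversible\tlb\tub",
                 "u\t -> A (ab)\t0\t0\t10",
                 "v1\tA (ab) -> B (ab)\t0\t0\t10",
                 "v2\tB (ab) -> P (ab)\t0\t0\t10",
                 "[substrate_labeling]", "A\t1\t0.7", "A\t2\t0.2"),
               collapse = "\n")
  net <- readNetworkModel(txt, unspecifiedPurity = 0)
  v <- c(u = 1, v1 = 1, v2 = 1)
  orc <- isotopomerOracle(net, v)
  expect_equal(as.numeric(orc$P),
               as.numeric(convolveMdv(c(0.3, 0.7), c(0.8, 0.2))),
               tolerance = 1e-10)
})

test_that("mean mass is conserved through the network", {
  ## labeled-carbon outflow equals labeled-carbon inflow on TOY1
  net <- fixtures()$toy1
  v <- toy1Truth(0.35)
  keys <- c(emuTarget("P", 1:2), emuTarget("CO2", 1), emuTarget("A", 1:3))
  sims <- simulateMdvs(net, v, targets = keys)
  inflow <- v[["v_upt"]] * mdvMeanMass(sims[[emuTarget("A", 1:3)]])
  outflow <- v[["v4"]] * mdvMeanMass(sims[[emuTarget("P", 1:2)]]) +
    v[["v5"]] * mdvMeanMass(sims[[emuTarget("CO2", 1)]])
  expect_equal(outflow, inflow, tolerance = 1e-10)
})
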