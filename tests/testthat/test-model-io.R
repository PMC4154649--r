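test_that("carbon-transition equations parse into mapped reactions", {
  net <- readNetworkModel(paste(c(
    "[reactions]", "id\tequation\treversible\tlb\tub",
    "vin\t -> A (abc)\t0\t0\t10",
    "v2\tA (abc) -> C (bc) + CO2 (a)\t0\t0\t10",
    "vc\tC (ab) -> \t0\t0\t10",
    "vco\tCO2 (a) -> \t0\t0\t10",
    "[substrate_labeling]", "A\t1\t1"), collapse = "\n"),
    unspecifiedPurity = 0)
  r <- net@reactions$v2
  expect_equal(r$products[[1]]$met, "C")
  expect_equal(r$products[[1]]$letters, c("b", "c"))  # inherits carbons 2,3
  expect_equal(r$products[[2]]$letters, "a")          # CO2 gets carbon 1
  expect_equal(sort(net@metabolites$id), c("A", "C", "CO2"))
})

test_that("unbalanced and duplicated mapping letters are rejected", {
  bad <- paste(c(
    "[reactions]", "id\tequation\treversible\tlb\tub",
    "vin\t -> A (abc)\t0\t0\t10",
    "vX\tA (abc) -> C (bc)\t0\t0\t10",
    "vc\tC (ab) -> \t0\t0\t10",
    "[substrate_labeling]", "A\t1\t1"), collapse = "\n")
  expect_error(readNetworkModel(bad), "'a' unbalanced")
  rxn <- list(list(id = "vd",
                   reactants = list(list(met = "A", letters = c("a", "b"))),
                   products = list(list(met = "B", letters = c("a", "a"))),
                   reversible = FALSE, lb = 0, ub = 10))
  rep <- checkAtomBalance(rxn)
  expect_true(any(rep$type == "duplicate_letter"))
  expect_true(any(grepl("'a' used twice", rep$detail)))
})

test_that("malformed equations raise parse errors naming the line", {
  bad <- paste(c(
    "[reactions]", "id\tequation\treversible\tlb\tub",
    "v1\tA -> B (ab)\t0\t0\t10"), collapse = "\n")
  expect_error(readNetworkModel(bad), "line 3")
})

test_that("TOY1 fixture parses with the documented structure", {
  net <- fixtures()$toy1
  expect_equal(nrow(net@metabolites), 5L)
  expect_equal(nrow(net@fluxes), 6L)
  expect_equal(nrow(checkAtomBalance(net)), 0L)
  ## rank of S by independent Gaussian elimination (qr)
  expect_equal(qr(net@S)$rank, 4L)
  ## free-flux dimension 1 after fixing uptake
  expect_equal(pepMFA:::.freeParam(net)$d, 1L)
})

test_that("deleting one product letter yields exactly one finding", {
  net <- fixtures()$toy1
  rxn <- net@reactions
  rxn$v3$products[[1]]$letters <- "a"  # drop letter 'b' from C
  rep <- checkAtomBalance(rxn)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$detail, "'b' unbalanced")
})

test_that("parse -> serialize -> parse is idempotent on the fixtures", {
  for (fx in c("toy1", "toy1c", "chainA", "ecc1")) {
    net <- readNetworkModel(toyModelText(fx), unspecifiedPurity = 0)
    txt2 <- writeNetworkModel(net)
    net2 <- readNetworkModel(paste(txt2, collapse = "\n"),
                             unspecifiedPurity = 0)
    expect_equal(net2@reactions, net@reactions, info = fx)
    expect_equal(net2@S, net@S, info = fx)
    expect_equal(net2@measuredFluxes$value, net@measuredFluxes$value,
                 info = fx)
    expect_equal(writeNetworkModel(net2), txt2, info = fx)
  }
})

test_that("reversible reactions split into inverse-mapped flux pairs", {
  net <- readNetworkModel(paste(c(
    "[reactions]", "id\tequation\treversible\tlb\tub",
    "vin\t -> A (ab)\t0\t0\t10",
    "iso\tA (ab) -> B (ba)\t1\t-10\t10",
    "out\tB (ab) -> \t0\t0\t10",
    "[substrate_labeling]", "A\t1\t1"), collapse = "\n"),
    unspecifiedPurity = 0)
  expect_true("iso_b" %in% net@fluxes$id)
  k <- match("iso_b", net@fluxes$id)
  kf <- match("iso", net@fluxes$id)
  ## backward mapping is the inverse of the forward mapping
  expect_identical(net@rxnSplit[[k]]$reactants,
                   net@rxnSplit[[kf]]$products)
  expect_identical(net@rxnSplit[[k]]$products,
                   net@rxnSplit[[kf]]$reactants)
  ## net flux of the pair enters S with opposite signs
  expect_equal(unname(net@S["A", kf]), -1)
  expect_equal(unname(net@S["A", k]), 1)
})

test_that("measurement tables round-trip and enforce integrity", {
  csv <- c("target_id,m,fraction,error",
           "P,0,0.4,0.01", "P,1,0.6,0.01", "P,2,0.0,0.01")
  ms <- readMeasurements(paste(csv, collapse = "\n"))
  expect_equal(as.numeric(observedMdv(ms, "P")), c(0.4, 0.6, 0))
  expect_identical(writeMeasurements(ms)[-1],
                   c("P,0,0.4,0.01", "P,1,0.6,0.01", "P,2,0,0.01"))
  ## write(read(x)) == x on a round trip through a file
  tf <- tempfile(fileext = ".csv")
  writeMeasurements(ms, tf)
  ms2 <- readMeasurements(tf)
  expect_identical(ms2@entries, ms@entries)
  ## sum deviating > 1e-6 is an integrity error
  bad <- sub("0.6", "0.5", paste(csv, collapse = "\n"), fixed = TRUE)
  expect_error(readMeasurements(bad), "sums to 0.9")
  expect_error(readMeasurements("P,0,-0.1,0.01\nP,1,1.1,0.01"), "negative")
})
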