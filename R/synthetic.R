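## Synthetic study material: toy carbon-transition networks, a reduced
## central-carbon model with amino-acid biosynthesis, a toy proteome for
## tryptic panels, feasible ground-truth flux sampling, and noisy
## simulated measurements.

#' Bundled toy model texts
#'
#' `toy1`: three-carbon substrate A with two routes to the measured
#' product P - a direct cleavage (v2, P inherits substrate carbons 2,3)
#' and a route through B (v1/v3, P inherits carbons 1,2). With a
#' [1-13C] substrate the MDV of P reads the v2/v3 flux split directly.
#' One free flux dimension once uptake is fixed.
#'
#' `toy1c`: toy1 plus a condensation branch (C + D -> E) exercising
#' combined-EMU convolution.
#'
#' `chainA` / `chainB`: the two members of the bundled two-species
#' community - a fermenter converting the community substrate LAC to an
#' exported intermediate AC (with an identifiable route split), and a
#' downstream consumer whose amino-acid labeling reads the positional
#' labeling of AC. `chainB`'s substrate section is a placeholder that
#' [solveCommunity()] replaces with the labeling predicted upstream.
#'
#' `ecc1`: a reduced synthetic central-carbon network (glycolysis,
#' pentose-phosphate pathway with standard transketolase/transaldolase
#' mappings, a lumped TCA cycle without symmetric-intermediate
#' scrambling, ppc anaplerosis and a malic-enzyme-like OAA->PYR route)
#' with biosynthesis of nine proteinogenic amino acids. [1-13C] glucose,
#' uptake 1, amino-acid drains fixed at 0.02. Three free flux
#' dimensions. This is a synthetic fixture in the style of published
#' central-carbon models, not a copy of any specific one.
#'
#' @param which fixture name.
#' @return character scalar of model text for [readNetworkModel()].
#' @export
toyModelText <- function(which = c("toy1", "toy1c", "chainA", "chainB",
                                   "ecc1")) {
  which <- match.arg(which)
  toy1 <- c(
    "[reactions]",
    "id\tequation\treversible\tlb\tub",
    "v_upt\t -> A (abc)\t0\t0\t10",
    "v1\tA (abc) -> B (abc)\t0\t0\t10",
    "v2\tA (abc) -> C (bc) + CO2 (a)\t0\t0\t10",
    "v3\tB (abc) -> C (ab) + CO2 (c)\t0\t0\t10",
    "v4\tC (ab) -> P (ab)\t0\t0\t10",
    "v5\tCO2 (a) -> \t0\t0\t10",
    "[substrate_labeling]",
    "metabolite\tcarbon_position\tpurity",
    "A\t1\t1", "A\t2\t0", "A\t3\t0",
    "[measured_fluxes]",
    "reaction\tvalue\terror",
    "v_upt\t1\t0.001")
  txt <- switch(which,
    toy1 = toy1,
    toy1c = c(toy1[1:8],
      "v6\tCO2 (a) -> D (a)\t0\t0\t10",
      "v7\tC (ab) + D (c) -> E (abc)\t0\t0\t10",
      "v8\tE (abc) -> Q (abc)\t0\t0\t10",
      toy1[9:length(toy1)]),
    chainA = c(
      "[reactions]",
      "id\tequation\treversible\tlb\tub",
      "u_lac\t -> LAC (abc)\t0\t0\t10",
      "r1\tLAC (abc) -> AC (bc) + CO2A (a)\t0\t0\t10",
      "r1b\tLAC (abc) -> AC (ab) + CO2A (c)\t0\t0\t10",
      "aa1\tLAC (abc) -> ALA (abc)\t0\t0\t10",
      "aa2\tAC (ab) -> GLY (ab)\t0\t0\t10",
      "ex_ac\tAC (ab) -> \t0\t0\t10",
      "co2a_x\tCO2A (a) -> \t0\t0\t10",
      "[substrate_labeling]",
      "metabolite\tcarbon_position\tpurity",
      "LAC\t1\t1", "LAC\t2\t0", "LAC\t3\t0",
      "[measured_fluxes]",
      "reaction\tvalue\terror",
      "u_lac\t1\t0.001", "aa1\t0.05\t0.001", "aa2\t0.05\t0.001"),
    chainB = c(
      "[reactions]",
      "id\tequation\treversible\tlb\tub",
      "u_ac\t -> AC (ab)\t0\t0\t10",
      "b1\tAC (ab) -> M1 (ab)\t0\t0\t10",
      "b2\tM1 (ab) -> GB (b) + CO2B (a)\t0\t0\t10",
      "b3\tAC (ab) -> GB (a) + CO2B (b)\t0\t0\t10",
      "aa3\tGB (a) -> GLY (a)\t0\t0\t10",
      "co2b_x\tCO2B (a) -> \t0\t0\t10",
      "[substrate_labeling]",
      "metabolite\tcarbon_position\tpurity",
      "AC\t1\t0", "AC\t2\t0",
      "[measured_fluxes]",
      "reaction\tvalue\terror",
      "u_ac\t0.9\t0.001"),
    ecc1 = c(
      "[reactions]",
      "id\tequation\treversible\tlb\tub",
      "upt\tGLC (abcdef) -> G6P (abcdef)\t0\t0\t10",
      "pgi\tG6P (abcdef) -> F6P (abcdef)\t0\t0\t10",
      "zwf\tG6P (abcdef) -> P5P (bcdef) + CO2 (a)\t0\t0\t10",
      "tk1\tP5P (abcde) + P5P (fghij) -> S7P (abfghij) + GAP (cde)\t0\t0\t10",
      "ta\tS7P (abcdefg) + GAP (hij) -> F6P (abchij) + E4P (defg)\t0\t0\t10",
      "tk2\tP5P (abcde) + E4P (fghi) -> F6P (abfghi) + GAP (cde)\t0\t0\t10",
      "fba\tF6P (abcdef) -> GAP (cba) + GAP (def)\t0\t0\t10",
      "gapd\tGAP (abc) -> PEP (abc)\t0\t0\t10",
      "pyk\tPEP (abc) -> PYR (abc)\t0\t0\t10",
      "pdh\tPYR (abc) -> ACA (bc) + CO2 (a)\t0\t0\t10",
      "cs\tOAA (abcd) + ACA (ef) -> AKG (abcfe) + CO2 (d)\t0\t0\t10",
      "akgd\tAKG (abcde) -> OAA (bcde) + CO2 (a)\t0\t0\t10",
      "ppc\tPEP (abc) + CO2 (d) -> OAA (abcd)\t0\t0\t10",
      "mae\tOAA (abcd) -> PYR (abc) + CO2 (d)\t0\t0\t10",
      "co2x\tCO2 (a) -> \t0\t0\t10",
      "alaS\tPYR (abc) -> ALA (abc)\t0\t0\t10",
      "serS\tPEP (abc) -> SER (abc)\t0\t0\t10",
      "glyS\tSER (abc) -> GLY (ab) + C1 (c)\t0\t0\t10",
      "c1x\tC1 (a) -> \t0\t0\t10",
      "aspS\tOAA (abcd) -> ASP (abcd)\t0\t0\t10",
      "thrS\tOAA (abcd) -> THR (abcd)\t0\t0\t10",
      "gluS\tAKG (abcde) -> GLU (abcde)\t0\t0\t10",
      "valS\tPYR (abc) + PYR (def) -> VAL (abcef) + CO2 (d)\t0\t0\t10",
      "lysS\tOAA (abcd) + PYR (efg) -> LYS (abcdef) + CO2 (g)\t0\t0\t10",
      "argS\tAKG (abcde) + CO2 (f) -> ARG (abcdef)\t0\t0\t10",
      "alaX\tALA (abc) -> \t0\t0\t10",
      "serX\tSER (abc) -> \t0\t0\t10",
      "glyX\tGLY (ab) -> \t0\t0\t10",
      "aspX\tASP (abcd) -> \t0\t0\t10",
      "thrX\tTHR (abcd) -> \t0\t0\t10",
      "gluX\tGLU (abcde) -> \t0\t0\t10",
      "valX\tVAL (abcde) -> \t0\t0\t10",
      "lysX\tLYS (abcdef) -> \t0\t0\t10",
      "argX\tARG (abcdef) -> \t0\t0\t10",
      "[substrate_labeling]",
      "metabolite\tcarbon_position\tpurity",
      "GLC\t1\t1", "GLC\t2\t0", "GLC\t3\t0",
      "GLC\t4\t0", "GLC\t5\t0", "GLC\t6\t0",
      "[measured_fluxes]",
      "reaction\tvalue\terror",
      "upt\t1\t0.001",
      "alaX\t0.02\t0.001", "serX\t0.02\t0.001", "glyX\t0.02\t0.001",
      "aspX\t0.02\t0.001", "thrX\t0.02\t0.001", "gluX\t0.02\t0.001",
      "valX\t0.02\t0.001", "lysX\t0.02\t0.001", "argX\t0.02\t0.001"))
  paste(txt, collapse = "\n")
}

#' Default residue-to-metabolite map
#'
#' Maps one-letter amino-acid codes to the metabolite ids used by the
#' bundled networks.
#' @return named character vector.
#' @export
defaultAaMap <- function()
  c(A = "ALA", S = "SER", G = "GLY", D = "ASP", E = "GLU",
    V = "VAL", T = "THR", K = "LYS", R = "ARG")

#' Generate every toy input
#'
#' Builds the bundled networks (parsed and validated), the toy proteome
#' (twelve proteins whose tryptic digest yields at least 30
#' composition-distinct peptides of each length 5, 10 and 15 over the
#' residues the reduced central-carbon network can label), and the
#' two-species community model skeleton. The proteome is generated with
#' a fixed internal seed: it is a fixture, not a random draw.
#'
#' @return list with elements toy1, toy1c, ecc1, chainA, chainB
#'   (networks), proteome (AAStringSet), proteomeFasta (character lines),
#'   aaMap.
#' @export
makeToyFixtures <- function() {
  nets <- lapply(c(toy1 = "toy1", toy1c = "toy1c", ecc1 = "ecc1",
                   chainA = "chainA", chainB = "chainB"),
                 function(w) readNetworkModel(toyModelText(w),
                                              unspecifiedPurity = 0))
  prot <- .toyProteome()
  c(nets, list(proteome = prot$set, proteomeFasta = prot$fasta,
               aaMap = defaultAaMap()))
}

.toyProteome <- function() {
  ## Tryptic peptides from real proteomes are strongly biased in
  ## composition (low-complexity stretches, protein-specific residue
  ## usage), and that bias is what lets short peptides carry almost as
  ## much labeling information as free amino acids: a peptide with
  ## several copies of co-sensitive residues sums their deviations.
  ## Each toy protein therefore gets its own residue-usage profile
  ## (a Dirichlet draw over the interior alphabet) instead of uniform
  ## i.i.d. residues.
  interior <- c("A", "S", "G", "D", "E", "V", "T")
  rng <- .localRNG(20140904L)
  on.exit(rng())
  drawProfile <- function() {
    w <- stats::rgamma(length(interior), shape = 0.4)
    w / sum(w)
  }
  peps <- character()
  for (L in c(5L, 10L, 15L)) {
    comps <- character(); got <- 0L
    while (got < 40L) {
      prof <- drawProfile()  # one usage profile per (toy) protein stretch
      for (k in 1:4) {
        body <- sample(interior, L - 1L, replace = TRUE, prob = prof)
        pep <- paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
        comp <- paste(sort(strsplit(pep, "")[[1]]), collapse = "")
        if (!comp %in% comps && got < 40L) {
          comps <- c(comps, comp); peps <- c(peps, pep); got <- got + 1L
        }
      }
    }
  }
  peps <- sample(peps)  # interleave lengths across proteins
  prot <- vapply(split(peps, ceiling(seq_along(peps) / 10)),
                 paste, "", collapse = "")
  names(prot) <- sprintf("toyprot%02d", seq_along(prot))
  fasta <- as.vector(rbind(paste0(">", names(prot)), unname(prot)))
  list(set = Biostrings::AAStringSet(prot), fasta = fasta)
}

## run code under a fixed RNG state, restoring the caller's state
.localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Uniform noise specification for simulated measurements
#'
#' Noise is applied per MDV element as value * (1 + delta * r) with
#' r ~ Uniform(-1, 1), followed by clamping at 0 and renormalization.
#'
#' @param delta relative amplitude (>= 0); 0 means noiseless.
#' @param seed RNG seed.
#' @return a NoiseSpec list.
#' @export
noiseSpec <- function(delta = 0, seed = 1L) {
  stopifnot(delta >= 0)
  structure(list(delta = delta, seed = as.integer(seed)),
            class = "NoiseSpec")
}

#' Sample a feasible ground-truth flux profile
#'
#' Draws an (approximately) uniform point from the flux polytope
#' {v : S v = 0, bounds, measured fluxes} by coordinate hit-and-run in
#' the free-flux (null-space) coordinates, with 1000 burn-in steps.
#' Deterministic given the seed.
#'
#' @param net a [MetabolicNetwork-class].
#' @param seed RNG seed.
#' @param n number of profiles (returned as a list when n > 1).
#' @param burnin burn-in steps.
#' @return named numeric split-flux profile (or list of them).
#' @export
sampleFluxProfile <- function(net, seed = 1L, n = 1L, burnin = 1000L) {
  fp <- .freeParam(net)
  rng <- .localRNG(as.integer(seed))
  on.exit(rng())
  d <- fp$d
  if (d == 0L) {
    v <- stats::setNames(fp$v0, net@fluxes$id)
    return(if (n == 1L) v else rep(list(v), n))
  }
  alpha <- fp$alpha0
  thin <- 10L
  out <- vector("list", n)
  total <- burnin + n * thin
  for (it in seq_len(total)) {
    u <- stats::rnorm(d); u <- u / sqrt(sum(u^2))
    rng2 <- .segment(fp, alpha, u)
    if (rng2[2] > rng2[1])
      alpha <- alpha + stats::runif(1, rng2[1], rng2[2]) * u
    if (it > burnin && (it - burnin) %% thin == 0L)
      out[[(it - burnin) %/% thin]] <-
        stats::setNames(fp$v0 + as.vector(fp$N %*% alpha), net@fluxes$id)
  }
  if (n == 1L) out[[1]] else out
}

## feasible step range t for alpha + t*u within lb <= v0 + N(alpha+tu) <= ub
.segment <- function(fp, alpha, u) {
  w <- as.vector(fp$N %*% u)
  v <- fp$v0 + as.vector(fp$N %*% alpha)
  lo <- -Inf; hi <- Inf
  for (i in seq_along(w)) {
    if (abs(w[i]) < 1e-12) next
    t1 <- (fp$lb[i] - v[i]) / w[i]
    t2 <- (fp$ub[i] - v[i]) / w[i]
    lo <- max(lo, min(t1, t2)); hi <- min(hi, max(t1, t2))
  }
  c(lo, hi)
}

#' Simulate a measurement set from a ground-truth profile
#'
#' Simulates amino-acid MDVs for the targets, optionally convolves them
#' into peptide MDVs over a panel, then applies elementwise uniform
#' relative noise (see [noiseSpec()]) and renormalizes. The recorded
#' error bound sigma is delta (or `sigmaDefault` when delta = 0).
#'
#' @param net a [MetabolicNetwork-class].
#' @param v ground-truth split flux profile.
#' @param panel [PeptidePanel-class], peptide character vector, or NULL
#'   for amino-acid mode.
#' @param noise a [noiseSpec()].
#' @param targets amino-acid metabolite ids (default: every metabolite
#'   named in `aaMap` present in the network).
#' @param aaMap residue-to-metabolite map (see [defaultAaMap()]).
#' @param sigmaDefault sigma recorded when delta = 0.
#' @param renormalize renormalize noisy MDVs to unit sum (the default).
#'   With `renormalize = FALSE` the raw perturbed table is returned as a
#'   data.frame for inspection (it is not a valid MDV set).
#' @return a [MeasurementSet-class] (or a data.frame, see
#'   `renormalize`).
#' @export
generateMeasurements <- function(net, v, panel = NULL,
                                 noise = noiseSpec(0),
                                 targets = NULL, aaMap = defaultAaMap(),
                                 sigmaDefault = 0.01,
                                 renormalize = TRUE) {
  aa <- .aaTargetMdvs(net, v, targets, aaMap)
  if (is.null(panel)) {
    mdvs <- aa$mdvs
    mode <- "amino_acid"
  } else {
    peps <- if (is(panel, "PeptidePanel")) panel@peptides$peptide else panel
    resMdvs <- .residueMdvs(aa, aaMap)
    mdvs <- lapply(peps, function(p) peptideMdv(p, resMdvs))
    names(mdvs) <- peps
    mode <- "peptide"
  }
  sig <- if (noise$delta > 0) noise$delta else sigmaDefault
  rng <- .localRNG(noise$seed)
  on.exit(rng())
  rows <- list()
  for (t in names(mdvs)) {
    x <- as.numeric(mdvs[[t]])
    if (noise$delta > 0) {
      r <- stats::runif(length(x), -1, 1)
      x <- pmax(x * (1 + noise$delta * r), 0)
      if (renormalize) x <- .renorm(x)
    }
    rows[[t]] <- data.frame(target = t, m = seq_along(x) - 1L,
                            value = x, sigma = sig)
  }
  entries <- do.call(rbind, rows)
  if (!renormalize && noise$delta > 0) return(entries)
  new("MeasurementSet", entries = entries, mode = mode)
}

## simulate the full-molecule MDVs of the amino-acid target metabolites
.aaTargetMdvs <- function(net, v, targets = NULL, aaMap = defaultAaMap()) {
  if (is.null(targets)) {
    targets <- intersect(aaMap, net@metabolites$id)
    if (length(targets) == 0)  # toy networks: measure every sink
      targets <- net@metabolites$id[net@metabolites$role == "sink"]
  }
  keys <- vapply(targets, function(m) emuTarget(m, net = net), "")
  sims <- simulateMdvs(net, v, targets = keys)
  mdvs <- stats::setNames(sims[keys], targets)
  list(targets = targets, mdvs = mdvs)
}

## residue letter -> MDV map derived from amino-acid metabolite MDVs
.residueMdvs <- function(aa, aaMap) {
  out <- list()
  for (r in names(aaMap))
    if (aaMap[[r]] %in% names(aa$mdvs))
      out[[r]] <- as.numeric(aa$mdvs[[aaMap[[r]]]])
  ## toy networks: metabolite ids double as residue letters
  for (m in names(aa$mdvs))
    if (!m %in% names(out)) out[[m]] <- as.numeric(aa$mdvs[[m]])
  out
}

#' Bundled two-species community demo
#'
#' Builds the fermenter -> consumer chain (see [toyModelText()]),
#' samples ground-truth flux profiles for both species, generates
#' peptide measurements (the downstream species' labeling is simulated
#' under the exchange-metabolite labeling implied by the upstream
#' truth), and assembles the [CommunityModel-class].
#'
#' @param seed RNG seed for the ground-truth draws and noise.
#' @param delta relative noise amplitude for the peptide measurements.
#' @return list with elements `model` (a [CommunityModel-class]) and
#'   `truth` (named list of ground-truth split-flux profiles).
#' @export
communityChainDemo <- function(seed = 1L, delta = 0) {
  netA <- readNetworkModel(toyModelText("chainA"), unspecifiedPurity = 0)
  netB <- readNetworkModel(toyModelText("chainB"), unspecifiedPurity = 0)
  truthA <- sampleFluxProfile(netA, seed = seed)
  truthB <- sampleFluxProfile(netB, seed = seed + 1L)
  pepsA <- c("AAG", "AGG", "AAAGG")
  pepsB <- c("G", "GG")
  measA <- generateMeasurements(netA, truthA, panel = pepsA,
                                noise = noiseSpec(delta, seed))
  ## downstream truth labeling under the upstream truth's exchange labeling
  keys <- c(.emuKey("AC", 1L), .emuKey("AC", 2L), .emuKey("AC", 1:2))
  sims <- simulateMdvs(netA, truthA, targets = keys)
  netBt <- netB
  netBt@substrateLabeling[["AC"]] <- list(
    type = "emu",
    mdvs = list("1" = as.numeric(sims[[keys[1]]]),
                "2" = as.numeric(sims[[keys[2]]]),
                "1,2" = as.numeric(sims[[keys[3]]])))
  measB <- generateMeasurements(netBt, truthB, panel = pepsB,
                                noise = noiseSpec(delta, seed + 1L))
  panelA <- new("PeptidePanel",
                peptides = data.frame(peptide = pepsA, protein = NA,
                                      species = "ferm",
                                      length = nchar(pepsA)),
                lengthSpec = "demo")
  panelB <- new("PeptidePanel",
                peptides = data.frame(peptide = pepsB, protein = NA,
                                      species = "meth",
                                      length = nchar(pepsB)),
                lengthSpec = "demo")
  model <- communityModel(
    species = list(
      ferm = list(network = netA, measurements = measA, panel = panelA),
      meth = list(network = netB, measurements = measB, panel = panelB)),
    exchanges = data.frame(from = "ferm", metabolite = "AC", to = "meth"),
    fractions = c(ferm = 0.5, meth = 0.5))
  list(model = model, truth = list(ferm = truthA, meth = truthB))
}
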