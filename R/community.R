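## Multi-species flux analysis.
##
## Species are compartmentalized: each has its own carbon-transition
## network, species-unique peptide measurements and measured exchange
## fluxes. When the exchange graph is acyclic the community problem
## decomposes into per-species problems solved in topological order,
## with the labeling of each exchanged metabolite predicted from the
## upstream fit and passed downstream as substrate labeling (at EMU
## resolution, so positional information survives the hand-off).

#' Construct a community model
#'
#' @param species named list; each element a list with fields
#'   `network` ([MetabolicNetwork-class]), `measurements`
#'   ([MeasurementSet-class]), optional `panel` ([PeptidePanel-class])
#'   and `compositions` (named target -> residue string map).
#' @param exchanges data.frame with columns from, metabolite, to.
#' @param fractions species biomass fractions (only used by
#'   [mixtureLabeling()]); defaults to equal.
#' @return a validated [CommunityModel-class].
#' @export
communityModel <- function(species, exchanges =
                             data.frame(from = character(),
                                        metabolite = character(),
                                        to = character()),
                           fractions = NULL) {
  if (is.null(fractions))
    fractions <- stats::setNames(rep(1 / length(species), length(species)),
                                 names(species))
  new("CommunityModel", species = species, exchanges = exchanges,
      fractions = fractions)
}

#' Mixture labeling of a community sample
#'
#' The labeling measured on an unseparated community sample is the
#' biomass-fraction-weighted convex combination of the per-species
#' labeling distributions. Fitting fluxes to this average labeling does
#' not recover the average fluxes (the labeling-to-flux map is
#' nonlinear) - the motivation for species-resolved peptides.
#'
#' @param labelings list (one per species) of named lists of MDVs
#'   (congruent names and lengths).
#' @param fractions species fractions, non-negative, summing to 1.
#' @return named list of mixed [MDV-class].
#' @export
mixtureLabeling <- function(labelings, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("species fractions must sum to 1")
  if (any(fractions < 0)) stop("species fractions must be non-negative")
  nms <- names(labelings[[1]])
  for (l in labelings)
    if (!identical(sort(names(l)), sort(nms)))
      stop("labeling sets are not congruent across species")
  out <- list()
  for (t in nms) {
    lens <- vapply(labelings, function(l) length(l[[t]]), 0L)
    if (length(unique(lens)) != 1)
      stop(sprintf("MDV lengths for '%s' differ across species", t))
    x <- 0
    for (s in seq_along(labelings))
      x <- x + fractions[s] * as.numeric(labelings[[s]][[t]])
    out[[t]] <- mdv(x, label = t, tol = 1e-6)
  }
  out
}

#' Solve a community model species by species
#'
#' Requires an acyclic exchange topology. Species are fitted in
#' topological order; each downstream species' exchanged-substrate
#' labeling is set to the EMU-resolved labeling simulated from the
#' upstream species' best-fit fluxes. Species-unique panels are
#' enforced before solving.
#'
#' @param cm a [CommunityModel-class].
#' @param config passed to [fitFluxes()] per species.
#' @return list with per-species elements `fit` ([FluxFit-class]) or
#'   `blocked` flag, and `exchangeLabeling`: predicted MDV (and EMU
#'   MDVs) of every exchanged metabolite.
#' @export
solveCommunity <- function(cm, config = list()) {
  sp <- names(cm@species)
  ex <- cm@exchanges
  if (.hasCycle(sp, ex))
    stop("cyclic exchange topologies are not supported; the iterative community solver requires an acyclic exchange graph")
  ## species-unique peptide guard across panels / measured peptides
  peps <- lapply(cm@species, function(s) {
    if (!is.null(s$panel)) s$panel@peptides$peptide
    else if (s$measurements@mode == "peptide")
      measurementTargets(s$measurements)
    else character()
  })
  allp <- unlist(peps)
  if (anyDuplicated(allp))
    stop(sprintf("peptide(s) shared between species' panels: %s",
                 paste(unique(allp[duplicated(allp)]), collapse = ", ")))
  ## topological order
  order <- character(); indeg <- stats::setNames(integer(length(sp)), sp)
  for (t in ex$to) indeg[t] <- indeg[t] + 1L
  q <- sp[indeg == 0L]
  while (length(q)) {
    n <- q[1]; q <- q[-1]; order <- c(order, n)
    for (t in ex$to[ex$from == n]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) q <- c(q, t)
    }
  }
  fits <- list(); exchangeLabeling <- list()
  blocked <- character()
  for (s in order) {
    entry <- cm@species[[s]]
    net <- entry$network
    ups <- ex[ex$to == s, , drop = FALSE]
    skip <- FALSE
    for (i in seq_len(nrow(ups))) {
      if (ups$from[i] %in% blocked) { skip <- TRUE; break }
      metab <- ups$metabolite[i]
      need <- .neededSubstrateEmus(net, entry, metab, config)
      upFit <- fits[[ups$from[i]]]
      upNet <- cm@species[[ups$from[i]]]$network
      keys <- vapply(need, function(p) .emuKey(metab, p), "")
      sims <- simulateMdvs(upNet, upFit@profile, targets = keys)
      mdvs <- lapply(need, function(p) as.numeric(sims[[.emuKey(metab, p)]]))
      names(mdvs) <- vapply(need, paste, "", collapse = ",")
      net@substrateLabeling[[metab]] <- list(type = "emu", mdvs = mdvs)
      exchangeLabeling[[metab]] <- list(
        from = ups$from[i], to = s,
        mdv = sims[[.emuKey(metab, seq_len(.metCarbons(upNet, metab)))]],
        emus = mdvs)
    }
    if (skip) { blocked <- c(blocked, s); fits[[s]] <- NULL; next }
    f <- tryCatch(fitFluxes(net, entry$measurements, entry$panel,
                            c(config, list(compositions = entry$compositions))),
                  error = function(e) e)
    if (inherits(f, "error")) {
      blocked <- c(blocked, s)
      fits[[s]] <- NULL
      warning(sprintf("species '%s' failed to fit: %s", s, conditionMessage(f)))
    } else fits[[s]] <- f
  }
  list(fits = fits, exchangeLabeling = exchangeLabeling,
       blocked = blocked, order = order)
}

## which EMUs of an exchanged substrate metabolite the downstream
## species' measurement simulation will need (plus the full molecule,
## for reporting)
.neededSubstrateEmus <- function(net, entry, metab, config) {
  aaMap <- config$aaMap %||% defaultAaMap()
  ## temporarily give the metabolite a dummy positional spec so the
  ## decomposition treats it as a source
  nc <- .metCarbons(net, metab)
  net@substrateLabeling[[metab]] <- list(
    type = "positional",
    components = list(list(weight = 1, purity = rep(0, nc))))
  ms <- .measSim(net, entry$measurements, aaMap, entry$compositions)
  keys <- ms$graph@nodes$key[ms$graph@nodes$kind == "source" &
                             ms$graph@nodes$met == metab]
  pos <- lapply(keys, .keyPos)
  pos <- c(pos, list(seq_len(nc)))
  unique(pos)
}

#' Read a community configuration file
#'
#' Tab-separated sections describing a community: a `[species]` section
#' (name, model path, measurements path, mode) and an `[exchanges]`
#' section (from, metabolite, to). Paths are resolved relative to the
#' configuration file.
#'
#' @param path configuration file.
#' @return a [CommunityModel-class].
#' @export
readCommunityConfig <- function(path) {
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- lines[trimws(lines) != ""]
  section <- ""
  species <- list()
  ex <- data.frame(from = character(), metabolite = character(),
                   to = character())
  base <- dirname(path)
  for (l in lines) {
    if (grepl("^\\[", trimws(l))) { section <- gsub("\\[|\\]", "", trimws(l)); next }
    f <- trimws(strsplit(l, "\t", fixed = TRUE)[[1]])
    if (section == "species") {
      if (identical(tolower(f[1]), "name")) next
      if (length(f) < 4) stop("species lines need: name, model, measurements, mode")
      species[[f[1]]] <- list(
        network = readNetworkModel(file.path(base, f[2]),
                                   unspecifiedPurity = 0),
        measurements = readMeasurements(file.path(base, f[3]), mode = f[4]))
    } else if (section == "exchanges") {
      if (identical(tolower(f[1]), "from")) next
      ex <- rbind(ex, data.frame(from = f[1], metabolite = f[2], to = f[3]))
    } else stop(sprintf("unknown section '%s'", section))
  }
  communityModel(species, ex)
}
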