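#' @import methods
NULL

#' MDV class
#'
#' Numeric vector of isotopomer mass fractions (m = 0, 1, ...). Construct
#' with [mdv()].
#'
#' @slot label character label for the EMU, metabolite or peptide.
#' @exportClass MDV
setClass("MDV", contains = "numeric",
         representation(label = "character"),
         prototype(label = NA_character_))

setValidity("MDV", function(object) {
  x <- as.numeric(object)
  if (length(x) < 1L) return("empty MDV")
  if (any(x < -1e-9) || any(x > 1 + 1e-9)) return("values outside [0, 1]")
  if (abs(sum(x) - 1) > 1e-6) return("values do not sum to 1")
  TRUE
})

#' Carbon-transition metabolic network
#'
#' A reaction network annotated with the fate of every carbon atom
#' (atom mappings), flux bounds, measured fluxes and the positional
#' 13C enrichment of the substrate(s). Reversible reactions are stored
#' as forward/backward flux pairs; reported net fluxes are their
#' difference. Construct with [readNetworkModel()].
#'
#' @slot metabolites data.frame: id, carbons, role
#'   (substrate / balanced / sink).
#' @slot reactions list of parsed reaction records (id, reversible, lb, ub,
#'   reactants, products; each side a list of (met, letters)).
#' @slot fluxes data.frame of the split (irreversible) flux set:
#'   id, reaction, dir, lb, ub.
#' @slot rxnSplit list parallel to `fluxes`: reactants/products per flux.
#' @slot S stoichiometric matrix, one row per balanced metabolite,
#'   one column per split flux.
#' @slot measuredFluxes data.frame: reaction, value, error (net fluxes,
#'   normalized to substrate uptake = 1).
#' @slot substrateLabeling named list of labeling specs per substrate
#'   metabolite; positional mixtures or explicit EMU MDVs.
#' @slot uptake id of the uptake reaction used for normalization.
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
         representation(metabolites = "data.frame",
                        reactions = "list",
                        fluxes = "data.frame",
                        rxnSplit = "list",
                        S = "matrix",
                        measuredFluxes = "data.frame",
                        substrateLabeling = "list",
                        uptake = "character"))

setValidity("MetabolicNetwork", function(object) {
  rep <- checkAtomBalance(object)
  if (nrow(rep) > 0)
    return(paste("atom-mapping problems:",
                 paste(rep$reaction, rep$detail, sep = ": ", collapse = "; ")))
  if (nrow(object@S) > 0 && ncol(object@S) != nrow(object@fluxes))
    return("S has wrong number of columns")
  TRUE
})

#' Set of measured MDVs
#'
#' Observed mass distribution vectors for amino-acid fragments or
#' peptides, with per-element error bounds (sigma).
#'
#' @slot entries data.frame with columns target, m, value, sigma.
#' @slot mode "amino_acid" or "peptide".
#' @exportClass MeasurementSet
setClass("MeasurementSet",
         representation(entries = "data.frame", mode = "character"))

setValidity("MeasurementSet", function(object) {
  e <- object@entries
  need <- c("target", "m", "value", "sigma")
  if (!all(need %in% names(e))) return("entries must have target, m, value, sigma")
  if (nrow(e) > 0) {
    if (any(e$sigma < 0)) return("negative error bound")
    if (any(e$value < -1e-9)) return("negative fraction")
    s <- tapply(e$value, e$target, sum)
    if (any(abs(s - 1) > 1e-6))
      return(sprintf("MDV for target '%s' does not sum to 1",
                     names(s)[which.max(abs(s - 1))]))
  }
  if (!object@mode %in% c("amino_acid", "peptide")) return("bad mode")
  TRUE
})

#' EMU dependency graph
#'
#' Size-stratified dependency graph of the elementary metabolite units
#' (EMUs) reachable backward from a set of target EMUs, including the
#' combined (convolution) nodes created by condensation reactions.
#' Construct with [emuDecompose()].
#'
#' @slot nodes data.frame: key, met, positions (comma string), size, kind
#'   (source / internal / combined).
#' @slot producers named list: for each internal node, a data.frame of
#'   (flux index, source key); for each combined node, its constituent keys.
#' @slot strata list mapping EMU size to node keys solved at that size.
#' @slot targets character vector of target keys.
#' @exportClass EMUGraph
setClass("EMUGraph",
         representation(nodes = "data.frame",
                        producers = "list",
                        strata = "list",
                        targets = "character"))

#' Peptide panel
#'
#' Peptides selected for flux inference: species-assignable, string-unique
#' across the supplied proteomes, and pairwise distinct in amino-acid
#' composition (peptide labeling depends only on composition).
#'
#' @slot peptides data.frame: peptide, protein, species, length.
#' @slot lengthSpec the requested length specification.
#' @exportClass PeptidePanel
setClass("PeptidePanel",
         representation(peptides = "data.frame", lengthSpec = "character"))

setValidity("PeptidePanel", function(object) {
  p <- object@peptides$peptide
  if (length(p) == 0) return(TRUE)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", p)
  if (!all(ok)) return("peptides contain non-canonical residues")
  comp <- vapply(strsplit(p, ""), function(s) paste(sort(s), collapse = ""), "")
  if (anyDuplicated(comp)) return("panel compositions are not pairwise distinct")
  TRUE
})

#' Flux fit result
#'
#' Best flux profile from a multi-start weighted nonlinear least-squares
#' fit of simulated to observed MDVs.
#'
#' @slot profile named numeric, best split-flux values.
#' @slot netFluxes named numeric, per-reaction net fluxes.
#' @slot objective best sum of squared error-weighted residuals.
#' @slot fitted list of fitted MDVs per target.
#' @slot starts data.frame convergence log (one row per start).
#' @slot mode "amino_acid" or "peptide".
#' @slot cache internal state reused by [fluxBounds()] (parameterization,
#'   EMU graph, config).
#' @exportClass FluxFit
setClass("FluxFit",
         representation(profile = "numeric", netFluxes = "numeric",
                        objective = "numeric", fitted = "list",
                        starts = "data.frame", mode = "character",
                        cache = "list"))

#' Per-flux confidence ranges
#'
#' For each reaction, the [min, max] net flux attainable while the
#' simulated labeling stays within the error bounds of the measurements.
#'
#' @slot ranges data.frame: reaction, vmin, vmax, width, status.
#' @slot method "nlp" or "grid".
#' @exportClass FluxBounds
setClass("FluxBounds",
         representation(ranges = "data.frame", method = "character"))

#' Flux information content
#'
#' FIC = -k * log of the enveloping-box volume of the flux region
#' compatible with the data, with a per-flux floor epsilon on range widths.
#'
#' @slot fic the FIC value.
#' @slot omega the enveloping-box volume approximation.
#' @slot ranges the per-flux ranges used (widths floored at epsilon).
#' @slot epsilon lower bound on range widths.
#' @slot k multiplicative constant (default 1).
#' @slot panelSize number of peptides used (NA for amino-acid mode).
#' @exportClass FICResult
setClass("FICResult",
         representation(fic = "numeric", omega = "numeric",
                        ranges = "data.frame", epsilon = "numeric",
                        k = "numeric", panelSize = "numeric"))

setValidity("FICResult", function(object) {
  w <- pmax(object@ranges$width, object@epsilon)
  if (abs(object@fic - (-object@k * sum(log(w)))) > 1e-6)
    return("stored FIC inconsistent with stored ranges")
  TRUE
})

#' Multi-species community model
#'
#' Species networks joined by exchanged metabolites. The exchange graph
#' must be acyclic; fluxes are solved species by species in topological
#' order, propagating the predicted labeling of exchanged metabolites.
#'
#' @slot species named list; each element a list with fields
#'   network (MetabolicNetwork), measurements (MeasurementSet),
#'   panel (PeptidePanel or NULL), compositions (optional named map from
#'   measurement target to residue string).
#' @slot exchanges data.frame: from, metabolite, to.
#' @slot fractions named numeric species fractions (used only by
#'   [mixtureLabeling()]).
#' @exportClass CommunityModel
setClass("CommunityModel",
         representation(species = "list", exchanges = "data.frame",
                        fractions = "numeric"))

setValidity("CommunityModel", function(object) {
  sp <- names(object@species)
  ex <- object@exchanges
  if (nrow(ex) > 0) {
    if (!all(c(ex$from, ex$to) %in% sp)) return("exchange names unknown species")
    if (.hasCycle(sp, ex)) return("exchange graph over species is cyclic")
    for (i in seq_len(nrow(ex))) {
      m <- ex$metabolite[i]
      cf <- .metCarbons(object@species[[ex$from[i]]]$network, m)
      ct <- .metCarbons(object@species[[ex$to[i]]]$network, m)
      if (!is.na(cf) && !is.na(ct) && cf != ct)
        return(sprintf("carbon count of exchanged metabolite '%s' disagrees", m))
    }
  }
  TRUE
})

.metCarbons <- function(net, m) {
  i <- match(m, net@metabolites$id)
  if (is.na(i)) NA_integer_ else net@metabolites$carbons[i]
}

.hasCycle <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (t in edges$to) indeg[t] <- indeg[t] + 1L
  q <- nodes[indeg == 0L]; seen <- 0L
  while (length(q)) {
    n <- q[1]; q <- q[-1]; seen <- seen + 1L
    out <- edges$to[edges$from == n]
    for (t in out) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) q <- c(q, t)
    }
  }
  seen < length(nodes)
}
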