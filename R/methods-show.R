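## show() methods and accessors

setMethod("show", "MDV", function(object) {
  lab <- if (is.na(object@label)) "" else paste0(" ", object@label)
  cat(sprintf("MDV%s (m = 0..%d): %s\n", lab, length(object) - 1L,
              paste(signif(as.numeric(object), 4), collapse = " ")))
})

setMethod("show", "MetabolicNetwork", function(object) {
  cat(sprintf("MetabolicNetwork: %d metabolites, %d reactions (%d split fluxes)\n",
              nrow(object@metabolites), length(object@reactions),
              nrow(object@fluxes)))
  cat(sprintf("  balanced rows: %d | substrates: %s | uptake: %s\n",
              nrow(object@S),
              paste(names(object@substrateLabeling), collapse = ","),
              object@uptake))
  if (nrow(object@measuredFluxes))
    cat(sprintf("  measured fluxes: %s\n",
                paste(object@measuredFluxes$reaction, collapse = ",")))
})

setMethod("show", "EMUGraph", function(object) {
  k <- table(object@nodes$kind)
  cat(sprintf("EMUGraph: %d nodes (%s), sizes %s, %d target(s)\n",
              nrow(object@nodes),
              paste(names(k), k, sep = ":", collapse = ", "),
              paste(names(object@strata), collapse = ","),
              length(object@targets)))
})

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf("MeasurementSet (%s): %d target(s)\n", object@mode,
              length(measurementTargets(object))))
})

setMethod("show", "PeptidePanel", function(object) {
  cat(sprintf("PeptidePanel: %d peptides (lengths %s)\n",
              nrow(object@peptides), object@lengthSpec))
})

setMethod("show", "FluxFit", function(object) {
  cat(sprintf("FluxFit (%s mode): objective %.4g, %d/%d starts converged\n",
              object@mode, object@objective,
              sum(object@starts$converged, na.rm = TRUE),
              nrow(object@starts)))
})

setMethod("show", "FluxBounds", function(object) {
  cat(sprintf("FluxBounds (%s): %d reactions, median width %.4g\n",
              object@method, nrow(object@ranges),
              stats::median(object@ranges$width, na.rm = TRUE)))
})

setMethod("show", "FICResult", function(object) {
  cat(sprintf("FIC = %.4f (epsilon %.3g, k %g, %d fluxes%s)\n",
              object@fic, object@epsilon, object@k, nrow(object@ranges),
              if (is.na(object@panelSize)) ""
              else sprintf(", panel size %d", as.integer(object@panelSize))))
})

setMethod("show", "CommunityModel", function(object) {
  cat(sprintf("CommunityModel: %d species (%s), %d exchange(s)\n",
              length(object@species),
              paste(names(object@species), collapse = ","),
              nrow(object@exchanges)))
})

#' Accessors for fit and range objects
#'
#' @param object a fitted object.
#' @return `fluxes()` returns the best per-reaction net fluxes of a
#'   [FluxFit-class]; `objective()` its objective value; `fittedMdvs()`
#'   its fitted MDVs; `fluxRanges()` the per-reaction range table of a
#'   [FluxBounds-class]; `ficValue()` the FIC number.
#' @export
fluxes <- function(object) object@netFluxes

#' @rdname fluxes
#' @export
objective <- function(object) object@objective

#' @rdname fluxes
#' @export
fittedMdvs <- function(object) object@fitted

#' @rdname fluxes
#' @export
fluxRanges <- function(object) object@ranges

#' @rdname fluxes
#' @export
ficValue <- function(object) object@fic

#' @rdname fluxes
#' @export
panelPeptides <- function(object) object@peptides
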