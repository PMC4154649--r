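## Carbon-transition model I/O
##
## Model files are tab-separated text with '#' comments and three sections:
##
##   [reactions]
##   id  equation                          reversible  lb  ub
##   v2  A (abc) -> C (bc) + CO2 (a)       0           0   10
##
##   [substrate_labeling]       # positional 13C purity, 1-based carbons
##   metabolite  carbon_position  purity
##
##   [measured_fluxes]          # net fluxes, normalized to uptake = 1
##   reaction  value  error
##
## Atom mappings are lowercase letters, one per carbon, reaction-local;
## each reactant letter must appear exactly once among the products.
## Boundary reactions (one empty side) are exempt. Reversible reactions
## are split into a forward and a backward flux; the backward atom
## mapping is the inverse of the forward one.

.parseSide <- function(txt, rxn, line) {
  txt <- trimws(txt)
  if (txt == "") return(list())
  terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
  out <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    t <- trimws(terms[k])
    m <- regmatches(t, regexec("^([A-Za-z0-9_]+)\\s*\\(([a-z]*)\\)$", t))[[1]]
    if (length(m) == 0) {
      m2 <- regmatches(t, regexec("^([A-Za-z0-9_]+)$", t))[[1]]
      if (length(m2))
        stop(sprintf("parse error in reaction '%s' (line %d): species '%s' lacks a carbon mapping",
                     rxn, line, t))
      stop(sprintf("parse error in reaction '%s' (line %d): cannot parse term '%s'",
                   rxn, line, t))
    }
    out[[k]] <- list(met = m[2], letters = strsplit(m[3], "")[[1]])
  }
  out
}

.parseEquation <- function(eq, rxn, line) {
  parts <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    if (length(parts) == 1 && grepl("->$", eq)) parts <- c(parts, "")
    else if (length(parts) == 1 && grepl("^\\s*->", eq)) parts <- c("", parts)
    else stop(sprintf("parse error in reaction '%s' (line %d): expected a single '->'",
                      rxn, line))
  }
  list(reactants = .parseSide(parts[1], rxn, line),
       products  = .parseSide(parts[2], rxn, line))
}

#' Read a carbon-transition metabolic model
#'
#' Parses the documented tab-separated dialect (see the package vignette)
#' into a [MetabolicNetwork-class]. Reversible reactions become
#' forward/backward flux pairs, the backward atom mapping being the
#' inverse of the forward one; backward fluxes are capped at
#' `exchangeCap` times the substrate uptake. Measured fluxes are
#' normalized so the uptake reaction carries flux 1.
#'
#' @param text model text, a character vector of lines, or a file path.
#' @param exchangeCap upper bound for backward fluxes of reversible
#'   reactions, in substrate-uptake units.
#' @param unspecifiedPurity 13C purity assigned to substrate carbon
#'   positions not covered by the labeling section (default natural
#'   abundance; set 0 for idealized tracers).
#' @return a validated [MetabolicNetwork-class].
#' @examples
#' net <- readNetworkModel(toyModelText("toy1"))
#' net
#' @export
readNetworkModel <- function(text, exchangeCap = 10, unspecifiedPurity = 0.0107) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else if (length(text) == 1)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text0 <- text
  text <- sub("#.*$", "", text)
  section <- ""
  reactions <- list()
  labRows <- list()
  measRows <- list()
  for (ln in seq_along(text)) {
    l <- trimws(text[ln])
    if (l == "") next
    if (grepl("^\\[", l)) {
      section <- gsub("\\[|\\]", "", l)
      next
    }
    f <- strsplit(text[ln], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (section == "reactions" || section == "") {
      if (identical(tolower(f[1]), "id")) next
      if (length(f) < 5)
        stop(sprintf("parse error at line %d: expected 5 tab-separated fields", ln))
      eq <- .parseEquation(f[2], f[1], ln)
      reactions[[f[1]]] <- list(id = f[1],
                                reactants = eq$reactants,
                                products = eq$products,
                                reversible = as.integer(f[3]) == 1L,
                                lb = as.numeric(f[4]), ub = as.numeric(f[5]))
    } else if (section == "substrate_labeling") {
      if (identical(tolower(f[1]), "metabolite")) next
      labRows[[length(labRows) + 1L]] <-
        data.frame(met = f[1], pos = as.integer(f[2]), purity = as.numeric(f[3]))
    } else if (section == "measured_fluxes") {
      if (identical(tolower(f[1]), "reaction")) next
      measRows[[length(measRows) + 1L]] <-
        data.frame(reaction = f[1], value = as.numeric(f[2]),
                   error = as.numeric(f[3]))
    } else {
      stop(sprintf("unknown section '%s' at line %d", section, ln))
    }
  }
  if (length(reactions) == 0) stop("model contains no reactions")
  lab <- if (length(labRows)) do.call(rbind, labRows) else NULL
  meas <- if (length(measRows)) do.call(rbind, measRows)
          else data.frame(reaction = character(), value = numeric(),
                          error = numeric())
  net <- buildNetwork(reactions, substrateRows = lab, measured = meas,
                      exchangeCap = exchangeCap,
                      unspecifiedPurity = unspecifiedPurity)
  attr(net, "sourceText") <- text0
  net
}

## Assemble a MetabolicNetwork from parsed reaction records.
buildNetwork <- function(reactions, substrateRows = NULL, measured = NULL,
                         substrateLabeling = NULL,
                         exchangeCap = 10, unspecifiedPurity = 0.0107) {
  ## metabolite table + carbon-count consistency
  mets <- new.env(parent = emptyenv())
  produced <- character(); consumed <- character()
  for (r in reactions) {
    for (side in c("reactants", "products")) {
      for (inst in r[[side]]) {
        nc <- length(inst$letters)
        old <- mets[[inst$met]]
        if (is.null(old)) assign(inst$met, nc, envir = mets)
        else if (old != nc)
          stop(sprintf("metabolite '%s' has %d carbons in reaction '%s' but %d elsewhere",
                       inst$met, nc, r$id, old))
      }
    }
    produced <- c(produced, vapply(r$products, `[[`, "", "met"))
    consumed <- c(consumed, vapply(r$reactants, `[[`, "", "met"))
    if (r$reversible) {
      produced <- c(produced, vapply(r$reactants, `[[`, "", "met"))
      consumed <- c(consumed, vapply(r$products, `[[`, "", "met"))
    }
  }
  ids <- ls(mets)
  carbons <- vapply(ids, function(i) mets[[i]], 0)

  ## substrate labeling spec
  subLab <- if (!is.null(substrateLabeling)) substrateLabeling else list()
  if (!is.null(substrateRows)) {
    for (m in unique(substrateRows$met)) {
      if (!m %in% ids) stop(sprintf("substrate '%s' is not in the model", m))
      pur <- rep(unspecifiedPurity, carbons[m])
      rows <- substrateRows[substrateRows$met == m, ]
      if (any(rows$pos < 1 | rows$pos > carbons[m]))
        stop(sprintf("substrate '%s': carbon position out of range", m))
      if (any(rows$purity < 0 | rows$purity > 1))
        stop(sprintf("substrate '%s': purity outside [0,1]", m))
      pur[rows$pos] <- rows$purity
      subLab[[m]] <- list(type = "positional",
                          components = list(list(weight = 1, purity = pur)))
    }
  }

  role <- ifelse(ids %in% names(subLab), "substrate",
          ifelse(ids %in% consumed & ids %in% produced, "balanced",
          ifelse(ids %in% produced, "sink", "boundary")))
  ## substrates with both producers and consumers still carry a balance row
  balanced <- ids[(ids %in% consumed & ids %in% produced)]
  bad <- ids[role == "boundary" & !ids %in% names(subLab)]
  if (length(bad))
    stop(sprintf("metabolite(s) with no producing reaction and no substrate labeling: %s",
                 paste(bad, collapse = ", ")))

  ## split fluxes
  fid <- character(); frxn <- character(); fdir <- integer()
  flb <- numeric(); fub <- numeric(); rxnSplit <- list()
  for (r in reactions) {
    fid <- c(fid, r$id); frxn <- c(frxn, r$id); fdir <- c(fdir, 1L)
    flb <- c(flb, max(r$lb, 0)); fub <- c(fub, r$ub)
    rxnSplit[[length(rxnSplit) + 1L]] <-
      list(reactants = r$reactants, products = r$products)
    if (r$reversible) {
      fid <- c(fid, paste0(r$id, "_b")); frxn <- c(frxn, r$id); fdir <- c(fdir, -1L)
      blb <- max(-r$ub, 0); bub <- if (r$lb < 0) min(-r$lb, exchangeCap) else exchangeCap
      flb <- c(flb, blb); fub <- c(fub, bub)
      rxnSplit[[length(rxnSplit) + 1L]] <-
        list(reactants = r$products, products = r$reactants)
    }
  }
  fluxes <- data.frame(id = fid, reaction = frxn, dir = fdir,
                       lb = flb, ub = fub, stringsAsFactors = FALSE)

  ## stoichiometric matrix over balanced metabolites
  S <- matrix(0, length(balanced), nrow(fluxes),
              dimnames = list(balanced, fluxes$id))
  for (k in seq_len(nrow(fluxes))) {
    for (inst in rxnSplit[[k]]$reactants)
      if (inst$met %in% balanced) S[inst$met, k] <- S[inst$met, k] - 1
    for (inst in rxnSplit[[k]]$products)
      if (inst$met %in% balanced) S[inst$met, k] <- S[inst$met, k] + 1
  }

  ## uptake reaction: first reaction importing into (or consuming nothing
  ## but producing from) a substrate metabolite
  uptake <- NA_character_
  for (r in reactions) {
    rmets <- vapply(r$reactants, `[[`, "", "met")
    if (length(r$reactants) == 0 ||
        any(rmets %in% names(subLab))) { uptake <- r$id; break }
  }
  measured <- if (is.null(measured))
    data.frame(reaction = character(), value = numeric(), error = numeric())
  else measured
  if (nrow(measured) > 0 && !all(measured$reaction %in% names(reactions)))
    stop("measured flux refers to unknown reaction")
  ## normalize to uptake = 1
  if (!is.na(uptake) && uptake %in% measured$reaction) {
    u <- measured$value[measured$reaction == uptake][1]
    if (is.finite(u) && u > 0 && abs(u - 1) > 1e-12) {
      measured$value <- measured$value / u
      measured$error <- measured$error / u
    }
  }

  net <- new("MetabolicNetwork",
             metabolites = data.frame(id = ids, carbons = unname(carbons),
                                      role = role, stringsAsFactors = FALSE),
             reactions = reactions,
             fluxes = fluxes, rxnSplit = rxnSplit, S = S,
             measuredFluxes = measured, substrateLabeling = subLab,
             uptake = uptake)
  net
}

#' Validate atom mappings of a network
#'
#' Reports, per reaction, unmatched or duplicated carbon mapping letters
#' and metabolite carbon-count conflicts. An empty report means every
#' reaction's mapping is a bijection from reactant to product carbons.
#' Boundary reactions (import/export with one empty side) are exempt.
#'
#' @param net a [MetabolicNetwork-class] (or a bare list of parsed
#'   reactions).
#' @return data.frame with columns reaction, type, detail.
#' @export
checkAtomBalance <- function(net) {
  reactions <- if (is(net, "MetabolicNetwork")) net@reactions else net
  out <- list()
  add <- function(rxn, type, detail)
    out[[length(out) + 1L]] <<- data.frame(reaction = rxn, type = type,
                                           detail = detail)
  for (r in reactions) {
    if (length(r$reactants) == 0 || length(r$products) == 0) next
    rl <- unlist(lapply(r$reactants, `[[`, "letters"))
    pl <- unlist(lapply(r$products, `[[`, "letters"))
    if (anyDuplicated(rl))
      add(r$id, "duplicate_letter",
          sprintf("letter '%s' used twice on reactant side",
                  rl[duplicated(rl)][1]))
    if (anyDuplicated(pl))
      add(r$id, "duplicate_letter",
          sprintf("letter '%s' used twice on product side",
                  pl[duplicated(pl)][1]))
    miss <- setdiff(rl, pl); extra <- setdiff(pl, rl)
    for (x in miss)
      add(r$id, "unbalanced_letter",
          sprintf("letter '%s' unbalanced (reactant side only)", x))
    for (x in extra)
      add(r$id, "unbalanced_letter",
          sprintf("letter '%s' unbalanced (product side only)", x))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(reaction = character(), type = character(),
                  detail = character())
}

#' Serialize a network back to model text
#'
#' Inverse of [readNetworkModel()]; parse -> serialize -> parse is
#' idempotent.
#'
#' @param net a [MetabolicNetwork-class].
#' @return character vector of lines.
#' @export
writeNetworkModel <- function(net) {
  fmtSide <- function(side)
    paste(vapply(side, function(i)
      sprintf("%s (%s)", i$met, paste(i$letters, collapse = "")), ""),
      collapse = " + ")
  lines <- c("[reactions]", "id\tequation\treversible\tlb\tub")
  for (r in net@reactions)
    lines <- c(lines, sprintf("%s\t%s -> %s\t%d\t%g\t%g", r$id,
                              fmtSide(r$reactants), fmtSide(r$products),
                              as.integer(r$reversible), r$lb, r$ub))
  lab <- net@substrateLabeling
  if (length(lab)) {
    lines <- c(lines, "[substrate_labeling]", "metabolite\tcarbon_position\tpurity")
    for (m in names(lab)) {
      if (lab[[m]]$type != "positional" || length(lab[[m]]$components) != 1)
        next  # mixtures / EMU specs are programmatic-only
      pur <- lab[[m]]$components[[1]]$purity
      for (p in seq_along(pur))
        lines <- c(lines, sprintf("%s\t%d\t%g", m, p, pur[p]))
    }
  }
  if (nrow(net@measuredFluxes)) {
    lines <- c(lines, "[measured_fluxes]", "reaction\tvalue\terror")
    mf <- net@measuredFluxes
    for (i in seq_len(nrow(mf)))
      lines <- c(lines, sprintf("%s\t%.12g\t%.12g", mf$reaction[i],
                                mf$value[i], mf$error[i]))
  }
  lines
}

#' Read / write MDV measurement tables
#'
#' CSV with columns target_id, m, fraction, error ('#' comments allowed).
#' The reader renormalizes an MDV only if its deviation from unit sum is
#' at most 1e-6 and errors otherwise; negative fractions are rejected.
#' Writing then reading reproduces the values exactly as decimal strings.
#'
#' @param x for reading: a path or CSV text; for writing: a
#'   [MeasurementSet-class].
#' @param mode measurement mode recorded on the returned set.
#' @param path optional output path for [writeMeasurements()]; when NULL
#'   the CSV lines are returned.
#' @return [readMeasurements()] returns a [MeasurementSet-class];
#'   [writeMeasurements()] a character vector (invisibly when writing to
#'   a file).
#' @export
readMeasurements <- function(x, mode = c("amino_acid", "peptide")) {
  mode <- match.arg(mode)
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- lines[trimws(lines) != ""]
  if (grepl("^\\s*target_id", lines[1])) lines <- lines[-1]
  f <- strsplit(lines, ",", fixed = TRUE)
  df <- data.frame(target = vapply(f, function(z) trimws(z[1]), ""),
                   m = as.integer(vapply(f, `[`, "", 2)),
                   value = as.numeric(vapply(f, `[`, "", 3)),
                   sigma = as.numeric(vapply(f, `[`, "", 4)))
  if (any(df$value < 0)) stop("negative fraction in measurement table")
  if (any(df$sigma < 0)) stop("negative error bound in measurement table")
  for (t in unique(df$target)) {
    i <- df$target == t
    df$m[i] <- df$m[i]  # keep order as read
    s <- sum(df$value[i])
    if (abs(s - 1) > 1e-6)
      stop(sprintf("MDV for target '%s' sums to %.6f (deviation > 1e-6)", t, s))
    if (abs(s - 1) > 0) df$value[i] <- df$value[i] / s
  }
  new("MeasurementSet", entries = df, mode = mode)
}

#' @rdname readMeasurements
#' @export
writeMeasurements <- function(x, path = NULL) {
  e <- x@entries
  lines <- c("target_id,m,fraction,error",
             sprintf("%s,%d,%s,%s", e$target, e$m,
                     vapply(e$value, format, "", digits = 15),
                     vapply(e$sigma, format, "", digits = 15)))
  if (is.null(path)) lines else { writeLines(lines, path); invisible(lines) }
}

#' Extract one observed MDV from a measurement set
#'
#' @param ms a [MeasurementSet-class].
#' @param target target id.
#' @return an [MDV-class].
#' @export
observedMdv <- function(ms, target) {
  e <- ms@entries[ms@entries$target == target, ]
  if (nrow(e) == 0) stop(sprintf("no measurement for target '%s'", target))
  e <- e[order(e$m), ]
  mdv(e$value, label = target, tol = 1e-6)
}

#' @rdname observedMdv
#' @export
measurementTargets <- function(ms) unique(ms@entries$target)

## sigma vector for a target, ordered by m
.sigmaOf <- function(ms, target) {
  e <- ms@entries[ms@entries$target == target, ]
  e$sigma[order(e$m)]
}
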