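## EMU decomposition and steady-state labeling simulation.
##
## An elementary metabolite unit (EMU) is a subset of a metabolite's
## carbon atoms. Tracing target EMUs backward through the atom mappings
## yields a dependency graph that is acyclic across size strata: a
## size-k EMU depends only on EMUs of size <= k, and strictly smaller
## ones through condensation (combined) nodes, whose MDVs are the
## convolution of their constituents. Labeling is then obtained by one
## linear solve per size stratum, in increasing size order.

.emuKey <- function(met, pos) paste0(met, ":", paste(pos, collapse = ","))
.keyMet <- function(key) sub(":.*$", "", key)
.keyPos <- function(key)
  as.integer(strsplit(sub("^.*:", "", key), ",", fixed = TRUE)[[1]])

#' Build an EMU target
#'
#' @param met metabolite id.
#' @param positions 1-based carbon positions (default: all carbons, in
#'   which case the network must be supplied).
#' @param net optional [MetabolicNetwork-class] used to default positions.
#' @return EMU key string "MET:p1,p2,..." used throughout the package.
#' @export
emuTarget <- function(met, positions = NULL, net = NULL) {
  if (is.null(positions)) {
    if (is.null(net)) stop("positions or net required")
    nc <- .metCarbons(net, met)
    if (is.na(nc)) stop(sprintf("metabolite '%s' not in network", met))
    positions <- seq_len(nc)
  }
  positions <- sort(unique(as.integer(positions)))
  .emuKey(met, positions)
}

#' EMU decomposition of a network
#'
#' Returns the dependency graph of all EMUs reachable backward from the
#' targets. Substrate metabolites (those with a labeling specification)
#' are source leaves; a reaction condensing two or more reactant
#' fragments into one product EMU creates a combined node whose MDV is
#' the convolution of its constituents.
#'
#' @param net a [MetabolicNetwork-class].
#' @param targets character vector of EMU keys (see [emuTarget()]).
#' @return an [EMUGraph-class].
#' @examples
#' net <- readNetworkModel(toyModelText("toy1"))
#' g <- emuDecompose(net, emuTarget("P", 1:2))
#' g
#' @export
emuDecompose <- function(net, targets) {
  mets <- net@metabolites
  subs <- names(net@substrateLabeling)
  ## producing flux indices per metabolite: list of (fluxIdx, instIdx)
  prodIdx <- list()
  for (k in seq_along(net@rxnSplit)) {
    ps <- net@rxnSplit[[k]]$products
    for (ii in seq_along(ps)) {
      m <- ps[[ii]]$met
      prodIdx[[m]] <- c(prodIdx[[m]], list(c(k, ii)))
    }
  }
  for (t in targets) {
    m <- .keyMet(t); p <- .keyPos(t)
    i <- match(m, mets$id)
    if (is.na(i)) stop(sprintf("target EMU on unknown metabolite '%s'", m))
    if (any(p < 1 | p > mets$carbons[i]))
      stop(sprintf("target EMU '%s': positions out of range", t))
  }
  nodes <- list(); producers <- list()
  queue <- unique(targets)
  seen <- character()
  while (length(queue)) {
    key <- queue[1]; queue <- queue[-1]
    if (key %in% seen) next
    seen <- c(seen, key)
    m <- .keyMet(key); pos <- .keyPos(key)
    if (m %in% subs) {
      nodes[[key]] <- list(met = m, size = length(pos), kind = "source")
      next
    }
    pr <- prodIdx[[m]]
    if (is.null(pr))
      stop(sprintf("EMU '%s' unreachable: metabolite '%s' has no producing reaction and no substrate labeling",
                   key, m))
    edges <- list()
    for (e in pr) {
      k <- e[1]; ii <- e[2]
      sp <- net@rxnSplit[[k]]
      inst <- sp$products[[ii]]
      letters <- inst$letters[pos]
      if (length(sp$reactants) == 0) {
        ## boundary import of a non-substrate metabolite: no carbon source
        stop(sprintf("EMU '%s': import flux '%s' has no labeling source; declare '%s' as substrate",
                     key, net@fluxes$id[k], m))
      }
      ## locate each letter among reactant instances
      srcs <- list()
      for (jj in seq_along(sp$reactants)) {
        rl <- sp$reactants[[jj]]$letters
        hit <- which(rl %in% letters)
        if (length(hit))
          srcs[[length(srcs) + 1L]] <-
            .emuKey(sp$reactants[[jj]]$met, sort(hit))
      }
      nfound <- sum(vapply(srcs, function(s) length(.keyPos(s)), 0L))
      if (nfound != length(pos))
        stop(sprintf("EMU '%s': atom mapping of flux '%s' does not cover all positions",
                     key, net@fluxes$id[k]))
      if (length(srcs) == 1L) {
        src <- srcs[[1]]
      } else {
        srcs <- sort(unlist(srcs))
        src <- paste0("cmb(", paste(srcs, collapse = "*"), ")")
        if (is.null(nodes[[src]])) {
          nodes[[src]] <- list(met = NA_character_,
                               size = length(pos), kind = "combined",
                               constituents = srcs)
          producers[[src]] <- srcs
        }
        queue <- c(queue, srcs)
      }
      edges[[length(edges) + 1L]] <- list(flux = k, src = src)
      if (!grepl("^cmb\\(", src)) queue <- c(queue, src)
    }
    nodes[[key]] <- list(met = m, size = length(pos), kind = "internal")
    producers[[key]] <- edges
  }
  keys <- names(nodes)
  nd <- data.frame(
    key = keys,
    met = vapply(nodes, function(n) n$met, ""),
    size = vapply(nodes, function(n) n$size, 0L),
    kind = vapply(nodes, function(n) n$kind, ""),
    stringsAsFactors = FALSE)
  sizes <- sort(unique(nd$size))
  strata <- lapply(sizes, function(s) nd$key[nd$size == s])
  names(strata) <- as.character(sizes)
  g <- new("EMUGraph", nodes = nd, producers = producers,
           strata = strata, targets = unique(targets))
  attr(g, "plan") <- .compilePlan(net, g)
  srcKeys <- nd$key[nd$kind == "source"]
  attr(g, "srcCache") <- lapply(stats::setNames(srcKeys, srcKeys),
                                function(k) .sourceMdv(net, k))
  g
}

## Precompile per-stratum index structures so repeated simulation calls
## only assemble numbers, not structure.
.compilePlan <- function(net, g) {
  nd <- g@nodes
  plan <- list()
  for (s in names(g@strata)) {
    keys <- g@strata[[s]]
    kinds <- nd$kind[match(keys, nd$key)]
    unknown <- keys[kinds == "internal"]
    combined <- keys[kinds == "combined"]
    sources <- keys[kinds == "source"]
    n <- length(unknown)
    aI <- integer(); aJ <- integer(); aF <- integer(); aS <- numeric()
    bI <- integer(); bF <- integer(); bKey <- character()
    if (n) {
      idx <- stats::setNames(seq_len(n), unknown)
      for (key in unknown) {
        i <- idx[[key]]
        for (e in g@producers[[key]]) {
          aI <- c(aI, i); aJ <- c(aJ, i); aF <- c(aF, e$flux); aS <- c(aS, -1)
          if (e$src %in% unknown) {
            aI <- c(aI, i); aJ <- c(aJ, idx[[e$src]])
            aF <- c(aF, e$flux); aS <- c(aS, 1)
          } else {
            bI <- c(bI, i); bF <- c(bF, e$flux); bKey <- c(bKey, e$src)
          }
        }
      }
    }
    cell <- (aJ - 1L) * n + aI
    ucell <- unique(cell)
    plan[[s]] <- list(size = as.integer(s), unknown = unknown,
                      combined = combined, sources = sources, n = n,
                      aF = aF, aS = aS,
                      aGroup = match(cell, ucell), aCells = ucell,
                      bI = bI, bF = bF, bKey = bKey)
  }
  plan
}

## MDV of a source (substrate) EMU from the labeling spec.
.sourceMdv <- function(net, key) {
  m <- .keyMet(key); pos <- .keyPos(key)
  spec <- net@substrateLabeling[[m]]
  if (is.null(spec)) stop(sprintf("no labeling spec for substrate '%s'", m))
  if (spec$type == "positional") {
    out <- 0
    for (cmp in spec$components) {
      x <- 1
      for (p in pos) x <- convolveMdv(x, c(1 - cmp$purity[p], cmp$purity[p]))
      out <- out + cmp$weight * x
    }
    out
  } else if (spec$type == "emu") {
    k2 <- paste(pos, collapse = ",")
    x <- spec$mdvs[[k2]]
    if (is.null(x))
      stop(sprintf("substrate '%s': no EMU MDV for positions %s", m, k2))
    as.numeric(x)
  } else stop("unknown substrate labeling type")
}

#' Simulate steady-state MDVs for a flux profile
#'
#' Solves the EMU labeling balances stratum by stratum (one linear
#' system per EMU size, in increasing order), computing combined-EMU
#' MDVs as convolutions of their constituents. The flux profile must be
#' at steady state (S v = 0 within `steadyTol`).
#'
#' @param net a [MetabolicNetwork-class].
#' @param v named numeric flux profile over `net@fluxes$id` (split
#'   fluxes, all >= 0).
#' @param graph an [EMUGraph-class] from [emuDecompose()]; defaults to
#'   decomposing for `targets`.
#' @param targets EMU keys (used when `graph` is NULL).
#' @param steadyTol tolerance on the steady-state residual.
#' @param all return every node's MDV instead of targets only.
#' @return named list of [MDV-class], one per target EMU.
#' @examples
#' net <- readNetworkModel(toyModelText("toy1"))
#' v <- c(v_upt = 1, v1 = 0.6, v2 = 0.4, v3 = 0.6, v4 = 1, v5 = 1)
#' simulateMdvs(net, v, targets = emuTarget("P", 1:2))
#' @export
simulateMdvs <- function(net, v, graph = NULL, targets = NULL,
                         steadyTol = 1e-8, all = FALSE) {
  if (is.null(graph)) {
    if (is.null(targets)) stop("graph or targets required")
    graph <- emuDecompose(net, targets)
  }
  v <- .alignFluxes(net, v)
  if (nrow(net@S) > 0) {
    res <- max(abs(net@S %*% v))
    if (res > steadyTol)
      stop(sprintf("flux profile is not at steady state (|S v| = %.3g)", res))
  }
  if (any(v < -1e-9)) stop("split fluxes must be non-negative")
  plan <- attr(graph, "plan")
  if (is.null(plan)) plan <- .compilePlan(net, graph)
  srcCache <- attr(graph, "srcCache")
  if (is.null(srcCache)) {
    srcKeys <- graph@nodes$key[graph@nodes$kind == "source"]
    srcCache <- lapply(stats::setNames(srcKeys, srcKeys),
                       function(k) .sourceMdv(net, k))
  }
  vals <- new.env(parent = emptyenv())
  for (st in plan) {
    for (key in st$sources)
      assign(key, srcCache[[key]], envir = vals)
    for (key in st$combined) {
      cons <- graph@producers[[key]]
      x <- get(cons[1], envir = vals)
      for (cc in cons[-1]) x <- convolveMdv(x, get(cc, envir = vals))
      assign(key, x, envir = vals)
    }
    n <- st$n
    if (n == 0L) next
    nm <- st$size + 1L
    A <- matrix(0, n, n)
    av <- v[st$aF] * st$aS
    A[st$aCells] <- rowsum(av, st$aGroup, reorder = FALSE)[, 1]
    B <- matrix(0, n, nm)
    if (length(st$bI)) {
      W <- v[st$bF]
      M <- matrix(0, length(st$bI), nm)
      for (q in seq_along(st$bI))
        M[q, ] <- .padTo(get(st$bKey[q], envir = vals), nm)
      BB <- rowsum(-W * M, st$bI, reorder = FALSE)
      B[as.integer(rownames(BB)), ] <- BB
    }
    dead <- which(abs(diag(A)) < 1e-12)
    if (length(dead))
      stop(sprintf("dead EMU (zero production): %s",
                   paste(st$unknown[dead], collapse = ", ")))
    X <- solve(A, B)
    for (i in seq_len(n)) {
      x <- X[i, ]
      x[x < 0 & x > -1e-9] <- 0
      assign(st$unknown[i], x / sum(x), envir = vals)
    }
  }
  keys <- if (all) graph@nodes$key else graph@targets
  out <- lapply(keys, function(k) mdv(get(k, envir = vals), label = k,
                                      tol = 1e-6))
  names(out) <- keys
  out
}

## align a (possibly per-reaction) flux vector to the split flux order
.alignFluxes <- function(net, v) {
  ids <- net@fluxes$id
  if (is.null(names(v))) {
    if (length(v) != length(ids)) stop("flux vector has wrong length")
    return(stats::setNames(as.numeric(v), ids))
  }
  miss <- setdiff(ids, names(v))
  if (length(miss))
    stop(sprintf("flux profile missing: %s", paste(miss, collapse = ", ")))
  stats::setNames(as.numeric(v[ids]), ids)
}

#' Net per-reaction fluxes of a split profile
#'
#' @param net a [MetabolicNetwork-class].
#' @param v split flux profile.
#' @return named numeric over reaction ids (forward minus backward).
#' @export
netFluxes <- function(net, v) {
  v <- .alignFluxes(net, v)
  fl <- net@fluxes
  out <- stats::setNames(numeric(length(net@reactions)), names(net@reactions))
  for (k in seq_len(nrow(fl)))
    out[fl$reaction[k]] <- out[fl$reaction[k]] + fl$dir[k] * v[k]
  out
}
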