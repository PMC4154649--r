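## Flux estimation by weighted nonlinear least squares and per-flux
## confidence ranges.
##
## Fluxes are parameterized over a null-space basis of the equality
## system {S v = 0, measured net fluxes}, so steady state and flux
## measurements hold exactly; flux bounds become linear constraints in
## the free coordinates and are enforced with an exterior quadratic
## penalty inside a multi-start local optimizer.

## null-space parameterization of {S v = 0, measured fluxes, bounds}
.freeParam <- function(net) {
  fl <- net@fluxes
  S <- net@S
  mf <- net@measuredFluxes
  E <- S; f <- rep(0, nrow(S))
  if (nrow(mf) > 0) {
    for (i in seq_len(nrow(mf))) {
      row <- numeric(nrow(fl))
      sel <- fl$reaction == mf$reaction[i]
      row[sel] <- fl$dir[sel]
      E <- rbind(E, row); f <- c(f, mf$value[i])
    }
  }
  if (nrow(E) == 0) {
    v0 <- rep(0, nrow(fl)); N <- diag(nrow(fl))
  } else {
    sv <- svd(E, nu = nrow(E), nv = ncol(E))
    tolr <- max(dim(E)) * max(sv$d) * .Machine$double.eps
    r <- sum(sv$d > tolr)
    v0 <- sv$v[, seq_len(r), drop = FALSE] %*%
      ((t(sv$u[, seq_len(r), drop = FALSE]) %*% f) / sv$d[seq_len(r)])
    v0 <- as.vector(v0)
    N <- sv$v[, seq(r + 1, length.out = ncol(E) - r), drop = FALSE]
  }
  d <- ncol(N)
  lb <- fl$lb; ub <- fl$ub
  viol <- function(alpha) {
    v <- v0 + as.vector(N %*% alpha)
    sum(pmax(lb - v, 0)^2 + pmax(v - ub, 0)^2)
  }
  alpha0 <- rep(0, d)
  if (d > 0 && viol(alpha0) > 1e-16)
    alpha0 <- stats::nlminb(alpha0, viol)$par
  if (viol(alpha0) > 1e-12)
    stop("no feasible stoichiometric point under the bounds and measured fluxes")
  list(v0 = v0, N = N, d = d, lb = lb, ub = ub, alpha0 = alpha0,
       ids = fl$id)
}

.alphaToV <- function(fp, alpha)
  stats::setNames(fp$v0 + as.vector(fp$N %*% alpha), fp$ids)

## interior samples of the free coordinates (hit-and-run)
.sampleAlphas <- function(fp, n, seed, burnin = 200L) {
  if (fp$d == 0L) return(matrix(numeric(0), nrow = n, ncol = 0))
  rng <- .localRNG(as.integer(seed))
  on.exit(rng())
  alpha <- fp$alpha0
  out <- matrix(0, n, fp$d)
  total <- burnin + n * 5L
  k <- 0L
  for (it in seq_len(total)) {
    u <- stats::rnorm(fp$d); u <- u / sqrt(sum(u^2))
    seg <- .segment(fp, alpha, u)
    if (seg[2] > seg[1])
      alpha <- alpha + stats::runif(1, seg[1], seg[2]) * u
    if (it > burnin && (it - burnin) %% 5L == 0L) {
      k <- k + 1L
      out[k, ] <- alpha
      if (k == n) break
    }
  }
  out
}

## resolve a measurement target / residue letter to a network metabolite
.resolveMet <- function(net, x, aaMap) {
  if (x %in% net@metabolites$id) return(x)
  if (x %in% names(aaMap) && aaMap[[x]] %in% net@metabolites$id)
    return(aaMap[[x]])
  stop(sprintf("cannot map target/residue '%s' to a network metabolite", x))
}

## build the simulation closure for a measurement set; returns
## list(graph, simFun(v) -> named list of simulated target MDVs)
.measSim <- function(net, meas, aaMap, compositions = NULL) {
  targets <- measurementTargets(meas)
  if (meas@mode == "amino_acid") {
    mets <- vapply(targets, .resolveMet, "", net = net, aaMap = aaMap)
    keys <- vapply(mets, function(m) emuTarget(m, net = net), "")
    graph <- emuDecompose(net, unique(keys))
    ## relaxed steady-state tolerance: optimizer iterates clamped to the
    ## flux bounds sit slightly off the S v = 0 manifold; the per-EMU
    ## normalization keeps the simulated MDVs valid
    simFun <- function(v) {
      sims <- simulateMdvs(net, v, graph, steadyTol = 1e-4)
      stats::setNames(lapply(keys, function(k) as.numeric(sims[[k]])), targets)
    }
  } else {
    seqs <- if (is.null(compositions)) stats::setNames(targets, targets)
            else vapply(targets, function(t)
              if (t %in% names(compositions)) compositions[[t]] else t, "")
    resid <- unique(unlist(strsplit(unname(seqs), "")))
    resid <- setdiff(resid, "X")
    mets <- vapply(resid, .resolveMet, "", net = net, aaMap = aaMap)
    keys <- vapply(mets, function(m) emuTarget(m, net = net), "")
    names(keys) <- resid
    graph <- emuDecompose(net, unique(keys))
    simFun <- function(v) {
      sims <- simulateMdvs(net, v, graph, steadyTol = 1e-4)
      resMdvs <- lapply(keys, function(k) as.numeric(sims[[k]]))
      stats::setNames(lapply(targets, function(t)
        as.numeric(peptideMdv(seqs[[t]], resMdvs))), targets)
    }
  }
  obs <- lapply(targets, function(t) as.numeric(observedMdv(meas, t)))
  sig <- lapply(targets, function(t) .sigmaOf(meas, t))
  names(obs) <- names(sig) <- targets
  list(graph = graph, simFun = simFun, targets = targets, obs = obs,
       sig = sig)
}

.ssr <- function(ms, sim) {
  s <- 0
  for (t in ms$targets) {
    x <- .padTo(sim[[t]], length(ms$obs[[t]]))
    s <- s + sum(((x - ms$obs[[t]]) / ms$sig[[t]])^2)
  }
  s
}

## max elementwise deviation beyond the error bounds
.maxExcess <- function(ms, sim, errs) {
  w <- 0
  for (t in ms$targets) {
    x <- .padTo(sim[[t]], length(ms$obs[[t]]))
    w <- max(w, max(abs(x - ms$obs[[t]]) - errs[[t]]))
  }
  w
}

#' Fit fluxes to amino-acid or peptide labeling
#'
#' Multi-start local minimization of the error-weighted sum of squared
#' MDV residuals, subject to steady state (exact, via the null-space
#' parameterization), flux bounds and measured-flux equalities. In
#' peptide mode the simulated amino-acid MDVs are convolved into
#' peptide MDVs before comparison.
#'
#' @param net a [MetabolicNetwork-class].
#' @param meas a [MeasurementSet-class]; its mode selects amino-acid or
#'   peptide fitting.
#' @param panel optional [PeptidePanel-class] (peptide mode); panel
#'   membership of the measured targets is checked.
#' @param config list: starts (default 10), seed (1), aaMap
#'   ([defaultAaMap()]), compositions (named map target id -> residue
#'   string when targets are not themselves sequences), penalty (1e6).
#' @return a [FluxFit-class].
#' @export
fitFluxes <- function(net, meas, panel = NULL, config = list()) {
  starts <- config$starts %||% 10L
  seed <- config$seed %||% 1L
  aaMap <- config$aaMap %||% defaultAaMap()
  pen <- config$penalty %||% 1e6
  if (!is.null(panel) && meas@mode == "peptide") {
    extra <- setdiff(measurementTargets(meas), panel@peptides$peptide)
    if (length(extra))
      stop(sprintf("measured peptides not in panel: %s",
                   paste(extra, collapse = ", ")))
  }
  fp <- .freeParam(net)
  ms <- .measSim(net, meas, aaMap, config$compositions)
  obj <- function(alpha) {
    v <- .alphaToV(fp, alpha)
    bviol <- sum(pmax(fp$lb - v, 0)^2 + pmax(v - fp$ub, 0)^2)
    if (bviol > 1e-10) return(1e8 + pen * bviol)  # outside the polytope
    sim <- tryCatch(ms$simFun(pmin(pmax(v, fp$lb), fp$ub)),
                    error = function(e) NULL)
    if (is.null(sim)) return(1e10)  # degenerate point (e.g. dead EMU)
    .ssr(ms, sim) + pen * bviol
  }
  if (fp$d == 0L) {
    val <- obj(numeric(0))
    best <- list(par = numeric(0), objective = val, convergence = 0L)
    log <- data.frame(start = 1L, objective = val, converged = TRUE)
  } else {
  A0 <- rbind(fp$alpha0,
              .sampleAlphas(fp, max(starts - 1L, 0L), seed))
  log <- data.frame(start = seq_len(nrow(A0)), objective = NA_real_,
                    converged = FALSE)
  best <- NULL
  for (i in seq_len(nrow(A0))) {
    r <- tryCatch(stats::nlminb(A0[i, ], obj,
                                control = list(rel.tol = 1e-12,
                                               abs.tol = 1e-14,
                                               eval.max = 2000,
                                               iter.max = 500)),
                  error = function(e) NULL)
    if (is.null(r)) next
    log$objective[i] <- r$objective
    log$converged[i] <- r$convergence == 0 || r$objective < 1e-10
    if (is.null(best) || r$objective < best$objective) best <- r
  }
  if (is.null(best)) stop("no start converged; fit failed")
  }
  vbest <- pmin(pmax(.alphaToV(fp, best$par), fp$lb), fp$ub)
  sims <- ms$simFun(vbest)
  new("FluxFit",
      profile = vbest, netFluxes = netFluxes(net, vbest),
      objective = .ssr(ms, sims),
      fitted = lapply(sims, function(x) mdv(.renorm(pmax(x, 0)), tol = 1e-6)),
      starts = log, mode = meas@mode,
      cache = list(fp = fp, ms = ms, alpha = best$par, net = net,
                   config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-flux confidence ranges under labeling error bounds
#'
#' For every reaction, finds the minimum and maximum net flux over all
#' steady-state profiles whose simulated labeling stays within the
#' elementwise error bounds of the measurements (bounds and measured
#' fluxes always enforced). Two methods:
#' `"nlp"` solves 2 per-flux penalized NLPs warm-started from the best
#' fit (with penalty continuation); `"grid"` scans a regular grid over
#' the free-flux polytope and reads ranges off the feasible points -
#' deterministic and cheap to reuse across many measurement subsets,
#' at the resolution of the grid.
#'
#' @param net a [MetabolicNetwork-class].
#' @param meas a [MeasurementSet-class].
#' @param fit a converged [FluxFit-class] for these measurements.
#' @param config list: method ("nlp" or "grid"), errBound (named list or
#'   single value; default the measurement sigmas), errModel ("absolute",
#'   the default, or "relative": bound_i = errBound * (obs_i +
#'   relOffset)), relOffset (0.05), gridN (points per free dimension,
#'   default 21), mu (penalty schedule), aaMap, compositions.
#' @return a [FluxBounds-class].
#' @export
fluxBounds <- function(net, meas, fit = NULL, config = list()) {
  method <- config$method %||% "nlp"
  aaMap <- config$aaMap %||% defaultAaMap()
  if (is.null(fit)) fit <- fitFluxes(net, meas, config = config)
  fp <- fit@cache$fp %||% .freeParam(net)
  ## always rebuild the measurement closure from `meas`: the fit may have
  ## been run with different error bounds
  ms <- .measSim(net, meas, aaMap, config$compositions)
  errs <- .errBounds(ms, config$errBound,
                     model = config$errModel %||% "absolute",
                     relOffset = config$relOffset %||% 0.05)
  rxns <- names(net@reactions)
  if (method == "grid") {
    gs <- config$gridCache %||% .gridSims(net, fp, ms, config)
    feas <- .gridFeasible(gs, ms, errs)
    ranges <- .rangesFromGrid(net, gs, feas, fit)
  } else {
    ranges <- .rangesFromNlp(net, fp, ms, errs, fit, config)
  }
  new("FluxBounds", ranges = ranges, method = method)
}

## Per-element absolute error bounds for the range subproblems.
## model "absolute": a flat bound per element (the measurement sigmas or
## a supplied amplitude). model "relative": bound_i = amp * (obs_i +
## relOffset) - the error scales with the element value as in the
## multiplicative MS noise model, with a detection-floor offset; this
## keeps amino-acid and peptide constraints like-for-like even though
## peptide MDVs spread the same signal over more masses.
.errBounds <- function(ms, errBound, model = "absolute",
                       relOffset = 0.05) {
  if (is.list(errBound)) return(errBound)
  if (model == "relative") {
    amp <- errBound %||% 0.05
    return(lapply(ms$obs, function(o) amp * (o + relOffset)))
  }
  if (is.null(errBound)) return(ms$sig)
  lapply(ms$obs, function(o) rep(errBound, length(o)))
}

## --- grid machinery (shared with the FIC curve) ---------------------------

## bounding interval of one free coordinate over the linear polytope
.alphaBox <- function(fp) {
  lo <- numeric(fp$d); hi <- numeric(fp$d)
  for (i in seq_len(fp$d)) {
    for (s in c(1, -1)) {
      f <- function(a) s * a[i] + 1e8 * sum(pmax(fp$lb - .alphaToV(fp, a), 0)^2 +
                                            pmax(.alphaToV(fp, a) - fp$ub, 0)^2)
      r <- stats::nlminb(fp$alpha0, f)
      if (s > 0) lo[i] <- r$par[i] else hi[i] <- r$par[i]
    }
  }
  cbind(lo, hi)
}

## simulate target amino-acid (residue-level) MDVs over a regular grid of
## the free-flux polytope; peptide MDVs are derived on demand. `extra`
## adds off-grid candidate points (e.g. the ground-truth profile, which
## is feasible by construction).
.gridSims <- function(net, fp, ms, config = list(), extra = NULL) {
  gridN <- config$gridN %||% 21L
  if (fp$d == 0L) {
    A <- matrix(numeric(0), nrow = 1, ncol = 0)
  } else {
    box <- .alphaBox(fp)
    axes <- lapply(seq_len(fp$d), function(i)
      seq(box[i, 1], box[i, 2], length.out = gridN))
    A <- as.matrix(expand.grid(axes))
    if (!is.null(extra)) A <- rbind(A, matrix(extra, ncol = fp$d))
  }
  keep <- logical(nrow(A)); sims <- vector("list", nrow(A))
  V <- matrix(NA_real_, nrow(A), length(fp$ids),
              dimnames = list(NULL, fp$ids))
  for (i in seq_len(nrow(A))) {
    v <- .alphaToV(fp, A[i, ])
    if (any(v < fp$lb - 1e-9) || any(v > fp$ub + 1e-9)) next
    v <- pmin(pmax(v, fp$lb), fp$ub)
    sims[[i]] <- tryCatch(ms$simFun(v), error = function(e) NULL)
    if (is.null(sims[[i]])) next
    keep[i] <- TRUE
    V[i, ] <- v
  }
  list(alpha = A[keep, , drop = FALSE], V = V[keep, , drop = FALSE],
       sims = sims[keep], fp = fp, net = net)
}

.gridFeasible <- function(gs, ms, errs) {
  vapply(gs$sims, function(sim) .maxExcess(ms, sim, errs) <= 1e-9, TRUE)
}

.rangesFromGrid <- function(net, gs, feas, fit = NULL) {
  rxns <- names(net@reactions)
  NV <- t(apply(gs$V, 1, function(v) netFluxes(net, v)))
  if (length(rxns) == 1L) NV <- matrix(NV, ncol = 1L,
                                       dimnames = list(NULL, rxns))
  pts <- NV[feas, , drop = FALSE]
  if (!is.null(fit)) pts <- rbind(pts, fit@netFluxes[rxns])
  if (nrow(pts) == 0)
    return(data.frame(reaction = rxns, vmin = NA_real_, vmax = NA_real_,
                      width = NA_real_, status = "infeasible"))
  data.frame(reaction = rxns,
             vmin = apply(pts, 2, min)[rxns],
             vmax = apply(pts, 2, max)[rxns],
             width = (apply(pts, 2, max) - apply(pts, 2, min))[rxns],
             status = "ok", row.names = NULL)
}

## --- NLP machinery --------------------------------------------------------

.rangesFromNlp <- function(net, fp, ms, errs, fit, config) {
  mu <- config$mu %||% c(1e3, 1e5, 1e7)
  rxns <- names(net@reactions)
  fl <- net@fluxes
  alpha0 <- fit@cache$alpha %||% fp$alpha0
  netRow <- function(rid) {
    row <- numeric(nrow(fl)); sel <- fl$reaction == rid
    row[sel] <- fl$dir[sel]; row
  }
  out <- data.frame(reaction = rxns, vmin = NA_real_, vmax = NA_real_,
                    width = NA_real_, status = "ok")
  ## total squared constraint violation at v (bounds + labeling); points
  ## outside the polytope or with degenerate labeling never count feasible
  constrAt <- function(v) {
    bviol <- sum(pmax(fp$lb - v, 0)^2 + pmax(v - fp$ub, 0)^2)
    if (bviol > 1e-10) return(1 + bviol)
    sim <- tryCatch(ms$simFun(pmin(pmax(v, fp$lb), fp$ub)),
                    error = function(e) NULL)
    if (is.null(sim)) return(1e6)
    bviol + .constraintExcess2(ms, sim, errs)
  }
  for (r in seq_along(rxns)) {
    row <- netRow(rxns[r])
    cvec <- as.vector(t(row) %*% fp$N)   # net flux = const + cvec . alpha
    cst <- sum(row * fp$v0)
    if (fp$d == 0L || all(abs(cvec) < 1e-12)) {
      val <- cst + if (fp$d) sum(cvec * alpha0) else 0
      out$vmin[r] <- out$vmax[r] <- val
      out$width[r] <- 0
      next
    }
    for (s in c(1, -1)) {
      a <- alpha0; val <- NA_real_
      for (m in mu) {
        f <- function(al)
          s * (cst + sum(cvec * al)) + m * constrAt(.alphaToV(fp, al))
        res <- tryCatch(stats::nlminb(a, f,
                                      control = list(rel.tol = 1e-11,
                                                     eval.max = 2000,
                                                     iter.max = 400)),
                        error = function(e) NULL)
        if (!is.null(res)) a <- res$par
      }
      ## pull the endpoint back toward the best fit until feasible,
      ## then refine the feasibility boundary by bisection
      feasAt <- function(t)
        constrAt(.alphaToV(fp, alpha0 + t * (a - alpha0))) < 1e-12
      ok <- FALSE; val <- NA_real_
      if (feasAt(1)) {
        ok <- TRUE; val <- cst + sum(cvec * a)
      } else if (feasAt(0)) {
        tlo <- 0; thi <- 1
        for (b in 1:40) {
          tm <- (tlo + thi) / 2
          if (feasAt(tm)) tlo <- tm else thi <- tm
        }
        ok <- TRUE
        val <- cst + sum(cvec * (alpha0 + tlo * (a - alpha0)))
      }
      if (!ok) out$status[r] <- "endpoint_infeasible"
      if (s > 0) out$vmin[r] <- val else out$vmax[r] <- val
    }
    bf <- fit@netFluxes[[rxns[r]]]
    out$vmin[r] <- min(out$vmin[r], bf, na.rm = TRUE)
    out$vmax[r] <- max(out$vmax[r], bf, na.rm = TRUE)
    out$width[r] <- out$vmax[r] - out$vmin[r]
  }
  out
}

.constraintExcess2 <- function(ms, sim, errs) {
  s <- 0
  for (t in ms$targets) {
    x <- .padTo(sim[[t]], length(ms$obs[[t]]))
    s <- s + sum(pmax(abs(x - ms$obs[[t]]) - errs[[t]], 0)^2)
  }
  s
}
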