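## Natural-isotope correction.
##
## GC-MS/LC-MS observes whole molecules, so the measured mass
## distribution includes shifts from naturally occurring heavy isotopes
## of the non-traced atoms (H, N, O, S, and any carbons outside the
## traced backbone). The correction matrix maps the traced-backbone MDV
## to the observed MDV: a lower-triangular banded matrix whose band is
## the natural mass-shift distribution of the heteroatoms.

## standard heavy-isotope abundances
.ISO <- list(
  H = c(0.000115),            # 2H
  C = c(0.0107),              # 13C (non-backbone carbons)
  N = c(0.00364),             # 15N
  O = c(0.00038, 0.00205),    # 17O, 18O
  S = c(0.0075, 0.0421))      # 33S, 34S

## free amino-acid molecular formulas (C H N O S)
.AA_FORMULA <- c(
  A = "C3H7NO2",   R = "C6H14N4O2", N = "C4H8N2O3",  D = "C4H7NO4",
  C = "C3H7NO2S",  E = "C5H9NO4",   Q = "C5H10N2O3", G = "C2H5NO2",
  H = "C6H9N3O2",  I = "C6H13NO2",  L = "C6H13NO2",  K = "C6H14N2O2",
  M = "C5H11NO2S", F = "C9H11NO2",  P = "C5H9NO2",   S = "C3H7NO3",
  T = "C4H9NO3",   V = "C5H11NO2",  W = "C11H12N2O2", Y = "C9H11NO3")

.parseFormula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  out <- integer()
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- gsub("[A-Za-z]", "", t)
    out[el] <- (if (el %in% names(out)) out[el] else 0L) +
      (if (n == "") 1L else as.integer(n))
  }
  out
}

## natural mass-shift distribution of one element with n atoms
.elementShift <- function(abund, n, window) {
  single <- c(1 - sum(abund), abund)
  d <- 1
  for (i in seq_len(n)) d <- convolveMdv(d, single)
  .padTo(d, window + 1L)
}

#' Natural-abundance correction matrix
#'
#' Builds the matrix mapping a traced-backbone MDV (carbon mass shifts
#' only) to the observed MDV including heteroatom natural isotopes. The
#' matrix has `backboneC + 1` columns and `backboneC + 1 + window`
#' rows; columns sum to at most 1 (mass shifts beyond the window are
#' truncated). For the dummy residue `"X"` (and an empty formula) the
#' matrix is the identity.
#'
#' @param x one-letter amino-acid code (uses the free amino-acid
#'   formula), `"X"` for the dummy residue, or an explicit molecular
#'   formula string such as `"C2H5NO2"`.
#' @param backboneC number of traced backbone carbons (defaults to the
#'   amino acid's full carbon count).
#' @param window maximum heteroatom mass shift retained (default +4).
#' @return numeric matrix.
#' @examples
#' cmG <- correctionMatrix("G")            # glycine, C2 backbone
#' applyCorrection(mdv(c(1, 0, 0)), cmG)
#' @export
correctionMatrix <- function(x, backboneC = NULL, window = 4L) {
  if (identical(x, "X")) {
    n <- if (is.null(backboneC)) 0L else backboneC
    return(diag(n + 1L))
  }
  formula <- if (nchar(x) == 1L) {
    if (!x %in% names(.AA_FORMULA)) stop(sprintf("unknown residue '%s'", x))
    .AA_FORMULA[[x]]
  } else x
  cnt <- .parseFormula(formula)
  totC <- if ("C" %in% names(cnt)) cnt[["C"]] else 0L
  if (is.null(backboneC)) backboneC <- totC
  if (totC > 0 && backboneC > totC)
    stop("backbone carbon count exceeds the formula's carbons")
  extraC <- max(totC - backboneC, 0L)
  nHet <- sum(cnt[names(cnt) %in% c("H", "N", "O", "S")]) + extraC
  if (nHet == 0L) return(diag(backboneC + 1L))  # nothing to correct
  shift <- 1
  if (extraC > 0) shift <- convolveMdv(shift, .elementShift(.ISO$C, extraC, window))
  for (el in c("H", "N", "O", "S")) {
    n <- if (el %in% names(cnt)) cnt[[el]] else 0L
    if (n > 0) shift <- convolveMdv(shift, .elementShift(.ISO[[el]], n, window))
  }
  shift <- .padTo(shift, window + 1L)
  nr <- backboneC + 1L + window
  nc <- backboneC + 1L
  A <- matrix(0, nr, nc)
  for (j in seq_len(nc))
    A[j:(j + window), j] <- shift
  A
}

#' Apply a correction matrix to an MDV
#'
#' Returns `cm %*% raw`, renormalized to unit sum. The lower-triangular
#' band structure guarantees no mass decrease.
#'
#' @param raw backbone [MDV-class] (length must equal `ncol(cm)`).
#' @param cm matrix from [correctionMatrix()].
#' @return corrected [MDV-class].
#' @export
applyCorrection <- function(raw, cm) {
  x <- as.numeric(raw)
  if (length(x) != ncol(cm))
    stop(sprintf("MDV length %d does not match correction matrix columns %d",
                 length(x), ncol(cm)))
  y <- as.vector(cm %*% x)
  mdv(.renorm(y), label = if (is(raw, "MDV")) raw@label else NA_character_,
      tol = 1e-6)
}

#' Carbon counts of the canonical amino acids
#' @return named integer vector over one-letter codes.
#' @export
aaCarbonCounts <- function()
  vapply(.AA_FORMULA, function(f) .parseFormula(f)[["C"]], 0L)
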