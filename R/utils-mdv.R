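#' Mass distribution vector helpers
#'
#' A mass distribution vector (MDV) holds the fractions of a molecule
#' population carrying m = 0, 1, 2, ... extra mass units. `mdv()` validates
#' and tags a numeric vector; `convolveMdv()` combines the MDVs of two
#' independent fragments (the Cauchy product of their generating
#' polynomials); `mdvMeanMass()` returns the first moment.
#'
#' @param x numeric vector of fractions for m = 0..length(x)-1.
#' @param label optional character label (EMU, metabolite or peptide id).
#' @param tol tolerance on the unit-sum check.
#' @return `mdv()` returns an object of class `MDV` (a numeric vector).
#' @examples
#' m <- mdv(c(0.4, 0.6, 0))
#' convolveMdv(m, m)   # labeling of two independent copies
#' mdvMeanMass(m)
#' @export
mdv <- function(x, label = NA_character_, tol = 1e-9) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("MDV must have at least one element")
  if (any(!is.finite(x))) stop("MDV contains non-finite values")
  if (any(x < -tol) || any(x > 1 + tol))
    stop("MDV values must lie in [0, 1]")
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("MDV must sum to 1 (got %.12f)", sum(x)))
  new("MDV", pmin(pmax(x, 0), 1), label = as.character(label))
}

#' @rdname mdv
#' @param y second MDV (numeric vector).
#' @export
convolveMdv <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  out <- numeric(nx + ny - 1L)
  for (i in seq_len(nx)) {
    if (x[i] != 0) {
      idx <- i:(i + ny - 1L)
      out[idx] <- out[idx] + x[i] * y
    }
  }
  out
}

#' @rdname mdv
#' @export
mdvMeanMass <- function(x) {
  x <- as.numeric(x)
  sum((seq_along(x) - 1L) * x)
}

## renormalize a non-negative vector to unit sum
.renorm <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot renormalize a vector with non-positive sum")
  x / s
}

## pad or truncate an MDV-like vector to length n (mass window)
.padTo <- function(x, n) {
  x <- as.numeric(x)
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}
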