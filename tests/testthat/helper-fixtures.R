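## Shared fixtures, built once per test run.

fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeToyFixtures()
    cache
  }
})

## the hand-traceable TOY1 steady-state profile: v2/v3 split 0.4/0.6
toy1Truth <- function(v2 = 0.4) {
  c(v_upt = 1, v1 = 1 - v2, v2 = v2, v3 = 1 - v2, v4 = 1, v5 = 1)
}

## independent polynomial-multiplication oracle for MDV convolution
polyProductOracle <- function(mdvList) {
  coefs <- Reduce(function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
      for (j in seq_along(b))
        out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    out
  }, mdvList)
  coefs
}

## random MDV of given length
randomMdv <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

## regular-expression tryptic digestion oracle
regexDigestOracle <- function(seq) {
  strsplit(seq, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}
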