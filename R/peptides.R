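## In-silico digestion, panel selection and peptide labeling.
##
## Peptide labeling depends only on amino-acid composition, not order:
## the peptide MDV is the sequential convolution (Cauchy product) of its
## residues' MDVs. Panels are therefore required to be pairwise distinct
## in composition, and - in community mode - string-unique to one
## species' proteome so each peptide is assignable.

#' In-silico proteolytic digestion
#'
#' Trypsin rules: cleave C-terminal to K or R except when the next
#' residue is P. Records containing non-amino-acid characters are
#' skipped with a warning.
#'
#' @param fasta protein sequences: an `AAStringSet`, a named character
#'   vector, or a path to a FASTA file (read with
#'   [Biostrings::readAAStringSet()]).
#' @param enzyme only "trypsin" is implemented.
#' @param missedCleavages maximum number of missed cleavages (default 0).
#' @return data.frame: peptide, protein, start, end, missed.
#' @examples
#' digestProteome(c(p1 = "AAKAAR"))$peptide     # "AAK", "AAR"
#' digestProteome(c(p1 = "AAKPAAR"))$peptide    # KP bond is not cleaved
#' @export
digestProteome <- function(fasta, enzyme = "trypsin", missedCleavages = 0L) {
  if (!identical(enzyme, "trypsin")) stop("only trypsin is implemented")
  seqs <- if (is(fasta, "AAStringSet")) {
    stats::setNames(as.character(fasta), names(fasta))
  } else if (is.character(fasta) && length(fasta) == 1 &&
             !grepl("[^A-Za-z0-9_./-]", fasta) && file.exists(fasta)) {
    x <- Biostrings::readAAStringSet(fasta)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else {
    if (is.null(names(fasta))) names(fasta) <- paste0("seq", seq_along(fasta))
    fasta
  }
  out <- list()
  for (nm in names(seqs)) {
    s <- toupper(seqs[[nm]])
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s)) {
      warning(sprintf("record '%s' contains non-amino-acid characters; skipped", nm))
      next
    }
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    cut <- which(ch %in% c("K", "R"))
    cut <- cut[cut < n & ch[pmin(cut + 1L, n)] != "P"]
    bounds <- c(0L, cut, n)
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1]
    nfrag <- length(starts)
    for (mc in 0:missedCleavages) {
      for (i in seq_len(max(nfrag - mc, 0L))) {
        st <- starts[i]; en <- ends[i + mc]
        out[[length(out) + 1L]] <-
          data.frame(peptide = substr(s, st, en), protein = nm,
                     start = st, end = en, missed = mc)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(peptide = character(), protein = character(),
                  start = integer(), end = integer(), missed = integer())
}

#' Select a measurement panel of peptides
#'
#' Filters digested peptides to the requested lengths, keeps only
#' peptides unique as strings across all supplied proteomes (community
#' mode) and pairwise distinct in amino-acid composition, then draws
#' `n` of them with a seeded RNG. Candidates are pre-sorted by
#' (length, lexicographic) so selection is deterministic given the seed;
#' among same-composition candidates the lexicographically first is
#' kept.
#'
#' @param peptides data.frame from [digestProteome()] (or a character
#'   vector of sequences).
#' @param n panel size.
#' @param lengths numeric lengths to admit (e.g. 5, c(5, 10, 15));
#'   `"mixed"` is shorthand for c(5, 10, 15) drawn in balanced
#'   round-robin order.
#' @param community optional named list of digests (or peptide vectors),
#'   one per species: peptides occurring in more than one species are
#'   excluded and each selected peptide is annotated with its species.
#' @param species species label for single-proteome panels.
#' @param seed RNG seed for the draw.
#' @return a [PeptidePanel-class].
#' @export
selectPanel <- function(peptides, n, lengths = c(5, 10, 15),
                        community = NULL, species = NA_character_,
                        seed = 1L) {
  mixed <- identical(lengths, "mixed")
  if (mixed) lengths <- c(5, 10, 15)
  lengths <- as.integer(lengths)
  asDf <- function(x, sp) {
    if (is.data.frame(x)) data.frame(peptide = x$peptide,
                                     protein = x$protein, species = sp)
    else data.frame(peptide = as.character(x), protein = NA_character_,
                    species = sp)
  }
  if (!is.null(community)) {
    all <- do.call(rbind, lapply(names(community),
                                 function(s) asDf(community[[s]], s)))
    tab <- unique(all[c("peptide", "species")])
    shared <- tab$peptide[duplicated(tab$peptide)]
    cand <- all[!all$peptide %in% shared, ]
  } else {
    cand <- asDf(peptides, species)
  }
  cand <- cand[!duplicated(cand$peptide), ]
  cand$length <- nchar(cand$peptide)
  cand <- cand[cand$length %in% lengths, ]
  cand <- cand[grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cand$peptide), ]
  cand <- cand[order(cand$length, cand$peptide), ]
  comp <- vapply(strsplit(cand$peptide, ""),
                 function(s) paste(sort(s), collapse = ""), "")
  cand <- cand[!duplicated(comp), ]
  if (nrow(cand) < n)
    stop(sprintf("insufficient candidates: %d composition-distinct peptides available, %d requested",
                 nrow(cand), n))
  rng <- .localRNG(as.integer(seed))
  on.exit(rng())
  if (mixed) {
    pick <- integer()
    byLen <- split(seq_len(nrow(cand)), cand$length)
    byLen <- lapply(byLen, function(i) i[sample.int(length(i))])
    li <- 1L
    while (length(pick) < n) {
      L <- as.character(lengths[(li - 1L) %% length(lengths) + 1L])
      if (length(byLen[[L]])) {
        pick <- c(pick, byLen[[L]][1]); byLen[[L]] <- byLen[[L]][-1]
      }
      li <- li + 1L
      if (all(vapply(byLen, length, 0L) == 0L)) break
    }
    if (length(pick) < n)
      stop(sprintf("insufficient candidates: only %d available", length(pick)))
  } else {
    pick <- sample.int(nrow(cand), n)
  }
  sel <- cand[pick, c("peptide", "protein", "species", "length")]
  rownames(sel) <- NULL
  new("PeptidePanel", peptides = sel,
      lengthSpec = if (mixed) "mixed" else paste(lengths, collapse = ","))
}

#' Peptide MDV by convolution of residue MDVs
#'
#' The MDV of a peptide is the Cauchy product of its residues' MDVs
#' (labeling depends on composition only, so any residue order gives the
#' same result). The dummy residue `X` contributes the delta MDV
#' `[1, 0]` and is inert. Optionally applies per-residue
#' natural-abundance correction matrices before convolving.
#'
#' @param seq peptide sequence (may include `X` padding).
#' @param aaMdvs named list/map residue letter -> MDV (numeric vectors).
#' @param correct apply [correctionMatrix()] per residue first.
#' @param window optional output truncation: keep only the first
#'   `window` mass shifts (renormalized); NULL keeps full length.
#' @return an [MDV-class] of length sum of residue MDV lengths minus
#'   (number of residues - 1) (before truncation).
#' @examples
#' peptideMdv("PP", list(P = c(0.4, 0.6, 0)))  # (0.4 + 0.6 x)^2
#' @export
peptideMdv <- function(seq, aaMdvs, correct = FALSE, window = NULL) {
  res <- strsplit(seq, "")[[1]]
  out <- 1
  for (r in res) {
    x <- if (r == "X") c(1, 0) else aaMdvs[[r]]
    if (is.null(x))
      stop(sprintf("no MDV supplied for residue '%s'", r))
    x <- as.numeric(x)
    if (correct && r != "X")
      x <- as.numeric(applyCorrection(mdv(x, tol = 1e-6),
                                      correctionMatrix(r, backboneC = length(x) - 1L)))
    out <- convolveMdv(out, x)
  }
  if (!is.null(window) && length(out) > window)
    out <- .renorm(out[seq_len(window)])
  mdv(out, label = seq, tol = 1e-6)
}
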