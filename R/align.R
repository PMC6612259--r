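#' @include AllClasses.R
NULL

#' IUPAC identity substitution matrix (DNA)
#'
#' Scores a match whenever the IUPAC ambiguity sets of the two symbols
#' intersect, so N matches everything at the match score. Used for the
#' strict read-overlap regime, where only near-exact matches should align.
#'
#' @param match,mismatch scores for intersecting / disjoint symbol sets.
#' @return Numeric matrix over the 15 IUPAC nucleotide letters.
#' @examples
#' iupacDNAMatrix()["N", "A"]
#' @export
iupacDNAMatrix <- function(match = 1, mismatch = -10) {
  map <- lapply(Biostrings::IUPAC_CODE_MAP, .chars)
  syms <- names(map)
  M <- matrix(mismatch, length(syms), length(syms),
              dimnames = list(syms, syms))
  for (x in syms) for (y in syms)
    if (length(intersect(map[[x]], map[[y]]))) M[x, y] <- match
  M
}

#' Identity substitution matrix (protein)
#'
#' Equality scoring over the 20 standard residues plus stop; the ambiguity
#' residue X matches everything at the match score (it arises from
#' unresolved N-containing codons and must not be penalized as a mismatch).
#'
#' @param match,mismatch match and mismatch scores.
#' @return Numeric matrix over the residues `ACDEFGHIKLMNPQRSTVWYX*`.
#' @export
identityProteinMatrix <- function(match = 1, mismatch = -10) {
  syms <- c(.chars("ACDEFGHIKLMNPQRSTVWY"), "X", "*")
  M <- matrix(mismatch, length(syms), length(syms),
              dimnames = list(syms, syms))
  diag(M) <- match
  M["X", ] <- match
  M[, "X"] <- match
  M
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Scoring schemes for the two alignment regimes
#'
#' `overlapScheme` builds the strict identity regime used to merge forward
#' and reverse sequencing products: high mismatch and gap penalties so that
#' only near-exact overlaps align. `modelScheme` builds the permissive
#' regime used to align clones to the reference model and to identify
#' clones: BLOSUM62 substitution scores (tolerating point mutations) with
#' high gap penalties (rejecting indels/frameshifts).
#'
#' @param level alphabet of the sequences to be aligned.
#' @param match,mismatch identity-matrix scores (overlap regime).
#' @param gap_open,gap_extend affine gap costs (negative).
#' @return A [ScoringScheme-class] object.
#' @examples
#' overlapScheme("protein")
#' modelScheme()
#' @export
overlapScheme <- function(level = c("protein", "dna"), match = 1,
                          mismatch = -10, gap_open = -20, gap_extend = -10) {
  level <- match.arg(level)
  M <- if (level == "dna") iupacDNAMatrix(match, mismatch)
       else identityProteinMatrix(match, mismatch)
  new("ScoringScheme", matrix = M, gap_open = gap_open,
      gap_extend = gap_extend, regime = "overlap_strict")
}

#' @rdname overlapScheme
#' @export
modelScheme <- function(gap_open = -12, gap_extend = -8) {
  new("ScoringScheme", matrix = .blosum62(), gap_open = gap_open,
      gap_extend = gap_extend, regime = "model_permissive")
}

#' Smith-Waterman local alignment
#'
#' Affine-gap local alignment returning the largest possible alignment with
#' the best score: among all cells attaining the maximal score, the
#' traceback with the longest aligned span wins; remaining ties break to
#' the smallest start on `a`, then on `b`.
#'
#' @param a,b residue strings (non-empty, uppercase).
#' @param scheme a [ScoringScheme-class].
#' @return A [LocalAlignment-class] object.
#' @examples
#' smithWaterman("ACGTT", "TTACG", overlapScheme("dna"))
#' @export
smithWaterman <- function(a, b, scheme) {
  stopifnot(is(scheme, "ScoringScheme"), nzchar(a), nzchar(b))
  syms <- rownames(scheme@matrix)
  ca <- .chars(a); cb <- .chars(b)
  ia <- match(ca, syms); ib <- match(cb, syms)
  if (anyNA(ia))
    stop("sequence 'a' contains symbols absent from the scoring matrix: ",
         paste(unique(ca[is.na(ia)]), collapse = ", "))
  if (anyNA(ib))
    stop("sequence 'b' contains symbols absent from the scoring matrix: ",
         paste(unique(cb[is.na(ib)]), collapse = ", "))
  r <- sw_align_cpp(ia, ib, scheme@matrix, scheme@gap_open, scheme@gap_extend)
  ga <- ifelse(r$col_a == 0L, "-", ca[pmax(r$col_a, 1L)])
  gb <- ifelse(r$col_b == 0L, "-", cb[pmax(r$col_b, 1L)])
  nid <- sum(r$col_a > 0L & r$col_b > 0L &
             ca[pmax(r$col_a, 1L)] == cb[pmax(r$col_b, 1L)])
  new("LocalAlignment", score = r$score,
      start_a = as.integer(r$start_a), end_a = as.integer(r$end_a),
      start_b = as.integer(r$start_b), end_b = as.integer(r$end_b),
      gapped_a = paste(ga, collapse = ""), gapped_b = paste(gb, collapse = ""),
      n_identical = as.integer(nid))
}
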