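#' @include hybridscreen-package.R
NULL

# ---------------------------------------------------------------- TrimParams

#' Quality-trimming parameters
#'
#' Sanger reads often start with unidentified base calls (N). Trimming keeps
#' only the sequence following the first N and truncates the 3' remainder
#' once the tolerated number of Ns (`n_cutoff`, counted globally including
#' the trimmed leading N) is exceeded.
#'
#' @slot n_cutoff integer(1), accepted number of unidentified bases
#'   (default 2: trim after the first N, truncate before the second).
#' @export
setClass("TrimParams", representation(n_cutoff = "integer"))

setValidity("TrimParams", function(object) {
  if (length(object@n_cutoff) != 1L || is.na(object@n_cutoff) ||
      object@n_cutoff < 1L)
    return("n_cutoff must be a single integer >= 1")
  TRUE
})

#' @param n_cutoff accepted number of N bases (>= 1).
#' @return A `TrimParams` object.
#' @examples
#' TrimParams()
#' @rdname TrimParams-class
#' @export
TrimParams <- function(n_cutoff = 2L) {
  new("TrimParams", n_cutoff = as.integer(n_cutoff))
}

# ------------------------------------------------------------------- TagSpec

#' Vector tag specification
#'
#' A short vector-derived sequence flanking the cloned insert in sequencing
#' products. Protein tags (e.g. the pAD tags STHAS at the 5' end and DPAFL
#' at the 3' end) are located by searching all six translation frames; DNA
#' tags are searched at the nucleotide level. `distance_to_orf` is the
#' number of residues (protein tags) or bases (DNA tags) between the tag
#' and the first in-frame codon of the insert.
#'
#' @slot sequence tag sequence (DNA or protein).
#' @slot alphabet `"dna"` or `"protein"`.
#' @slot end which end of the insert the tag marks: `"five_prime"` or
#'   `"three_prime"`.
#' @slot max_mismatch 0 or 1; mismatches are only tried when no exact match
#'   exists.
#' @slot distance_to_orf non-negative distance to the ORF, in residues
#'   (protein tag) or bases (DNA tag).
#' @export
setClass("TagSpec", representation(
  sequence = "character", alphabet = "character", end = "character",
  max_mismatch = "integer", distance_to_orf = "integer"))

setValidity("TagSpec", function(object) {
  msg <- character()
  if (nchar(object@sequence) < 3L) msg <- c(msg, "tag sequence length must be >= 3")
  if (!object@alphabet %in% c("dna", "protein"))
    msg <- c(msg, "alphabet must be 'dna' or 'protein'")
  if (!object@end %in% c("five_prime", "three_prime"))
    msg <- c(msg, "end must be 'five_prime' or 'three_prime'")
  if (!object@max_mismatch %in% c(0L, 1L))
    msg <- c(msg, "max_mismatch must be 0 or 1")
  if (object@distance_to_orf < 0L) msg <- c(msg, "distance_to_orf must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param sequence,alphabet,end,max_mismatch,distance_to_orf see slots.
#' @return A `TagSpec` object.
#' @examples
#' TagSpec("STHAS", "protein", "five_prime", distance_to_orf = 6)
#' @rdname TagSpec-class
#' @export
TagSpec <- function(sequence, alphabet = c("protein", "dna"),
                    end = c("five_prime", "three_prime"),
                    max_mismatch = 1L, distance_to_orf = 0L) {
  new("TagSpec", sequence = toupper(sequence), alphabet = match.arg(alphabet),
      end = match.arg(end), max_mismatch = as.integer(max_mismatch),
      distance_to_orf = as.integer(distance_to_orf))
}

#' Default pAD vector tags
#'
#' The 5' tag STHAS and 3' tag DPAFL of the pAD prey vector, with the
#' distances used in a typical full-length RY2H screen (six residues of
#' linker after the 5' tag, ORF ending directly before the 3' tag).
#'
#' @param dist5,dist3 distance to the ORF of the 5' and 3' tag, in residues.
#' @param max_mismatch allowed mismatches in the tag search (0 or 1).
#' @return Named list with elements `tag5` and `tag3`.
#' @examples
#' defaultTags()
#' @export
defaultTags <- function(dist5 = 6L, dist3 = 0L, max_mismatch = 1L) {
  list(tag5 = TagSpec("STHAS", "protein", "five_prime", max_mismatch, dist5),
       tag3 = TagSpec("DPAFL", "protein", "three_prime", max_mismatch, dist3))
}

# ------------------------------------------------------------- OverlapParams

#' Overlap-merge parameters
#'
#' Acceptance thresholds for merging a forward (AD) and reverse (TERM)
#' sequencing product. The defaults (18 bp / 6 amino acids, 5 perfect
#' matches) correspond to the minimum complete-codon stretch expected to be
#' unique in the human genome.
#'
#' @slot min_overlap_nt minimum overlap, nucleotide-level merges (default 18).
#' @slot min_overlap_aa minimum overlap, protein-level merges (default 6).
#' @slot min_perfect minimum number of identical aligned columns (default 5).
#' @slot level merge level: `"protein"` (default) or `"dna"`.
#' @export
setClass("OverlapParams", representation(
  min_overlap_nt = "integer", min_overlap_aa = "integer",
  min_perfect = "integer", level = "character"))

setValidity("OverlapParams", function(object) {
  msg <- character()
  if (!object@level %in% c("protein", "dna"))
    msg <- c(msg, "level must be 'protein' or 'dna'")
  min_ov <- if (identical(object@level, "protein")) object@min_overlap_aa
            else object@min_overlap_nt
  if (object@min_perfect > min_ov)
    msg <- c(msg, "min_perfect must not exceed the minimum overlap at the chosen level")
  if (object@min_overlap_nt < 1L || object@min_overlap_aa < 1L)
    msg <- c(msg, "minimum overlaps must be positive")
  if (length(msg)) msg else TRUE
})

#' @param min_overlap_nt,min_overlap_aa,min_perfect,level see slots.
#' @return An `OverlapParams` object.
#' @examples
#' OverlapParams()
#' @rdname OverlapParams-class
#' @export
OverlapParams <- function(min_overlap_nt = 18L, min_overlap_aa = 6L,
                          min_perfect = 5L, level = c("protein", "dna")) {
  new("OverlapParams", min_overlap_nt = as.integer(min_overlap_nt),
      min_overlap_aa = as.integer(min_overlap_aa),
      min_perfect = as.integer(min_perfect), level = match.arg(level))
}

# ------------------------------------------------------------ ScoringScheme

#' Alignment scoring scheme
#'
#' Two regimes are used: a strict identity regime for read overlap (near
#' exact matches only) and a permissive BLOSUM62 regime for clone-to-model
#' alignment (tolerates substitutions but not indels). Gap costs are affine:
#' the first gap column costs `gap_open`, each further column `gap_extend`.
#'
#' @slot matrix numeric substitution matrix with residue dimnames.
#' @slot gap_open,gap_extend negative gap costs, `gap_open <= gap_extend < 0`.
#' @slot regime label: `"overlap_strict"` or `"model_permissive"`.
#' @export
setClass("ScoringScheme", representation(
  matrix = "matrix", gap_open = "numeric", gap_extend = "numeric",
  regime = "character"))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (is.null(rownames(object@matrix)) ||
      !identical(rownames(object@matrix), colnames(object@matrix)))
    msg <- c(msg, "matrix must be square with identical row/col names")
  if (!(object@gap_open <= object@gap_extend && object@gap_extend < 0))
    msg <- c(msg, "gap costs must satisfy gap_open <= gap_extend < 0")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------------ LocalAlignment

#' Local pairwise alignment result
#'
#' Coordinates are 1-based inclusive on the input strings; an empty
#' alignment (score 0) has all coordinates 0.
#'
#' @slot score alignment score (>= 0).
#' @slot start_a,end_a,start_b,end_b aligned span on each sequence.
#' @slot gapped_a,gapped_b aligned strings with `-` gaps.
#' @slot n_identical number of identical aligned columns.
#' @export
setClass("LocalAlignment", representation(
  score = "numeric", start_a = "integer", end_a = "integer",
  start_b = "integer", end_b = "integer",
  gapped_a = "character", gapped_b = "character", n_identical = "integer"))

setMethod("show", "LocalAlignment", function(object) {
  cat(sprintf("LocalAlignment: score %g, a[%d-%d] vs b[%d-%d], %d/%d identical\n",
              object@score, object@start_a, object@end_a, object@start_b,
              object@end_b, object@n_identical, nchar(object@gapped_a)))
  if (nchar(object@gapped_a) > 0) {
    cat(" ", object@gapped_a, "\n ", object@gapped_b, "\n", sep = "")
  }
})

#' @rdname LocalAlignment-class
#' @param x a `LocalAlignment`.
#' @return `alignmentScore` returns the numeric score; `alignedLength` the
#'   number of aligned columns; `nIdentical` the identical-column count.
#' @export
alignmentScore <- function(x) x@score

#' @rdname LocalAlignment-class
#' @export
alignedLength <- function(x) nchar(x@gapped_a)

#' @rdname LocalAlignment-class
#' @export
nIdentical <- function(x) x@n_identical

# ------------------------------------------------------------------ ModelSeq

#' Reference model sequence
#'
#' The wild-type reference (DNA or protein) against which RY2H clones are
#' aligned to call mutations. DNA models are translated in forward frame 1;
#' a trailing stop is removed from the stored protein.
#'
#' @slot name record identifier.
#' @slot kind `"dna"` or `"protein"`.
#' @slot dna the DNA sequence, or `NA` for protein models.
#' @slot protein the protein sequence (20 standard residues plus X).
#' @export
setClass("ModelSeq", representation(
  name = "character", kind = "character", dna = "character",
  protein = "character"))

setValidity("ModelSeq", function(object) {
  msg <- character()
  if (!object@kind %in% c("dna", "protein"))
    msg <- c(msg, "kind must be 'dna' or 'protein'")
  if (!nzchar(object@protein)) msg <- c(msg, "protein must be non-empty")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", object@protein))
    msg <- c(msg, "protein may only contain the 20 standard residues plus X")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModelSeq", function(object) {
  cat(sprintf("ModelSeq '%s' (%s): %d aa%s\n", object@name, object@kind,
              nchar(object@protein),
              if (identical(object@kind, "dna"))
                sprintf(" from %d nt", nchar(object@dna)) else ""))
})

#' @rdname ModelSeq-class
#' @param x a `ModelSeq`.
#' @return `modelProtein` returns the protein string, `modelLength` its
#'   length in residues.
#' @export
modelProtein <- function(x) x@protein

#' @rdname ModelSeq-class
#' @export
modelLength <- function(x) nchar(x@protein)

# --------------------------------------------------------------- GeneticCode

#' Genetic code
#'
#' The universal code, or the bacterial code for bacterial two-hybrid
#' screens where GTG and TTG initiator codons are translated as methionine
#' at a declared ORF start.
#'
#' @slot name `"universal"` or `"bacterial"`.
#' @slot table named character of all 64 codon translations (`*` = stop).
#' @slot alt_starts start codons recoded to M at a declared ORF start.
#' @export
setClass("GeneticCode", representation(
  name = "character", table = "character", alt_starts = "character"))

setValidity("GeneticCode", function(object) {
  if (length(object@table) != 64L) return("codon table must have 64 entries")
  if (identical(object@name, "universal") &&
      !identical(object@alt_starts, "ATG"))
    return("universal code must have alt_starts = ATG")
  TRUE
})

#' @param name which code to use.
#' @return A `GeneticCode` object.
#' @examples
#' geneticCode("bacterial")
#' @rdname GeneticCode-class
#' @export
geneticCode <- function(name = c("universal", "bacterial")) {
  name <- match.arg(name)
  tab <- Biostrings::getGeneticCode(if (name == "universal") "1" else "11")
  attributes(tab) <- list(names = names(tab))
  alt <- if (name == "universal") "ATG" else c("ATG", "GTG", "TTG")
  new("GeneticCode", name = name, table = tab, alt_starts = alt)
}
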