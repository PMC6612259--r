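#' @include AllClasses.R
NULL

#' Reverse complement with IUPAC-aware complementation
#'
#' @param dna DNA string over the IUPAC alphabet.
#' @return The reverse complement (N stays N, R becomes Y, ...).
#' @examples
#' revComp("AACRN")
#' @export
revComp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Translate DNA with IUPAC ambiguity handling
#'
#' Codons containing N (or other IUPAC ambiguity codes) translate to the
#' unambiguous amino acid when every resolution agrees (e.g. GTN is valine);
#' otherwise they render as X, which downstream is treated as ambiguity and
#' never as a mutation. Stop codons render as `*`. At a declared ORF start
#' (`is_orf_start = TRUE`), an alternative initiator codon of the genetic
#' code (bacterial: GTG, TTG) is emitted as M. A trailing incomplete codon
#' is dropped.
#'
#' @param dna DNA string.
#' @param code a [GeneticCode-class].
#' @param frame 0, 1 or 2: bases skipped before the first codon.
#' @param strand `"+"` or `"-"` (the reverse complement is translated).
#' @param is_orf_start whether the first codon is a declared ORF start.
#' @return Protein string (possibly empty when fewer than 3 bases remain).
#' @examples
#' translateDNA("ATGGTNAAA")                      # "MVK"
#' translateDNA("GTGAAA", geneticCode("bacterial"), is_orf_start = TRUE)
#' @export
translateDNA <- function(dna, code = geneticCode(), frame = 0L,
                         strand = c("+", "-"), is_orf_start = FALSE) {
  strand <- match.arg(strand)
  stopifnot(frame %in% 0:2)
  s <- if (strand == "-") revComp(dna) else toupper(dna)
  s <- substr(s, frame + 1L, nchar(s))
  n <- 3L * (nchar(s) %/% 3L)
  if (n == 0L) return("")
  s <- substr(s, 1L, n)
  gc <- code@table
  attr(gc, "alt_init_codons") <- character(0)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(s), genetic.code = gc,
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  if (is_orf_start && substr(s, 1L, 3L) %in% code@alt_starts)
    substr(aa, 1L, 1L) <- "M"
  aa
}

# longest stop-free stretch of a translated sequence, in residues
.longestStretch <- function(aa) {
  if (!nzchar(aa)) return(0L)
  max(nchar(strsplit(aa, "*", fixed = TRUE)[[1]]), 0L)
}

#' Global reading-frame selection (ORF analysis)
#'
#' Translates every sequence in all six strand/frame combinations and
#' retains the combination with the highest mean translated size, where the
#' translated size of one sequence is the length of its longest stop-free
#' amino-acid stretch. Ties break to the forward strand, lowest frame. The
#' selection is global across all sequences, matching libraries cloned in a
#' single frame.
#'
#' @param seqs character vector of DNA sequences (at least one).
#' @param code a [GeneticCode-class].
#' @return List with `strand` (`"+"`/`"-"`), `frame` (0, 1 or 2) and
#'   `mean_size` (mean longest stretch at the winner).
#' @examples
#' findBestOrf(c("ATGAAAGCTTAA"))
#' @export
findBestOrf <- function(seqs, code = geneticCode()) {
  stopifnot(length(seqs) >= 1L)
  combos <- expand.grid(frame = 0:2, strand = c("+", "-"),
                        stringsAsFactors = FALSE)[, 2:1]
  means <- apply(combos, 1L, function(cmb) {
    mean(vapply(seqs, function(s)
      as.numeric(.longestStretch(translateDNA(s, code, as.integer(cmb[["frame"]]),
                                              cmb[["strand"]]))),
      numeric(1)))
  })
  if (max(means) == 0) stop("no open reading frame")
  i <- which.max(means) # first maximum: forward strand, lowest frame
  list(strand = combos$strand[i], frame = as.integer(combos$frame[i]),
       mean_size = means[i])
}
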