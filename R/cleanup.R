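#' @include AllClasses.R
NULL

#' Quality trimming by unidentified bases
#'
#' The start of a Sanger read often contains N calls from poor early signal.
#' Only the sequence following the first N is used; toward the 3' end the
#' read is truncated strictly before the N at which the tolerated count
#' (`n_cutoff`, counted including the trimmed leading N) is exceeded. The
#' result never starts or ends with N. An empty result means the read
#' failed quality trimming and should be excluded (reason `"quality"`).
#'
#' @param dna non-empty DNA string.
#' @param params a [TrimParams-class] (default `n_cutoff = 2`).
#' @return Trimmed DNA string, possibly empty.
#' @examples
#' qualityTrim("NACGTNAA")   # "ACGT"
#' qualityTrim("ACGNTTNAA")  # "TT"
#' @export
qualityTrim <- function(dna, params = TrimParams()) {
  stopifnot(nzchar(dna))
  dna <- toupper(dna)
  npos <- gregexpr("N", dna, fixed = TRUE)[[1]]
  if (npos[1] == -1L) return(dna)
  rest <- substr(dna, npos[1] + 1L, nchar(dna))
  if (!nzchar(rest)) return("")
  k <- max(1L, params@n_cutoff - 1L) # index of the terminating N in `rest`
  rn <- gregexpr("N", rest, fixed = TRUE)[[1]]
  if (rn[1] != -1L && length(rn) >= k)
    rest <- substr(rest, 1L, rn[k] - 1L)
  # boundary Ns can remain when fewer than k Ns exist; strip them
  gsub("^N+|N+$", "", rest)
}

# Hamming search for `tag` in `seq`: exact first, then leftmost window with
# at most max_mismatch mismatches. Returns 1-based position or NA.
.findTag <- function(seq, tag, max_mismatch) {
  p <- regexpr(tag, seq, fixed = TRUE)[1]
  if (p > 0L) return(as.integer(p))
  t <- nchar(tag)
  if (max_mismatch > 0L && t <= nchar(seq)) {
    tc <- .chars(tag)
    for (i in seq_len(nchar(seq) - t + 1L)) {
      if (sum(.chars(substr(seq, i, i + t - 1L)) != tc) <= max_mismatch)
        return(i)
    }
  }
  NA_integer_
}

#' Locate a vector tag in a sequence
#'
#' Exact substring search first; only if no exact match exists, the
#' sequence is rescanned allowing up to `max_mismatch` Hamming mismatches,
#' returning the leftmost qualifying position (vector tags sit at the
#' beginning of sequencing products, so the first match is the real one).
#'
#' @param dna sequence to search (DNA, or protein when searching
#'   translations).
#' @param tag tag sequence, same alphabet as `dna`.
#' @param max_mismatch allowed mismatches in the fallback scan (0 or 1).
#' @return 1-based match position, or `NA` when absent.
#' @examples
#' findTag("AAATGGAAA", "TAG", 1)  # 4 (one mismatch)
#' @export
findTag <- function(dna, tag, max_mismatch = 1L) {
  stopifnot(nchar(tag) <= nchar(dna))
  .findTag(toupper(dna), toupper(tag), as.integer(max_mismatch))
}

#' Locate a protein tag across all six reading frames
#'
#' Translates the read in all six strand/frame combinations and applies the
#' exact-then-mismatch tag search at the amino-acid level. The exact pass
#' covers all six frames before any mismatch is considered. If the tag is
#' found in more than one frame, the forward strand, lowest frame and
#' leftmost position win and a warning is recorded.
#'
#' @param dna the read (DNA).
#' @param tag_aa protein tag (length >= 2).
#' @param max_mismatch allowed amino-acid mismatches (fallback only).
#' @param code a [GeneticCode-class].
#' @return `NULL` when absent, else a list with `strand`, `frame`,
#'   `aa_start` (1-based residue position in the frame translation) and
#'   `nt_start` (1-based base offset of the tag start on the reading
#'   strand, i.e. on `revComp(dna)` when `strand == "-"`).
#' @export
locateProteinTag <- function(dna, tag_aa, max_mismatch = 1L,
                             code = geneticCode()) {
  stopifnot(nchar(tag_aa) >= 2L)
  tag_aa <- toupper(tag_aa)
  combos <- list(c("+", 0), c("+", 1), c("+", 2),
                 c("-", 0), c("-", 1), c("-", 2))
  aas <- lapply(combos, function(cmb)
    translateDNA(dna, code, as.integer(cmb[2]), cmb[1]))
  for (mm in unique(c(0L, as.integer(max_mismatch)))) {
    hits <- list()
    for (i in seq_along(combos)) {
      if (nchar(aas[[i]]) < nchar(tag_aa)) next
      p <- .findTag(aas[[i]], tag_aa, mm)
      if (!is.na(p)) hits[[length(hits) + 1L]] <-
          list(strand = combos[[i]][1], frame = as.integer(combos[[i]][2]),
               aa_start = p)
    }
    if (length(hits)) {
      if (length(hits) > 1L)
        warning("vector tag '", tag_aa, "' found in ", length(hits),
                " frames; using forward strand, lowest frame")
      h <- hits[[1]]
      h$nt_start <- h$frame + 3L * (h$aa_start - 1L) + 1L
      return(h)
    }
  }
  NULL
}

#' Trim a read to its open reading frame
#'
#' Locates the vector tag (after quality trimming) and discards all bases
#' outside the insert: for a 5' tag the retained sequence starts at tag end
#' plus the configured distance to the ORF (3 bases per residue for protein
#' tags); for a 3' tag it ends at tag start minus that distance, and any
#' leading remainder bases are dropped so the result is in frame. The
#' returned sequence is always in sense (coding) orientation, so a reverse
#' sequencing product is orientation-corrected by this step.
#'
#' @param dna quality-trimmed read.
#' @param tag a [TagSpec-class].
#' @param code a [GeneticCode-class] (protein-tag search).
#' @return In-frame DNA string in sense orientation, or `NA_character_`
#'   when the tag is not found at the allowed mismatch count (the read is
#'   then excluded with reason `"no-vector-tag"`).
#' @export
trimToOrf <- function(dna, tag, code = geneticCode()) {
  stopifnot(is(tag, "TagSpec"))
  dna <- toupper(dna)
  if (tag@alphabet == "protein") {
    hit <- locateProteinTag(dna, tag@sequence, tag@max_mismatch, code)
    if (is.null(hit)) return(NA_character_)
    s <- if (hit$strand == "-") revComp(dna) else dna
    tstart <- hit$nt_start
    tlen <- 3L * nchar(tag@sequence)
    dist <- 3L * tag@distance_to_orf
  } else {
    p <- findTag(dna, tag@sequence, tag@max_mismatch)
    if (!is.na(p)) {
      s <- dna; tstart <- p
    } else {
      rc <- revComp(dna)
      p <- findTag(rc, tag@sequence, tag@max_mismatch)
      if (is.na(p)) return(NA_character_)
      s <- rc; tstart <- p
    }
    tlen <- nchar(tag@sequence)
    dist <- tag@distance_to_orf
  }
  if (tag@end == "five_prime") {
    out <- substr(s, tstart + tlen + dist, nchar(s))
  } else {
    out <- substr(s, 1L, tstart - 1L - dist)
    out <- substr(out, nchar(out) %% 3L + 1L, nchar(out)) # start in frame
  }
  out
}
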