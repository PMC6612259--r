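#' @include cleanup.R align.R translate.R
NULL

# Trim the secondary vector tag from an in-frame sense-orientation insert
# sequence, when the read ran through the opposite end of the insert.
.trimOtherEnd <- function(seq, tag, code = geneticCode()) {
  if (!nzchar(seq)) return(seq)
  if (tag@alphabet == "protein") {
    aa <- translateDNA(seq, code, 0L, "+")
    p <- if (nchar(aa) >= nchar(tag@sequence))
      .findTag(aa, tag@sequence, tag@max_mismatch) else NA_integer_
    if (is.na(p)) return(seq)
    if (tag@end == "three_prime") {
      substr(seq, 1L, 3L * (p - 1L) - 3L * tag@distance_to_orf)
    } else {
      substr(seq, 3L * (p - 1L + nchar(tag@sequence) + tag@distance_to_orf) + 1L,
             nchar(seq))
    }
  } else {
    p <- if (nchar(seq) >= nchar(tag@sequence))
      .findTag(seq, tag@sequence, tag@max_mismatch) else NA_integer_
    if (is.na(p)) return(seq)
    if (tag@end == "three_prime") substr(seq, 1L, p - 1L - tag@distance_to_orf)
    else substr(seq, p + nchar(tag@sequence) + tag@distance_to_orf, nchar(seq))
  }
}

#' Merge forward and reverse sequences over their overlap
#'
#' Aligns the (already orientation-corrected and trimmed) forward and
#' reverse sequences with the strict identity regime and accepts the merge
#' when the aligned span reaches the minimum overlap, contains at least
#' `min_perfect` identical columns, and is compatible with a
#' suffix-of-forward / prefix-of-reverse layout (alignment ends within 3
#' residues of the forward end and starts within 3 residues of the reverse
#' start). In the merged sequence the forward read wins over the overlap.
#'
#' @param fwd_seq,rev_seq residue strings at the merge level (protein or
#'   DNA); the reverse sequence must already be in sense orientation.
#' @param params an [OverlapParams-class].
#' @param scheme a [ScoringScheme-class]; default is the strict identity
#'   scheme at `params@level`.
#' @return List with `merged` (string or `NA`), `status`
#'   (`"AD-TERM OVERLAPPED"` or `"TERM NON-OVERLAPPED"`) and `alignment`.
#' @examples
#' overlapMerge("MKLVNQWERTY", "WERTYAADDSS",
#'              OverlapParams(min_overlap_aa = 5, min_perfect = 5))
#' @export
overlapMerge <- function(fwd_seq, rev_seq, params = OverlapParams(),
                         scheme = overlapScheme(params@level)) {
  aln <- smithWaterman(fwd_seq, rev_seq, scheme)
  min_ov <- if (params@level == "protein") params@min_overlap_aa
            else params@min_overlap_nt
  ok <- alignedLength(aln) >= min_ov &&
    nIdentical(aln) >= params@min_perfect &&
    aln@end_a > 0L &&
    (nchar(fwd_seq) - aln@end_a) <= 3L &&
    (aln@start_b - 1L) <= 3L
  if (!ok)
    return(list(merged = NA_character_, status = "TERM NON-OVERLAPPED",
                alignment = aln))
  merged <- paste0(substr(fwd_seq, 1L, aln@end_a),
                   substr(rev_seq, aln@end_b + 1L, nchar(rev_seq)))
  list(merged = merged, status = "AD-TERM OVERLAPPED", alignment = aln)
}

.cloneRow <- function(clone_name, status, dna, protein, mutation_eligible,
                      forward_id = NA_character_, reverse_id = NA_character_,
                      note = "") {
  S4Vectors::DataFrame(clone_name = clone_name, status = status, dna = dna,
                       protein = protein, mutation_eligible = mutation_eligible,
                       forward_id = forward_id, reverse_id = reverse_id,
                       note = note)
}

#' Assemble one clone from its read pair
#'
#' Applies quality trimming and vector-tag trimming to each present read
#' (the reverse read comes out orientation-corrected), merges the two at
#' the configured level, and translates the result. Status labels follow
#' the screening convention: `"AD-TERM OVERLAPPED"` for an accepted merge,
#' `"TERM NON-OVERLAPPED"` for a reverse product without (matching) forward
#' sequence, and `"AD DISCARDED"` for a forward product without usable
#' reverse partner, for which neither translation nor overlap is attempted.
#'
#' @param pair one element of `pairReads()$pairs`.
#' @param tag5,tag3 [TagSpec-class] for the 5' and 3' vector tags.
#' @param trim a [TrimParams-class].
#' @param params an [OverlapParams-class].
#' @param code a [GeneticCode-class].
#' @return A one-row `DataFrame` (clone_name, status, dna, protein,
#'   mutation_eligible, forward_id, reverse_id, note), or a `"droppedClone"`
#'   marker (list with the exclusion `reason`) when both reads are excluded
#'   by trimming.
#' @export
assembleClone <- function(pair, tag5, tag3, trim = TrimParams(),
                          params = OverlapParams(), code = geneticCode()) {
  prep <- function(read, tag, other) {
    if (is.na(read)) return(list(seq = NA_character_, reason = "absent"))
    q <- qualityTrim(read, trim)
    if (!nzchar(q)) return(list(seq = NA_character_, reason = "quality"))
    s <- trimToOrf(q, tag, code)
    if (is.na(s) || !nzchar(s))
      return(list(seq = NA_character_, reason = "no-vector-tag"))
    list(seq = .trimOtherEnd(s, other, code), reason = NA_character_)
  }
  f <- prep(pair$forward, tag5, tag3)
  r <- prep(pair$reverse, tag3, tag5)
  fok <- !is.na(f$seq) && nzchar(f$seq)
  rok <- !is.na(r$seq) && nzchar(r$seq)

  if (!fok && !rok) {
    reason <- paste0("forward:", f$reason, ";reverse:", r$reason)
    return(structure(list(reason = reason), class = "droppedClone"))
  }
  if (fok && !rok) {
    # no usable C-terminal sequence: discarded, not translated
    return(.cloneRow(pair$clone_name, "AD DISCARDED", NA_character_,
                     NA_character_, FALSE, pair$forward_id, pair$reverse_id,
                     note = paste0("reverse:", r$reason)))
  }
  rp <- translateDNA(r$seq, code, 0L, "+")
  if (!fok && rok) {
    return(.cloneRow(pair$clone_name, "TERM NON-OVERLAPPED", r$seq, rp, FALSE,
                     pair$forward_id, pair$reverse_id,
                     note = paste0("forward:", f$reason)))
  }
  fp <- translateDNA(f$seq, code, 0L, "+", is_orf_start = TRUE)
  if (params@level == "protein") {
    m <- overlapMerge(fp, rp, params)
    if (identical(m$status, "AD-TERM OVERLAPPED")) {
      gapless <- !grepl("-", m$alignment@gapped_a, fixed = TRUE) &&
                 !grepl("-", m$alignment@gapped_b, fixed = TRUE)
      dna <- if (gapless)
        paste0(substr(f$seq, 1L, 3L * m$alignment@end_a),
               substr(r$seq, 3L * m$alignment@end_b + 1L, nchar(r$seq)))
      else NA_character_
      return(.cloneRow(pair$clone_name, m$status, dna, m$merged, TRUE,
                       pair$forward_id, pair$reverse_id))
    }
    # merge rejected: the reverse (C-terminal) sequence is retained
    return(.cloneRow(pair$clone_name, m$status, r$seq, rp, FALSE,
                     pair$forward_id, pair$reverse_id,
                     note = "overlap-rejected"))
  }
  m <- overlapMerge(f$seq, r$seq, params)
  if (identical(m$status, "AD-TERM OVERLAPPED")) {
    prot <- translateDNA(m$merged, code, 0L, "+", is_orf_start = TRUE)
    return(.cloneRow(pair$clone_name, m$status, m$merged, prot, TRUE,
                     pair$forward_id, pair$reverse_id))
  }
  .cloneRow(pair$clone_name, m$status, r$seq, rp, FALSE,
            pair$forward_id, pair$reverse_id, note = "overlap-rejected")
}

#' Assemble all clone pairs of a screen
#'
#' @param pairing result of [pairReads()].
#' @param tag5,tag3,trim,params,code as in [assembleClone()]; forward reads
#'   discarded at pairing are carried through as `"AD DISCARDED"` records.
#' @return A [CloneAssembly-class] object.
#' @export
assembleClones <- function(pairing, tag5, tag3, trim = TrimParams(),
                           params = OverlapParams(), code = geneticCode()) {
  rows <- list()
  dropped <- data.frame(clone_name = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (pair in pairing$pairs) {
    row <- assembleClone(pair, tag5, tag3, trim, params, code)
    if (inherits(row, "droppedClone")) {
      dropped <- rbind(dropped, data.frame(
        clone_name = pair$clone_name, reason = row$reason,
        stringsAsFactors = FALSE))
    } else {
      rows[[length(rows) + 1L]] <- row
    }
  }
  disc <- pairing$discarded
  fwd_disc <- disc[disc$reason == "no-reverse-partner", , drop = FALSE]
  for (i in seq_len(nrow(fwd_disc))) {
    stem <- .idTokens(fwd_disc$id[i])$stem
    rows[[length(rows) + 1L]] <- .cloneRow(
      stem, "AD DISCARDED", NA_character_, NA_character_, FALSE,
      forward_id = fwd_disc$id[i], note = "no-reverse-partner")
  }
  clones <- if (length(rows)) do.call(rbind, rows) else
    .cloneRow(character(0), character(0), character(0), character(0),
              logical(0), character(0), character(0), character(0))
  new("CloneAssembly", clones = clones, dropped = dropped, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assembled clones of a screen
#'
#' Container for the per-clone assembly outcomes of a screen: one row per
#' clone with its status label, merged DNA and protein where applicable,
#' and read provenance. Clones whose reads were all excluded by trimming
#' are listed in `dropped` with the exclusion reason.
#'
#' @slot clones `DataFrame` with columns clone_name, status, dna, protein,
#'   mutation_eligible, forward_id, reverse_id, note.
#' @slot dropped data.frame of dropped clones and reasons.
#' @slot params the [OverlapParams-class] used.
#' @export
setClass("CloneAssembly", representation(
  clones = "DataFrame", dropped = "data.frame", params = "OverlapParams"))

setMethod("show", "CloneAssembly", function(object) {
  st <- table(object@clones$status)
  cat(sprintf("CloneAssembly: %d clones (%s), %d dropped\n",
              nrow(object@clones),
              paste(names(st), st, sep = ": ", collapse = ", "),
              nrow(object@dropped)))
})

#' @rdname CloneAssembly-class
#' @param x a `CloneAssembly`.
#' @return `clones()` returns the per-clone `DataFrame`; `cloneStatus()` a
#'   named character vector of status labels; `cloneProteins()` a named
#'   character vector of the translated proteins of clones that have one.
#' @export
clones <- function(x) x@clones

#' @rdname CloneAssembly-class
#' @export
cloneStatus <- function(x) {
  stats::setNames(x@clones$status, x@clones$clone_name)
}

#' @rdname CloneAssembly-class
#' @export
cloneProteins <- function(x) {
  sel <- !is.na(x@clones$protein) & nzchar(x@clones$protein)
  stats::setNames(x@clones$protein[sel], x@clones$clone_name[sel])
}

#' Write assembled clones to FASTA
#'
#' Record identifiers carry the status label (e.g.
#' `"clone1 AD-TERM OVERLAPPED"`), mirroring the renaming convention of
#' screening reports.
#'
#' @param x a [CloneAssembly-class].
#' @param path output FASTA path.
#' @param what `"protein"` (default) or `"dna"`.
#' @return `path`, invisibly.
#' @export
writeClones <- function(x, path, what = c("protein", "dna")) {
  what <- match.arg(what)
  df <- x@clones
  seqs <- df[[what]]
  sel <- !is.na(seqs) & nzchar(seqs)
  writeFasta(stats::setNames(seqs[sel],
                             paste(df$clone_name[sel], df$status[sel])), path)
}
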