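#' @include AllClasses.R
NULL

#' Read Sanger sequencing products from FASTA
#'
#' Reads one or several multi-record FASTA files of Sanger sequencing
#' products into a single ordered collection. Sequence lines are
#' concatenated, whitespace stripped and residues uppercased. Record order
#' is preserved, files are appended in the order given.
#'
#' @param paths character vector of FASTA file paths.
#' @return Named character vector of DNA sequences; names are the full
#'   record identifiers (text after `>`).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 AD", "acgt"), f)
#' readSangerReads(f)
#' @export
readSangerReads <- function(paths) {
  out <- character()
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    first <- which(nzchar(trimws(lines)))[1]
    if (!is.na(first) && !startsWith(trimws(lines[first]), ">"))
      stop("malformed FASTA in '", path, "': sequence before first header at line ",
           first)
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
    names(seqs) <- names(set)
    out <- c(out, seqs)
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become record identifiers).
#' @param path output file path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# last whitespace- or underscore-delimited token of an id, and the stem
.idTokens <- function(id) {
  toks <- strsplit(trimws(id), "[[:space:]_]+")[[1]]
  if (!length(toks)) toks <- ""
  list(last = toks[length(toks)],
       stem = paste(toks[-length(toks)], collapse = " "))
}

#' Derive read roles from identifier suffixes
#'
#' The sequencing primer name is carried as the last whitespace- or
#' underscore-delimited token of the record identifier: the forward
#' (N-terminal) product is conventionally labeled `AD`, the reverse
#' (C-terminal) product `TERM`. Matching is case-insensitive.
#'
#' @param ids character vector of record identifiers.
#' @param fwd_suffix,rev_suffix primer suffix tokens.
#' @return Character vector in `{"forward", "reverse", "unknown"}`.
#' @export
readRoles <- function(ids, fwd_suffix = "AD", rev_suffix = "TERM") {
  vapply(ids, function(id) {
    last <- toupper(.idTokens(id)$last)
    if (identical(last, toupper(fwd_suffix))) "forward"
    else if (identical(last, toupper(rev_suffix))) "reverse"
    else "unknown"
  }, character(1), USE.NAMES = FALSE)
}

#' Pair forward and reverse reads of each clone
#'
#' Reads sharing an identifier stem (the identifier minus the primer suffix
#' token) are paired. A reverse read without a forward partner is kept as a
#' one-sided pair (it will be labeled `TERM NON-OVERLAPPED` downstream); a
#' forward read without a reverse partner is routed to `discarded` and
#' excluded from translation and overlap. Reads whose suffix matches
#' neither primer are also discarded.
#'
#' @param reads named character vector from [readSangerReads()].
#' @param fwd_suffix,rev_suffix primer suffix tokens (non-empty, distinct).
#' @return List with `pairs` (list of lists with `clone_name`, `forward`,
#'   `reverse`, `forward_id`, `reverse_id`; absent reads are `NA`) and
#'   `discarded` (data.frame of `id`, `role`, `reason`).
#' @examples
#' reads <- c("c1 AD" = "ACGT", "c1 TERM" = "TTTT", "c2 TERM" = "AAAA")
#' pairReads(reads)
#' @export
pairReads <- function(reads, fwd_suffix = "AD", rev_suffix = "TERM") {
  stopifnot(nzchar(fwd_suffix), nzchar(rev_suffix))
  if (identical(toupper(fwd_suffix), toupper(rev_suffix)))
    stop("forward and reverse suffixes must be distinct")
  ids <- names(reads)
  roles <- readRoles(ids, fwd_suffix, rev_suffix)
  stems <- vapply(ids, function(id) .idTokens(id)$stem, character(1),
                  USE.NAMES = FALSE)
  for (role in c("forward", "reverse")) {
    sel <- roles == role
    dup <- stems[sel][duplicated(stems[sel])]
    if (length(dup))
      stop("duplicate ", role, " reads for clone(s): ",
           paste(unique(ids[sel][stems[sel] %in% dup]), collapse = "; "))
  }
  discarded <- data.frame(id = character(), role = character(),
                          reason = character(), stringsAsFactors = FALSE)
  unk <- roles == "unknown"
  if (any(unk))
    discarded <- rbind(discarded, data.frame(
      id = ids[unk], role = "unknown", reason = "unrecognized-suffix",
      stringsAsFactors = FALSE))
  pairs <- list()
  for (stem in unique(stems[!unk])) {
    fi <- which(stems == stem & roles == "forward")
    ri <- which(stems == stem & roles == "reverse")
    if (length(fi) && !length(ri)) {
      # forward read with no reverse partner: discarded as printed
      discarded <- rbind(discarded, data.frame(
        id = ids[fi], role = "forward", reason = "no-reverse-partner",
        stringsAsFactors = FALSE))
      next
    }
    pairs[[length(pairs) + 1L]] <- list(
      clone_name = stem,
      forward = if (length(fi)) unname(reads[[fi]]) else NA_character_,
      reverse = if (length(ri)) unname(reads[[ri]]) else NA_character_,
      forward_id = if (length(fi)) ids[fi] else NA_character_,
      reverse_id = if (length(ri)) ids[ri] else NA_character_)
  }
  list(pairs = pairs, discarded = discarded)
}

#' Load a reference model sequence
#'
#' Loads the single-record FASTA model against which RY2H clones are
#' aligned. With `kind = "auto"` the record is treated as protein when it
#' contains residues outside `A,C,G,T,N,U`. DNA models are translated in
#' forward frame 1 and a trailing stop is removed.
#'
#' @param path single-record FASTA file.
#' @param kind `"auto"`, `"dna"` or `"protein"`.
#' @param code [GeneticCode-class] used to translate DNA models.
#' @return A [ModelSeq-class] object.
#' @export
loadModel <- function(path, kind = c("auto", "dna", "protein"),
                      code = geneticCode()) {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L)
    stop("model file must contain exactly one record, found ", length(set))
  seq <- toupper(gsub("[[:space:]]", "", as.character(set[[1]])))
  if (!nzchar(seq)) stop("model sequence is empty")
  if (kind == "auto")
    kind <- if (grepl("[^ACGTNU]", seq)) "protein" else "dna"
  if (kind == "dna") {
    seq <- gsub("U", "T", seq, fixed = TRUE)
    prot <- translateDNA(seq, code = code, frame = 0L, strand = "+")
    prot <- sub("\\*$", "", prot)
    if (grepl("*", prot, fixed = TRUE))
      stop("model translation contains internal stop codons")
    new("ModelSeq", name = names(set)[1], kind = "dna", dna = seq,
        protein = prot)
  } else {
    new("ModelSeq", name = names(set)[1], kind = "protein",
        dna = NA_character_, protein = seq)
  }
}
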