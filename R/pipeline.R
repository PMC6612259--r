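#' @include seqio.R assemble.R modelmap.R identify.R
NULL

#' Screen analysis result
#'
#' End-to-end result of [runScreen()]: the assembled clones, the model
#' alignments and mutation summary in RY2H mode, the identification table
#' when a protein database was supplied, and conserved per-stage counts.
#'
#' @slot assembly the [CloneAssembly-class].
#' @slot mode `"Y2H"` or `"RY2H"`.
#' @slot alignments model-alignment table (RY2H) or `NULL`.
#' @slot summary a [MutationSummary-class] (RY2H) or `NULL`.
#' @slot hits identification table or `NULL`.
#' @slot counts named integer vector of stage counts.
#' @slot log character vector of per-read/per-clone exclusion messages.
#' @export
setClass("ScreenResult", representation(
  assembly = "CloneAssembly", mode = "character", alignments = "ANY",
  summary = "ANY", hits = "ANY", counts = "integer", log = "character"))

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult (%s mode)\n", object@mode))
  for (nm in names(object@counts))
    cat(sprintf("  %-22s %d\n", nm, object@counts[[nm]]))
})

#' @rdname ScreenResult-class
#' @param x a `ScreenResult`.
#' @return `screenCounts()` returns the named count vector;
#'   `mutationSummary()` the [MutationSummary-class] (or `NULL` in Y2H
#'   mode); `screenAssembly()` the [CloneAssembly-class].
#' @export
screenCounts <- function(x) x@counts

#' @rdname ScreenResult-class
#' @export
mutationSummary <- function(x) x@summary

#' @rdname ScreenResult-class
#' @export
screenAssembly <- function(x) x@assembly

#' Run the full screen analysis
#'
#' Executes the pipeline: quality trimming, vector trimming, translation,
#' assembly of paired forward/reverse products, and — when a model is
#' loaded (RY2H mode) — model alignment, gating and mutation summary; when
#' a protein database is supplied, local best-hit identification. Without a
#' model the run is a Y2H analysis (translation and identification only).
#'
#' @param reads named character vector of reads (as from
#'   [readSangerReads()] or [simulateScreen()]), or FASTA path(s).
#' @param tag5,tag3 [TagSpec-class] vector tags (default [defaultTags()]).
#' @param fwd_suffix,rev_suffix primer suffix tokens.
#' @param trim a [TrimParams-class].
#' @param overlap an [OverlapParams-class].
#' @param code a [GeneticCode-class].
#' @param model a [ModelSeq-class] to enable RY2H mode, or `NULL`.
#' @param db protein database ([loadProteinDb()]) for identification, or
#'   `NULL`.
#' @param min_score model score gate; default [defaultModelScore()].
#' @param sort sort identification output alphabetically by hit.
#' @param paired `TRUE` for paired forward/reverse assembly, `FALSE` for
#'   single-end analysis (each read is its own clone, no overlap stage);
#'   `NULL` (default) auto-detects from the presence of reverse-suffix
#'   identifiers.
#' @param find_orfs run the global reading-frame analysis ([findBestOrf()])
#'   on the trimmed single-end sequences and translate in the selected
#'   frame instead of frame 1 forward (single-end mode only); frame
#'   information is appended to the clone identifier.
#' @return A [ScreenResult-class] object.
#' @examples
#' sim <- simulateScreen(simConfig(randomModel(60), n_clones = 3,
#'                                 sub_rate = 0, overlap_nt = 60, seed = 1))
#' res <- runScreen(sim$reads, model = randomModel(60))
#' @export
runScreen <- function(reads, tag5 = defaultTags()$tag5,
                      tag3 = defaultTags()$tag3, fwd_suffix = "AD",
                      rev_suffix = "TERM", trim = TrimParams(),
                      overlap = OverlapParams(), code = geneticCode(),
                      model = NULL, db = NULL,
                      min_score = if (!is.null(model))
                        defaultModelScore(model) else NULL,
                      sort = FALSE, paired = NULL, find_orfs = FALSE) {
  if (is.character(reads) && is.null(names(reads)) && all(file.exists(reads)))
    reads <- readSangerReads(reads)
  if (!length(reads)) stop("no reads supplied")
  log <- character()
  n_loaded <- length(reads)
  if (is.null(paired))
    paired <- any(readRoles(names(reads), fwd_suffix, rev_suffix) == "reverse")

  if (!paired)
    return(.runSingleEnd(reads, tag5, trim, code, model, db, min_score,
                         sort, find_orfs))

  pairing <- pairReads(reads, fwd_suffix, rev_suffix)
  for (i in seq_len(nrow(pairing$discarded)))
    log <- c(log, sprintf("read '%s' excluded: %s", pairing$discarded$id[i],
                          pairing$discarded$reason[i]))
  assembly <- assembleClones(pairing, tag5, tag3, trim, overlap, code)
  for (i in seq_len(nrow(assembly@dropped)))
    log <- c(log, sprintf("clone '%s' dropped: %s",
                          assembly@dropped$clone_name[i],
                          assembly@dropped$reason[i]))

  st <- cloneStatus(assembly)
  counts <- c(n_loaded = n_loaded,
              n_pairs = length(pairing$pairs),
              n_reads_discarded_at_pairing = nrow(pairing$discarded),
              n_clones = nrow(clones(assembly)),
              n_overlapped = sum(st == "AD-TERM OVERLAPPED"),
              n_non_overlapped = sum(st == "TERM NON-OVERLAPPED"),
              n_ad_discarded = sum(st == "AD DISCARDED"),
              n_dropped = nrow(assembly@dropped))
  counts <- stats::setNames(as.integer(counts), names(counts))

  alignments <- NULL; summ <- NULL; hits <- NULL
  mode <- "Y2H"
  if (!is.null(model)) {
    mode <- "RY2H"
    mm <- mapToModel(assembly, model, min_score = min_score)
    alignments <- mm$alignments
    summ <- mm$summary
    counts <- c(counts,
                n_model_kept = as.integer(sum(alignments$kept)),
                n_mutation_eligible = as.integer(sum(alignments$kept &
                                                     alignments$equal_length)),
                n_mutations = as.integer(nrow(mutationCalls(summ))))
  }
  if (!is.null(db)) {
    hits <- identifyClones(assembly, db, sort = sort)
    counts <- c(counts, n_identified = as.integer(sum(hits$found)))
  }
  new("ScreenResult", assembly = assembly, mode = mode,
      alignments = alignments, summary = summ, hits = hits,
      counts = counts, log = log)
}

# single-end (classic Y2H) analysis: trim, translate, identify per read
.runSingleEnd <- function(reads, tag5, trim, code, model, db, min_score,
                          sort, find_orfs) {
  log <- character()
  ids <- names(reads)
  seqs <- character(); keep <- character()
  for (i in seq_along(reads)) {
    q <- qualityTrim(reads[[i]], trim)
    if (!nzchar(q)) { log <- c(log, sprintf("read '%s' excluded: quality",
                                            ids[i])); next }
    s <- if (!is.null(tag5)) trimToOrf(q, tag5, code) else q
    if (is.null(tag5)) s <- q
    if (is.na(s) || !nzchar(s)) {
      log <- c(log, sprintf("read '%s' excluded: no-vector-tag", ids[i]))
      next
    }
    seqs[ids[i]] <- s
  }
  frame <- 0L; strand <- "+"; orf_note <- ""
  if (find_orfs && length(seqs)) {
    orf <- findBestOrf(unname(seqs), code)
    frame <- orf$frame; strand <- orf$strand
    orf_note <- sprintf(" ORF(%s,%d)", strand, frame)
  }
  rows <- lapply(names(seqs), function(id) {
    prot <- translateDNA(seqs[[id]], code, frame, strand,
                         is_orf_start = !find_orfs && !is.null(tag5))
    .cloneRow(paste0(id, orf_note), "TRANSLATED", seqs[[id]], prot, FALSE,
              forward_id = id)
  })
  cl <- if (length(rows)) do.call(rbind, rows) else
    .cloneRow(character(0), character(0), character(0), character(0),
              logical(0), character(0), character(0), character(0))
  assembly <- new("CloneAssembly", clones = cl,
                  dropped = data.frame(clone_name = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE),
                  params = OverlapParams())
  counts <- c(n_loaded = length(reads), n_clones = nrow(cl),
              n_excluded = length(reads) - nrow(cl))
  counts <- stats::setNames(as.integer(counts), names(counts))
  alignments <- NULL; summ <- NULL; hits <- NULL; mode <- "Y2H"
  if (!is.null(model)) {
    mode <- "RY2H"
    mm <- mapToModel(assembly, model, min_score = min_score)
    alignments <- mm$alignments; summ <- mm$summary
    counts <- c(counts, n_model_kept = as.integer(sum(alignments$kept)),
                n_mutations = as.integer(nrow(mutationCalls(summ))))
  }
  if (!is.null(db)) {
    hits <- identifyClones(assembly, db, sort = sort)
    counts <- c(counts, n_identified = as.integer(sum(hits$found)))
  }
  new("ScreenResult", assembly = assembly, mode = mode,
      alignments = alignments, summary = summ, hits = hits,
      counts = counts, log = log)
}

#' Write all report files of a screen run
#'
#' Writes, into `dir`: the assembled clone FASTA files (protein, and DNA
#' where available) with status labels in the headers, the stage counts and
#' exclusion log, and in RY2H mode the per-clone mutation report TSV, the
#' aggregated summary TSV, the 50-residue block text report and the
#' per-position heatmap TSV; with a database, the identification TSV.
#' Re-running on identical inputs yields byte-identical files.
#'
#' @param result a [ScreenResult-class].
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
writeReports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(name) { f <- file.path(dir, name); files <<- c(files, f); f }
  tsv <- function(df, name)
    write.table(df, put(name), sep = "\t", quote = FALSE, row.names = FALSE)

  asm <- result@assembly
  if (any(!is.na(asm@clones$protein) & nzchar(asm@clones$protein)))
    writeClones(asm, put("clones_protein.fasta"), "protein")
  if (any(!is.na(asm@clones$dna) & nzchar(asm@clones$dna)))
    writeClones(asm, put("clones_dna.fasta"), "dna")
  writeLines(c(sprintf("%s\t%d", names(result@counts), result@counts),
               result@log), put("counts_and_log.txt"))
  if (!is.null(result@alignments))
    tsv(result@alignments, "model_alignments.tsv")
  if (!is.null(result@summary)) {
    tsv(mutationCalls(result@summary), "mutation_report.tsv")
    tsv(mutationTable(result@summary), "mutation_summary.tsv")
    tsv(heatmapTable(result@summary), "mutation_heatmap.tsv")
    writeLines(blockReport(result@summary), put("mutation_blocks.txt"))
  }
  if (!is.null(result@hits)) tsv(result@hits, "identification.tsv")
  invisible(files)
}
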