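#' @include align.R assemble.R
NULL

#' Default model-alignment score threshold
#'
#' Clones are kept when their BLOSUM62 local-alignment score against the
#' model reaches 5 x model length x 80%. Since the smallest BLOSUM62
#' diagonal entry is 4, a clone identical to the model always passes.
#'
#' @param model a [ModelSeq-class] or a model length in residues.
#' @return The default minimum score (`4 * length`).
#' @examples
#' defaultModelScore(100)  # 400
#' @export
defaultModelScore <- function(model) {
  L <- if (is(model, "ModelSeq")) modelLength(model) else as.numeric(model)
  5 * L * 0.80
}

#' Align a clone protein to the model
#'
#' Permissive BLOSUM62 local alignment of a translated clone against the
#' reference model. Clones scoring below `min_score` are rejected with
#' reason `"low-score"`. Non-overlapped C-terminal fragments are aligned
#' too (they can pass the score gate for long models only if close enough,
#' and never contribute mutations because of the length gate).
#'
#' @param protein translated clone protein (a trailing stop is ignored).
#' @param model a [ModelSeq-class].
#' @param min_score score threshold; default [defaultModelScore()].
#' @param scheme a [ScoringScheme-class] (default [modelScheme()]).
#' @param strict_gt keep only scores strictly greater than `min_score`
#'   (default `FALSE`: `>=`, so a minimal-diagonal self-alignment at the
#'   exact threshold passes).
#' @return List with `alignment` ([LocalAlignment-class]), `kept` (flag)
#'   and `reason` (`NA` or `"low-score"`).
#' @export
alignToModel <- function(protein, model, min_score = defaultModelScore(model),
                         scheme = modelScheme(), strict_gt = FALSE) {
  stopifnot(nzchar(protein))
  p <- sub("\\*$", "", protein)
  aln <- smithWaterman(p, modelProtein(model), scheme)
  kept <- if (strict_gt) alignmentScore(aln) > min_score
          else alignmentScore(aln) >= min_score
  list(alignment = aln, kept = kept,
       reason = if (kept) NA_character_ else "low-score")
}

#' Equal-length gate for mutation retrieval
#'
#' Clones shorter or longer than the model are excluded from mutation
#' retrieval (they remain in the alignment output): length differences
#' indicate frameshifts or premature termination, which would otherwise
#' flood the report with false positive substitutions. A trailing stop on
#' the clone protein is stripped before comparison.
#'
#' @param protein translated clone protein.
#' @param model a [ModelSeq-class].
#' @return `TRUE` when the lengths match.
#' @export
lengthGate <- function(protein, model) {
  nchar(sub("\\*$", "", protein)) == modelLength(model)
}

#' Call mutations of a clone against the model
#'
#' For a clone that passed the score and equal-length gates, the
#' correspondence to the model is positional (equal lengths, indels
#' rejected), so every position where the clone residue differs from the
#' model residue yields a mutation. X residues (ambiguous codons) are never
#' reported as mutations.
#'
#' @param protein clone protein of model length (trailing stop ignored).
#' @param model a [ModelSeq-class].
#' @param clone_name clone identifier for the report.
#' @return data.frame with columns clone, position (1-based on the model),
#'   model_aa, clone_aa; zero rows when the clone matches the model.
#' @export
callMutations <- function(protein, model, clone_name = "clone") {
  p <- sub("\\*$", "", protein)
  mp <- modelProtein(model)
  if (nchar(p) != nchar(mp))
    stop("internal consistency error: clone and model lengths differ (",
         nchar(p), " vs ", nchar(mp), "); apply lengthGate() first")
  pc <- .chars(p); mc <- .chars(mp)
  sel <- which(pc != mc & pc != "X")
  data.frame(clone = rep(clone_name, length(sel)), position = sel,
             model_aa = mc[sel], clone_aa = pc[sel],
             stringsAsFactors = FALSE)
}

#' Per-residue mutation summary of a screen
#'
#' Aggregated mutation counts across all accepted clones of a reverse
#' two-hybrid screen, by model position and mutation nature.
#'
#' @slot model the [ModelSeq-class] reference.
#' @slot calls data.frame of individual mutation records (clone, position,
#'   model_aa, clone_aa).
#' @slot table aggregated data.frame (position, model_aa, clone_aa, count).
#' @slot n_clones_analyzed,n_clones_rejected clone counts.
#' @export
setClass("MutationSummary", representation(
  model = "ModelSeq", calls = "data.frame", table = "data.frame",
  n_clones_analyzed = "integer", n_clones_rejected = "integer"))

setMethod("show", "MutationSummary", function(object) {
  cat(sprintf(paste0("MutationSummary: %d mutation calls at %d positions ",
                     "(%d clones analyzed, %d rejected)\n"),
              nrow(object@calls), length(unique(object@calls$position)),
              object@n_clones_analyzed, object@n_clones_rejected))
})

#' Summarize mutations across clones
#'
#' @param mutations data.frame of mutation records as produced by
#'   [callMutations()] (rows from several clones may be concatenated).
#' @param model a [ModelSeq-class].
#' @param n_clones_analyzed,n_clones_rejected clone counts for the report.
#' @return A [MutationSummary-class] object.
#' @export
summarizeMutations <- function(mutations, model, n_clones_analyzed = NA_integer_,
                               n_clones_rejected = NA_integer_) {
  if (is.null(mutations) || !nrow(mutations)) {
    tab <- data.frame(position = integer(), model_aa = character(),
                      clone_aa = character(), count = integer(),
                      stringsAsFactors = FALSE)
    mutations <- data.frame(clone = character(), position = integer(),
                            model_aa = character(), clone_aa = character(),
                            stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(count = mutations$position),
                            by = list(position = mutations$position,
                                      model_aa = mutations$model_aa,
                                      clone_aa = mutations$clone_aa),
                            FUN = length)
    tab <- agg[order(agg$position, agg$clone_aa), , drop = FALSE]
    rownames(tab) <- NULL
  }
  new("MutationSummary", model = model, calls = mutations, table = tab,
      n_clones_analyzed = as.integer(n_clones_analyzed),
      n_clones_rejected = as.integer(n_clones_rejected))
}

#' @rdname MutationSummary-class
#' @param x a `MutationSummary`.
#' @return `mutationTable()` returns the aggregated (position, model_aa,
#'   clone_aa, count) data.frame; `mutationCalls()` the per-clone records.
#' @export
mutationTable <- function(x) x@table

#' @rdname MutationSummary-class
#' @export
mutationCalls <- function(x) x@calls

#' Per-position total mutation counts (heatmap table)
#'
#' One row per model residue with the total number of mutations observed,
#' the tabular form of the color-coded mutation-distribution heatmap.
#'
#' @param x a [MutationSummary-class].
#' @return data.frame with columns position, model_aa, total_count, of
#'   model length.
#' @export
heatmapTable <- function(x) {
  L <- modelLength(x@model)
  counts <- integer(L)
  if (nrow(x@table)) {
    at <- tapply(x@table$count, x@table$position, sum)
    counts[as.integer(names(at))] <- as.integer(at)
  }
  data.frame(position = seq_len(L), model_aa = .chars(modelProtein(x@model)),
             total_count = counts, stringsAsFactors = FALSE)
}

#' Text block report of mutations along the model
#'
#' Renders the model sequence in blocks of `width` residues (headers
#' "1-50 aa", "51-100 aa", ...) with observed mutation natures stacked
#' above the reference residue at each position, followed by a per-block
#' list of `REF<pos>ALT xCOUNT` annotations.
#'
#' @param x a [MutationSummary-class].
#' @param width residues per block (default 50).
#' @return Character vector of report lines.
#' @export
blockReport <- function(x, width = 50L) {
  mp <- modelProtein(x@model)
  L <- nchar(mp)
  tab <- x@table
  lines <- character()
  for (start in seq(1L, L, by = width)) {
    end <- min(start + width - 1L, L)
    lines <- c(lines, sprintf("%d-%d aa", start, end))
    blk <- tab[tab$position >= start & tab$position <= end, , drop = FALSE]
    if (nrow(blk)) {
      depth <- max(table(blk$position))
      ann <- matrix(" ", nrow = depth, ncol = end - start + 1L)
      for (pos in unique(blk$position)) {
        alts <- blk$clone_aa[blk$position == pos]
        ann[seq_along(alts), pos - start + 1L] <- alts
      }
      for (r in rev(seq_len(depth)))
        lines <- c(lines, paste(ann[r, ], collapse = ""))
    }
    lines <- c(lines, substr(mp, start, end))
    if (nrow(blk))
      lines <- c(lines, paste(sprintf("%s%d%s x%d", blk$model_aa,
                                      blk$position, blk$clone_aa, blk$count),
                              collapse = "  "))
    lines <- c(lines, "")
  }
  lines
}

#' Plot the mutation-distribution heatmap
#'
#' Color-coded per-residue mutation counts along the model, left to right.
#'
#' @param x a [MutationSummary-class].
#' @param col color ramp (any monotone colormap).
#' @return Invisibly, the heatmap table.
#' @export
plotMutationHeatmap <- function(x, col = grDevices::hcl.colors(32, "YlOrRd",
                                                              rev = TRUE)) {
  ht <- heatmapTable(x)
  graphics::image(z = matrix(ht$total_count, ncol = 1), x = ht$position,
                  col = col, yaxt = "n", xlab = "model residue", ylab = "",
                  main = "mutation counts")
  invisible(ht)
}

#' Model alignment and mutation mapping for an assembled screen
#'
#' Aligns every translated clone (including non-overlapped C-terminal
#' fragments) to the model, applies the score gate, then the equal-length
#' gate for mutation retrieval, and aggregates the mutation summary.
#'
#' @param assembly a [CloneAssembly-class].
#' @param model a [ModelSeq-class].
#' @param min_score,scheme,strict_gt passed to [alignToModel()].
#' @return List with `alignments` (data.frame: clone, status, score, kept,
#'   reason, equal_length) and `summary` (a [MutationSummary-class]).
#' @export
mapToModel <- function(assembly, model, min_score = defaultModelScore(model),
                       scheme = modelScheme(), strict_gt = FALSE) {
  prots <- cloneProteins(assembly)
  df <- data.frame(clone = names(prots), score = NA_real_, kept = FALSE,
                   reason = NA_character_, equal_length = FALSE,
                   stringsAsFactors = FALSE)
  calls <- list()
  for (i in seq_along(prots)) {
    res <- alignToModel(prots[[i]], model, min_score, scheme, strict_gt)
    df$score[i] <- alignmentScore(res$alignment)
    df$kept[i] <- res$kept
    df$reason[i] <- res$reason
    if (!res$kept) next
    df$equal_length[i] <- lengthGate(prots[[i]], model)
    if (df$equal_length[i])
      calls[[length(calls) + 1L]] <- callMutations(prots[[i]], model,
                                                   names(prots)[i])
  }
  muts <- if (length(calls)) do.call(rbind, calls) else NULL
  summ <- summarizeMutations(muts, model,
                             n_clones_analyzed = sum(df$kept & df$equal_length),
                             n_clones_rejected = sum(!df$kept | !df$equal_length))
  list(alignments = df, summary = summ)
}
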