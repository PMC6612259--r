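#' @include align.R assemble.R
NULL

#' Load a protein database for clone identification
#'
#' @param path protein FASTA file.
#' @return Named character vector of protein sequences (names are the full
#'   record descriptions).
#' @export
loadProteinDb <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Best database hit for a clone protein
#'
#' Local best-hit search replacing a remote BLAST service: the query is
#' aligned (BLOSUM62, permissive regime) against every database record and
#' the top score wins, with ties broken by database order. Scores below the
#' floor report no hit.
#'
#' @param protein query protein.
#' @param db named character vector from [loadProteinDb()].
#' @param scheme a [ScoringScheme-class] (default [modelScheme()]).
#' @param floor minimum score for a hit; default `0.5 * 5 * query length`.
#' @return List with `subject_id` (first token of the description),
#'   `subject_desc`, `score` and `found`; subject fields are `NA` when
#'   `found` is `FALSE`.
#' @export
bestHit <- function(protein, db, scheme = modelScheme(),
                    floor = 0.5 * 5 * nchar(protein)) {
  if (!length(db)) stop("empty database")
  protein <- sub("\\*$", "", protein)
  scores <- vapply(db, function(s)
    alignmentScore(smithWaterman(protein, s, scheme)), numeric(1))
  i <- which.max(scores)
  if (scores[i] < floor)
    return(list(subject_id = NA_character_, subject_desc = NA_character_,
                score = unname(scores[i]), found = FALSE))
  desc <- names(db)[i]
  list(subject_id = strsplit(trimws(desc), "[[:space:]]+")[[1]][1],
       subject_desc = desc, score = unname(scores[i]), found = TRUE)
}

#' Identify all clones of a screen against a protein database
#'
#' Each translated clone is matched to its best database hit; the hit
#' description is appended to the clone identifier (or `"no hit"` when the
#' search stayed below the floor).
#'
#' @param assembly a [CloneAssembly-class] (or a named character vector of
#'   proteins).
#' @param db named character vector from [loadProteinDb()].
#' @param sort sort the result alphabetically by hit description
#'   ([sortHits()]); default `FALSE` preserves input order.
#' @param scheme,floor passed to [bestHit()]; `floor = NULL` (default) uses
#'   the per-query default.
#' @return data.frame with columns clone, subject_id, subject_desc, score,
#'   found, annotated_id.
#' @export
identifyClones <- function(assembly, db, sort = FALSE,
                           scheme = modelScheme(), floor = NULL) {
  prots <- if (is(assembly, "CloneAssembly")) cloneProteins(assembly)
           else assembly
  rows <- lapply(seq_along(prots), function(i) {
    h <- bestHit(prots[[i]], db, scheme,
                 floor = if (is.null(floor))
                   0.5 * 5 * nchar(sub("\\*$", "", prots[[i]])) else floor)
    data.frame(clone = names(prots)[i], subject_id = h$subject_id,
               subject_desc = h$subject_desc, score = h$score,
               found = h$found, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(clone = character(), subject_id = character(),
                     subject_desc = character(), score = numeric(),
                     found = logical(), stringsAsFactors = FALSE)
  df$annotated_id <- ifelse(df$found, paste(df$clone, df$subject_desc),
                            paste(df$clone, "no hit"))
  if (sort) sortHits(df) else df
}

#' Sort identified clones alphabetically by hit
#'
#' Stable alphabetical sort on the hit description so that clones hitting
#' the same subject are contiguous; clones without a hit sort last.
#'
#' @param hits data.frame from [identifyClones()].
#' @param enabled when `FALSE`, the input order is preserved.
#' @return The reordered data.frame.
#' @export
sortHits <- function(hits, enabled = TRUE) {
  if (!enabled || !nrow(hits)) return(hits)
  key <- ifelse(hits$found, hits$subject_desc, NA_character_)
  out <- hits[order(!hits$found, key, na.last = TRUE, method = "radix"), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}
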