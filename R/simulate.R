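#' @include AllClasses.R translate.R
NULL

# fixed injective back-translation map (one codon per residue)
.CODON_MAP <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
                "*" = "TAA")

#' Back-translate a protein with a fixed codon map
#'
#' @param protein protein string (20 standard residues, optionally `*`).
#' @return DNA string, 3 bases per residue.
#' @export
backTranslate <- function(protein) {
  codons <- .CODON_MAP[.chars(protein)]
  if (anyNA(codons)) stop("cannot back-translate residue(s): ",
                          paste(unique(.chars(protein)[is.na(codons)]),
                                collapse = ", "))
  paste(codons, collapse = "")
}

.AA20 <- .chars("ACDEFGHIKLMNPQRSTVWY")

#' Simulated-screen configuration
#'
#' Defines the conditions a synthetic reverse two-hybrid screen is drawn
#' under: a reference model, a library of randomly substituted full-length
#' clones, and Sanger-like forward/reverse sequencing products with vector
#' tags, optional leading Ns and base miscalls.
#'
#' @slot model the [ModelSeq-class] to mutate.
#' @slot n_clones number of full clone pairs.
#' @slot sub_rate per-residue substitution probability.
#' @slot read_len_nt read length used when `overlap_nt` is `NA`.
#' @slot overlap_nt designed forward/reverse overlap in bases (`NA` derives
#'   it from `read_len_nt`); must be >= 18 for reconstructable designs.
#' @slot tag5,tag3 [TagSpec-class] vector tags flanking the insert.
#' @slot n_prefix_max maximum leading Ns per read (0 or 1 at the default
#'   N-cutoff of 2).
#' @slot seq_error_rate per-base miscall probability.
#' @slot n_lone_fwd,n_lone_rev extra clones sequenced from one end only
#'   (unmatched forward / reverse products).
#' @slot seed RNG seed; the same seed yields byte-identical output.
#' @export
setClass("SimConfig", representation(
  model = "ModelSeq", n_clones = "integer", sub_rate = "numeric",
  read_len_nt = "integer", overlap_nt = "integer", tag5 = "TagSpec",
  tag3 = "TagSpec", n_prefix_max = "integer", seq_error_rate = "numeric",
  n_lone_fwd = "integer", n_lone_rev = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_clones < 0L) msg <- c(msg, "n_clones must be >= 0")
  if (object@sub_rate < 0 || object@sub_rate > 1)
    msg <- c(msg, "sub_rate must be in [0, 1]")
  if (object@seq_error_rate < 0 || object@seq_error_rate > 1)
    msg <- c(msg, "seq_error_rate must be in [0, 1]")
  if (object@n_prefix_max < 0L) msg <- c(msg, "n_prefix_max must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param model,n_clones,sub_rate,read_len_nt,overlap_nt,tag5,tag3
#'   see slots; `tag5`/`tag3` default to [defaultTags()].
#' @param n_prefix_max,seq_error_rate,n_lone_fwd,n_lone_rev,seed see slots.
#' @return A `SimConfig` object.
#' @rdname SimConfig-class
#' @export
simConfig <- function(model, n_clones = 90L, sub_rate = 0.01,
                      read_len_nt = 600L, overlap_nt = NA_integer_,
                      tag5 = defaultTags()$tag5, tag3 = defaultTags()$tag3,
                      n_prefix_max = 1L, seq_error_rate = 0,
                      n_lone_fwd = 0L, n_lone_rev = 0L, seed = 1L) {
  new("SimConfig", model = model, n_clones = as.integer(n_clones),
      sub_rate = sub_rate, read_len_nt = as.integer(read_len_nt),
      overlap_nt = as.integer(overlap_nt), tag5 = tag5, tag3 = tag3,
      n_prefix_max = as.integer(n_prefix_max),
      seq_error_rate = seq_error_rate, n_lone_fwd = as.integer(n_lone_fwd),
      n_lone_rev = as.integer(n_lone_rev), seed = as.integer(seed))
}

.randBases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Simulate a reverse two-hybrid sequencing screen
#'
#' For each clone, residues of the model protein are substituted at
#' `sub_rate` (never recreating the reference residue, never creating a
#' stop), the mutant is back-translated with a fixed codon map and embedded
#' in a vector construct (5' flank, 5' tag, linker of
#' `tag5@distance_to_orf` residues, ORF with stop, linker, 3' tag,
#' 3' flank). A forward read is cut from the 5' end and a reverse read
#' (reverse-complemented) from the 3' end with the designed overlap; reads
#' optionally receive a low-quality leader (junk bases and a leading N) and
#' per-base miscalls. Identifiers follow the `"cloneK AD"` / `"cloneK TERM"`
#' convention. Output is deterministic for a given seed.
#'
#' @param cfg a [SimConfig-class].
#' @return List with `reads` (named character, FASTA-ready) and `truth`:
#'   `substitutions` (data.frame clone, position, model_aa, new_aa for all
#'   clones), `aggregate` (data.frame position, model_aa, clone_aa, count
#'   over full pairs only — the expected mutation summary), `codon_map`,
#'   and `paired_clones` (clone names with both reads).
#' @export
simulateScreen <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  mp <- modelProtein(cfg@model)
  L <- nchar(mp)
  mpc <- .chars(mp)
  if (any(!mpc %in% .AA20))
    stop("model protein must use the 20 standard residues for simulation")

  tagDna <- function(tag) if (tag@alphabet == "protein")
    backTranslate(tag@sequence) else tag@sequence
  linker5 <- if (cfg@tag5@distance_to_orf > 0L)
    backTranslate(paste(sample(.AA20, cfg@tag5@distance_to_orf,
                               replace = TRUE), collapse = "")) else ""
  linker3 <- if (cfg@tag3@distance_to_orf > 0L)
    backTranslate(paste(sample(.AA20, cfg@tag3@distance_to_orf,
                               replace = TRUE), collapse = "")) else ""
  lead5 <- .randBases(30L)
  tail3 <- .randBases(30L)
  pre_orf <- paste0(lead5, tagDna(cfg@tag5), linker5)
  post_orf <- paste0(linker3, tagDna(cfg@tag3), tail3)
  Lc <- nchar(pre_orf) + 3L * (L + 1L) + nchar(post_orf)
  orf_start <- nchar(pre_orf) + 1L
  orf_end <- nchar(pre_orf) + 3L * (L + 1L)

  if (is.na(cfg@overlap_nt)) {
    rlf <- rlr <- min(cfg@read_len_nt, Lc)
    ov <- rlf + rlr - Lc
  } else {
    ov <- cfg@overlap_nt
    rlf <- (Lc + ov) %/% 2L
    rlr <- Lc + ov - rlf
  }
  if (ov < 1L)
    stop("infeasible geometry: reads do not overlap (designed overlap ", ov,
         " nt); increase read_len_nt or overlap_nt")
  if (rlf > Lc || rlr > Lc)
    stop("infeasible geometry: read length exceeds construct length ", Lc)
  if (rlf < orf_start + 3L || rlr < Lc - orf_end + 3L)
    stop("infeasible geometry: reads do not reach the ORF")

  mutateProtein <- function() {
    hit <- which(runif(L) < cfg@sub_rate)
    new <- vapply(hit, function(i)
      sample(setdiff(.AA20, mpc[i]), 1L), character(1))
    list(positions = hit, new_aa = new)
  }
  corrupt <- function(read) {
    if (cfg@seq_error_rate <= 0) return(read)
    rc <- .chars(read)
    hit <- which(runif(length(rc)) < cfg@seq_error_rate & rc != "N")
    for (i in hit) rc[i] <- sample(setdiff(c("A", "C", "G", "T"), rc[i]), 1L)
    paste(rc, collapse = "")
  }
  leader <- function() {
    k <- sample.int(cfg@n_prefix_max + 1L, 1L) - 1L
    if (k == 0L) "" else paste0(.randBases(sample(5:15, 1L)),
                                strrep("N", k))
  }

  n_total <- cfg@n_clones + cfg@n_lone_fwd + cfg@n_lone_rev
  reads <- character()
  subs <- list()
  paired <- character()
  for (k in seq_len(n_total)) {
    clone <- paste0("clone", k)
    mut <- mutateProtein()
    cp <- mpc
    cp[mut$positions] <- mut$new_aa
    construct <- paste0(pre_orf, backTranslate(paste(cp, collapse = "")),
                        "TAA", post_orf)
    if (length(mut$positions))
      subs[[length(subs) + 1L]] <- data.frame(
        clone = clone, position = mut$positions,
        model_aa = mpc[mut$positions], new_aa = mut$new_aa,
        stringsAsFactors = FALSE)
    want_fwd <- k <= cfg@n_clones ||
      (k > cfg@n_clones && k <= cfg@n_clones + cfg@n_lone_fwd)
    want_rev <- k <= cfg@n_clones || k > cfg@n_clones + cfg@n_lone_fwd
    if (want_fwd && want_rev) paired <- c(paired, clone)
    if (want_fwd)
      reads[paste(clone, "AD")] <-
        corrupt(paste0(leader(), substr(construct, 1L, rlf)))
    if (want_rev)
      reads[paste(clone, "TERM")] <-
        corrupt(paste0(leader(), revComp(substr(construct, Lc - rlr + 1L, Lc))))
  }
  substitutions <- if (length(subs)) do.call(rbind, subs) else
    data.frame(clone = character(), position = integer(),
               model_aa = character(), new_aa = character(),
               stringsAsFactors = FALSE)
  psubs <- substitutions[substitutions$clone %in% paired, , drop = FALSE]
  aggregate <- if (nrow(psubs)) {
    agg <- stats::aggregate(list(count = psubs$position),
                            by = list(position = psubs$position,
                                      model_aa = psubs$model_aa,
                                      clone_aa = psubs$new_aa), FUN = length)
    agg <- agg[order(agg$position, agg$clone_aa), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  } else data.frame(position = integer(), model_aa = character(),
                    clone_aa = character(), count = integer(),
                    stringsAsFactors = FALSE)
  list(reads = reads,
       truth = list(substitutions = substitutions, aggregate = aggregate,
                    codon_map = .CODON_MAP, paired_clones = paired,
                    designed_overlap_nt = ov))
}

#' Generate a random protein model for simulations
#'
#' Convenience generator of a synthetic reference: a random protein of the
#' requested length (M first) wrapped in a [ModelSeq-class] with its
#' back-translated DNA (stop codon appended), so a model of `n` residues
#' has a cDNA of `3 * (n + 1)` bases.
#'
#' @param n_aa protein length in residues.
#' @param name record name.
#' @return A [ModelSeq-class] of kind `"dna"`.
#' @export
randomModel <- function(n_aa = 298L, name = "synthetic-model") {
  prot <- paste(c("M", sample(.AA20, n_aa - 1L, replace = TRUE)),
                collapse = "")
  new("ModelSeq", name = name, kind = "dna",
      dna = paste0(backTranslate(prot), "TAA"), protein = prot)
}
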