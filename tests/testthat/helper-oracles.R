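# Independent oracles and fixture builders for the test suite.

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

AA20 <- chars("ACDEFGHIKLMNPQRSTVWY")
BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# The standard genetic code, frozen as the classic TCAG-order table.
oracle_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      b <- c("T", "C", "A", "G")
      aa <- chars(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"))
      codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4),
                       rep(b, 16))
      tab <<- stats::setNames(aa, codons)
    }
    tab
  }
})

# Brute-force ambiguity resolution: expand every IUPAC base of the codon
# and return the amino acid if all resolutions agree, else "X".
oracle_fuzzy_codon <- function(codon) {
  map <- Biostrings::IUPAC_CODE_MAP
  opts <- lapply(chars(codon), function(b) chars(map[[b]]))
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  aas <- unique(oracle_codon_table()[apply(grid, 1, paste, collapse = "")])
  if (length(aas) == 1L) aas else "X"
}

# Score-only affine-gap local alignment DP, written independently of the
# package's C++ engine (row-by-row vectors, max over all cells).
oracle_sw_score <- function(a, b, M, gap_open, gap_extend) {
  ca <- chars(a); cb <- chars(b)
  m <- length(ca); n <- length(cb)
  NEG <- -Inf
  prevH <- numeric(n + 1); prevF <- rep(NEG, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    H <- numeric(n + 1); E <- rep(NEG, n + 1); F <- rep(NEG, n + 1)
    for (j in seq_len(n)) {
      E[j + 1] <- max(H[j] + gap_open, E[j] + gap_extend)
      F[j + 1] <- max(prevH[j + 1] + gap_open, prevF[j + 1] + gap_extend)
      H[j + 1] <- max(0, prevH[j] + M[ca[i], cb[j]], E[j + 1], F[j + 1])
      best <- max(best, H[j + 1])
    }
    prevH <- H; prevF <- F
  }
  best
}

# Naive leftmost substring position (1-based), NA if absent.
oracle_substring <- function(seq, tag) {
  t <- nchar(tag)
  for (i in seq_len(max(nchar(seq) - t + 1L, 0L)))
    if (substr(seq, i, i + t - 1L) == tag) return(i)
  NA_integer_
}

# Naive leftmost Hamming match (1-based), NA if absent.
oracle_hamming_search <- function(seq, tag, max_mm) {
  tc <- chars(tag); t <- length(tc)
  for (i in seq_len(max(nchar(seq) - t + 1L, 0L)))
    if (sum(chars(substr(seq, i, i + t - 1L)) != tc) <= max_mm) return(i)
  NA_integer_
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# ModelSeq built directly from a protein (no RNG involved).
protein_model <- function(prot, name = "model") {
  methods::new("ModelSeq", name = name, kind = "protein",
               dna = NA_character_, protein = prot)
}
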