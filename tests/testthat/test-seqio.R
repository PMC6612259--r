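test_that("FASTA reading concatenates wrapped lines, uppercases and preserves order", {
  f <- write_fasta_lines(c(">c1 AD", "acgt", ">c2 TERM", "AAcc", "ggTT"))
  reads <- readSangerReads(f)
  expect_identical(names(reads), c("c1 AD", "c2 TERM"))
  expect_identical(unname(reads), c("ACGT", "AACCGGTT"))

  set.seed(11)
  long <- random_dna(180)
  f2 <- write_fasta_lines(c(">wrapped", substring(long, c(1, 61, 121),
                                                  c(60, 120, 180))))
  expect_identical(unname(readSangerReads(f2)), long)

  # multiple files are appended in order
  both <- readSangerReads(c(f, f2))
  expect_identical(names(both), c("c1 AD", "c2 TERM", "wrapped"))
})

test_that("malformed FASTA (sequence before first header) errors with the line", {
  f <- write_fasta_lines(c("ACGT", ">late"))
  expect_error(readSangerReads(f), "line 1")
})

test_that("write/read round-trip is the identity on ids and sequences", {
  set.seed(21)
  seqs <- stats::setNames(vapply(1:8, function(i) random_dna(5 + 37 * i),
                                 character(1)),
                          paste0("clone", 1:8, c(" AD", " TERM")))
  f <- tempfile(fileext = ".fasta")
  writeFasta(seqs, f)
  back <- readSangerReads(f)
  expect_identical(back, seqs)
  # wrapped at 60 columns
  expect_true(all(nchar(readLines(f)) <= 60))
})

test_that("pairing groups reads by stem and routes singletons as specified", {
  reads <- c("c1 AD" = "ACGT", "c1 TERM" = "TTTT",
             "c2 TERM" = "AAAA", "c3 AD" = "CCCC")
  p <- pairReads(reads)
  expect_length(p$pairs, 2L)
  expect_identical(p$pairs[[1]]$clone_name, "c1")
  expect_identical(p$pairs[[1]]$forward, "ACGT")
  expect_identical(p$pairs[[1]]$reverse, "TTTT")
  # lone reverse kept as one-sided pair
  expect_true(is.na(p$pairs[[2]]$forward))
  expect_identical(p$pairs[[2]]$reverse, "AAAA")
  # lone forward discarded
  expect_identical(p$discarded$id, "c3 AD")
  expect_identical(p$discarded$reason, "no-reverse-partner")
  # partition: every read in exactly one of pairs/discarded
  in_pairs <- unlist(lapply(p$pairs, function(x)
    c(x$forward_id, x$reverse_id)))
  accounted <- c(in_pairs[!is.na(in_pairs)], p$discarded$id)
  expect_setequal(accounted, names(reads))
  expect_length(accounted, length(reads))
})

test_that("suffix matching is case-insensitive on the last token, any delimiter", {
  reads <- c("x7_ad" = "ACGT", "x7_term" = "TTTT", "odd label" = "GGGG")
  p <- pairReads(reads)
  expect_length(p$pairs, 1L)
  expect_identical(p$pairs[[1]]$clone_name, "x7")
  expect_identical(p$discarded$reason, "unrecognized-suffix")
})

test_that("duplicate stems with the same role are an error naming the reads", {
  reads <- c("c1 AD" = "ACGT", "c1_AD" = "TTTT", "c1 TERM" = "AAAA")
  expect_error(pairReads(reads), "duplicate forward.*c1")
})

test_that("model loading infers kind, translates DNA models and gates input", {
  set.seed(31)
  prot <- paste0("M", random_protein(297))
  f <- write_fasta_lines(c(">nsp-like", paste0(backTranslate(prot), "TAA")))
  m <- loadModel(f)
  expect_identical(m@kind, "dna")
  expect_identical(nchar(m@dna), 897L)
  expect_identical(modelLength(m), 298L)   # trailing stop removed
  expect_identical(modelProtein(m), prot)

  fp <- write_fasta_lines(c(">prot", "MKV"))
  mp <- loadModel(fp)
  expect_identical(mp@kind, "protein")
  expect_identical(modelProtein(mp), "MKV")

  f2 <- write_fasta_lines(c(">a", "ACGT", ">b", "ACGT"))
  expect_error(loadModel(f2), "exactly one record")
  expect_error(loadModel(write_fasta_lines(c(">empty", ""))), "empty")
})
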