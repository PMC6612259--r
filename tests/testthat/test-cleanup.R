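test_that("quality trimming applies the first-N / second-N rule", {
  expect_identical(qualityTrim("ACGTACGT"), "ACGTACGT")
  expect_identical(qualityTrim("NACGTNAA"), "ACGT")
  expect_identical(qualityTrim("ACGNTTNAA"), "TT")
  expect_identical(qualityTrim("NN"), "")   # empty: read excluded (quality)
  # higher cutoff tolerates more Ns after the 5' trim
  expect_identical(qualityTrim("NACGTNAAANCC", TrimParams(3)), "ACGTNAAA")
})

test_that("quality-trimmed output never has boundary Ns and respects the cutoff", {
  set.seed(41)
  for (i in 1:50) {
    s <- chars(random_dna(40))
    s[sample(40, sample(0:6, 1))] <- "N"
    out <- qualityTrim(paste(s, collapse = ""))
    if (nzchar(out)) {
      expect_false(startsWith(out, "N"))
      expect_false(endsWith(out, "N"))
      expect_lte(sum(chars(out) == "N"), 1L)
      # on an N-free output a second application is the identity
      if (!grepl("N", out)) expect_identical(qualityTrim(out), out)
    }
  }
})

test_that("tag search is exact-first, then leftmost with mismatches", {
  expect_identical(findTag("AAATAGAAA", "TAG", 1), 4L)   # exact
  expect_identical(findTag("AAATGGAAA", "TAG", 1), 4L)   # one mismatch
  expect_true(is.na(findTag("CCCCCCC", "TAG", 1)))
  # an exact match beats an earlier mismatched window
  expect_identical(findTag("TGGAATAGAA", "TAG", 1),
                   oracle_substring("TGGAATAGAA", "TAG"))
})

test_that("findTag with max_mismatch = 0 equals naive substring search", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_dna(sample(10:40, 1))
    tag <- random_dna(sample(3:5, 1))
    expect_identical(findTag(s, tag, 0), oracle_substring(s, tag))
  }
})

test_that("findTag with mismatches equals the naive Hamming oracle when no exact hit", {
  set.seed(43)
  for (i in 1:100) {
    s <- random_dna(sample(12:40, 1))
    tag <- random_dna(5)
    if (!is.na(oracle_substring(s, tag))) next
    expect_identical(findTag(s, tag, 1), oracle_hamming_search(s, tag, 1))
  }
})

test_that("protein tags are located across all six frames", {
  dna <- backTranslate("STHASMKV")
  hit <- locateProteinTag(dna, "STHAS")
  expect_identical(hit[c("strand", "frame", "nt_start")],
                   list(strand = "+", frame = 0L, nt_start = 1L))
  # same coding sequence reverse-complemented: found on the minus strand,
  # with nt_start expressed on the reading (sense) strand
  rc <- revComp(dna)
  hit2 <- locateProteinTag(rc, "STHAS")
  expect_identical(hit2$strand, "-")
  expect_identical(substr(revComp(rc), hit2$nt_start, hit2$nt_start + 14L),
                   backTranslate("STHAS"))
  # offset frames
  hit3 <- locateProteinTag(paste0("GG", dna), "STHAS")
  expect_identical(hit3$frame, 2L)
  expect_identical(hit3$nt_start, 3L)
  expect_null(locateProteinTag(random_dna(60), "WWWWW", 0))
})

test_that("trimming to the ORF applies the tag-distance arithmetic", {
  set.seed(44)
  tag_dna <- backTranslate("STHAS")           # occupies bases 1-15
  orf <- backTranslate(paste0("M", random_protein(30)))
  linker <- backTranslate(random_protein(6))  # 18 nt between tag and ORF
  read <- paste0(tag_dna, linker, orf)
  tag5 <- TagSpec("STHAS", "protein", "five_prime", distance_to_orf = 6)
  out <- trimToOrf(read, tag5)
  expect_identical(out, substr(read, 34, nchar(read)))  # 15 + 18 + 1
  expect_identical(out, orf)

  # 3' tag at distance 0: retained sequence ends immediately before the tag
  read3 <- paste0(orf, "TAA", backTranslate("DPAFL"), "ACGTAC")
  tag3 <- TagSpec("DPAFL", "protein", "three_prime", distance_to_orf = 0)
  expect_identical(trimToOrf(read3, tag3), paste0(orf, "TAA"))

  # reverse sequencing product: orientation-corrected by the trim
  expect_identical(trimToOrf(revComp(read3), tag3), paste0(orf, "TAA"))

  # no tag at <= 1 mismatch: excluded
  expect_true(is.na(trimToOrf(random_dna(90), tag5)))
})
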