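test_that("reverse complement is IUPAC-aware and an involution", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("AAC"), "GTT")
  expect_identical(revComp("AACRN"), "NYGTT")
  expect_error(revComp("AJC"))
  set.seed(71)
  for (i in 1:20) {
    x <- random_dna(sample(1:50, 1))
    expect_identical(revComp(revComp(x)), x)
  }
})

test_that("error-free splits with sufficient overlap reconstruct the original", {
  set.seed(72)
  for (i in 1:30) {
    full <- random_protein(100)
    ov <- sample(6:30, 1)
    cut <- sample((ov + 5):90, 1)
    fwd <- substr(full, 1, cut)
    rev <- substr(full, cut - ov + 1, 100)
    m <- overlapMerge(fwd, rev)
    expect_identical(m$status, "AD-TERM OVERLAPPED")
    expect_identical(m$merged, full)
    # merged length = len(fwd) + len(rev) - overlap
    expect_identical(nchar(m$merged), nchar(fwd) + nchar(rev) - ov)
  }
})

test_that("overlaps below the defaults are rejected with the reverse retained", {
  set.seed(73)
  full <- random_protein(80)
  for (ov in c(4L, 5L)) {
    fwd <- substr(full, 1, 40)
    rev <- substr(full, 41 - ov, 80)
    m <- overlapMerge(fwd, rev)
    expect_identical(m$status, "TERM NON-OVERLAPPED")
    expect_true(is.na(m$merged))
  }
})

test_that("a 6-residue overlap with only 4 identities is rejected", {
  set.seed(74)
  pre <- random_protein(30)
  fwd <- paste0(pre, "KLMNPQ")
  rev <- paste0("KAMNPE", random_protein(30))  # 2 mismatches in the overlap
  m <- overlapMerge(fwd, rev)
  expect_identical(m$status, "TERM NON-OVERLAPPED")
})

test_that("clone assembly carries status labels and provenance", {
  set.seed(75)
  model <- protein_model(paste0("M", random_protein(59)))
  cfg <- simConfig(model, n_clones = 3, sub_rate = 0, overlap_nt = 60,
                   seq_error_rate = 0, seed = 9)
  sim <- simulateScreen(cfg)
  p <- pairReads(sim$reads)
  asm <- assembleClones(p, defaultTags()$tag5, defaultTags()$tag3)
  expect_identical(unname(cloneStatus(asm)),
                   rep("AD-TERM OVERLAPPED", 3))
  # error-free clones reproduce the simulated truth exactly
  expect_identical(unname(cloneProteins(asm)),
                   rep(paste0(modelProtein(model), "*"), 3))

  # pair with forward absent
  one <- assembleClone(list(clone_name = "c9", forward = NA_character_,
                            reverse = sim$reads[["clone1 TERM"]],
                            forward_id = NA_character_,
                            reverse_id = "clone1 TERM"),
                       defaultTags()$tag5, defaultTags()$tag3)
  expect_identical(one$status, "TERM NON-OVERLAPPED")
  expect_false(one$mutation_eligible)

  # pair with reverse absent: discarded, not translated
  two <- assembleClone(list(clone_name = "c10",
                            forward = sim$reads[["clone1 AD"]],
                            reverse = NA_character_,
                            forward_id = "clone1 AD",
                            reverse_id = NA_character_),
                       defaultTags()$tag5, defaultTags()$tag3)
  expect_identical(two$status, "AD DISCARDED")
  expect_true(is.na(two$protein))
})

test_that("clone counts are conserved through assembly", {
  set.seed(76)
  model <- protein_model(paste0("M", random_protein(59)))
  sim <- simulateScreen(simConfig(model, n_clones = 4, sub_rate = 0.02,
                                  overlap_nt = 60, seed = 10))
  reads <- sim$reads
  reads[["junkclone AD"]] <- "NN"   # forward dies at quality trimming
  reads[["junkclone TERM"]] <- "NN" # reverse dies too: clone dropped
  p <- pairReads(reads)
  asm <- assembleClones(p, defaultTags()$tag5, defaultTags()$tag3)
  expect_identical(length(p$pairs), nrow(clones(asm)) + nrow(asm@dropped))
  expect_identical(asm@dropped$clone_name, "junkclone")
  expect_match(asm@dropped$reason, "quality")
})

test_that("merged DNA stays consistent with the merged protein", {
  set.seed(77)
  model <- protein_model(paste0("M", random_protein(79)))
  sim <- simulateScreen(simConfig(model, n_clones = 2, sub_rate = 0.01,
                                  overlap_nt = 90, seed = 11))
  asm <- assembleClones(pairReads(sim$reads), defaultTags()$tag5,
                        defaultTags()$tag3)
  df <- clones(asm)
  for (i in seq_len(nrow(df)))
    expect_identical(translateDNA(df$dna[i], is_orf_start = TRUE),
                     df$protein[i])
})
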