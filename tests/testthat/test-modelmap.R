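test_that("the default score gate is 5 x model length x 80%", {
  expect_identical(defaultModelScore(100), 400)
  set.seed(81)
  m <- protein_model(random_protein(137))
  expect_identical(defaultModelScore(m), 5 * 137 * 0.8)
})

test_that("score gate keeps model-like clones and rejects unrelated peptides", {
  set.seed(82)
  model <- protein_model(random_protein(100))
  # a clone identical to the model always passes (min diagonal of BLOSUM62
  # is 4 = 0.8 * 5, so the self-score reaches the threshold)
  self <- alignToModel(modelProtein(model), model)
  expect_true(self$kept)
  # a random 10-aa peptide scores far below 400
  pep <- alignToModel(random_protein(10), model)
  expect_false(pep$kept)
  expect_identical(pep$reason, "low-score")
  # strict '>' mode is available
  W22 <- paste(rep("W", 22), collapse = "")
  exact <- alignToModel(W22, protein_model(W22),
                        min_score = 11 * 22, strict_gt = TRUE)
  expect_false(exact$kept)
  expect_true(alignToModel(W22, protein_model(W22), min_score = 11 * 22)$kept)
})

test_that("raising the score threshold never increases accepted clones", {
  set.seed(83)
  model <- protein_model(random_protein(60))
  mp <- chars(modelProtein(model))
  clones <- vapply(1:12, function(i) {
    p <- mp
    k <- sample(0:25, 1)
    idx <- sample(60, k)
    p[idx] <- vapply(idx, function(j) sample(setdiff(AA20, mp[j]), 1),
                     character(1))
    paste(p, collapse = "")
  }, character(1))
  thresholds <- c(100, 200, 240, 280, 300)
  kept <- vapply(thresholds, function(th)
    sum(vapply(clones, function(p) alignToModel(p, model, th)$kept,
               logical(1))), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("the equal-length gate drops frameshift/termination candidates", {
  set.seed(84)
  model <- protein_model(random_protein(298))
  expect_true(lengthGate(random_protein(298), model))
  expect_true(lengthGate(paste0(random_protein(298), "*"), model))
  expect_false(lengthGate(random_protein(297), model))
  expect_false(lengthGate(random_protein(299), model))
  # equal length containing X is accepted (handled at mutation calling)
  p <- chars(modelProtein(model)); p[5] <- "X"
  expect_true(lengthGate(paste(p, collapse = ""), model))
})

test_that("mutation calling is positional, skips X, and checks consistency", {
  model <- protein_model("MAAAGHKLVW")
  expect_identical(nrow(callMutations("MAAAGHKLVW", model)), 0L)
  one <- callMutations("MAAAGHKLVT", model, "c1")
  expect_identical(one$position, 10L)
  expect_identical(one$model_aa, "W")
  expect_identical(one$clone_aa, "T")
  # X at position 5 is ambiguity, never a mutation
  expect_identical(nrow(callMutations("MAAAXHKLVW", model)), 0L)
  # trailing stop is stripped before comparison
  expect_identical(nrow(callMutations("MAAAGHKLVW*", model)), 0L)
  expect_error(callMutations("MAAAG", model), "consistency")
})

test_that("summaries aggregate by position and nature; blocks place mutations", {
  set.seed(85)
  model <- protein_model(random_protein(100))
  mp <- chars(modelProtein(model))
  alt1 <- setdiff(AA20, mp[10])[1]
  alt2 <- setdiff(AA20, c(mp[10], alt1))[1]
  altR <- setdiff(AA20, mp[60])[1]
  calls <- data.frame(
    clone = c("c1", "c2", "c3", "c4"),
    position = c(10L, 10L, 10L, 60L),
    model_aa = mp[c(10, 10, 10, 60)],
    clone_aa = c(alt1, alt1, alt2, altR),
    stringsAsFactors = FALSE)
  s <- summarizeMutations(calls, model, 4L, 0L)
  tab <- mutationTable(s)
  expect_identical(tab$count[tab$position == 10 & tab$clone_aa == alt1], 2L)
  expect_identical(tab$count[tab$position == 10 & tab$clone_aa == alt2], 1L)
  expect_identical(sum(tab$count), nrow(calls))

  ht <- heatmapTable(s)
  expect_identical(nrow(ht), 100L)
  expect_identical(ht$total_count[10], 3L)
  expect_identical(ht$total_count[60], 1L)
  expect_identical(sum(ht$total_count), nrow(calls))

  blocks <- blockReport(s, width = 50)
  expect_identical(blocks[1], "1-50 aa")
  # the second block (51-100 aa) carries the position-60 annotation
  i2 <- which(blocks == "51-100 aa")
  expect_true(any(grepl(sprintf("%s60%s x1", mp[60], altR),
                        blocks[i2:length(blocks)], fixed = TRUE)))

  empty <- summarizeMutations(NULL, model, 0L, 0L)
  expect_identical(sum(heatmapTable(empty)$total_count), 0L)
})
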