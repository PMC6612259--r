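test_that("simulation is deterministic under a seed and honors n_clones = 0", {
  set.seed(101)
  model <- protein_model(paste0("M", random_protein(59)))
  cfg <- simConfig(model, n_clones = 4, sub_rate = 0.02, overlap_nt = 60,
                   seed = 5)
  a <- simulateScreen(cfg)
  b <- simulateScreen(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth$substitutions, b$truth$substitutions)

  empty <- simulateScreen(simConfig(model, n_clones = 0, overlap_nt = 60,
                                    seed = 5))
  expect_length(empty$reads, 0L)
  expect_identical(nrow(empty$truth$substitutions), 0L)
})

test_that("read identifiers and truth bookkeeping follow the conventions", {
  set.seed(102)
  model <- protein_model(paste0("M", random_protein(59)))
  sim <- simulateScreen(simConfig(model, n_clones = 2, n_lone_fwd = 1,
                                  n_lone_rev = 1, sub_rate = 0.05,
                                  overlap_nt = 60, seed = 6))
  expect_setequal(names(sim$reads),
                  c("clone1 AD", "clone1 TERM", "clone2 AD", "clone2 TERM",
                    "clone3 AD", "clone4 TERM"))
  expect_identical(sim$truth$paired_clones, c("clone1", "clone2"))
  # the aggregate covers full pairs only and equals the per-clone union
  psub <- sim$truth$substitutions[
    sim$truth$substitutions$clone %in% sim$truth$paired_clones, ]
  expect_identical(sum(sim$truth$aggregate$count), nrow(psub))
})

test_that("substitutions never recreate the reference and never create stops", {
  set.seed(103)
  model <- protein_model(paste0("M", random_protein(99)))
  mp <- chars(modelProtein(model))
  sim <- simulateScreen(simConfig(model, n_clones = 30, sub_rate = 0.05,
                                  overlap_nt = 90, seed = 7))
  subs <- sim$truth$substitutions
  expect_gt(nrow(subs), 0L)
  expect_true(all(subs$new_aa != subs$model_aa))
  expect_true(all(subs$new_aa != "*"))
  expect_identical(subs$model_aa, mp[subs$position])
})

test_that("an error-free screen recovers its ground truth exactly", {
  set.seed(104)
  model <- protein_model(paste0("M", random_protein(79)))
  for (rate in c(0, 0.005, 0.02)) {
    sim <- simulateScreen(simConfig(model, n_clones = 15, sub_rate = rate,
                                    overlap_nt = 90, seq_error_rate = 0,
                                    seed = 200 + round(1000 * rate)))
    res <- runScreen(sim$reads, model = model)
    expect_identical(unname(cloneStatus(screenAssembly(res))),
                     rep("AD-TERM OVERLAPPED", 15))
    expect_identical(mutationTable(mutationSummary(res)),
                     sim$truth$aggregate)
  }
})

test_that("a designed overlap below 18 bp leaves all clones non-overlapped", {
  set.seed(105)
  model <- protein_model(paste0("M", random_protein(59)))
  sim <- simulateScreen(simConfig(model, n_clones = 5, sub_rate = 0,
                                  overlap_nt = 9, seed = 8))
  res <- runScreen(sim$reads, model = model)
  expect_identical(unname(cloneStatus(screenAssembly(res))),
                   rep("TERM NON-OVERLAPPED", 5))
})

test_that("infeasible geometries error before generation", {
  set.seed(106)
  model <- protein_model(paste0("M", random_protein(59)))
  expect_error(simulateScreen(simConfig(model, n_clones = 2,
                                        overlap_nt = 0, seed = 1)),
               "infeasible")
  expect_error(simulateScreen(simConfig(model, n_clones = 2,
                                        read_len_nt = 60, overlap_nt = NA,
                                        seed = 1)),
               "infeasible")
})
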