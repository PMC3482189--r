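test_that("MP search recovers a perfectly compatible split system", {
  # four compatible binary characters defining ((A,B),(C,D),(E,F))
  X <- cbind(c(1, 1, 2, 2, 2, 2), c(2, 2, 1, 1, 2, 2),
             c(2, 2, 2, 2, 1, 1), c(1, 1, 1, 1, 2, 2))
  rownames(X) <- LETTERS[1:6]
  res <- search_trees(X, config = search_config("mp", n_starts = 5, seed = 3))
  expect_equal(res$score, 4)   # total length = number of characters
  truth <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  expect_equal(robinson_foulds(res$tree, truth), 0)
})

test_that("searches are deterministic given the seed", {
  withr::with_seed(31, {
    tr <- simulate_tree(6, seed = 55)
    sim <- simulate_alignment(tr, sim_spec(6, n_loop_sites = 30,
                                           n_stem_pairs = 30, seed = 55))
    sa <- recode_alignment(sim$alignment, sim$annotation)
  })
  cfg <- search_config("mp", n_starts = 3, seed = 99)
  r1 <- search_trees(sa, config = cfg)
  r2 <- search_trees(sa, config = cfg)
  expect_identical(ape::write.tree(r1$tree), ape::write.tree(r2$tree))
  expect_identical(r1$score, r2$score)

  m <- build_model("poisson", 20, frequencies = "empirical", data = sa)
  cfg_ml <- search_config("ml", n_starts = 1, seed = 7)
  e1 <- search_trees(sa, m, cfg_ml)
  e2 <- search_trees(sa, m, cfg_ml)
  expect_identical(ape::write.tree(e1$tree), ape::write.tree(e2$tree))
  expect_equal(e1$score, e2$score, tolerance = 1e-12)
})

test_that("search refuses fewer than four taxa", {
  X <- rbind(a = 1L, b = 2L, c = 1L)
  expect_error(search_trees(X, config = search_config("mp", seed = 1)),
               "at least 4")
})

test_that("bootstrap replicates are seeded, sized like the data, and reproducible", {
  withr::with_seed(32, {
    tr <- simulate_tree(6, seed = 8)
    sim <- simulate_alignment(tr, sim_spec(6, n_loop_sites = 20,
                                           n_stem_pairs = 20, seed = 8))
    sa <- recode_alignment(sim$alignment, sim$annotation)
  })
  cfg <- search_config("mp", n_starts = 2, seed = 5, bootstrap_replicates = 5)
  b1 <- bootstrap_trees(sa, config = cfg)
  b2 <- bootstrap_trees(sa, config = cfg)
  expect_length(b1, 5)
  expect_identical(vapply(b1, ape::write.tree, character(1)),
                   vapply(b2, ape::write.tree, character(1)))
  # replicate resampling plan: original site count, reproducible columns
  plan1 <- withr::with_seed(cfg$seed, lapply(1:5, function(b)
    sample.int(ncol(sa$codes), ncol(sa$codes), replace = TRUE)))
  plan2 <- withr::with_seed(cfg$seed, lapply(1:5, function(b)
    sample.int(ncol(sa$codes), ncol(sa$codes), replace = TRUE)))
  expect_identical(plan1, plan2)
  expect_true(all(lengths(plan1) == ncol(sa$codes)))
})

test_that("an overwhelming split is supported in nearly all bootstrap replicates", {
  # one long internal branch separating {A,B,C} from {D,E,F}
  tr <- ape::read.tree(
    text = "(((A:0.05,B:0.05):0.05,C:0.1):0.5,(D:0.1,(E:0.05,F:0.05):0.05):0.5);")
  X <- simulate_characters_matrix(tr, 16, 1, 400, seed = 21)
  cfg <- search_config("mp", n_starts = 2, seed = 13, bootstrap_replicates = 40)
  boots <- bootstrap_trees(X, config = cfg, k = 16)
  freq <- brute_split_freq(boots, c("D", "E", "F"))
  expect_gte(freq, 0.95)
  # and the annotated best tree carries that support
  best <- search_trees(X, config = cfg, k = 16)
  ann <- majority_consensus(boots, annotate_onto = best$tree)
  sup <- suppressWarnings(as.numeric(ann$node.label))
  expect_true(any(sup >= 95, na.rm = TRUE))
})

test_that("consensus handles unanimity, total conflict, and matches the split oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  cons <- majority_consensus(rep(list(t1), 10))
  expect_equal(robinson_foulds(cons, t1), 0)
  sup <- suppressWarnings(as.numeric(cons$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  star <- majority_consensus(list(t1, t2))
  expect_equal(star$Nnode, 1L)   # all internal edges conflict -> star

  expect_error(majority_consensus(list(t1, ape::read.tree(text = "((A,B),(C,F),E);"))),
               "taxon sets")

  # split frequencies against the brute-force monophyly oracle
  withr::with_seed(33, {
    trees <- lapply(1:7, function(i) {
      tr <- ape::rtree(6); tr$tip.label <- paste0("t", 1:6); ape::unroot(tr)
    })
  })
  ann <- majority_consensus(trees, annotate_onto = trees[[1]])
  keys <- strucphylo:::.split_keys(trees[[1]], "t1")
  ntip <- 6L
  for (i in seq_along(keys)) {
    members <- strsplit(keys[i], "|", fixed = TRUE)[[1]]
    if (length(members) < 2 || length(members) > 4) next
    lab <- ann$node.label[as.integer(names(keys)[i]) - ntip]
    # node labels are rounded to 0.1 percentage points
    expect_equal(as.numeric(lab) / 100, brute_split_freq(trees, members),
                 tolerance = 1e-3)
  }
})

test_that("support percentages always lie in [0, 100] and consensus keeps only majority splits", {
  withr::with_seed(34, {
    trees <- lapply(1:9, function(i) {
      tr <- ape::rtree(7); tr$tip.label <- paste0("t", 1:7); ape::unroot(tr)
    })
  })
  cons <- majority_consensus(trees)
  sup <- suppressWarnings(as.numeric(cons$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 50 & sup <= 100))
})
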