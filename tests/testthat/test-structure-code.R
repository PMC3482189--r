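test_that("dot-bracket parsing records nested pairs and flags imbalance", {
  pt <- parse_structure("((..))")
  expect_equal(pt$length, 6L)
  expect_equal(unname(pt$pairs), rbind(c(0L, 5L), c(1L, 4L)))

  expect_equal(nrow(parse_structure("....")$pairs), 0L)
  expect_error(parse_structure("((."), "unclosed")
  expect_error(parse_structure("))"), "unmatched")
  # crossing tiers
  pt2 <- parse_structure("([)]")
  expect_equal(unname(pt2$pairs), rbind(c(0L, 2L), c(1L, 3L)))
})

test_that("CT and bpseq parsing agree with dot-bracket and check reciprocity", {
  db <- parse_structure("((..))")
  ct <- parse_structure(c("6 toy",
                          "1 G 0 2 6 1", "2 C 1 3 5 2", "3 A 2 4 0 3",
                          "4 A 3 5 0 4", "5 G 4 6 2 5", "6 C 5 0 1 6"),
                        format = "ct")
  expect_equal(ct$pairs, db$pairs)
  bp <- parse_structure(c("1 G 6", "2 C 5", "3 A 0", "4 A 0", "5 G 2", "6 C 1"),
                        format = "bpseq")
  expect_equal(bp$pairs, db$pairs)
  expect_error(parse_structure(c("1 G 2", "2 C 3", "3 A 0"), format = "bpseq"),
               "not reciprocated")
})

test_that("pair table invariants are enforced", {
  expect_error(pair_table(4, rbind(c(0, 1), c(1, 3))), "more than one pair")
  expect_error(pair_table(4, rbind(c(0, 4))), "out of range")
  expect_error(pair_table(4, rbind(c(2, 2))), "pair with itself")
  # pairs are stored 5' first regardless of input order
  pt <- pair_table(4, rbind(c(3, 0)))
  expect_equal(unname(pt$pairs), rbind(c(0L, 3L)))
})

test_that("projection maps structure through the gapped reference row", {
  pt <- pair_table(4, rbind(c(0L, 3L)))
  ann <- project_to_alignment(pt, "A-CGU")
  expect_equal(ann$role, c("stem5", "uncovered", "loop", "loop", "stem3"))
  expect_equal(ann$partner, c(5L, NA, NA, NA, 1L))

  ann2 <- project_to_alignment(pair_table(2, NULL), "AC")
  expect_equal(ann2$role, c("loop", "loop"))

  ann3 <- project_to_alignment(pair_table(2, rbind(c(0L, 1L))), "A--U")
  expect_equal(ann3$role, c("stem5", "uncovered", "uncovered", "stem3"))

  expect_error(project_to_alignment(pt, "ACG"), "residues")
  expect_error(project_to_alignment(pt, ""), "empty")
})

test_that("projection involution: un-gapping the annotation recovers the pair table", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(10:30, 1)
      npairs <- sample(0:(n %/% 3), 1)
      pos <- sample(n) - 1L
      pairs <- if (npairs > 0)
        matrix(pos[seq_len(2 * npairs)], ncol = 2) else NULL
      pt <- pair_table(n, pairs)
      # random gapped row over the reference
      row <- character(0)
      i <- 0L
      while (i < n) {
        if (stats::runif(1) < 0.25) row <- c(row, "-")
        else { row <- c(row, sample(c("A", "C", "G", "U"), 1)); i <- i + 1L }
      }
      ann <- project_to_alignment(pt, paste(row, collapse = ""))
      back <- annotation_to_pair_table(ann)
      expect_equal(back$pairs, pt$pairs)
      expect_equal(back$length, pt$length)
      # partner is an involution
      stem <- which(!is.na(ann$partner))
      expect_equal(ann$partner[ann$partner[stem]], stem)
    }
  })
})

test_that("recoding emits unpaired and doublet symbols with missing-data rules", {
  # loop A -> 0; stem (G,C) -> 13; stem with gap -> missing
  ann <- project_to_alignment(pair_table(4, rbind(c(0L, 3L))), "GCAU")
  aln <- rbind(ref = c("G", "C", "A", "U"),
               x   = c("G", "A", "A", "-"),
               y   = c("-", "C", "N", "C"))
  sa <- recode_alignment(aln, ann)
  expect_equal(ncol(sa$codes), 3L)   # 1 pair + 2 loops
  expect_equal(sa$codes["ref", ], c(doublet_symbol("G", "U"),
                                    unpaired_symbol("C"), unpaired_symbol("A")))
  expect_equal(doublet_symbol("G", "C"), 13L)
  expect_true(is.na(sa$codes["x", 1L]))   # partner gap kills the doublet
  expect_true(is.na(sa$codes["y", 1L]))
  expect_true(is.na(sa$codes["y", 3L]))   # ambiguity code N -> missing
  expect_equal(unname(sa$codes["x", 3L]), 0L)

  expect_error(recode_alignment(rbind(a = c("A", "Z")),
                                project_to_alignment(pair_table(2, NULL), "AC")),
               "unknown residue")
})

test_that("site count and ordering invariants hold for random inputs", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      tr <- simulate_tree(5, seed = rep)
      sim <- simulate_alignment(tr, sim_spec(5, n_loop_sites = 11,
                                             n_stem_pairs = 7, seed = rep))
      sa <- recode_alignment(sim$alignment, sim$annotation)
      ann <- sim$annotation
      expect_equal(ncol(sa$codes),
                   sum(ann$role == "loop") + sum(ann$role == "uncovered") +
                     sum(ann$role == "stem5"))
      expect_false(is.unsorted(sa$site_map$col5))
      # closure: all non-missing symbols in 0..19
      expect_true(all(sa$codes[!is.na(sa$codes)] %in% 0:19))
      # determinism
      sa2 <- recode_alignment(sim$alignment, sim$annotation)
      expect_identical(sa, sa2)
    }
  })
})

test_that("drop_uncovered removes reference-gap columns from the coding", {
  ann <- project_to_alignment(pair_table(2, NULL), "A-C")
  aln <- rbind(r = c("A", "G", "C"), s = c("C", "U", "G"))
  expect_equal(ncol(recode_alignment(aln, ann)$codes), 3L)
  kept <- recode_alignment(aln, ann, drop_uncovered = TRUE)
  expect_equal(ncol(kept$codes), 2L)
  expect_equal(kept$site_map$role, c("loop", "loop"))
})

test_that("amino-acid aliasing is the fixed bijection and round-trips", {
  ab <- structure_alphabet()
  expect_equal(nrow(ab), 20L)
  expect_equal(sum(!ab$paired), 4L)
  expect_equal(sum(ab$paired), 16L)
  expect_setequal(ab$aa, c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  expect_equal(ab$aa[ab$index == 0], "A")
  expect_equal(ab$aa[ab$index == 3], "T")     # unpaired U
  expect_equal(ab$aa[ab$symbol == "GC"], "P")
  expect_equal(ab$aa[ab$index == 19], "Y")    # doublet UU

  codes <- matrix(c(0:19, rep(NA, 4)), nrow = 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
  sa <- structure_alignment(codes)
  seqs <- to_protein_letters(sa)
  expect_equal(substr(seqs[["a"]], 1, 4), "ACGT")
  back <- from_protein_letters(seqs)
  expect_equal(back$codes, sa$codes)
})

test_that("alignment IO round-trips through FASTA and relaxed PHYLIP", {
  seqs <- c(Saccharomyces_cerevisiae = "ACGU-ACGU",
            Neolecta_vitellina = "ACGGNAC-U")
  for (fmt in c("fasta", "phylip")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_alignment(seqs, f, fmt)
    m <- read_alignment(f)
    expect_equal(rownames(m), names(seqs))
    expect_equal(apply(m, 1, paste, collapse = ""), seqs)
  }
})

test_that("site map TSV is written with source columns", {
  ann <- project_to_alignment(pair_table(4, rbind(c(0L, 3L))), "GCAU")
  sa <- recode_alignment(rbind(a = c("G", "C", "A", "U")), ann)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_map(sa, f)
  tab <- read.delim(f)
  expect_equal(tab$role, c("stem", "loop", "loop"))
  expect_equal(tab$col5, c(1L, 2L, 3L))
  expect_equal(tab$col3, c(4L, NA, NA))
})
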