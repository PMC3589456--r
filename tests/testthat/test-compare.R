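records_with_folds <- function(folds, labels = NULL) {
  n <- length(folds)
  data.frame(kmer = if (is.null(labels)) all_words(5)[seq_len(n)] else labels,
             observed = 1, expected_1 = 1, expected_2 = 1, expected_mean = 1,
             fold_1 = folds, fold_2 = folds, fold = folds, zscore = 0,
             pvalue = 0.5, significant = FALSE, defined = TRUE)
}

test_that("equal-width bins use the boundary rule [lo, hi) with closed top", {
  rec <- records_with_folds(0:8)
  bp <- make_bins(rec, 8)
  expect_equal(diff(bp$edges), rep(1, 8), tolerance = 1e-9)
  sizes <- vapply(bp$members, length, integer(1))
  # folds 0..6 land in bins 1..7; fold 7 starts bin 8, fold 8 hits the
  # closed right edge of bin 8
  expect_equal(sizes, c(rep(1L, 7), 2L))
  expect_equal(bp$members[[8]], c(rec$kmer[8], rec$kmer[9]))
})

test_that("degenerate fold ranges collapse into the first bin", {
  rec <- records_with_folds(rep(2.5, 6))
  bp <- make_bins(rec, 8)
  expect_equal(length(bp$members[[1]]), 6L)
  expect_equal(sum(vapply(bp$members, length, integer(1))), 6L)
})

test_that("bin membership conserves the defined record count", {
  ss <- sequence_set(c(s = random_dna(4000, seed = 55)), label = "x")
  r <- enrich(ss, 4, background_spec("ak1"))
  bp <- make_bins(r, 8)
  expect_equal(sum(vapply(bp$members, length, integer(1))),
               sum(r$defined))
  expect_error(make_bins(r[0, ], 8), "empty")
})

test_that("overlap profiles hit their 100%/0% limits", {
  rec <- records_with_folds(c(0, 1, 2, 3, 4, 5, 6, 7, 8))
  ref <- make_bins(rec, 8, source_label = "ref")
  copy <- make_bins(rec, 8, source_label = "copy")
  pr <- overlap_profile(ref, copy)
  expect_true(all(pr$per_bin$percent[pr$per_bin$ref_count > 0] == 100))
  disj <- make_bins(records_with_folds(0:8, labels = all_words(5)[30:38]), 8,
                    source_label = "disj")
  pr0 <- overlap_profile(ref, disj)
  expect_true(all(pr0$per_bin$percent[pr0$per_bin$ref_count > 0] == 0))
})

test_that("per-bin percentages follow the hand-computed intersection", {
  ref <- list(n_bins = 1L, edges = c(0, 1),
              members = list(c("w1", "w2", "w3", "w4")),
              source_label = "ref")
  class(ref) <- "BinPartition"
  oth <- ref
  oth$members <- list(c("w2", "w4", "w9"))
  oth$source_label <- "oth"
  class(oth) <- "BinPartition"
  pr <- overlap_profile(ref, oth)
  expect_equal(pr$per_bin$percent, 50.0)
  expect_equal(pr$per_bin$shared_count, 2L)
})

test_that("empty reference bins report missing, not zero", {
  rec <- records_with_folds(c(0, 8))   # middle bins empty
  ref <- make_bins(rec, 8, source_label = "ref")
  pr <- overlap_profile(ref, ref)
  expect_true(all(is.na(pr$per_bin$percent[pr$per_bin$ref_count == 0])))
  expect_false(anyNA(pr$per_bin$percent[pr$per_bin$ref_count > 0]))
})

test_that("adding a species to a combination never raises a percentage", {
  sp <- synthetic_species(3, 20000, gc = 0.4, mutation_rate = 0.05,
                          seed = 303)
  profiles <- run_comparison(sp, 4, background_spec("ak1"),
                             reference_label = "species_1")
  expect_equal(length(profiles), 3L)  # 2 singles + 1 pair
  pair <- profiles[["species_2+species_3"]]$per_bin$percent
  for (single in c("species_2", "species_3")) {
    s <- profiles[[single]]$per_bin$percent
    ok <- !is.na(pair) & !is.na(s)
    expect_true(all(pair[ok] <= s[ok] + 1e-9))
  }
  all_pct <- unlist(lapply(profiles, function(p) p$per_bin$percent))
  expect_true(all(is.na(all_pct) | (all_pct >= 0 & all_pct <= 100)))
})

test_that("four species yield seven combinations in deterministic order", {
  sp <- synthetic_species(4, 6000, gc = 0.4, mutation_rate = 0.02, seed = 99)
  profiles <- run_comparison(sp, 3, background_spec("ak1"),
                             reference_label = "species_1")
  expect_equal(names(profiles),
               c("species_2", "species_3", "species_4",
                 "species_2+species_3", "species_2+species_4",
                 "species_3+species_4", "species_2+species_3+species_4"))
})

test_that("identical genomes give full overlap in every occupied bin", {
  g <- random_sequences(1, 8000, gc = 0.4, seed = 77, label = "g1")
  g2 <- g
  g2$label <- "g2"
  profiles <- run_comparison(list(g, g2), 4, background_spec("ak1"),
                             reference_label = "g1")
  pct <- profiles[["g2"]]$per_bin
  expect_true(all(pct$percent[pct$ref_count > 0] == 100))
})

test_that("a shared ancestor raises top-bin overlap above independence", {
  related <- synthetic_species(2, 30000, gc = 0.4, mutation_rate = 0.01,
                               seed = 11)
  indep <- list(random_sequences(1, 30000, gc = 0.4, seed = 12,
                                 label = "species_1"),
                random_sequences(1, 30000, gc = 0.4, seed = 13,
                                 label = "species_2"))
  top_overlap <- function(species) {
    pr <- run_comparison(species, 5, background_spec("ak1"),
                         reference_label = "species_1")[["species_2"]]
    pb <- pr$per_bin
    occupied <- which(pb$ref_count > 0)
    pb$percent[max(occupied)]
  }
  expect_gt(top_overlap(related), top_overlap(indep))
})

test_that("profiles are invariant under reordering of non-reference species", {
  sp <- synthetic_species(3, 10000, gc = 0.4, mutation_rate = 0.03,
                          seed = 21)
  a <- run_comparison(sp, 4, background_spec("ak1"), "species_1")
  b <- run_comparison(sp[c(1, 3, 2)], 4, background_spec("ak1"), "species_1")
  expect_equal(a[["species_2+species_3"]]$per_bin,
               b[["species_2+species_3"]]$per_bin)
})
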