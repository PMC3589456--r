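test_that("background specs validate their parameter combinations", {
  expect_s3_class(background_spec("ak1"), "BackgroundSpec")
  expect_error(background_spec("markov"), "markov_order")
  expect_error(background_spec("ak1", markov_order = 2), "only to the Markov")
  expect_error(background_spec("c0c1", rank_statistic = "binomial"),
               "binomial")
  expect_equal(background_spec("markov", 3)$rank_statistic, "zscore")
})

test_that("Ak-1 homopolymer input reproduces the closed-form limit", {
  h <- sequence_set(c(s = "AAAAAA"), label = "homo")
  t3 <- build_count_table(h, 3, "forward_only")
  t2 <- build_count_table(h, 2, "forward_only")
  mono <- mono_frequencies(h, "forward_only")
  e <- ak1_expected("AAA", t3, t2, mono)
  expect_equal(e$E1, 2)  # C1 = C2 = 3, N = 3, M = 2, p(A) = 1
  expect_equal(e$E2, 2)
  rec <- ak1_score("AAA", t3, t2, mono)
  expect_equal(rec$fold, 1)
  expect_equal(rec$zscore, 0)
  expect_equal(rec$pvalue, 0.5)
  expect_true(rec$defined)
})

test_that("Ak-1 expectation is zero for an unobserved subword", {
  ss <- sequence_set(c(s = "ACGTACGTACGT"), label = "x")
  t3 <- build_count_table(ss, 3, "forward_only")
  t2 <- build_count_table(ss, 2, "forward_only")
  mono <- mono_frequencies(ss, "forward_only")
  e <- ak1_expected("AAA", t3, t2, mono)  # prefix AA never occurs
  expect_equal(e$E1, 0)
  rec <- ak1_score("AAA", t3, t2, mono)
  expect_false(rec$defined)
  expect_true(is.na(rec$fold))
})

test_that("Ak-1 fold is near 1 for fixed words in a long iid sequence", {
  ss <- iid_megabase()
  t4 <- build_count_table(ss, 4)
  t3 <- build_count_table(ss, 3)
  mono <- mono_frequencies(ss)
  rec <- ak1_score(c("ACGT", "TTAG", "GGCC", "CATA"), t4, t3, mono)
  expect_true(all(rec$observed / rec$expected_mean > 0.8))
  expect_true(all(rec$observed / rec$expected_mean < 1.2))
})

test_that("Z-score is zero at O == E-bar and increases with O at fixed E-bar", {
  # direct check on the record arithmetic via a small constructed table
  h <- sequence_set(c(s = "AAAAAA"), label = "homo")
  t3 <- build_count_table(h, 3, "forward_only")
  t2 <- build_count_table(h, 2, "forward_only")
  mono <- mono_frequencies(h, "forward_only")
  rec <- ak1_score("AAA", t3, t2, mono)
  expect_equal(rec$zscore, 0)
  z <- function(o, ebar) (o - ebar) / sqrt(ebar)
  expect_true(all(diff(z(1:10, 3)) > 0))
})

test_that("C0/C1 degenerates when every neighbor is unobserved", {
  ss <- sequence_set(c(s = strrep("ACGT", 25)), label = "rep")
  t4 <- build_count_table(ss, 4, "forward_only")
  rec <- c0c1_score("ACGT", t4)
  expect_false(rec$defined)
  expect_true(is.na(rec$fold))
  expect_equal(rec$observed, 25)
  # with a pseudocount the record becomes defined
  rec2 <- c0c1_score("ACGT", t4, pseudocount = 1)
  expect_true(rec2$defined)
})

test_that("C0/C1 neighborhood has exactly 3k distinct words excluding self", {
  nb <- akmer:::.mismatch_neighbors("ATGCCGTA")
  expect_equal(ncol(nb), 24L)
  expect_equal(length(unique(as.vector(nb))), 24L)
  expect_false("ATGCCGTA" %in% nb)
  expect_true(all(nchar(nb) == 8L))
})

test_that("C0/C1 fold is near 1 for fixed words in a long iid sequence", {
  ss <- iid_megabase()
  t4 <- build_count_table(ss, 4)
  rec <- c0c1_score(c("ACGT", "TTAG", "GGCC", "CATA"), t4)
  expect_true(all(rec$fold > 0.8 & rec$fold < 1.2))
  expect_equal(rec$expected_1, rec$expected_2)
  expect_equal(rec$fold_1, rec$fold_2)
})

test_that("order-0 Markov expectation equals the composition product", {
  ss <- sequence_set(c(s = strrep("ACGT", 30)), label = "rep")
  t4 <- build_count_table(ss, 4, "forward_only")
  mono <- mono_frequencies(ss, "forward_only")
  e <- markov_expected("ACGT", ss, 0, strand_policy = "forward_only")
  expect_equal(e, t4$total_occurrences * prod(mono[c("A", "C", "G", "T")]))
})

test_that("order-0 expectations over all 2-mers sum to the 2-mer total", {
  ss <- sequence_set(c(s = random_dna(3000, seed = 31)), label = "iid")
  t2 <- build_count_table(ss, 2)
  e <- markov_expected(all_words(2), ss, 0)
  expect_equal(sum(e), t2$total_occurrences, tolerance = 1e-9)
})

test_that("maximal-order Markov on a homopolymer recovers the observed count", {
  ss <- sequence_set(c(s = "AAAAAA"), label = "homo")
  e <- markov_expected("AAA", ss, 1, strand_policy = "forward_only")
  t3 <- build_count_table(ss, 3, "forward_only")
  expect_equal(e, unname(kmer_count(t3, "AAA")))
})

test_that("Markov order bounds are enforced", {
  ss <- sequence_set(c(s = random_dna(500, seed = 3)), label = "x")
  expect_error(markov_expected("ACGTACGT", ss, 7), "order too high")
  expect_error(markov_score("ACGTACGT", ss, 9), "order too high")
})

test_that("Markov Z and binomial p-values behave at their fixed points", {
  # O == E at the self-consistent maximal order: Z is 0 (up to NA from the
  # degenerate variance) and the certain binomial event has p-value 1
  ss <- sequence_set(c(s = "AAAAAA"), label = "homo")
  rec <- markov_score("AAA", ss, 1, rank_statistic = "binomial",
                      strand_policy = "forward_only")
  expect_equal(rec$observed, rec$expected_1)
  expect_equal(rec$pvalue, 1)  # O = M, E/M = 1: P(X >= O) is certain
  # Z at O == E with non-degenerate variance
  ss2 <- sequence_set(c(s = random_dna(2000, seed = 8)), label = "x")
  rec2 <- markov_score(all_words(3), ss2, 1)
  near <- abs(rec2$observed - rec2$expected_1) < 1e-9
  if (any(near)) expect_true(all(abs(rec2$zscore[near]) < 1e-9))
})

test_that("binomial upper tail agrees with direct mass summation", {
  direct_upper <- function(o, m, p)
    sum(vapply(o:m, function(x) choose(m, x) * p^x * (1 - p)^(m - x),
               numeric(1)))
  for (case in list(c(10, 0.1, 3), c(20, 0.25, 8), c(15, 0.5, 15),
                    c(12, 0.05, 0))) {
    m <- case[1]; p <- case[2]; o <- case[3]
    expect_equal(pbinom(o - 1, m, p, lower.tail = FALSE),
                 direct_upper(o, m, p), tolerance = 1e-12)
  }
})

test_that("scores are invariant under reverse-complementing the input", {
  x <- vapply(1:3, function(i) random_dna(400, seed = 60 + i), character(1))
  names(x) <- paste0("r", 1:3)
  ss <- sequence_set(x, label = "fwd")
  rc <- sequence_set(setNames(reverse_complement(x), names(x)), label = "fwd")
  for (spec in list(background_spec("ak1"), background_spec("c0c1"),
                    background_spec("markov", 1))) {
    a <- enrich(ss, 4, spec)
    b <- enrich(rc, 4, spec)
    expect_equal(a, b)
  }
})

test_that("ranked lists order by the statistic with deterministic ties", {
  ss <- sequence_set(c(s = random_dna(2000, seed = 21)), label = "x")
  r <- enrich(ss, 3, background_spec("ak1"))
  expect_s3_class(r, "RankedList")
  expect_equal(r$rank, seq_len(nrow(r)))
  def <- r[r$defined, ]
  expect_true(all(diff(def$fold) <= 1e-12))
  r2 <- enrich(ss, 3, background_spec("ak1"))
  expect_identical(r, r2)
})
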