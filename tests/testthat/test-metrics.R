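# Evaluation metrics: slip rule, pooling, inserted-domain accuracy, t-test.

test_that("the slip rule accepts exactly the five pairing variants", {
  known <- cbind(2L, 10L)
  expect_true(pair_matches(c(2, 10), known))             # exact
  expect_true(pair_matches(c(3, 10), known))             # (i+1)-j
  expect_true(pair_matches(c(1, 10), known))             # (i-1)-j
  expect_true(pair_matches(c(2, 9), known))              # i-(j-1)
  expect_true(pair_matches(c(2, 11), known))             # i-(j+1)
  expect_false(pair_matches(c(3, 9), known))             # double slip
  expect_false(pair_matches(c(2, 9), known, strict = TRUE))
  expect_true(pair_matches(c(2, 10), known, strict = TRUE))
})

test_that("per-pair scoring pools the two sequences and handles 0/0", {
  k1 <- cbind(c(1L, 2L), c(10L, 9L)); k2 <- k1
  r <- score_pair(k1, k2, k1, k2, strict = TRUE)
  expect_identical(r$sensitivity, 1); expect_identical(r$ppv, 1)
  none <- k1[integer(0), , drop = FALSE]
  r2 <- score_pair(none, none, k1, k2, strict = TRUE)
  expect_identical(r2$sensitivity, 0)
  expect_true(is.na(r2$ppv))
  p1 <- cbind(c(1L, 3L), c(10L, 8L))
  r3 <- score_pair(p1, none, k1, none, strict = TRUE)
  expect_identical(r3$sensitivity, 0.5)
  expect_identical(r3$ppv, 0.5)
})

test_that("family pooling is a ratio of summed counts, order-invariant", {
  reps <- list(list(correct_known = 1, correct_pred = 1, n_known = 2, n_pred = 2),
               list(correct_known = 3, correct_pred = 3, n_known = 3, n_pred = 3))
  expect_identical(pool_family(reps)$sensitivity, 4 / 5)
  expect_identical(pool_family(rev(reps))$sensitivity, 4 / 5)
  perfect <- list(list(correct_known = 5, correct_pred = 5, n_known = 5, n_pred = 5))
  expect_identical(pool_family(perfect)$sensitivity, 1)
  expect_identical(pool_family(perfect)$ppv, 1)
  expect_error(pool_family(list()), "no reports")
})

test_that("flexible-mode rates never fall below strict-mode rates", {
  set.seed(501)
  for (rep in 1:10) {
    s <- rand_rna(12)
    es <- enumerate_structures(s, P)
    if (length(es) < 3) next
    a <- es[[sample(length(es), 1)]]$pairs
    b <- es[[sample(length(es), 1)]]$pairs
    rs <- score_pair(a, a, b, b, strict = TRUE)
    rf <- score_pair(a, a, b, b, strict = FALSE)
    if (!is.na(rs$sensitivity)) expect_gte(rf$sensitivity, rs$sensitivity)
    if (!is.na(rs$ppv)) expect_gte(rf$ppv, rs$ppv)
  }
})

test_that("inserted domains are maximal unaligned blocks holding a nested pair", {
  # 20-nt sequences; positions 6..15 of seq2 unaligned
  aln1 <- c(1:5, rep(0L, 0), 6:10)          # seq1 fully aligned (10 nt)
  aln2 <- c(1:5, rep(0L, 10), 6:10)         # seq2 has a 10-nt unaligned block
  k1 <- matrix(integer(0), 0, 2)
  k2 <- cbind(c(7L, 8L, 9L), c(14L, 13L, 12L))  # 3-pair stem inside the block
  d <- find_inserted_domains(k1, k2, aln1, aln2)
  expect_identical(nrow(d), 1L)
  expect_identical(d$start, 6L); expect_identical(d$end, 15L)
  # a pair straddling the block boundary disqualifies it
  k2b <- cbind(7L, 17L)
  expect_identical(nrow(find_inserted_domains(k1, k2b, aln1, aln2)), 0L)
  # no unaligned block with a pair: empty
  expect_identical(nrow(find_inserted_domains(k1, k1, 1:10, 1:10)), 0L)
})

test_that("inserted-domain accuracy distinguishes the move sets", {
  fx <- make_fixture(fixture_spec(seed = 52), P)
  kd <- find_inserted_domains(fx$ref$pairs1, fx$ref$pairs2, fx$ref$aln1, fx$ref$aln2)
  expect_identical(nrow(kd), 1L)
  cs <- suppressWarnings(predict_common(fx$seq1, fx$seq2, P, "dynalign2",
                                        band_width = 20))
  acc <- inserted_domain_accuracy(cs, fx$ref$pairs1, fx$ref$pairs2, kd)
  expect_identical(acc$sensitivity, 1)
  cs0 <- suppressWarnings(predict_common(fx$seq1, fx$seq2, P, "original",
                                         band_width = 20))
  acc0 <- inserted_domain_accuracy(cs0, fx$ref$pairs1, fx$ref$pairs2, kd)
  expect_identical(acc0$sensitivity, 0)
  expect_true(is.na(acc0$ppv))       # no inserted pairs are possible at all
  # no known inserted domains and none predicted: both rates undefined
  kd0 <- kd[integer(0), , drop = FALSE]
  accn <- inserted_domain_accuracy(cs0, fx$ref$pairs1, fx$ref$pairs2, kd0)
  expect_true(is.na(accn$sensitivity) && is.na(accn$ppv))
})

test_that("paired one-tailed t-test matches its closed form and conventions", {
  expect_identical(paired_one_tailed_test(c(.5, .6, .7), c(.5, .6, .7)), 0.5)
  # constant positive differences: zero variance, p -> 0
  expect_lt(paired_one_tailed_test(c(.6, .6, .6, .6), c(.5, .5, .5, .5)), 0.05)
  # general case against stats::t.test
  a <- c(0.62, 0.71, 0.55, 0.68, 0.80)
  b <- c(0.60, 0.65, 0.57, 0.61, 0.72)
  expect_equal(paired_one_tailed_test(a, b),
               stats::t.test(a, b, paired = TRUE, alternative = "greater")$p.value)
  # swapping the arguments reflects the p-value
  expect_equal(paired_one_tailed_test(a, b) + paired_one_tailed_test(b, a), 1)
  expect_error(paired_one_tailed_test(a, b[-1]), "length")
})
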