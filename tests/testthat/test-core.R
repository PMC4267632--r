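# Joint fold-and-align core: band, fill, traceback, rescoring, modes.

test_that("alignment band membership and widening behave as specified", {
  b <- make_band(50, 50, 10)
  expect_true(b$contains(25, 25))
  expect_true(b$contains(25, 30))
  expect_false(b$contains(25, 31))
  expect_true(b$contains(0, 0) && b$contains(50, 50))
  # full diagonal is always inside for equal lengths
  b2 <- make_band(30, 30, 2)
  expect_true(all(vapply(0:30, function(i) b2$contains(i, i), logical(1))))
  # symmetric under reflection through the center
  expect_identical(b$contains(10, 14), b$contains(50 - 10, 50 - 14))
  expect_warning(b3 <- make_band(40, 60, 6), "widened to 40")
  expect_identical(b3$d, 40L)
  expect_error(make_band(0, 10, 4), "positive")
})

test_that("identical hairpin homologs double the single-sequence MFE", {
  s <- "GGGGAAAACCCC"
  tb <- joint_fill(s, s, "dynalign2")
  sf <- fold_single(s, P)
  expect_identical(tb$energy_t, 2L * sf$mfe_t)
  expect_identical(tb$energy_t, tb$w3_11_t)
  cs <- traceback_structure(tb)
  expect_identical(cs$n_gap, 0L)
  expect_identical(nrow(cs$domains), 0L)
  # traced pairs equal the single-sequence MFE pairs on both sides
  mp <- mfe_structure(s, P)
  exp_pairs <- cbind(i = which(mp > seq_along(mp)), j = mp[mp > seq_along(mp)])
  expect_identical(unname(cs$pairs1), unname(exp_pairs))
  expect_identical(unname(cs$pairs2), unname(exp_pairs))
})

test_that("the joint optimum equals the exhaustive oracle on random pairs", {
  set.seed(301)
  for (rep in 1:12) {
    s1 <- rand_rna(sample(6:9, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    s2 <- rand_rna(sample(6:9, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    for (mode in c("original", "no_insert", "dynalign2")) {
      dp <- joint_fill(s1, s2, mode)
      or <- enumerate_common(s1, s2, P, mode)
      expect_identical(dp$energy_t, or$energy_t, label = paste(mode, s1, s2))
    }
  }
})

test_that("traceback rescoring reproduces the DP optimum exactly", {
  set.seed(302)
  for (rep in 1:10) {
    s1 <- rand_rna(sample(7:10, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    s2 <- rand_rna(sample(7:10, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    for (mode in c("original", "dynalign2")) {
      tb <- joint_fill(s1, s2, mode)
      cs <- traceback_structure(tb) # stops internally on any disagreement
      expect_identical(cs$energy$total_t, tb$energy_t)
      expect_identical(tb$energy_t, tb$w3_11_t)
    }
  }
})

test_that("move-set nesting orders the optima", {
  set.seed(303)
  for (rep in 1:10) {
    s1 <- rand_rna(sample(7:10, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    s2 <- rand_rna(sample(7:10, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    e_orig <- joint_fill(s1, s2, "original")$energy_t
    e_noins <- joint_fill(s1, s2, "no_insert")$energy_t
    e_dyn <- joint_fill(s1, s2, "dynalign2")$energy_t
    expect_lte(e_dyn, e_noins)
    expect_lte(e_noins, e_orig)
  }
})

test_that("widening the band never raises the optimum", {
  fx <- make_fixture(fixture_spec(seed = 41), P)
  es <- vapply(c(30, 40, 60), function(d) {
    suppressWarnings(predict_common(fx$seq1, fx$seq2, P, "dynalign2",
                                    band_width = d))$energy$total_t
  }, integer(1))
  expect_true(all(diff(es) <= 0))
})

test_that("planted insertions are recovered in recorded intervals", {
  fx <- make_fixture(fixture_spec(seed = 42), P)
  cs <- suppressWarnings(predict_common(fx$seq1, fx$seq2, P, "dynalign2",
                                        band_width = 20))
  expect_gt(nrow(cs$domains), 0L)
  # the planted stem's pairs appear inside a recorded inserted interval
  ref_dom <- fx$ref$domains
  planted <- fx$ref$pairs2[fx$ref$pairs2[, 1] >= ref_dom$start &
                             fx$ref$pairs2[, 2] <= ref_dom$end, , drop = FALSE]
  hit <- vapply(seq_len(nrow(planted)), function(r) {
    any(cs$pairs2[, 1] == planted[r, 1] & cs$pairs2[, 2] == planted[r, 2]) &&
      any(cs$domains$seq == 2L & cs$domains$start <= planted[r, 1] &
            cs$domains$end >= planted[r, 2])
  }, logical(1))
  expect_true(all(hit))
  # the original move set cannot place inserted pairs
  cs0 <- suppressWarnings(predict_common(fx$seq1, fx$seq2, P, "original",
                                         band_width = 20))
  expect_identical(nrow(cs0$domains), 0L)
  expect_lt(cs$energy$total_t, cs0$energy$total_t)
})

test_that("raising insertion penalties never lowers the optimum", {
  fx <- make_fixture(fixture_spec(seed = 43), P)
  run <- function(open, elong) {
    p2 <- P
    p2$domain_opening <- as_tenths(open)
    p2$domain_elongation <- as_tenths(elong)
    cs <- suppressWarnings(predict_common(fx$seq1, fx$seq2, p2, "dynalign2",
                                          band_width = 20))
    list(e = cs$energy$total_t, nd = nrow(cs$domains))
  }
  a <- run(0.2, 0.05); b <- run(0.5, 0.1); c <- run(3.0, 0.8)
  expect_lte(a$e, b$e)
  expect_lte(b$e, c$e)
  expect_gte(a$nd, c$nd)
})

test_that("gap and domain arithmetic of the total follows the affine model", {
  # pure arithmetic checks of the total-energy formula on a traced structure
  fx <- make_fixture(fixture_spec(seed = 44), P)
  cs <- suppressWarnings(predict_common(fx$seq1, fx$seq2, P, "dynalign2",
                                        band_width = 20))
  br <- cs$energy
  expect_identical(br$total_t,
                   br$dg1_t + br$dg2_t + br$gap_t + br$dom_t)
  expect_identical(br$gap_t, cs$n_gap * P$gap_penalty)
  dl <- sum(cs$domains$end - cs$domains$start + 1L)
  expect_identical(br$dom_t,
                   nrow(cs$domains) * P$domain_opening + dl * P$domain_elongation)
})

test_that("empty structures on equal-length sequences rescore to zero", {
  n <- 12L
  cs <- structure(list(
    seq1 = strsplit("AAAAAAAAAAAA", "")[[1]], seq2 = strsplit("CCCCCCCCCCCC", "")[[1]],
    pairs1 = matrix(integer(0), 0, 2), pairs2 = matrix(integer(0), 0, 2),
    matched = matrix(integer(0), 0, 4),
    domains = data.frame(seq = integer(0), start = integer(0), end = integer(0)),
    aln1 = 1:n, aln2 = 1:n, mode = "dynalign2", n_gap = 0L),
    class = "common_structure")
  br <- total_energy(cs, "AAAAAAAAAAAA", "CCCCCCCCCCCC", P)
  expect_identical(br$total, 0)
  expect_identical(br$n_gap, 0L)
})

test_that("degenerate inputs are rejected cleanly", {
  expect_error(predict_common("GGGAAAACCC", "GGGANAACCC", P), "invalid nucleotide")
  f1 <- fold_single("GGGAAAACCC", P)
  expect_error(fill("GGGAAAACCC", "GGGAAAACCC", f1, f1,
                    make_band(10, 11, 4), P), "different sequence lengths")
})
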