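# Enumeration oracles and the fixture generator.

test_that("structure enumeration handles degenerate sequences", {
  expect_length(enumerate_structures("AAAA", P), 1L)      # empty only
  expect_length(enumerate_structures("GCGC", P), 1L)      # any pair leaves loop < 3
  expect_error(enumerate_structures(strrep("A", 15), P), "guard")
})

test_that("structure counts match an independent recurrence", {
  for (s in c("GGGAAAACCC", "GCAUGCAUGC", "GGGGAAAACCCC", "AUAUAUAUAU")) {
    expect_identical(length(enumerate_structures(s, P)), as.integer(count_structures(s)),
                     label = s)
  }
})

test_that("joint enumeration: identical sequences double the single MFE", {
  s <- "GGGGAAAACC"
  res <- enumerate_common(s, s, P, "dynalign2")
  expect_identical(res$energy_t, 2L * fold_single(s, P)$mfe_t)
  expect_identical(res$breakdown$n_gap, 0L)
  # swapping the inputs leaves the optimum unchanged
  s2 <- "GCGGAAAACC"
  a <- enumerate_common(s, s2, P, "dynalign2")$energy_t
  b <- enumerate_common(s2, s, P, "dynalign2")$energy_t
  expect_identical(a, b)
  expect_error(enumerate_common(strrep("G", 11), s, P), "guard")
})

test_that("fixtures are deterministic and respect their spec", {
  sp <- fixture_spec(seed = 12, insertion = list(host = 2L, stem = 4L, loop = 5L))
  f1 <- make_fixture(sp, P)
  f2 <- make_fixture(sp, P)
  expect_identical(f1$seq1, f2$seq1)
  expect_identical(f1$seq2, f2$seq2)
  # planted domain length is 2*stem + loop
  expect_identical(f1$ref$domains$end - f1$ref$domains$start + 1L, 2L * 4L + 5L)
  expect_identical(f1$ref$domains$seq, 2L)
  # the reference structure rescoring is finite and counts the domain
  te <- total_energy(f1$ref, f1$seq1, f1$seq2, P)
  expect_identical(te$n_domains, 1L)

  # no insertion + zero mutation: the homolog is the sequence itself
  f0 <- make_fixture(fixture_spec(seed = 12, mut_rate = 0, insertion = NULL), P)
  expect_identical(f0$seq1, f0$seq2)
  expect_identical(nrow(f0$ref$domains), 0L)
  # conserved helices exist
  expect_gt(nrow(f0$ref$matched), 0L)

  expect_error(make_fixture(fixture_spec(seed = 1, stem_len = 4L,
                                         insertion = list(host = 2L, stem = 30L, loop = 4L)), P),
               "unsatisfiable")
})

test_that("helix jitter shortens a helix in the homolog", {
  f <- make_fixture(fixture_spec(seed = 30, jitter = 1L, insertion = NULL), P)
  expect_identical(nchar(f$seq2), nchar(f$seq1) - 2L)
  expect_identical(nrow(f$ref$pairs2), nrow(f$ref$pairs1) - 1L)
})
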