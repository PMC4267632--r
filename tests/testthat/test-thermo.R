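# Nearest-neighbor energy model: bundle loading, motif dispatch, grid.

test_that("shipped defaults carry the documented alignment penalties", {
  expect_identical(P$gap_penalty, 4L)        # 0.4 kcal/mol
  expect_identical(P$domain_opening, 5L)     # 0.5 kcal/mol
  expect_identical(P$domain_elongation, 1L)  # 0.1 kcal/mol per nucleotide
  expect_identical(P$max_internal_side, 20L)
  expect_identical(P$max_stackII_extension, 5L)
  expect_identical(P$min_hairpin, 3L)
})

test_that("bundle round-trips bit-exactly and rejects missing tables", {
  f <- withr::local_tempfile(fileext = ".params")
  write_params(P, f)
  expect_identical(load_params(f), P)

  src <- readLines(system.file("extdata", "params", "default.params",
                               package = "costruct"))
  cut <- src[seq_len(which(src == "[hairpin_init]") - 1L)]
  f2 <- withr::local_tempfile(fileext = ".params")
  writeLines(cut, f2)
  expect_error(load_params(f2), "hairpin_init")
})

test_that("canonical pairs are exactly the Watson-Crick and wobble pairs", {
  expect_true(is_canonical("G", "C"))
  expect_true(is_canonical("G", "U"))
  expect_true(is_canonical("U", "G"))
  expect_false(is_canonical("A", "G"))
  expect_false(is_canonical("A", "A"))
  expect_error(is_canonical("A", "N"), "invalid nucleotide")
})

test_that("terminal penalty applies to AU/GU helix ends only", {
  expect_identical(end_penalty("GAAAAC", 1, 6, P), 0)
  expect_identical(end_penalty("AAAAAU", 1, 6, P), from_tenths(P$au_gu_end_penalty))
  expect_identical(end_penalty("GAAAAU", 1, 6, P), from_tenths(P$au_gu_end_penalty))
  expect_error(end_penalty("AAAAAG", 1, 6, P), "non-canonical")
})

test_that("hairpin energy is initiation plus closing-end penalty", {
  # loop below the minimum size is a sentinel, not an exception
  expect_identical(hairpin_energy("GAAC", 1, 4, P), Inf)
  # GGGAAAACCC: pair (3,8) closes an AAAA tetraloop -> init[4]; pair (1,10)
  # closes an 8-loop -> init[8]; both G-C closings carry no penalty
  expect_identical(hairpin_energy("GGGAAAACCC", 3, 8, P),
                   from_tenths(P$hairpin_init[["4"]]))
  expect_identical(hairpin_energy("GGGAAAACCC", 1, 10, P),
                   from_tenths(P$hairpin_init[["8"]]))
  # same tetraloop closed by A-U adds the end penalty
  expect_identical(hairpin_energy("AAAAAU", 1, 6, P),
                   from_tenths(P$hairpin_init[["4"]] + P$au_gu_end_penalty))
})

test_that("motif energy dispatches to stack, internal loop and bulge", {
  # helix stack G-C on C-G: direct bundle lookup
  expect_identical(motif_energy("GCAAAGC", 1, 2, 7, 6, P),
                   from_tenths(P$stack["GC", "CG"]))
  # symmetric 1x1 internal loop between two G-C pairs: init only
  expect_identical(motif_energy("GAGACAC", 1, 3, 7, 5, P),
                   from_tenths(P$internal_init[["2"]]))
  # 2x0 bulge between G-C pairs: bulge initiation + (zero) end penalties
  expect_identical(motif_energy("GAAGAAACC", 1, 4, 9, 8, P),
                   from_tenths(P$bulge_init[["2"]]))
  # single-nucleotide bulge keeps the helix stack and takes no end penalty
  expect_identical(motif_energy("GAGAAACC", 1, 3, 8, 7, P),
                   from_tenths(P$bulge_init[["1"]] + P$stack["GC", "GC"]))
  # 2x1 asymmetric internal loop: size init + asymmetry + UA end penalty
  expect_identical(motif_energy("UAAGAAACAA", 1, 4, 10, 8, P),
                   from_tenths(P$internal_init[["3"]] + 1L * P$asymmetry_coef +
                               P$au_gu_end_penalty + 0L))
  # side over the cap is forbidden
  long <- paste0("G", strrep("A", 25), "GAAACC")
  expect_identical(motif_energy(long, 1, 27, nchar(long), nchar(long) - 1, P), Inf)
  expect_error(motif_energy("AAGAAACA", 1, 3, 8, 7, P), "non-canonical")
})

test_that("stack_energy is motif_energy on the stack case, exhaustively", {
  set.seed(101)
  for (rep in 1:50) {
    s <- rand_rna(sample(10:30, 1))
    n <- nchar(s)
    m <- sample(seq_len(n - 5), 1)
    p <- sample((m + 4):n, 1)
    ch <- strsplit(s, "")[[1]]
    if (!is_canonical(ch[m], ch[p])) next
    expect_identical(stack_energy(s, m, p, P), motif_energy(s, m, m + 1, p, p - 1, P))
  }
})

test_that("a hand-summed helix equals the sum of its stack terms", {
  s <- "GGGGGAAAACCCCC"
  total <- sum(vapply(1:4, function(m) stack_energy(s, m, 15 - m, P), numeric(1)))
  expect_identical(total, from_tenths(4L * P$stack["GC", "GC"]))
})

test_that("all energies fall on the 0.1 kcal/mol grid", {
  set.seed(102)
  vals <- c()
  for (rep in 1:30) {
    s <- rand_rna(12)
    ch <- strsplit(s, "")[[1]]
    for (i in 1:6) for (j in (i + 4):12) {
      if (!is_canonical(ch[i], ch[j])) next
      vals <- c(vals, hairpin_energy(s, i, j, P))
    }
  }
  vals <- vals[is.finite(vals)]
  expect_true(all(abs(vals * 10 - round(vals * 10)) < 1e-9))
})

test_that("motif energy is invariant under exchanging the two strands", {
  # rotating the motif 180 degrees exchanges the strand roles: the outer
  # closing pair becomes the old inner pair read backwards and the two loop
  # sides swap (n1 x n2 -> n2 x n1).  With the shipped strand-symmetric
  # stack table the energy must not change.
  set.seed(103)
  checked <- 0
  while (checked < 40) {
    s <- rand_rna(sample(10:16, 1))
    n <- nchar(s)
    ch <- strsplit(s, "")[[1]]
    m <- sample(1:(n - 7), 1)
    p <- sample((m + 6):n, 1)
    a <- sample(1:3, 1); b <- sample(1:3, 1)
    nn <- m + a; qq <- p - b
    if (nn >= qq - 3) next
    if (!is_canonical(ch[m], ch[p]) || !is_canonical(ch[nn], ch[qq])) next
    # build the rotated motif explicitly: new top strand = old bottom strand
    flip <- c(ch[qq:p], rep("A", 3), ch[m:nn])
    L <- length(flip)
    new_m <- 1L; new_n <- p - qq + 1L
    new_q <- L - (nn - m); new_p <- L
    e1 <- motif_energy(s, m, nn, p, qq, P)
    e2 <- motif_energy(flip, new_m, new_n, new_p, new_q, P)
    expect_identical(e1, e2)
    checked <- checked + 1
  }
})
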