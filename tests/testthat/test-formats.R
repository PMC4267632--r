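# FASTA / CT / dot-bracket / alignment I/O.

test_that("FASTA reading normalizes case and T/U and pinpoints bad characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgu"), f)
  expect_identical(read_fasta(f), list(a = "ACGU"))
  writeLines(c(">a", "ACGT"), f)
  expect_identical(read_fasta(f)$a, "ACGU")
  writeLines(c(">a", "ACGN"), f)
  expect_error(read_fasta(f), "position 4")
  writeLines(c(">a", "ACGU", ">a", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("CT files round-trip and reject inconsistent pairing", {
  f <- withr::local_tempfile(fileext = ".ct")
  r <- structure_record("x", "GGGAAAACCC", cbind(c(1, 2, 3), c(10, 9, 8)))
  write_ct(r, f, energy = -1.2)
  expect_identical(read_ct(f), r)
  # unpaired record: four data lines, partner column 0
  r0 <- structure_record("y", "ACGU")
  write_ct(r0, f)
  lines <- readLines(f)
  expect_length(lines, 5L)
  expect_true(all(vapply(strsplit(lines[-1], " +"), function(x) x[5] == "0",
                         logical(1))))
  expect_identical(read_ct(f), r0)
  # asymmetric pairing: 2 pairs 9 but 9 claims 3
  bad <- c("10 x", vapply(1:10, function(i) {
    pr <- if (i == 2) 9L else if (i == 9) 3L else 0L
    sprintf("%d N %d %d %d %d", i, i - 1L, i + 1L, pr, i)
  }, character(1)))
  writeLines(bad, f)
  expect_error(read_ct(f), "asymmetric")
  # out-of-range partner
  bad2 <- c("4 x", "1 A 0 2 9 1", "2 C 1 3 0 2", "3 G 2 4 0 3", "4 U 3 0 0 4")
  writeLines(bad2, f)
  expect_error(read_ct(f), "out of range")
  # crossing pairs are rejected on read
  bad3 <- c("10 x", vapply(1:10, function(i) {
    pr <- c(6L, 8L, 0L, 0L, 0L, 1L, 0L, 2L, 0L, 0L)[i]
    sprintf("%d A %d %d %d %d", i, i - 1L, i + 1L, pr, i)
  }, character(1)))
  writeLines(bad3, f)
  expect_error(read_ct(f), "crossing")
})

test_that("dot-bracket is bijective with the pair list", {
  r <- read_dotbracket("((..))", seq = "GGAACC")
  expect_identical(unname(r$pairs), cbind(c(1L, 2L), c(6L, 5L)))
  expect_identical(read_dotbracket("....", seq = "ACGU")$pairs,
                   matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  expect_error(read_dotbracket("(()", seq = "GGC"), "unbalanced")
  expect_error(read_dotbracket("())", seq = "GCC"), "unbalanced")
  r2 <- structure_record("z", "GGGAAAACCC", cbind(c(1, 2), c(10, 9)))
  db <- write_dotbracket(r2)
  expect_identical(read_dotbracket(strsplit(db, "\n")[[1]][3],
                                   seq = "GGGAAAACCC", id = "z")$pairs,
                   r2$pairs)
})

test_that("random records round-trip bit-exactly through CT and dot-bracket", {
  set.seed(401)
  fct <- withr::local_tempfile(fileext = ".ct")
  fdb <- withr::local_tempfile(fileext = ".db")
  for (rep in 1:25) {
    s <- rand_rna(sample(8:14, 1))
    es <- enumerate_structures(s, P)
    pk <- es[[sample(length(es), 1)]]$pairs
    r <- structure_record(paste0("r", rep), s, pk)
    write_ct(r, fct)
    expect_identical(read_ct(fct), r)
    write_dotbracket(r, fdb)
    expect_identical(read_dotbracket(fdb)$pairs, r$pairs)
  }
})

test_that("alignments round-trip with gaps and insertion annotations", {
  fx <- make_fixture(fixture_spec(seed = 51), P)
  cs <- suppressWarnings(predict_common(fx$seq1, fx$seq2, P, "dynalign2",
                                        band_width = 20))
  txt <- write_alignment(cs)
  back <- read_alignment(txt)
  expect_identical(back$aln1, cs$aln1)
  expect_identical(back$aln2, cs$aln2)
  expect_identical(back$n_gap, cs$n_gap)
  expect_identical(back$domains$start, cs$domains$start)
  expect_identical(back$seq1, paste(cs$seq1, collapse = ""))
  # one inserted domain: its nucleotides appear against '-' in the other row
  rows <- strsplit(txt, "\n")[[1]]
  rows <- rows[!startsWith(rows, "#")]
  dlen <- cs$domains$end[1] - cs$domains$start[1] + 1L
  expect_gte(sum(strsplit(rows[1], "")[[1]] == "-"), dlen)
  # identical sequences: two identical rows, no gap characters
  s <- "GGGGAAAACCCC"
  cs2 <- predict_common(s, s, P, "dynalign2")
  rows2 <- strsplit(write_alignment(cs2), "\n")[[1]]
  rows2 <- rows2[!startsWith(rows2, "#")]
  expect_identical(rows2[1], rows2[2])
  expect_false(grepl("-", rows2[1], fixed = TRUE))
})
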