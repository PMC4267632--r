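# Single-sequence minimization vs the enumeration oracle; pair filter.

test_that("unpairable and hairpin-forming sequences fold as expected", {
  s <- fold_single("AAAA", P)
  expect_identical(s$mfe, 0)
  expect_true(all(s$v[-1, -1] >= INF_TENTHS | upper.tri(s$v[-1, -1]) == FALSE))

  s2 <- fold_single("GGGGAAAACCCC", P)
  expect_identical(s2$mfe_t, enumerate_mfe("GGGGAAAACCCC", P)$mfe_t)
  # 4-pair hairpin: 3 GC stacks + tetraloop initiation, by hand from the bundle
  expect_identical(s2$mfe_t, 3L * P$stack[["GC", "GC"]] + P$hairpin_init[["4"]])
})

test_that("mfe matches exhaustive enumeration on random sequences", {
  set.seed(201)
  for (rep in 1:40) {
    s <- rand_rna(sample(5:12, 1))
    sf <- fold_single(s, P)
    expect_identical(sf$mfe_t, enumerate_mfe(s, P)$mfe_t, label = s)
    # mfe equals the exterior value of the full fragment
    expect_identical(sf$mfe_t, sf_we(sf, 1, nchar(s)))
  }
})

test_that("v_s support equals pairs occurring in enumerable structures", {
  set.seed(202)
  for (rep in 1:10) {
    s <- rand_rna(10)
    sf <- fold_single(s, P)
    es <- enumerate_structures(s, P)
    seen <- unique(do.call(rbind, lapply(es, `[[`, "pairs")))
    for (i in 1:9) for (j in (i + 1):10) {
      fin <- sf$v[i + 1, j + 1] < INF_TENTHS
      inoracle <- nrow(seen) > 0 && any(seen[, 1] == i & seen[, 2] == j)
      expect_identical(fin, inoracle,
                       label = paste(s, i, j))
    }
  }
})

test_that("appending nucleotides never raises the mfe", {
  set.seed(203)
  for (rep in 1:15) {
    s <- rand_rna(sample(6:11, 1))
    ext <- paste0(s, sample(c("A", "C", "G", "U"), 1))
    expect_lte(fold_single(ext, P)$mfe_t, fold_single(s, P)$mfe_t)
  }
})

test_that("pair filter windows match the enumeration rule", {
  set.seed(204)
  for (rep in 1:8) {
    s <- rand_rna(sample(9:12, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    n <- nchar(s)
    sf <- fold_single(s, P)
    es <- enumerate_structures(s, P)
    et <- vapply(es, function(x) ifelse(is.na(x$energy_t), INF_TENTHS, x$energy_t),
                 integer(1))
    mfe <- min(et)
    best_with <- function(i, j) {
      has <- vapply(es, function(x)
        nrow(x$pairs) > 0 && any(x$pairs[, 1] == i & x$pairs[, 2] == j), logical(1))
      if (!any(has)) return(INF_TENTHS)
      min(et[has])
    }
    al1 <- filter_pairs(s, sf, 1)
    al0 <- filter_pairs(s, sf, 0)
    alw <- filter_pairs(s, sf, 0.2)
    thr <- mfe + as.integer(floor(0.2 * abs(mfe) + 1e-9))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      bw <- best_with(i, j)
      expect_identical(al1[i, j], sf$v[i + 1, j + 1] < INF_TENTHS)
      expect_identical(al0[i, j], bw <= mfe)
      expect_identical(alw[i, j], bw <= thr, label = paste(s, i, j))
    }
  }
  expect_error(filter_pairs("GGGAAAACCC", fold_single("GGGAAAACCC", P), -0.1),
               "window_percent")
})
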