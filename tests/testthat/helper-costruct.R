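# Shared test helpers: parameters, random sequences, small joint runs, and
# an independent structure counter.

P <- load_params()

rand_rna <- function(n, prob = c(0.2, 0.3, 0.3, 0.2)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob),
        collapse = "")
}

wide_band <- function(s1, s2) {
  make_band(nchar(s1), nchar(s2), 2L * max(nchar(s1), nchar(s2)))
}

# fill with an unconstrained band and no pair filtering (oracle conditions)
joint_fill <- function(s1, s2, mode, params = P) {
  f1 <- fold_single(s1, params)
  f2 <- fold_single(s2, params)
  fill(s1, s2, f1, f2, wide_band(s1, s2), params, mode, window_percent = 1)
}

tenths <- function(x) as.integer(round(10 * x))

# Independent count of pseudoknot-free structures over canonical pairs with
# a minimum hairpin size: a Motzkin-style recurrence, sharing nothing with
# enumerate_structures.
count_structures <- function(seq, min_hp = 3L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- array(NA_real_, dim = c(n + 2, n + 2))
  cnt <- function(i, j) {
    if (i >= j) return(1)
    if (!is.na(memo[i, j])) return(memo[i, j])
    total <- cnt(i + 1L, j)
    for (q in (i + min_hp + 1L):j) {
      if (q > j) break
      if (!paste0(ch[i], ch[q]) %in% canon) next
      total <- total + cnt(i + 1L, q - 1L) * cnt(q + 1L, j)
    }
    memo[i, j] <<- total
    total
  }
  cnt(1L, n)
}
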