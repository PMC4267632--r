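# Independent rescoring of a common structure (the declarative counterpart
# of the dynamic program).
#
# A configuration is (pairs1, pairs2, matched quadruples, inserted-domain
# intervals).  Scoring decomposes each structure into loops, with these
# conventions mirroring the joint model:
#   * a loop's class is decided per conserved quadruple: hairpin when both
#     effective closing pairs have empty loops; a two-pair motif when both
#     have exactly one conserved child; multibranch otherwise -- and a loop
#     aligned to a multibranch loop is scored as multibranch even if it has
#     a single branch (the stem-loop-as-branch simplification of the
#     insertion recursions);
#   * unmatched pairs are either inserted-domain content (scored with the
#     single-sequence branch/exterior conventions plus the affine domain
#     penalty) or chain decorations: motifs inserted below a conserved pair
#     (each charged its motif energy plus one gap per inserted-side
#     nucleotide), with a run of inserted stacks aligned to a symmetric
#     internal loop in the homolog recognized as a stem extension (no gaps);
#   * gaps are counted region-wise: between consecutive aligned anchors the
#     shorter side's unpaired nucleotides align and the length difference
#     is charged, inserted-domain nucleotides excluded.
# The function is pure: it never consults the DP arrays.

.build_tree <- function(pairs, n) {
  np <- nrow(pairs)
  if (np == 0)
    return(list(np = 0L, pairs = pairs, parent = integer(0),
                children = list(), top = integer(0), pof = integer(n)))
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  pof <- integer(n)
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i >= j || i < 1 || j > n) stop("invalid pair (", i, ",", j, ")")
    if (pof[i] != 0L || pof[j] != 0L) stop("position in more than one pair")
    pof[i] <- j; pof[j] <- i
  }
  # non-crossing check + parents via a stack
  parent <- integer(np); children <- rep(list(integer(0)), np)
  stk <- integer(0)
  rowat <- integer(n); for (r in seq_len(np)) rowat[pairs[r, 1]] <- r
  for (pos in seq_len(n)) {
    if (pof[pos] > pos) {
      r <- rowat[pos]
      parent[r] <- if (length(stk)) stk[length(stk)] else 0L
      if (parent[r]) children[[parent[r]]] <- c(children[[parent[r]]], r)
      stk <- c(stk, r)
    } else if (pof[pos] != 0L) {
      r <- if (length(stk)) stk[length(stk)] else 0L
      if (r == 0L || pairs[r, 2] != pos) stop("crossing base pairs")
      stk <- stk[-length(stk)]
    }
  }
  list(np = np, pairs = pairs, parent = parent, children = children,
       top = which(parent == 0L), pof = pof)
}

# Score the subtree rooted at pair row r with the plain single-sequence
# model (used for inserted-domain content).  Returns tenths or INF.
.single_subtree_t <- function(seq, tree, r, params) {
  i <- tree$pairs[r, 1]; j <- tree$pairs[r, 2]
  ch <- tree$children[[r]]
  if (length(ch) == 0L) return(.hairpin_t(seq, i, j, params))
  if (length(ch) == 1L) {
    c1 <- ch[[1]]
    m <- .motif_t(seq, i, tree$pairs[c1, 1], j, tree$pairs[c1, 2], params)
    if (m >= INF_TENTHS) return(INF_TENTHS)
    sub <- .single_subtree_t(seq, tree, c1, params)
    if (sub >= INF_TENTHS) return(INF_TENTHS)
    return(m + sub)
  }
  tot <- params$mbl_closure + params$mbl_branch + .end_penalty_t(seq, i, j, params)
  unp <- j - i - 1L
  for (c1 in ch) {
    ci <- tree$pairs[c1, 1]; cj <- tree$pairs[c1, 2]
    unp <- unp - (cj - ci + 1L)
    sub <- .single_subtree_t(seq, tree, c1, params)
    if (sub >= INF_TENTHS) return(INF_TENTHS)
    tot <- tot + params$mbl_branch + .end_penalty_t(seq, ci, cj, params) + sub
  }
  tot + unp * params$mbl_unpaired
}

# Domain content energy: top-level pairs of the interval as branches.
# context "mbl": branch penalty + end penalty per branch, per-unpaired cost;
# context "exterior": end penalty only, unpaired free.
.domain_content_t <- function(seq, tree, rows_top, start, end, context, params) {
  tot <- 0L
  unp <- end - start + 1L
  for (r in rows_top) {
    ci <- tree$pairs[r, 1]; cj <- tree$pairs[r, 2]
    unp <- unp - (cj - ci + 1L)
    sub <- .single_subtree_t(seq, tree, r, params)
    if (sub >= INF_TENTHS) return(INF_TENTHS)
    tot <- tot + .end_penalty_t(seq, ci, cj, params) + sub
    if (context == "mbl") tot <- tot + params$mbl_branch
  }
  if (context == "mbl") tot <- tot + unp * params$mbl_unpaired
  tot
}

# Core rescorer.  Returns NULL when the configuration is not expressible in
# the selected move set, a list with total_t = INF when expressible but
# energetically forbidden, else the full breakdown.
.score_config <- function(seq1, seq2, pairs1, pairs2, matched, domains,
                          params, mode = "dynalign2") {
  n1 <- length(seq1); n2 <- length(seq2)
  t1 <- .build_tree(pairs1, n1); t2 <- .build_tree(pairs2, n2)
  nm <- nrow(matched)
  if (mode == "original" && (t1$np != nm || t2$np != nm)) return(NULL)
  if (mode != "dynalign2" && nrow(domains) > 0) return(NULL)

  # matched lookup: row index in tree per quadruple
  key1 <- paste(t1$pairs[, 1], t1$pairs[, 2]); key2 <- paste(t2$pairs[, 1], t2$pairs[, 2])
  mrow1 <- match(paste(matched[, 1], matched[, 2]), key1)
  mrow2 <- match(paste(matched[, 3], matched[, 4]), key2)
  if (anyNA(mrow1) || anyNA(mrow2)) return(NULL)
  if (anyDuplicated(mrow1) || anyDuplicated(mrow2)) return(NULL)
  is_m1 <- logical(t1$np); is_m1[mrow1] <- TRUE
  is_m2 <- logical(t2$np); is_m2[mrow2] <- TRUE
  quad_of1 <- integer(t1$np); quad_of1[mrow1] <- seq_len(max(nm, 0L))
  quad_of2 <- integer(t2$np); quad_of2[mrow2] <- seq_len(max(nm, 0L))

  # monotone nesting isomorphism of the matching
  if (nm > 1) {
    for (a in seq_len(nm - 1)) for (b in (a + 1):nm) {
      rel <- function(pa, pb) {
        if (pb[1] > pa[1] && pb[2] < pa[2]) return("in")
        if (pa[1] > pb[1] && pa[2] < pb[2]) return("out")
        if (pa[2] < pb[1]) return("lt")
        if (pb[2] < pa[1]) return("gt")
        "x"
      }
      r1 <- rel(matched[a, 1:2], matched[b, 1:2])
      r2 <- rel(matched[a, 3:4], matched[b, 3:4])
      if (r1 != r2 || r1 == "x") return(NULL)
    }
  }

  # domains: per sequence, validate and index
  dom1 <- domains[domains$seq == 1L, , drop = FALSE]
  dom2 <- domains[domains$seq == 2L, , drop = FALSE]
  prep_domains <- function(dd, tree, n, is_m) {
    if (nrow(dd) == 0)
      return(list(df = dd, mask = logical(n), pair_dom = integer(tree$np),
                  tops = list(), host = integer(0)))
    dd <- dd[order(dd$start), , drop = FALSE]
    mask <- logical(n)
    pair_dom <- integer(tree$np)
    tops <- rep(list(integer(0)), nrow(dd))
    host <- integer(nrow(dd)) # enclosing pair row (0 = exterior)
    for (x in seq_len(nrow(dd))) {
      a <- dd$start[x]; b <- dd$end[x]
      if (a < 1 || b > n || a > b) return("bad")
      if (any(mask[a:b])) return("bad") # overlapping domains
      mask[a:b] <- TRUE
      inside <- which(tree$pairs[, 1] >= a & tree$pairs[, 2] <= b)
      straddle <- which((tree$pairs[, 1] >= a & tree$pairs[, 1] <= b) !=
                        (tree$pairs[, 2] >= a & tree$pairs[, 2] <= b))
      if (length(straddle)) return("bad")
      if (length(inside) == 0) return("bad")     # a domain folds
      if (any(is_m[inside])) return("bad")       # conserved pairs cannot be inserted
      pair_dom[inside] <- x
      tops[[x]] <- inside[!(tree$parent[inside] %in% inside)]
      # enclosing pair: deepest pair strictly containing [a,b] and outside it
      enc <- which(tree$pairs[, 1] < a & tree$pairs[, 2] > b)
      host[x] <- if (length(enc)) enc[which.max(tree$pairs[enc, 1])] else 0L
    }
    list(df = dd, mask = mask, pair_dom = pair_dom, tops = tops, host = host)
  }
  d1 <- prep_domains(dom1, t1, n1, is_m1); if (identical(d1, "bad")) return(NULL)
  d2 <- prep_domains(dom2, t2, n2, is_m2); if (identical(d2, "bad")) return(NULL)

  # chain descent from each matched pair; returns terminal row and chain rows
  descend <- function(tree, is_m, pair_dom, r) {
    chain <- integer(0)
    e <- r
    repeat {
      ch <- tree$children[[e]]
      ch <- ch[pair_dom[ch] == 0L]
      if (length(ch) == 1L && !is_m[ch]) { chain <- c(chain, ch); e <- ch }
      else break
    }
    list(e = e, chain = chain)
  }

  visited1 <- logical(t1$np); visited2 <- logical(t2$np)
  INF <- INF_TENTHS
  dg <- c(0L, 0L)
  ngap <- 0L
  bad <- FALSE

  trees <- list(t1, t2); seqs <- list(seq1, seq2)
  doms <- list(d1, d2); is_m <- list(is_m1, is_m2)

  # helper: count unpaired, non-domain nucleotides in [a,b] of sequence s
  unp_count <- function(s, a, b) {
    if (a > b) return(0L)
    idx <- a:b
    sum(trees[[s]]$pof[idx] == 0L & !doms[[s]]$mask[idx])
  }

  loop_gaps <- function(lo1, hi1, rows1, lo2, hi2, rows2) {
    # rows*: conserved branch rows in order; region r between branches
    p1 <- trees[[1]]$pairs[rows1, , drop = FALSE]
    p2 <- trees[[2]]$pairs[rows2, , drop = FALSE]
    s1s <- c(lo1, if (nrow(p1)) p1[, 2] + 1L); s1e <- c(if (nrow(p1)) p1[, 1] - 1L, hi1)
    s2s <- c(lo2, if (nrow(p2)) p2[, 2] + 1L); s2e <- c(if (nrow(p2)) p2[, 1] - 1L, hi2)
    g <- 0L
    for (x in seq_along(s1s))
      g <- g + abs(unp_count(1L, s1s[x], s1e[x]) - unp_count(2L, s2s[x], s2e[x]))
    g
  }

  qdone <- logical(nm)

  # score one conserved quadruple (recursion over conserved structure)
  score_quad <- function(q) {
    qdone[q] <<- TRUE
    r1 <- mrow1[q]; r2 <- mrow2[q]
    de1 <- descend(t1, is_m1, d1$pair_dom, r1)
    de2 <- descend(t2, is_m2, d2$pair_dom, r2)
    visited1[de1$chain] <<- TRUE; visited2[de2$chain] <<- TRUE

    # chain steps: motif + per-nucleotide gaps
    chain_info <- function(s, tree, rfrom, chain) {
      tot <- 0L; gaps <- 0L; all11 <- TRUE
      prev <- rfrom
      for (z in chain) {
        pi <- tree$pairs[prev, 1]; pj <- tree$pairs[prev, 2]
        zi <- tree$pairs[z, 1]; zj <- tree$pairs[z, 2]
        off5 <- zi - pi; off3 <- pj - zj
        m <- .motif_t(seqs[[s]], pi, zi, pj, zj, params)
        if (m >= INF) return(NULL)
        tot <- tot + m
        gaps <- gaps + off5 + off3
        if (off5 != 1L || off3 != 1L) all11 <- FALSE
        prev <- z
      }
      list(tot = tot, gaps = gaps, all11 = all11, e = prev)
    }
    c1 <- chain_info(1L, t1, r1, de1$chain); if (is.null(c1)) { bad <<- TRUE; return(INF) }
    c2 <- chain_info(2L, t2, r2, de2$chain); if (is.null(c2)) { bad <<- TRUE; return(INF) }
    dg[1] <<- dg[1] + c1$tot; dg[2] <<- dg[2] + c2$tot
    gap_here <- c1$gaps + c2$gaps

    e1 <- de1$e; e2 <- de2$e
    ei1 <- t1$pairs[e1, 1]; ej1 <- t1$pairs[e1, 2]
    ei2 <- t2$pairs[e2, 1]; ej2 <- t2$pairs[e2, 2]
    ch1 <- t1$children[[e1]]; ch1 <- ch1[d1$pair_dom[ch1] == 0L]
    ch2 <- t2$children[[e2]]; ch2 <- ch2[d2$pair_dom[ch2] == 0L]
    ld1 <- which(d1$host == e1); ld2 <- which(d2$host == e2)

    # any remaining unmatched non-domain child is unreachable
    if (any(!is_m1[ch1]) || any(!is_m2[ch2])) { bad <<- TRUE; return(INF) }
    if (length(ch1) != length(ch2)) { bad <<- TRUE; return(INF) }
    if (length(ch1) && any(quad_of1[ch1] != quad_of2[ch2])) { bad <<- TRUE; return(INF) }

    mbl <- length(ch1) >= 2L || length(ld1) > 0L || length(ld2) > 0L
    tot <- 0L

    if (!mbl && length(ch1) == 0L) {
      # conserved hairpin
      h1 <- .hairpin_t(seq1, ei1, ej1, params); h2 <- .hairpin_t(seq2, ei2, ej2, params)
      if (h1 >= INF || h2 >= INF) return(INF)
      dg[1] <<- dg[1] + h1; dg[2] <<- dg[2] + h2
      ngap <<- ngap + gap_here + abs((ej1 - ei1) - (ej2 - ei2))
      return(0L)
    }
    if (!mbl && length(ch1) == 1L) {
      ci1 <- t1$pairs[ch1, 1]; cj1 <- t1$pairs[ch1, 2]
      ci2 <- t2$pairs[ch2, 1]; cj2 <- t2$pairs[ch2, 2]
      m1 <- .motif_t(seq1, ei1, ci1, ej1, cj1, params)
      m2 <- .motif_t(seq2, ei2, ci2, ej2, cj2, params)
      if (m1 >= INF || m2 >= INF) return(INF)
      gap_motif <- abs((ci1 - ei1) - (ci2 - ei2)) + abs((ej1 - cj1) - (ej2 - cj2))
      # stem extension: a pure stack run in one homolog (chain of (1,1)
      # steps ending on the conserved child) aligned to a symmetric
      # internal loop in the other scores without gaps
      host_last1 <- (ci1 - ei1 == 1L && ej1 - cj1 == 1L)
      host_last2 <- (ci2 - ei2 == 1L && ej2 - cj2 == 1L)
      sym1 <- (ci1 - ei1 == ej1 - cj1)
      sym2 <- (ci2 - ei2 == ej2 - cj2)
      run2 <- length(de2$chain) >= 1L && length(de1$chain) == 0L && c2$all11 &&
        host_last2 && sym1 && (ci1 - ei1) == length(de2$chain) + 1L &&
        (ci1 - ei1) <= params$max_stackII_extension
      run1 <- length(de1$chain) >= 1L && length(de2$chain) == 0L && c1$all11 &&
        host_last1 && sym2 && (ci2 - ei2) == length(de1$chain) + 1L &&
        (ci2 - ei2) <= params$max_stackII_extension
      if ((run1 || run2) && mode != "original") {
        gap_here <- 0L; gap_motif <- 0L
      }
      dg[1] <<- dg[1] + m1; dg[2] <<- dg[2] + m2
      ngap <<- ngap + gap_here + gap_motif
      return(score_quad(quad_of1[ch1]))
    }
    # multibranch (possibly by the aligned-loop convention)
    if (length(ch1) == 0L) { bad <<- TRUE; return(INF) } # insertion needs a conserved branch
    mb <- function(s, e, ch, ld, dinfo, tree, seqv, lo, hi, closei, closej) {
      tot <- params$mbl_closure + params$mbl_branch +
        .end_penalty_t(seqv, closei, closej, params)
      unp <- unp_count(s, lo, hi)
      tot <- tot + unp * params$mbl_unpaired
      for (r in ch) {
        ci <- tree$pairs[r, 1]; cj <- tree$pairs[r, 2]
        tot <- tot + params$mbl_branch + .end_penalty_t(seqv, ci, cj, params)
      }
      for (x in ld) {
        dc <- .domain_content_t(seqv, tree, dinfo$tops[[x]], dinfo$df$start[x],
                                dinfo$df$end[x], "mbl", params)
        if (dc >= INF) return(INF)
        tot <- tot + dc
      }
      tot
    }
    v1 <- mb(1L, e1, ch1, ld1, d1, t1, seq1, ei1 + 1L, ej1 - 1L, ei1, ej1)
    v2 <- mb(2L, e2, ch2, ld2, d2, t2, seq2, ei2 + 1L, ej2 - 1L, ei2, ej2)
    if (v1 >= INF || v2 >= INF) return(INF)
    dg[1] <<- dg[1] + v1; dg[2] <<- dg[2] + v2
    ngap <<- ngap + gap_here +
      loop_gaps(ei1 + 1L, ej1 - 1L, ch1, ei2 + 1L, ej2 - 1L, ch2)
    for (x in seq_along(ch1)) {
      if (score_quad(quad_of1[ch1[x]]) >= INF) return(INF)
    }
    0L
  }

  # exterior loop
  top1 <- t1$top[d1$pair_dom[t1$top] == 0L]
  top2 <- t2$top[d2$pair_dom[t2$top] == 0L]
  if (any(!is_m1[top1]) || any(!is_m2[top2])) return(NULL)
  if (length(top1) != length(top2)) return(NULL)
  if (length(top1) && any(quad_of1[top1] != quad_of2[top2])) return(NULL)
  for (r in top1) {
    pr <- t1$pairs[r, ]
    dg[1] <- dg[1] + .end_penalty_t(seq1, pr[1], pr[2], params)
  }
  for (r in top2) {
    pr <- t2$pairs[r, ]
    dg[2] <- dg[2] + .end_penalty_t(seq2, pr[1], pr[2], params)
  }
  # exterior domains
  ext1 <- which(d1$host == 0L); ext2 <- which(d2$host == 0L)
  for (x in ext1) {
    dc <- .domain_content_t(seq1, t1, d1$tops[[x]], d1$df$start[x], d1$df$end[x],
                            "exterior", params)
    if (dc >= INF_TENTHS) return(list(total_t = INF_TENTHS))
    dg[1] <- dg[1] + dc
  }
  for (x in ext2) {
    dc <- .domain_content_t(seq2, t2, d2$tops[[x]], d2$df$start[x], d2$df$end[x],
                            "exterior", params)
    if (dc >= INF_TENTHS) return(list(total_t = INF_TENTHS))
    dg[2] <- dg[2] + dc
  }
  ngap <- ngap + loop_gaps(1L, n1, top1, 1L, n2, top2)
  for (r in top1) {
    res <- score_quad(quad_of1[r])
    if (bad) return(NULL)
    if (res >= INF_TENTHS) return(list(total_t = INF_TENTHS))
  }
  if (bad) return(NULL)
  if (any(!visited1 & !is_m1 & d1$pair_dom == 0L)) return(NULL)
  if (any(!visited2 & !is_m2 & d2$pair_dom == 0L)) return(NULL)
  if (!all(qdone)) return(NULL)

  dom_len <- if (nrow(domains)) sum(domains$end - domains$start + 1L) else 0L
  ngap <- as.integer(unname(ngap)); dg <- as.integer(unname(dg))
  dom_t <- nrow(domains) * params$domain_opening + dom_len * params$domain_elongation
  gap_t <- ngap * params$gap_penalty
  total_t <- dg[1] + dg[2] + gap_t + dom_t
  if (dg[1] >= INF_TENTHS || dg[2] >= INF_TENTHS) total_t <- INF_TENTHS
  list(total_t = min(total_t, INF_TENTHS), dg1_t = dg[1], dg2_t = dg[2],
       n_gap = ngap, gap_t = gap_t, dom_t = dom_t,
       n_domains = nrow(domains), dom_len = dom_len)
}

#' Recompute the energy breakdown of a common structure
#'
#' Rescoring is independent of the dynamic-programming arrays: each
#' structure is decomposed into loops under the nearest-neighbor model (with
#' the stem-loop-as-branch convention applied to loops aligned to
#' multibranch loops with inserted domains), gaps are counted region-wise
#' between aligned anchors (inserted-domain nucleotides excluded), and each
#' inserted domain adds its affine opening + elongation penalty.  The total
#' equals `dG1 + dG2 + n_gap * gap_penalty + sum(opening + x_i * elongation)`.
#'
#' @param cs a `common_structure` (from [traceback_structure()]).
#' @param seq1,seq2 the two sequences.
#' @param params an [load_params()] bundle.
#' @return list with `dg1`, `dg2`, `gap_total`, `domain_total`, `total`
#'   (kcal/mol), `n_gap`, `n_domains`, and the `_t` integer-tenths fields.
#' @export
total_energy <- function(cs, seq1, seq2, params) {
  stopifnot(inherits(cs, "common_structure"))
  sc <- .score_config(.seq_chars(seq1), .seq_chars(seq2), cs$pairs1, cs$pairs2,
                      cs$matched, cs$domains, params, mode = cs$mode %||% "dynalign2")
  if (is.null(sc))
    stop("structure violates the move-set invariants (unmatched pair is neither ",
         "inserted-domain content nor a chain/stem-extension decoration)")
  if (sc$total_t >= INF_TENTHS)
    stop("structure contains an energetically forbidden motif")
  list(dg1 = from_tenths(sc$dg1_t), dg2 = from_tenths(sc$dg2_t),
       gap_total = from_tenths(sc$gap_t), domain_total = from_tenths(sc$dom_t),
       total = from_tenths(sc$total_t), n_gap = sc$n_gap,
       n_domains = sc$n_domains, dom_len = sc$dom_len,
       dg1_t = sc$dg1_t, dg2_t = sc$dg2_t, gap_t = sc$gap_t,
       dom_t = sc$dom_t, total_t = sc$total_t)
}
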