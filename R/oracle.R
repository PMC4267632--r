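# Brute-force reference implementations.
#
# These oracles share the thermodynamic lookup tables and the declarative
# rescorer with the rest of the package but none of the dynamic-programming
# recursion code: they enumerate complete configurations and rescore each
# one, which is what makes them able to catch recursion-design errors.

#' Enumerate all pseudoknot-free structures of a short sequence
#'
#' All structures over canonical pairs respecting `min_hairpin`, each scored
#' by loop decomposition under the nearest-neighbor model.  Guarded to
#' sequences of length at most 14.
#'
#' @param seq RNA sequence (length <= 14).
#' @param params an [load_params()] bundle.
#' @return list with one element per structure: `pairs` (matrix) and
#'   `energy_t` (integer tenths; `NA` for structures containing a motif the
#'   model forbids, e.g. an oversized internal-loop side).
#' @export
enumerate_structures <- function(seq, params) {
  ch <- .seq_chars(seq)
  n <- length(ch)
  if (n > 14) stop("enumeration is guarded to length <= 14 (got ", n, ")")
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1L, j) # i unpaired
    for (q in seq_len(j)) {
      if (q < i + params$min_hairpin + 1L) next
      if (!paste0(ch[i], ch[q]) %in% PAIR_LEVELS) next
      inner <- enum(i + 1L, q - 1L)
      outer <- enum(q + 1L, j)
      for (a in inner) for (b in outer)
        out <- c(out, list(rbind(cbind(i, q), a, b)))
    }
    memo[[key]] <- out
    out
  }
  structs <- enum(1L, n)
  lapply(structs, function(p) {
    colnames(p) <- c("i", "j")
    e <- .single_energy_t(ch, p, params)
    list(pairs = p, energy_t = if (e >= INF_TENTHS) NA_integer_ else e)
  })
}

# single-sequence structure energy (exterior + subtree decomposition)
.single_energy_t <- function(seq, pairs, params) {
  tree <- .build_tree(pairs, length(seq))
  tot <- 0L
  for (r in tree$top) {
    pr <- tree$pairs[r, ]
    sub <- .single_subtree_t(seq, tree, r, params)
    if (sub >= INF_TENTHS) return(INF_TENTHS)
    tot <- tot + .end_penalty_t(seq, pr[1], pr[2], params) + sub
  }
  tot
}

#' Single-sequence minimum free energy by enumeration
#'
#' @inheritParams enumerate_structures
#' @return list with `mfe_t` (integer tenths), `mfe` (kcal/mol) and the
#'   minimizing `pairs`.
#' @export
enumerate_mfe <- function(seq, params) {
  es <- enumerate_structures(seq, params)
  et <- vapply(es, function(x) ifelse(is.na(x$energy_t), INF_TENTHS, x$energy_t), integer(1))
  b <- which.min(et)
  list(mfe_t = et[b], mfe = from_tenths(et[b]), pairs = es[[b]]$pairs)
}

# all monotone, nesting-isomorphic partial matchings between two pair sets
.enumerate_matchings <- function(P1, P2) {
  n1 <- nrow(P1); n2 <- nrow(P2)
  if (n1 == 0 || n2 == 0) return(list(matrix(integer(0), 0, 2)))
  edges <- expand.grid(a = seq_len(n1), b = seq_len(n2))
  rel <- function(p, q) {
    if (q[1] > p[1] && q[2] < p[2]) return(1L)
    if (p[1] > q[1] && p[2] < q[2]) return(2L)
    if (p[2] < q[1]) return(3L)
    if (q[2] < p[1]) return(4L)
    5L
  }
  compatible <- function(e1, e2) {
    if (e1[1] == e2[1] || e1[2] == e2[2]) return(FALSE)
    r1 <- rel(P1[e1[1], ], P1[e2[1], ])
    r2 <- rel(P2[e1[2], ], P2[e2[2], ])
    r1 == r2 && r1 != 5L
  }
  out <- list()
  ne <- nrow(edges)
  recurse <- function(idx, chosen) {
    if (idx > ne) {
      out[[length(out) + 1L]] <<- if (length(chosen))
        as.matrix(edges[chosen, , drop = FALSE]) else matrix(integer(0), 0, 2)
      return(invisible())
    }
    recurse(idx + 1L, chosen) # skip this edge
    ok <- TRUE
    for (c0 in chosen) if (!compatible(unlist(edges[idx, ]), unlist(edges[c0, ]))) { ok <- FALSE; break }
    if (ok) recurse(idx + 1L, c(chosen, idx))
    invisible()
  }
  recurse(1L, integer(0))
  out
}

# candidate inserted-domain intervals for one sequence
.candidate_intervals <- function(n, pairs, matched_rows) {
  if (nrow(pairs) == 0) return(list())
  unmatched <- setdiff(seq_len(nrow(pairs)), matched_rows)
  if (length(unmatched) == 0) return(list())
  pof <- integer(n)
  for (r in seq_len(nrow(pairs))) { pof[pairs[r, 1]] <- pairs[r, 2]; pof[pairs[r, 2]] <- pairs[r, 1] }
  res <- list()
  for (u in seq_len(n)) for (v in u:n) {
    rows_in <- which(pairs[, 1] >= u & pairs[, 2] <= v)
    strad <- which((pairs[, 1] >= u & pairs[, 1] <= v) != (pairs[, 2] >= u & pairs[, 2] <= v))
    if (length(strad)) next
    if (length(rows_in) == 0) next
    if (any(rows_in %in% matched_rows)) next
    res[[length(res) + 1L]] <- c(u, v)
  }
  res
}

# all subsets of pairwise-disjoint intervals (including the empty set)
.disjoint_subsets <- function(intervals) {
  if (length(intervals) == 0) return(list(list()))
  out <- list()
  gen <- function(idx, chosen) {
    if (idx > length(intervals)) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    gen(idx + 1L, chosen)
    ok <- all(vapply(chosen, function(c0)
      intervals[[idx]][1] > c0[2] || intervals[[idx]][2] < c0[1], logical(1)))
    if (ok) gen(idx + 1L, c(chosen, intervals[idx]))
    invisible()
  }
  gen(1L, list())
  out
}

#' Exhaustive optimum of the joint model for two short sequences
#'
#' Enumerates all pairs of pseudoknot-free structures, all monotone
#' nesting-isomorphic matchings of their base pairs, and (in `dynalign2`
#' mode) all disjoint inserted-domain interval assignments; scores every
#' configuration with the declarative rescorer and returns the minimum.
#' Shares no recursion code with [fill()].
#'
#' @param seq1,seq2 RNA sequences (each length <= 10).
#' @param params an [load_params()] bundle.
#' @param mode move set, as in [fill()].
#' @return list with `energy_t`, `energy` (kcal/mol), and the optimal
#'   configuration (`pairs1`, `pairs2`, `matched`, `domains`, breakdown).
#' @export
enumerate_common <- function(seq1, seq2, params,
                             mode = c("dynalign2", "no_insert", "original")) {
  mode <- match.arg(mode)
  ch1 <- .seq_chars(seq1); ch2 <- .seq_chars(seq2)
  if (length(ch1) > 10 || length(ch2) > 10)
    stop("joint enumeration is guarded to lengths <= 10")
  S1 <- enumerate_structures(ch1, params)
  S2 <- enumerate_structures(ch2, params)
  best <- list(total_t = INF_TENTHS)
  best_cfg <- NULL
  empty_dom <- data.frame(seq = integer(0), start = integer(0), end = integer(0))
  for (x1 in S1) {
    if (is.na(x1$energy_t)) next
    for (x2 in S2) {
      if (is.na(x2$energy_t)) next
      P1 <- x1$pairs; P2 <- x2$pairs
      for (M in .enumerate_matchings(P1, P2)) {
        matched <- cbind(P1[M[, 1], 1], P1[M[, 1], 2], P2[M[, 2], 1], P2[M[, 2], 2])
        if (nrow(M) == 0) matched <- matrix(integer(0), 0, 4)
        dsets <- list(empty_dom)
        if (mode == "dynalign2") {
          iv1 <- .candidate_intervals(length(ch1), P1, M[, 1])
          iv2 <- .candidate_intervals(length(ch2), P2, M[, 2])
          sub1 <- .disjoint_subsets(iv1); sub2 <- .disjoint_subsets(iv2)
          dsets <- list()
          for (a in sub1) for (b in sub2) {
            df <- empty_dom
            for (x in a) df <- rbind(df, data.frame(seq = 1L, start = x[1], end = x[2]))
            for (x in b) df <- rbind(df, data.frame(seq = 2L, start = x[1], end = x[2]))
            dsets[[length(dsets) + 1L]] <- df
          }
        }
        for (D in dsets) {
          sc <- .score_config(ch1, ch2, P1, P2, matched, D, params, mode)
          if (is.null(sc) || sc$total_t >= INF_TENTHS) next
          if (sc$total_t < best$total_t) {
            best <- sc
            best_cfg <- list(pairs1 = P1, pairs2 = P2, matched = matched, domains = D)
          }
        }
      }
    }
  }
  if (is.null(best_cfg)) stop("no valid configuration found (unexpected)")
  c(list(energy_t = best$total_t, energy = from_tenths(best$total_t)),
    best_cfg, list(breakdown = best))
}
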