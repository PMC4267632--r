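# Synthetic homolog-pair fixtures.
#
# The generator emulates the structural variation seen between real ncRNA
# homologs that share a conserved core: compensatory mutations in paired
# positions, free mutations in loops, optional helix-length changes, and
# optionally a thermodynamically stable stem-loop domain planted in one
# sequence and absent from the other.

#' Describe a synthetic homolog-pair fixture
#'
#' @param seed integer seed; the same spec always yields the same fixture.
#' @param n_modules number of conserved hairpin modules in the core.
#' @param stem_len stem length (base pairs) of each core module; recycled.
#' @param loop_len hairpin loop length of each core module; recycled.
#' @param mut_rate per-pair probability of a compensatory mutation and
#'   per-loop-nucleotide probability of a point mutation in the homolog.
#' @param jitter number of core helices whose terminal pair is opened in
#'   the homolog (helix-length change).
#' @param insertion `NULL`, or `list(host =, stem =, loop =)`: plant a
#'   stem-loop of `stem` pairs and a `loop`-nt hairpin loop into the
#'   exterior linker of sequence `host` (1 or 2).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_modules = 2L, stem_len = 6L, loop_len = 5L,
                         mut_rate = 0.15, jitter = 0L,
                         insertion = list(host = 2L, stem = 5L, loop = 4L)) {
  if (!is.null(insertion)) {
    stopifnot(insertion$host %in% c(1L, 2L), insertion$stem >= 1L,
              insertion$loop >= 3L)
  }
  structure(list(seed = as.integer(seed), n_modules = as.integer(n_modules),
                 stem_len = as.integer(stem_len), loop_len = as.integer(loop_len),
                 mut_rate = mut_rate, jitter = as.integer(jitter),
                 insertion = insertion),
            class = "fixture_spec")
}

.draw_pair <- function(n) {
  # favor stable pairs so the conserved core is well determined
  sample(c("GC", "CG", "AU", "UA", "GU", "UG"), n, replace = TRUE,
         prob = c(0.34, 0.34, 0.13, 0.13, 0.03, 0.03))
}
.draw_loopbase <- function(n) {
  # A/C-rich to avoid accidental stable structure in single strands
  sample(c("A", "C", "U", "G"), n, replace = TRUE, prob = c(0.5, 0.25, 0.2, 0.05))
}

#' Generate a synthetic homolog pair with a reference common structure
#'
#' Builds a core of conserved hairpin modules separated by single-stranded
#' linkers, derives the homolog by compensatory/point mutation and optional
#' helix shortening, and (if requested) splices a stable stem-loop domain
#' into one sequence's exterior linker.  Planted insertions are self-checked
#' for thermodynamic stability (their hairpin folds below 0 kcal/mol under
#' the shipped bundle).
#'
#' @param spec a [fixture_spec()].
#' @param params bundle used for the stability self-check (defaults loaded
#'   if `NULL`).
#' @return list with `seq1`, `seq2` (strings), `ref` (a reference
#'   `common_structure` carrying conserved pairs, the planted domain
#'   interval and the reference alignment), and `spec`.
#' @export
make_fixture <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(params)) params <- load_params()
  set.seed(spec$seed)
  nm <- spec$n_modules
  stems <- rep_len(spec$stem_len, nm)
  loops <- rep_len(spec$loop_len, nm)
  if (!is.null(spec$insertion) && spec$insertion$stem > min(stems) + 20L)
    stop("unsatisfiable fixture spec: inserted stem much longer than the core modules")

  linkers <- sample(4:7, nm + 1L, replace = TRUE) # tails + between-module linkers
  # lay out sequence 1 and the core pair list
  chars <- character(0)
  pairs <- matrix(integer(0), 0, 2)
  pair_types <- character(0)
  pos <- 0L
  add <- function(x) { chars <<- c(chars, x); pos <<- pos + length(x) }
  add(.draw_loopbase(linkers[1]))
  for (m in seq_len(nm)) {
    st <- stems[m]
    tys <- .draw_pair(st)
    open_at <- pos
    add(vapply(tys, function(t) substr(t, 1, 1), character(1)))
    add(.draw_loopbase(loops[m]))
    for (x in st:1) add(substr(tys[x], 2, 2))
    close_at <- pos
    for (x in seq_len(st))
      pairs <- rbind(pairs, c(open_at + x, close_at - x + 1L))
    pair_types <- c(pair_types, tys)
    add(.draw_loopbase(linkers[m + 1L]))
  }
  seq1 <- chars
  n1 <- length(seq1)

  # homolog: compensatory + point mutations, optional helix shortening
  seq2 <- seq1
  keep2 <- rep(TRUE, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (stats::runif(1) < spec$mut_rate) {
      ty <- .draw_pair(1)
      seq2[pairs[r, 1]] <- substr(ty, 1, 1)
      seq2[pairs[r, 2]] <- substr(ty, 2, 2)
    }
  }
  unpaired <- setdiff(seq_len(n1), c(pairs))
  mut <- unpaired[stats::runif(length(unpaired)) < spec$mut_rate]
  if (length(mut)) seq2[mut] <- .draw_loopbase(length(mut))
  drop2 <- integer(0)
  if (spec$jitter > 0L) {
    # open the outermost pair of `jitter` modules in the homolog
    outer_rows <- cumsum(stems) - stems + 1L
    pick <- utils::head(outer_rows, spec$jitter)
    for (r in pick) {
      drop2 <- c(drop2, pairs[r, 1], pairs[r, 2])
      keep2[r] <- FALSE
    }
  }
  # delete jittered nucleotides from seq2 so helix length truly changes
  keep_pos2 <- setdiff(seq_len(n1), drop2)
  map12 <- match(seq_len(n1), keep_pos2) # seq1 pos -> seq2 pos (pre-insertion)
  seq2 <- seq2[keep_pos2]

  # planted insertion
  dom <- NULL
  ins_pairs_host <- matrix(integer(0), 0, 2)
  if (!is.null(spec$insertion)) {
    st <- spec$insertion$stem; lp <- spec$insertion$loop
    tys <- sample(c("GC", "CG"), st, replace = TRUE)
    frag <- c(vapply(tys, function(t) substr(t, 1, 1), character(1)),
              .draw_loopbase(lp),
              rev(vapply(tys, function(t) substr(t, 2, 2), character(1))))
    sfrag <- fold_single(frag, params)
    if (sfrag$mfe >= 0) stop("planted insertion failed the stability self-check")
    host <- spec$insertion$host
    # insertion point: middle of the central linker of the host
    mid_linker_start1 <- linkers[1] + sum(2L * stems[1] + loops[1]) # end of module 1 in seq1
    ip1 <- mid_linker_start1 + max(2L, linkers[2] %/% 2L) # after this seq1 position
    if (host == 1L) {
      at <- ip1
      seqh <- append(seq1, frag, after = at)
      dom <- data.frame(seq = 1L, start = at + 1L, end = at + length(frag))
      for (x in seq_len(st))
        ins_pairs_host <- rbind(ins_pairs_host,
                                c(at + x, at + length(frag) - x + 1L))
      seq1 <- seqh
    } else {
      at <- map12[ip1]
      stopifnot(!is.na(at))
      seqh <- append(seq2, frag, after = at)
      dom <- data.frame(seq = 2L, start = at + 1L, end = at + length(frag))
      for (x in seq_len(st))
        ins_pairs_host <- rbind(ins_pairs_host,
                                c(at + x, at + length(frag) - x + 1L))
      seq2 <- seqh
    }
  }

  # reference structure and alignment in final coordinates
  shift1 <- function(p) {
    if (!is.null(dom) && dom$seq == 1L) p + ifelse(p >= dom$start, dom$end - dom$start + 1L, 0L) else p
  }
  shift2 <- function(p) {
    if (!is.null(dom) && dom$seq == 2L) p + ifelse(p >= dom$start, dom$end - dom$start + 1L, 0L) else p
  }
  n2 <- length(seq2)
  matched <- matrix(integer(0), 0, 4)
  pairs1 <- matrix(integer(0), 0, 2)
  pairs2 <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(pairs))) {
    i1 <- shift1(pairs[r, 1]); j1 <- shift1(pairs[r, 2])
    pairs1 <- rbind(pairs1, c(i1, j1))
    if (keep2[r]) {
      k2 <- shift2(map12[pairs[r, 1]]); l2 <- shift2(map12[pairs[r, 2]])
      pairs2 <- rbind(pairs2, c(k2, l2))
      matched <- rbind(matched, c(i1, j1, k2, l2))
    }
  }
  if (nrow(ins_pairs_host)) {
    if (dom$seq == 1L) pairs1 <- rbind(pairs1, ins_pairs_host)
    else pairs2 <- rbind(pairs2, ins_pairs_host)
  }
  aln1 <- integer(length(seq1)); aln2 <- integer(n2)
  for (p1 in seq_len(n1)) {
    p2 <- map12[p1]
    if (is.na(p2)) next
    a <- shift1(p1); b <- shift2(p2)
    aln1[a] <- b; aln2[b] <- a
  }
  # inserted-domain nucleotides are aligned to nothing
  if (!is.null(dom)) {
    if (dom$seq == 1L) { aln2[aln1[dom$start:dom$end]] <- 0L; aln1[dom$start:dom$end] <- 0L }
    else { aln1[aln2[dom$start:dom$end]] <- 0L; aln2[dom$start:dom$end] <- 0L }
  }
  domains <- if (is.null(dom)) data.frame(seq = integer(0), start = integer(0), end = integer(0)) else dom
  colnames(pairs1) <- colnames(pairs2) <- c("i", "j")
  colnames(matched) <- c("i", "j", "k", "l")
  ref <- structure(list(seq1 = seq1, seq2 = seq2, pairs1 = pairs1, pairs2 = pairs2,
                        matched = matched, domains = domains,
                        aln1 = aln1, aln2 = aln2, mode = "dynalign2"),
                   class = "common_structure")
  ref$n_gap <- sum(aln1 == 0L & !.in_domain_mask(ref, 1L)) +
    sum(aln2 == 0L & !.in_domain_mask(ref, 2L))
  list(seq1 = paste(seq1, collapse = ""), seq2 = paste(seq2, collapse = ""),
       ref = ref, spec = spec)
}
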