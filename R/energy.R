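# Nearest-neighbor motif energies (R reference implementation).
#
# These functions are the package's authoritative definition of the energy
# model: the enumeration oracles and the independent rescorer are built on
# them, and the C++ dynamic-programming core mirrors them.  All internal
# arithmetic is on the integer tenths-of-kcal/mol grid; exported functions
# return kcal/mol with `Inf` as the forbidden-state sentinel.

.seq_chars <- function(seq) {
  if (length(seq) == 1L && is.character(seq)) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(seq)
  seq[seq == "T"] <- "U"
  bad <- which(!seq %in% BASE_LEVELS)
  if (length(bad))
    stop("invalid nucleotide '", seq[bad[1]], "' at position ", bad[1])
  seq
}

#' Is a base pair canonical?
#'
#' Canonical pairs are the Watson-Crick pairs AU/UA and GC/CG plus the GU/UG
#' wobble pairs.
#'
#' @param b1,b2 single nucleotides (`A`, `C`, `G`, `U`; `T` is accepted and
#'   read as `U`).
#' @return `TRUE` exactly for AU, UA, GC, CG, GU, UG.
#' @export
is_canonical <- function(b1, b2) {
  b1 <- .seq_chars(b1); b2 <- .seq_chars(b2)
  paste0(b1, b2) %in% PAIR_LEVELS
}

.pair_name <- function(seq, i, j) paste0(seq[i], seq[j])

# map internal tenths to kcal/mol with the Inf sentinel restored
.as_kcal <- function(t) if (t >= INF_TENTHS) Inf else from_tenths(t)

# Integer-tenths end penalty; stops on non-canonical pairs.
.end_penalty_t <- function(seq, i, j, params) {
  pr <- .pair_name(seq, i, j)
  if (!pr %in% PAIR_LEVELS) stop("non-canonical pair ", pr, " at (", i, ",", j, ")")
  if (pr %in% c("AU", "UA", "GU", "UG")) params$au_gu_end_penalty else 0L
}

#' Terminal AU/GU helix-end penalty
#'
#' The destabilizing penalty applied when a helix ends in an A-U or G-U pair.
#'
#' @param seq RNA sequence (string or character vector).
#' @param i,j 1-based positions of the pair.
#' @param params an [load_params()] bundle.
#' @return energy in kcal/mol (0 for G-C/C-G ends).
#' @export
end_penalty <- function(seq, i, j, params) {
  from_tenths(.end_penalty_t(.seq_chars(seq), i, j, params))
}

# Loop initiation with log extrapolation past the tabled lengths.
.loop_init_t <- function(tab, n, params) {
  n_max <- as.integer(names(tab)[length(tab)])
  n_min <- as.integer(names(tab)[1])
  if (n < n_min) return(INF_TENTHS)
  if (n <= n_max) return(tab[[as.character(n)]])
  tab[[as.character(n_max)]] +
    as.integer(round(params$log_extrapolation * log(n / n_max)))
}

.hairpin_t <- function(seq, i, j, params) {
  size <- j - i - 1L
  if (size < params$min_hairpin) return(INF_TENTHS)
  .loop_init_t(params$hairpin_init, size, params) + .end_penalty_t(seq, i, j, params)
}

#' Hairpin loop energy
#'
#' Loop initiation by length (log-extrapolated beyond the table) plus the
#' terminal AU/GU penalty of the closing pair.  Loops shorter than
#' `min_hairpin` return `Inf` rather than raising, so minimization over
#' candidate pairs is unaffected.
#'
#' @inheritParams end_penalty
#' @return energy in kcal/mol, or `Inf`.
#' @export
hairpin_energy <- function(seq, i, j, params) {
  .as_kcal(.hairpin_t(.seq_chars(seq), i, j, params))
}

# Motif energy in tenths: closing pair (m,p), inner pair (n,q), m < n < q < p.
# Dispatch: stack / bulge / internal loop.  Terminal AU/GU penalties are
# charged on both closing pairs for internal loops and bulges of length >= 2;
# single-nucleotide bulges keep the stack term and carry no end penalties;
# stacks carry none (standard convention).
.motif_t <- function(seq, m, n, p, q, params) {
  if (!(m < n && n < q && q < p)) stop("motif positions must satisfy m < n < q < p")
  pr_out <- .pair_name(seq, m, p); pr_in <- .pair_name(seq, n, q)
  if (!pr_out %in% PAIR_LEVELS) stop("non-canonical pair ", pr_out)
  if (!pr_in %in% PAIR_LEVELS) return(INF_TENTHS)
  s5 <- n - m - 1L
  s3 <- p - q - 1L
  cap <- params$max_internal_side
  if (n - m > cap || p - q > cap) return(INF_TENTHS)
  if (s5 == 0L && s3 == 0L) return(params$stack[pr_out, pr_in])
  if (s5 == 0L || s3 == 0L) {
    len <- s5 + s3
    init <- .loop_init_t(params$bulge_init, len, params)
    if (len == 1L) return(init + params$stack[pr_out, pr_in])
    return(init + .end_penalty_t(seq, m, p, params) + .end_penalty_t(seq, n, q, params))
  }
  init <- .loop_init_t(params$internal_init, s5 + s3, params)
  asym <- min(params$asymmetry_max,
              as.integer(abs(s5 - s3)) * params$asymmetry_coef)
  init + as.integer(asym) +
    .end_penalty_t(seq, m, p, params) + .end_penalty_t(seq, n, q, params)
}

#' Internal loop / bulge / stack motif energy
#'
#' Energy of the two-pair motif closed by pairs `m`-`p` (outer) and `n`-`q`
#' (inner), with `m < n < q < p`.  Dispatches on the unpaired side sizes:
#' a stack when both sides are empty, a bulge when exactly one side is
#' empty, an internal loop otherwise (size initiation plus an asymmetry term
#' capped at `asymmetry_max`, plus AU/GU end penalties on both closing
#' pairs).  A side larger than `max_internal_side` returns `Inf`.
#'
#' @inheritParams end_penalty
#' @param m,n,p,q pair positions, `m < n < q < p`; `(m,p)` must be canonical.
#' @return energy in kcal/mol, or `Inf`.
#' @export
motif_energy <- function(seq, m, n, p, q, params) {
  .as_kcal(.motif_t(.seq_chars(seq), m, n, p, q, params))
}

#' Base-pair stack energy
#'
#' The stacking contribution of pair `m`-`p` on `(m+1)`-`(p-1)`; identical by
#' definition to `motif_energy(seq, m, m+1, p, p-1, params)`.
#'
#' @inheritParams end_penalty
#' @param m,p outer pair positions.
#' @return energy in kcal/mol, or `Inf` if the inner pair is non-canonical.
#' @export
stack_energy <- function(seq, m, p, params) {
  seq <- .seq_chars(seq)
  .as_kcal(.motif_t(seq, m, m + 1L, p, p - 1L, params))
}
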