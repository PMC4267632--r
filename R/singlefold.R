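# Single-sequence free-energy minimization and the allowed-pair filter.

.seq_codes <- function(seq) {
  ch <- .seq_chars(seq)
  match(ch, BASE_LEVELS) - 1L
}

.params_for_cpp <- function(params) {
  stopifnot(inherits(params, "energy_params"))
  unclass(params)
}

#' Fold a single RNA sequence
#'
#' Zuker-style free-energy minimization under the package's motif set
#' (hairpins; stacks, bulges and internal loops with sides up to
#' `max_internal_side`; linear-model multibranch loops).  Besides the usual
#' `v_s` array (fragment closed by a pair), two auxiliary arrays required by
#' the inserted-domain recursions of the joint model are produced:
#' `w_branch_s`, the minimum energy of a fragment placed as one or more
#' branches of a multibranch loop (charging the per-branch penalty, helix-end
#' penalties, and the per-unpaired-nucleotide multibranch cost), and
#' `w_ext_s`, the minimum energy of a fragment placed in an exterior loop
#' (branches pay only helix-end penalties; unpaired nucleotides are free).
#'
#' @param seq RNA sequence (string or character vector over A/C/G/U; T read
#'   as U).
#' @param params an [load_params()] bundle.
#' @return an object of class `single_fold`: integer-tenths matrices `v_s`,
#'   `w_branch_s`, `w_ext_s` (position i,j at `[i+1, j+1]` of an
#'   (N+1)x(N+1) matrix, i.e. 1-based positions index rows/columns 2..N+1
#'   minus one -- use the accessor [sf_v()]), exterior prefix/suffix vectors,
#'   `mfe` (kcal/mol) and the sequence.
#' @export
fold_single <- function(seq, params) {
  ch <- .seq_chars(seq)
  if (length(ch) == 0L) {
    out <- list(seq = character(0), v = matrix(INF_TENTHS, 1, 1),
                wb = matrix(INF_TENTHS, 1, 1), we = matrix(INF_TENTHS, 1, 1),
                w5 = 0L, w3 = c(0L, 0L), mfe_t = 0L, mfe = 0,
                params = params)
    class(out) <- "single_fold"
    return(out)
  }
  res <- .fold_single_cpp(.seq_codes(ch), .params_for_cpp(params))
  out <- list(seq = ch, v = res$v, wb = res$wb, we = res$we,
              w5 = res$w5, w3 = res$w3, mfe_t = res$mfe,
              mfe = from_tenths(res$mfe), params = params)
  class(out) <- "single_fold"
  out
}

#' Accessors for `single_fold` arrays
#'
#' Return the integer-tenths energy of a fragment `[i, j]` from the `v_s`,
#' `w_branch_s` or `w_ext_s` array (positions 1-based); `NA` encodes the
#' forbidden-state sentinel.
#'
#' @param sf a [fold_single()] result.
#' @param i,j fragment bounds.
#' @export
sf_v <- function(sf, i, j) {
  t <- sf$v[i + 1L, j + 1L]
  if (t >= INF_TENTHS) NA_integer_ else t
}
#' @rdname sf_v
#' @export
sf_wb <- function(sf, i, j) {
  t <- sf$wb[i + 1L, j + 1L]
  if (t >= INF_TENTHS) NA_integer_ else t
}
#' @rdname sf_v
#' @details `sf_we` returns the exterior-loop value of the fragment: 0 when
#'   leaving it entirely unpaired is best (exterior nucleotides are free),
#'   otherwise the best branched exterior arrangement.  The stored `we`
#'   matrix keeps the branched-only value, which is what the joint model's
#'   inserted-domain recursions consume (a domain must fold).
#' @export
sf_we <- function(sf, i, j) {
  min(sf$we[i + 1L, j + 1L], 0L)
}

#' @export
print.single_fold <- function(x, ...) {
  cat("<single_fold> ", length(x$seq), " nt, MFE ",
      sprintf("%.1f", x$mfe), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Filter candidate base pairs by suboptimal-energy window
#'
#' A pair (i,j) is retained if the best whole-sequence structure containing
#' it -- computed by an interior + exterior decomposition, i.e.
#' `v_s(i,j)` plus the exterior closure of the complement -- lies within
#' `window_percent` of the minimum free energy.  `window_percent = 1`
#' disables filtering (every pair with finite `v_s` is retained); 0 keeps
#' only pairs found in some MFE structure.
#'
#' @inheritParams fold_single
#' @param tables a [fold_single()] result for `seq` (consistency check).
#' @param window_percent fraction of |MFE|, in `[0, 1]`.
#' @return logical matrix, `[i, j]` upper-triangle entries `TRUE` for
#'   allowed pairs.
#' @export
filter_pairs <- function(seq, tables, window_percent) {
  ch <- .seq_chars(seq)
  if (!identical(ch, tables$seq)) stop("tables were computed for a different sequence")
  if (window_percent < 0) stop("window_percent must be >= 0")
  m <- .filter_pairs_cpp(.seq_codes(ch), .params_for_cpp(tables$params),
                         window_percent)
  m[-1, -1, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: filter with explicit params (avoids re-deriving from tables).
.filter_pairs_t <- function(seq, params, window_percent) {
  ch <- .seq_chars(seq)
  m <- .filter_pairs_cpp(.seq_codes(ch), .params_for_cpp(params), window_percent)
  m[-1, -1, drop = FALSE]
}

#' One minimum-free-energy structure of a single sequence
#'
#' @inheritParams fold_single
#' @return integer vector `p` with `p[i]` the partner of position i (0 if
#'   unpaired).
#' @export
mfe_structure <- function(seq, params) {
  ch <- .seq_chars(seq)
  if (length(ch) == 0L) return(integer(0))
  .trace_single_cpp(.seq_codes(ch), .params_for_cpp(params))
}
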