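# Joint fold-and-align: fill, traceback, end-to-end prediction.

.mode_code <- function(mode) {
  mode <- match.arg(mode, c("dynalign2", "no_insert", "original"))
  c(original = 0L, no_insert = 1L, dynalign2 = 2L)[[mode]]
}

#' Fill the joint dynamic-programming arrays
#'
#' Computes the 4D arrays V (fragments closed by an aligned pair of base
#' pairs) and W (aligned multibranch-branch fragments) and the 2D exterior
#' arrays W5/W3 for two sequences under a diagonal alignment band, with the
#' move set selected by `mode`:
#' \describe{
#'   \item{original}{conserved motifs only: hairpin, internal/stack,
#'     multibranch, bifurcation, exterior extension.}
#'   \item{no_insert}{adds the stem-extension and motif-insertion terms (an
#'     internal loop in one homolog aligned to consecutive stacked pairs in
#'     the other; stacks/internal/bulge loops inserted in one homolog).}
#'   \item{dynalign2}{additionally allows inserted folding domains, scored
#'     with an affine opening + per-nucleotide elongation penalty and routed
#'     through the single-sequence branch/exterior arrays.}
#' }
#'
#' @param seq1,seq2 RNA sequences.
#' @param singles1,singles2 [fold_single()] results for the two sequences.
#' @param band an [make_band()] object.
#' @param params an [load_params()] bundle.
#' @param mode one of `"dynalign2"`, `"no_insert"`, `"original"`.
#' @param window_percent pair-filter window passed to [filter_pairs()]
#'   (default 1 = no filtering).
#' @return a `dp_tables` object holding the joint optimum (`energy`,
#'   kcal/mol), the `W3(1,1)` cross-check, and the traced optimal solution.
#' @export
fill <- function(seq1, seq2, singles1, singles2, band, params,
                 mode = c("dynalign2", "no_insert", "original"),
                 window_percent = 1) {
  ch1 <- .seq_chars(seq1); ch2 <- .seq_chars(seq2)
  if (!identical(ch1, singles1$seq) || !identical(ch2, singles2$seq))
    stop("single-sequence tables do not match the input sequences")
  if (band$N1 != length(ch1) || band$N2 != length(ch2))
    stop("band was built for different sequence lengths")
  mcode <- .mode_code(match.arg(mode))
  al1 <- .filter_pairs_cpp(.seq_codes(ch1), .params_for_cpp(params), window_percent)
  al2 <- .filter_pairs_cpp(.seq_codes(ch2), .params_for_cpp(params), window_percent)
  res <- .joint_fill_cpp(.seq_codes(ch1), .seq_codes(ch2),
                         .params_for_cpp(params), band$d, mcode,
                         singles1$wb, singles2$wb, singles1$we, singles2$we,
                         al1, al2, TRUE)
  if (is.na(res$energy))
    stop("no finite joint optimum; the band is degenerate for these inputs")
  out <- list(seq1 = ch1, seq2 = ch2, band = band, params = params,
              mode = match.arg(mode), window_percent = window_percent,
              energy_t = res$energy, w3_11_t = res$w3_11,
              energy = from_tenths(res$energy),
              w3_11 = from_tenths(res$w3_11),
              stats = list(n_allowed1 = sum(al1), n_allowed2 = sum(al2),
                           band_d = band$d,
                           n_cells = as.numeric(length(ch1))^2 *
                             (band$d + 1)^2 / 2),
              trace = res$trace)
  class(out) <- "dp_tables"
  out
}

#' @export
print.dp_tables <- function(x, ...) {
  cat("<dp_tables> mode=", x$mode, " band d=", x$band$d,
      " optimum ", sprintf("%.1f", x$energy), " kcal/mol\n", sep = "")
  cat("  candidate pairs ", x$stats$n_allowed1, " + ", x$stats$n_allowed2,
      ", ~", format(x$stats$n_cells, big.mark = ","), " banded cells\n", sep = "")
  invisible(x)
}

.pairs_from_partner <- function(p) {
  i <- which(p > seq_along(p))
  cbind(i = i, j = p[i])
}

#' Extract the optimal common structure from filled tables
#'
#' Converts the traced optimum into a `common_structure`: per-sequence pair
#' lists, the conserved-pair alignment, the full nucleotide-level alignment
#' used for gap counting, inserted-domain intervals, and the energy
#' breakdown recomputed by the independent rescorer ([total_energy()]).  A
#' disagreement between the rescored total and the dynamic-programming
#' optimum raises an internal-consistency error.
#'
#' @param tables a [fill()] result.
#' @return an object of class `common_structure`.
#' @export
traceback_structure <- function(tables) {
  stopifnot(inherits(tables, "dp_tables"))
  tr <- tables$trace
  if (is.null(tr)) stop("tables carry no trace")
  dm <- tr$domains
  domains <- data.frame(seq = integer(0), start = integer(0), end = integer(0))
  if (nrow(dm)) {
    domains <- data.frame(seq = dm[, 1], start = dm[, 2], end = dm[, 3])
    domains <- domains[order(domains$seq, domains$start), , drop = FALSE]
    rownames(domains) <- NULL
  }
  matched <- tr$matched
  colnames(matched) <- c("i", "j", "k", "l")
  cs <- list(
    seq1 = tables$seq1, seq2 = tables$seq2,
    pairs1 = .pairs_from_partner(tr$pair1of),
    pairs2 = .pairs_from_partner(tr$pair2of),
    matched = matched,
    domains = domains,
    aln1 = tr$aln1, aln2 = tr$aln2,
    mode = tables$mode
  )
  class(cs) <- "common_structure"
  ins1 <- .in_domain_mask(cs, 1L); ins2 <- .in_domain_mask(cs, 2L)
  cs$n_gap <- sum(cs$aln1 == 0L & !ins1) + sum(cs$aln2 == 0L & !ins2)
  br <- total_energy(cs, tables$seq1, tables$seq2, tables$params)
  if (br$total_t != tables$energy_t)
    stop("internal inconsistency: rescored total ", br$total_t,
         " (tenths) != DP optimum ", tables$energy_t)
  cs$energy <- br
  cs
}

.in_domain_mask <- function(cs, which_seq) {
  n <- if (which_seq == 1L) length(cs$seq1) else length(cs$seq2)
  m <- logical(n)
  dd <- cs$domains[cs$domains$seq == which_seq, , drop = FALSE]
  if (nrow(dd)) for (r in seq_len(nrow(dd))) m[dd$start[r]:dd$end[r]] <- TRUE
  m
}

#' @export
print.common_structure <- function(x, ...) {
  cat("<common_structure> ", length(x$seq1), " + ", length(x$seq2), " nt, ",
      nrow(x$pairs1), "/", nrow(x$pairs2), " pairs (",
      nrow(x$matched), " conserved), ", x$n_gap, " gaps, ",
      nrow(x$domains), " inserted domain(s)\n", sep = "")
  if (!is.null(x$energy))
    cat("  total ", sprintf("%.1f", x$energy$total), " kcal/mol  (dG1 ",
        sprintf("%.1f", x$energy$dg1), ", dG2 ", sprintf("%.1f", x$energy$dg2),
        ", gaps ", sprintf("%.1f", x$energy$gap_total), ", domains ",
        sprintf("%.1f", x$energy$domain_total), ")\n", sep = "")
  invisible(x)
}

#' Predict the common structure of two RNA homologs
#'
#' End-to-end composition: fold each sequence alone, filter candidate pairs,
#' build the alignment band, fill the joint arrays, and trace the optimal
#' common structure.
#'
#' @param seq1,seq2 RNA sequences.
#' @param params an [load_params()] bundle (defaults loaded if `NULL`).
#' @param mode move set, see [fill()].
#' @param band_width band width `d`; default [default_band_width()].
#' @param window_percent pair-filter window (default 0.2: candidate pairs
#'   must appear in some single-sequence structure within 20% of its MFE,
#'   which accelerates the joint fill substantially and in practice does
#'   not change the optimum; set to 1 to disable).
#' @return a `common_structure`; the filled tables are attached as
#'   attribute `"tables"`.
#' @export
predict_common <- function(seq1, seq2, params = NULL,
                           mode = c("dynalign2", "no_insert", "original"),
                           band_width = NULL, window_percent = 0.2) {
  if (is.null(params)) params <- load_params()
  mode <- match.arg(mode)
  ch1 <- .seq_chars(seq1); ch2 <- .seq_chars(seq2)
  if (is.null(band_width)) band_width <- default_band_width(length(ch1), length(ch2))
  s1 <- fold_single(ch1, params); s2 <- fold_single(ch2, params)
  band <- make_band(length(ch1), length(ch2), band_width)
  tb <- fill(ch1, ch2, s1, s2, band, params, mode, window_percent)
  cs <- traceback_structure(tb)
  attr(cs, "tables") <- tb
  cs
}
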