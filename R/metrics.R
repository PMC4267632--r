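# Accuracy evaluation: slip-tolerant sensitivity/PPV, family pooling,
# inserted-domain-restricted metrics, and a paired one-tailed t-test.

.pair_key <- function(p) paste(p[, 1], p[, 2])

#' Does a predicted pair match a known pair?
#'
#' In flexible (slip-tolerant) mode a predicted pair i-j is correct if i-j,
#' (i+1)-j, (i-1)-j, i-(j-1) or i-(j+1) is in the known set; strict mode
#' requires the exact pair.
#'
#' @param pred length-2 vector (i, j).
#' @param known 2-column matrix of known pairs.
#' @param strict logical.
#' @return `TRUE`/`FALSE`.
#' @export
pair_matches <- function(pred, known, strict = FALSE) {
  if (nrow(known) == 0) return(FALSE)
  keys <- .pair_key(known)
  i <- pred[1]; j <- pred[2]
  cand <- if (strict) paste(i, j)
          else c(paste(i, j), paste(i + 1, j), paste(i - 1, j),
                 paste(i, j - 1), paste(i, j + 1))
  any(cand %in% keys)
}

.count_correct <- function(pred, known, strict) {
  if (nrow(pred) == 0) return(0L)
  sum(vapply(seq_len(nrow(pred)), function(r)
    pair_matches(pred[r, ], known, strict), logical(1)))
}

#' Sensitivity and PPV for one sequence pair
#'
#' Counts are pooled over the two sequences of the pair: sensitivity is
#' correctly predicted / known pairs, PPV is correctly predicted /
#' predicted pairs.  A zero denominator yields `NA` (excluded from pooling
#' numerators and denominators).
#'
#' @param pred1,pred2 predicted pair matrices for the two sequences.
#' @param known1,known2 reference pair matrices.
#' @param strict exact matching if `TRUE`, else the slip rule.
#' @return list with `sensitivity`, `ppv` and the raw counts.
#' @export
score_pair <- function(pred1, pred2, known1, known2, strict = FALSE) {
  correct_sens <- .count_correct(known1, pred1, strict) +
    .count_correct(known2, pred2, strict)
  correct_ppv <- .count_correct(pred1, known1, strict) +
    .count_correct(pred2, known2, strict)
  n_known <- nrow(known1) + nrow(known2)
  n_pred <- nrow(pred1) + nrow(pred2)
  list(sensitivity = if (n_known) correct_sens / n_known else NA_real_,
       ppv = if (n_pred) correct_ppv / n_pred else NA_real_,
       correct_known = correct_sens, correct_pred = correct_ppv,
       n_known = n_known, n_pred = n_pred)
}

#' Pool per-pair counts into family rates
#'
#' The pooled rate is the ratio of summed counts over all sequence pairs,
#' not the mean of per-pair ratios.
#'
#' @param reports list of [score_pair()] results.
#' @return list with pooled `sensitivity` and `ppv`.
#' @export
pool_family <- function(reports) {
  if (length(reports) == 0) stop("no reports to pool")
  ck <- sum(vapply(reports, `[[`, numeric(1), "correct_known"))
  cp <- sum(vapply(reports, `[[`, numeric(1), "correct_pred"))
  nk <- sum(vapply(reports, `[[`, numeric(1), "n_known"))
  np <- sum(vapply(reports, `[[`, numeric(1), "n_pred"))
  list(sensitivity = if (nk) ck / nk else NA_real_,
       ppv = if (np) cp / np else NA_real_,
       n_known = nk, n_pred = np)
}

#' Locate inserted domains from reference structures and alignment
#'
#' A maximal unaligned interval of one sequence counts as an inserted
#' domain when it contains at least one base pair fully nested within it.
#'
#' @param known1,known2 reference pair matrices.
#' @param aln1,aln2 reference alignment maps (0 = unaligned).
#' @return data.frame with columns `seq`, `start`, `end`.
#' @export
find_inserted_domains <- function(known1, known2, aln1, aln2) {
  if (length(aln1) && max(aln1) > length(aln2)) stop("alignment exceeds sequence 2")
  if (length(aln2) && max(aln2) > length(aln1)) stop("alignment exceeds sequence 1")
  one <- function(s, aln, known) {
    out <- data.frame(seq = integer(0), start = integer(0), end = integer(0))
    r <- rle(aln == 0L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (x in which(r$values)) {
      a <- starts[x]; b <- ends[x]
      if (nrow(known) && any(known[, 1] >= a & known[, 2] <= b))
        out <- rbind(out, data.frame(seq = s, start = a, end = b))
    }
    out
  }
  rbind(one(1L, aln1, known1), one(2L, aln2, known2))
}

.pairs_in_intervals <- function(pairs, domains, s) {
  dd <- domains[domains$seq == s, , drop = FALSE]
  if (nrow(pairs) == 0 || nrow(dd) == 0) return(pairs[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(pairs)), function(r)
    any(pairs[r, 1] >= dd$start & pairs[r, 2] <= dd$end), logical(1))
  pairs[keep, , drop = FALSE]
}

#' Accuracy restricted to inserted-domain base pairs
#'
#' Sensitivity over pairs inside the known inserted domains; PPV over pairs
#' inside the predicted inserted-domain intervals (as recorded by the
#' traceback).  Zero denominators yield `NA`; in particular a move set that
#' cannot predict inserted pairs has sensitivity 0 and undefined PPV.
#'
#' @param pred a `common_structure` (prediction).
#' @param known1,known2 reference pair matrices.
#' @param known_domains reference domains ([find_inserted_domains()]).
#' @param strict matching mode.
#' @return list with `sensitivity`, `ppv` and counts.
#' @export
inserted_domain_accuracy <- function(pred, known1, known2, known_domains,
                                     strict = FALSE) {
  stopifnot(inherits(pred, "common_structure"))
  kd1 <- .pairs_in_intervals(known1, known_domains, 1L)
  kd2 <- .pairs_in_intervals(known2, known_domains, 2L)
  pd1 <- .pairs_in_intervals(pred$pairs1, pred$domains, 1L)
  pd2 <- .pairs_in_intervals(pred$pairs2, pred$domains, 2L)
  n_known <- nrow(kd1) + nrow(kd2)
  n_pred <- nrow(pd1) + nrow(pd2)
  correct_sens <- .count_correct(kd1, pred$pairs1, strict) +
    .count_correct(kd2, pred$pairs2, strict)
  correct_ppv <- .count_correct(pd1, known1, strict) +
    .count_correct(pd2, known2, strict)
  list(sensitivity = if (n_known) correct_sens / n_known else NA_real_,
       ppv = if (n_pred) correct_ppv / n_pred else NA_real_,
       correct_known = correct_sens, correct_pred = correct_ppv,
       n_known_inserted = n_known, n_pred_inserted = n_pred)
}

#' Paired one-tailed t-test on per-pair accuracies
#'
#' Tests the alternative that `mean(acc_a - acc_b) > 0` using the paired
#' t statistic with n-1 degrees of freedom.  Degenerate inputs (zero
#' variance of the differences) return p = 0.5 for zero mean, 0 for a
#' positive mean and 1 for a negative mean.
#'
#' @param acc_a,acc_b equal-length numeric vectors (length >= 2), paired by
#'   sequence pair.
#' @return one-tailed p-value.
#' @export
paired_one_tailed_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("paired vectors differ in length")
  if (length(acc_a) < 2) stop("need at least two pairs")
  d <- acc_a - acc_b
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  tstat <- mean(d) / (s / sqrt(length(d)))
  stats::pt(tstat, df = length(d) - 1, lower.tail = FALSE)
}
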