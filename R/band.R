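# Diagonal alignment band.

#' Construct a diagonal alignment band
#'
#' Restricts the joint dynamic program to alignment cut points `(i, k)` with
#' `|k - i * N2 / N1| <= d/2`.  Membership is evaluated on the exact rational
#' inequality `|2 (k N1 - i N2)| <= d N1`, which is symmetric under
#' `(i, k) -> (N1 - i, N2 - k)` and always contains `(0, 0)` and
#' `(N1, N2)`.  A width too small to reach the endpoints
#' (`d < 2 |N1 - N2|`) is widened with a warning.
#'
#' @param N1,N2 sequence lengths (positive).
#' @param d band width in nucleotides (even).
#' @return an object of class `alignment_band` with elements `N1`, `N2`,
#'   `d`, and `contains(i, k)`.
#' @export
make_band <- function(N1, N2, d) {
  if (N1 <= 0 || N2 <= 0) stop("sequence lengths must be positive")
  N1 <- as.integer(N1); N2 <- as.integer(N2)
  d <- as.integer(d)
  need <- 2L * abs(N1 - N2)
  if (d < need) {
    warning("band width ", d, " cannot reach the alignment endpoints; widened to ", need)
    d <- need
  }
  if (d %% 2L == 1L) d <- d + 1L
  N1 <- as.integer(N1); N2 <- as.integer(N2)
  contains <- function(i, k) {
    abs(2 * (as.numeric(k) * N1 - as.numeric(i) * N2)) <= as.numeric(d) * N1
  }
  structure(list(N1 = N1, N2 = N2, d = d, contains = contains),
            class = "alignment_band")
}

#' Default band width
#'
#' `max(10, 0.2 * max(N1, N2))`, rounded up to an even integer, then widened
#' if needed to reach the endpoints.
#'
#' @inheritParams make_band
#' @return even integer width.
#' @export
default_band_width <- function(N1, N2) {
  d <- max(10L, as.integer(ceiling(0.2 * max(N1, N2))))
  if (d %% 2L == 1L) d <- d + 1L
  max(d, 2L * abs(N1 - N2))
}

#' @export
print.alignment_band <- function(x, ...) {
  cat("<alignment_band> N1=", x$N1, " N2=", x$N2, " d=", x$d, "\n", sep = "")
  invisible(x)
}
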