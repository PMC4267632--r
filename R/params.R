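#' @useDynLib costruct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical pair vocabulary, in fixed order used throughout the package
# (R side and C++ side agree on these codes).
PAIR_LEVELS <- c("AU", "CG", "GC", "UA", "GU", "UG")
BASE_LEVELS <- c("A", "C", "G", "U")

#' Convert kcal/mol to the internal integer grid (tenths of kcal/mol)
#'
#' All free energies are carried internally as integer tenths of kcal/mol so
#' that dynamic-programming minima and ties are exact integer comparisons.
#'
#' @param x numeric energies in kcal/mol.
#' @return integer vector of tenths of kcal/mol.
#' @export
as_tenths <- function(x) as.integer(round(x * 10))

#' @rdname as_tenths
#' @param t integer tenths of kcal/mol.
#' @export
from_tenths <- function(t) as.numeric(t) / 10

# Sentinel used for forbidden states.  Large enough never to be optimal,
# small enough that sums of a handful of sentinels stay inside int range.
INF_TENTHS <- 100000000L

.param_scalar_names <- c(
  "au_gu_end_penalty", "mbl_closure", "mbl_branch", "mbl_unpaired",
  "gap_penalty", "domain_opening", "domain_elongation",
  "asymmetry_coef", "asymmetry_max", "log_extrapolation"
)
.param_int_names <- c("max_internal_side", "max_stackII_extension", "min_hairpin")

#' Load a nearest-neighbor energy parameter bundle
#'
#' Reads the plain-text bundle format shipped at
#' `system.file("extdata/params/default.params", package = "costruct")`.
#' The bundle holds the sequence-dependent stack table, length-dependent
#' hairpin/bulge/internal loop initiations, the linear multibranch-loop
#' constants, the terminal AU/GU helix-end penalty, and the three alignment
#' penalties of the joint model: the per-gap penalty (default 0.4 kcal/mol)
#' and the affine inserted-domain opening and per-nucleotide elongation
#' penalties (defaults 0.5 and 0.1 kcal/mol).
#'
#' @param source path to a parameter bundle, or `NULL` for the shipped
#'   defaults.
#' @return an object of class `energy_params`: a list of integer tables in
#'   tenths of kcal/mol plus integer size caps (`max_internal_side`,
#'   `max_stackII_extension`, `min_hairpin`).
#' @export
load_params <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "params", "default.params",
                          package = "costruct", mustWork = TRUE)
  }
  if (!file.exists(source)) stop("parameter bundle not found: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  section <- NA_character_
  scal <- list()
  stack <- matrix(NA_integer_, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  hairpin <- rep(NA_integer_, 28); names(hairpin) <- 3:30
  bulge <- rep(NA_integer_, 30); names(bulge) <- 1:30
  internal <- rep(NA_integer_, 29); names(internal) <- 2:30

  num_or_stop <- function(tok, where) {
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) stop("non-numeric entry '", tok, "' in table ", where)
    v
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- substr(ln, 2, nchar(ln) - 1)
      next
    }
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (is.na(section)) stop("entry before any section header: ", ln)
    switch(section,
      scalars = {
        if (length(toks) != 2) stop("malformed scalar line: ", ln)
        scal[[toks[1]]] <- num_or_stop(toks[2], "scalars")
      },
      stack = {
        if (length(toks) != 3) stop("malformed stack line: ", ln)
        if (!toks[1] %in% PAIR_LEVELS || !toks[2] %in% PAIR_LEVELS)
          stop("unknown pair in stack table: ", ln)
        stack[toks[1], toks[2]] <- as_tenths(num_or_stop(toks[3], "stack"))
      },
      hairpin_init = {
        hairpin[toks[1]] <- as_tenths(num_or_stop(toks[2], "hairpin_init"))
      },
      bulge_init = {
        bulge[toks[1]] <- as_tenths(num_or_stop(toks[2], "bulge_init"))
      },
      internal_init = {
        internal[toks[1]] <- as_tenths(num_or_stop(toks[2], "internal_init"))
      },
      stop("unknown section [", section, "]")
    )
  }

  for (nm in .param_scalar_names)
    if (is.null(scal[[nm]])) stop("format error: missing scalar '", nm, "'")
  for (nm in .param_int_names)
    if (is.null(scal[[nm]])) stop("format error: missing scalar '", nm, "'")
  if (anyNA(stack)) stop("format error: stack table incomplete")
  if (anyNA(hairpin)) stop("format error: hairpin_init table incomplete")
  if (anyNA(bulge)) stop("format error: bulge_init table incomplete")
  if (anyNA(internal)) stop("format error: internal_init table incomplete")

  p <- list(stack = stack, hairpin_init = hairpin, bulge_init = bulge,
            internal_init = internal)
  for (nm in .param_scalar_names) p[[nm]] <- as_tenths(scal[[nm]])
  for (nm in .param_int_names) p[[nm]] <- as.integer(scal[[nm]])

  if (p$gap_penalty < 0L || p$domain_opening < 0L || p$domain_elongation < 0L)
    stop("gap_penalty, domain_opening and domain_elongation must be >= 0")
  if (p$min_hairpin < 1L) stop("min_hairpin must be >= 1")
  class(p) <- "energy_params"
  p
}

#' Write a parameter bundle
#'
#' Serializes an `energy_params` object back to the plain-text bundle format;
#' `load_params(write_params(p, f))` reproduces `p` bit-exactly.
#'
#' @param params an `energy_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "energy_params"))
  fmt <- function(t) sprintf("%.1f", from_tenths(t))
  out <- c("[scalars]")
  for (nm in .param_scalar_names) out <- c(out, paste(nm, fmt(params[[nm]])))
  for (nm in .param_int_names) out <- c(out, paste(nm, params[[nm]]))
  out <- c(out, "", "[stack]")
  for (p1 in PAIR_LEVELS) for (p2 in PAIR_LEVELS)
    out <- c(out, paste(p1, p2, fmt(params$stack[p1, p2])))
  tab <- function(name, v) c("", paste0("[", name, "]"),
                             paste(names(v), fmt(v)))
  out <- c(out, tab("hairpin_init", params$hairpin_init),
           tab("bulge_init", params$bulge_init),
           tab("internal_init", params$internal_init))
  writeLines(out, path)
  invisible(path)
}

#' @export
print.energy_params <- function(x, ...) {
  cat("<energy_params> nearest-neighbor bundle (kcal/mol)\n")
  cat("  gap penalty        ", sprintf("%.1f", from_tenths(x$gap_penalty)), "\n")
  cat("  domain opening     ", sprintf("%.1f", from_tenths(x$domain_opening)), "\n")
  cat("  domain elongation  ", sprintf("%.1f", from_tenths(x$domain_elongation)), "/nt\n")
  cat("  AU/GU end penalty  ", sprintf("%.1f", from_tenths(x$au_gu_end_penalty)), "\n")
  cat("  multibranch        closure", sprintf("%.1f", from_tenths(x$mbl_closure)),
      " branch", sprintf("%.1f", from_tenths(x$mbl_branch)),
      " unpaired", sprintf("%.1f", from_tenths(x$mbl_unpaired)), "\n")
  invisible(x)
}
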