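# External representations: FASTA, CT, dot-bracket, pairwise alignment.

#' Structure record
#'
#' A minimal container tying a sequence to a pair list: `id`, `seq`
#' (character vector, U-alphabet), `pairs` (2-column 1-based matrix,
#' non-crossing, each index in at most one pair).
#'
#' @param id sequence identifier.
#' @param seq sequence (string or character vector).
#' @param pairs 2-column integer matrix (may have zero rows).
#' @return a `structure_record`.
#' @export
structure_record <- function(id, seq, pairs = matrix(integer(0), 0, 2)) {
  seq <- .seq_chars(seq)
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs)) {
    pairs <- cbind(i = pmin(pairs[, 1], pairs[, 2]),
                   j = pmax(pairs[, 1], pairs[, 2]))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  .build_tree(pairs, length(seq)) # validates range/crossing/duplicates
  structure(list(id = id, seq = seq, pairs = pairs), class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("<structure_record> ", x$id, ": ", length(x$seq), " nt, ",
      nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Case and T/U are normalized to the uppercase U-alphabet; ambiguity codes
#' are rejected with a position-specific message; duplicate ids and empty
#' files are errors.
#'
#' @param source path to a FASTA file.
#' @return named list of sequence strings.
#' @export
read_fasta <- function(source) {
  if (!file.exists(source)) stop("FASTA file not found: ", source)
  set <- Biostrings::readBStringSet(source)
  if (length(set) == 0) stop("empty FASTA file: ", source)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  out <- list()
  for (x in seq_along(set)) {
    ch <- toupper(strsplit(as.character(set[[x]]), "")[[1]])
    ch[ch == "T"] <- "U"
    bad <- which(!ch %in% BASE_LEVELS)
    if (length(bad))
      stop("sequence '", ids[x], "': invalid character '", ch[bad[1]],
           "' at position ", bad[1])
    out[[ids[x]]] <- paste(ch, collapse = "")
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named list or character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  out <- character(0)
  for (nm in names(seqs)) out <- c(out, paste0(">", nm), as.character(seqs[[nm]]))
  writeLines(out, path)
  invisible(path)
}

#' Read / write connectivity-table (CT) files
#'
#' Standard 6-column CT, 1-based, single structure.  `read_ct` rejects
#' out-of-range indices, asymmetric pairing and crossing pairs;
#' `write_ct(read_ct(f))` round-trips bit-exactly for files this package
#' writes.  The header line is `N  ENERGY = <kcal/mol>  <id>` (the energy
#' part is omitted when unknown); unknown header decorations are ignored on
#' read.
#'
#' @param source path to a CT file.
#' @return a `structure_record`.
#' @export
read_ct <- function(source) {
  if (!file.exists(source)) stop("CT file not found: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty CT file: ", source)
  hd <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(hd[1]))
  if (is.na(n) || n < 0) stop("malformed CT header: ", lines[1])
  id <- if (length(hd) > 1) hd[length(hd)] else "structure"
  if (length(lines) - 1 != n) stop("CT body has ", length(lines) - 1,
                                   " rows, header claims ", n)
  partner <- integer(n); seq <- character(n)
  for (x in seq_len(n)) {
    f <- strsplit(trimws(lines[x + 1]), "[[:space:]]+")[[1]]
    if (length(f) < 6) stop("malformed CT line ", x + 1)
    idx <- as.integer(f[1])
    if (is.na(idx) || idx != x) stop("CT line ", x + 1, ": index ", f[1],
                                     " out of order")
    seq[x] <- f[2]
    pr <- as.integer(f[5])
    if (is.na(pr) || pr < 0 || pr > n)
      stop("CT line ", x + 1, ": partner index ", f[5], " out of range")
    partner[x] <- pr
  }
  for (x in seq_len(n)) {
    if (partner[x] != 0 && partner[partner[x]] != x)
      stop("asymmetric pairing: ", x, " pairs ", partner[x], " but ",
           partner[x], " pairs ", partner[partner[x]])
    if (partner[x] == x) stop("position ", x, " pairs itself")
  }
  structure_record(id, seq, .pairs_from_partner(partner))
}

#' @rdname read_ct
#' @param record a `structure_record`.
#' @param path output path.
#' @param energy optional energy (kcal/mol) written in the header.
#' @export
write_ct <- function(record, path, energy = NULL) {
  stopifnot(inherits(record, "structure_record"))
  n <- length(record$seq)
  partner <- integer(n)
  if (nrow(record$pairs)) {
    partner[record$pairs[, 1]] <- record$pairs[, 2]
    partner[record$pairs[, 2]] <- record$pairs[, 1]
  }
  hdr <- if (is.null(energy)) paste(n, record$id)
         else paste(n, " ENERGY =", sprintf("%.1f", energy), " ", record$id)
  body <- vapply(seq_len(n), function(x)
    sprintf("%d %s %d %d %d %d", x, record$seq[x], x - 1L,
            if (x == n) 0L else x + 1L, partner[x], x), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write dot-bracket notation
#'
#' Single-level brackets (pseudoknot-free model).  `read_dotbracket`
#' accepts either a path to a file (`>id`, sequence line, structure line)
#' or the bracket string itself together with `seq`.
#'
#' @param source path or bracket string.
#' @param seq sequence (required when `source` is a bracket string).
#' @param id record id.
#' @return a `structure_record`.
#' @export
read_dotbracket <- function(source, seq = NULL, id = "structure") {
  if (is.null(seq)) {
    lines <- readLines(source, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3 || !startsWith(lines[1], ">"))
      stop("expected >id, sequence and structure lines")
    id <- sub("^>", "", lines[1])
    seq <- lines[2]
    db <- trimws(lines[3])
  } else db <- source
  ch <- strsplit(db, "")[[1]]
  sq <- .seq_chars(seq)
  if (length(ch) != length(sq))
    stop("structure length ", length(ch), " != sequence length ", length(sq))
  stk <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (x in seq_along(ch)) {
    if (ch[x] == "(") stk <- c(stk, x)
    else if (ch[x] == ")") {
      if (!length(stk)) stop("unbalanced brackets: unmatched ) at ", x)
      pairs <- rbind(pairs, c(stk[length(stk)], x))
      stk <- stk[-length(stk)]
    } else if (ch[x] != ".") stop("unexpected character '", ch[x], "' at ", x)
  }
  if (length(stk)) stop("unbalanced brackets: unmatched ( at ", stk[1])
  structure_record(id, sq, pairs)
}

#' @rdname read_dotbracket
#' @param record a `structure_record`.
#' @export
write_dotbracket <- function(record, path = NULL) {
  stopifnot(inherits(record, "structure_record"))
  db <- rep(".", length(record$seq))
  if (nrow(record$pairs)) {
    db[record$pairs[, 1]] <- "("
    db[record$pairs[, 2]] <- ")"
  }
  txt <- c(paste0(">", record$id), paste(record$seq, collapse = ""),
           paste(db, collapse = ""))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(path)
}

#' Write / read the plain-text pairwise alignment of a common structure
#'
#' Two gapped rows of equal length; a column holds two residues exactly
#' when the alignment maps the positions to one another.  Inserted-domain
#' intervals are recorded in `# insertion:` header lines (host sequence and
#' 1-based sequence coordinates).  `read_alignment` recovers the mapping,
#' the gap count and the domain list exactly.
#'
#' @param cs a `common_structure`.
#' @param seq1,seq2 sequences (defaults: those stored in `cs`).
#' @param path output path, or `NULL` to return the text.
#' @export
write_alignment <- function(cs, seq1 = NULL, seq2 = NULL, path = NULL) {
  stopifnot(inherits(cs, "common_structure"))
  s1 <- if (is.null(seq1)) cs$seq1 else .seq_chars(seq1)
  s2 <- if (is.null(seq2)) cs$seq2 else .seq_chars(seq2)
  # verify mutual consistency of the mapping
  for (i in which(cs$aln1 != 0L))
    if (cs$aln2[cs$aln1[i]] != i) stop("alignment mapping is not mutual at ", i)
  r1 <- character(0); r2 <- character(0)
  i <- 1L; k <- 1L
  n1 <- length(s1); n2 <- length(s2)
  while (i <= n1 || k <= n2) {
    if (i <= n1 && cs$aln1[i] == 0L) {
      r1 <- c(r1, s1[i]); r2 <- c(r2, "-"); i <- i + 1L
    } else if (k <= n2 && cs$aln2[k] == 0L) {
      r1 <- c(r1, "-"); r2 <- c(r2, s2[k]); k <- k + 1L
    } else if (i <= n1 && k <= n2 && cs$aln1[i] == k) {
      r1 <- c(r1, s1[i]); r2 <- c(r2, s2[k]); i <- i + 1L; k <- k + 1L
    } else stop("alignment mapping is not monotone near (", i, ",", k, ")")
  }
  hdr <- c("# pairwise structural alignment", paste0("# n_gap: ", cs$n_gap))
  if (nrow(cs$domains))
    for (r in seq_len(nrow(cs$domains)))
      hdr <- c(hdr, paste0("# insertion: seq", cs$domains$seq[r], " ",
                           cs$domains$start[r], "-", cs$domains$end[r]))
  txt <- c(hdr, paste(r1, collapse = ""), paste(r2, collapse = ""))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_alignment
#' @param source path or text of a written alignment.
#' @export
read_alignment <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else strsplit(source, "\n")[[1]]
  hdr <- lines[startsWith(lines, "#")]
  rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(rows) != 2) stop("expected two alignment rows")
  a <- strsplit(rows[1], "")[[1]]; b <- strsplit(rows[2], "")[[1]]
  if (length(a) != length(b)) stop("alignment rows differ in length")
  aln1 <- integer(sum(a != "-")); aln2 <- integer(sum(b != "-"))
  i <- 0L; k <- 0L
  for (x in seq_along(a)) {
    if (a[x] != "-") i <- i + 1L
    if (b[x] != "-") k <- k + 1L
    if (a[x] != "-" && b[x] != "-") { aln1[i] <- k; aln2[k] <- i }
  }
  ng <- sub("^# n_gap: ", "", hdr[startsWith(hdr, "# n_gap:")])
  ins <- hdr[startsWith(hdr, "# insertion:")]
  domains <- data.frame(seq = integer(0), start = integer(0), end = integer(0))
  for (ln in ins) {
    m <- regmatches(ln, regexec("seq([12]) ([0-9]+)-([0-9]+)", ln))[[1]]
    domains <- rbind(domains, data.frame(seq = as.integer(m[2]),
                                         start = as.integer(m[3]),
                                         end = as.integer(m[4])))
  }
  list(aln1 = aln1, aln2 = aln2, n_gap = as.integer(ng), domains = domains,
       seq1 = paste(a[a != "-"], collapse = ""),
       seq2 = paste(b[b != "-"], collapse = ""))
}
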