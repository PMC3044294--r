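# Sequence, alignment and structure I/O.
#
# Sequences are named character vectors over {A,C,G,U,N}; alignments are
# `rna_msa` objects (named gapped strings of equal width, optionally with a
# dot-bracket consensus).  All coordinates are 1-based.

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Normalize an RNA residue string
#'
#' Uppercases, converts T to U (DNA-alphabet input is common) and rejects any
#' character outside A, C, G, U, N (plus `-` when `allow_gap`).
#'
#' @param s character string of residues.
#' @param id record label used in error messages.
#' @param allow_gap logical; permit the gap character `-`.
#' @return normalized residue string.
#' @keywords internal
normalize_residues <- function(s, id = "<sequence>", allow_gap = FALSE) {
  s <- chartr("acgutT", "ACGUUU", toupper(s))
  allowed <- c(RNA_ALPHABET, if (allow_gap) "-")
  ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, allowed)
  if (length(bad) > 0)
    stop(sprintf("record '%s': illegal character(s) %s after normalization",
                 id, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  s
}

#' Read unaligned RNA sequences from a FASTA file
#'
#' Residues are normalized (uppercase, T to U); gap characters and anything
#' outside A, C, G, U, N are format errors, as are duplicate record ids and
#' empty files.
#'
#' @param path path to a FASTA file.
#' @return named character vector of residue strings (names are record ids).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "ggcu"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0)) stop("empty sequence record in ", path, call. = FALSE)
  out <- vapply(seq_along(seqs), function(k)
    normalize_residues(seqs[k], ids[k], allow_gap = FALSE), character(1))
  names(out) <- ids
  out
}

#' Construct a multiple alignment object
#'
#' @param rows named character vector of gapped rows (equal widths, gap `-`).
#' @param structure optional dot-bracket consensus string of the same width.
#' @return an object of class `rna_msa`.
#' @export
rna_msa <- function(rows, structure = NULL) {
  if (length(rows) < 1 || is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("rows must be a named character vector with unique names", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1)
    stop("alignment rows have unequal lengths", call. = FALSE)
  rows[] <- vapply(seq_along(rows), function(k)
    normalize_residues(rows[k], names(rows)[k], allow_gap = TRUE), character(1))
  if (!is.null(structure)) {
    if (nchar(structure) != widths[1])
      stop("consensus structure width does not match alignment", call. = FALSE)
    parse_dotbracket(structure)  # validates
  }
  structure(list(rows = rows, structure = structure), class = "rna_msa")
}

#' Remove gaps from alignment rows
#' @param aln an `rna_msa`.
#' @return named character vector of ungapped sequences.
#' @export
degap <- function(aln) {
  stopifnot(inherits(aln, "rna_msa"))
  gsub("-", "", aln$rows, fixed = TRUE)
}

#' @method print rna_msa
#' @export
print.rna_msa <- function(x, ...) {
  cat(sprintf("RNA multiple alignment: %d sequences, %d columns\n",
              length(x$rows), nchar(x$rows[1])))
  wid <- max(nchar(names(x$rows)))
  for (k in seq_along(x$rows))
    cat(sprintf("  %-*s %s\n", wid, names(x$rows)[k], x$rows[k]))
  if (!is.null(x$structure))
    cat(sprintf("  %-*s %s\n", wid, "SS_cons", x$structure))
  invisible(x)
}

#' @method summary rna_msa
#' @export
summary.rna_msa <- function(object, ...) {
  rows <- object$rows
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ngap <- sum(mat == "-")
  cat(sprintf("RNA multiple alignment\n  sequences : %d\n  columns   : %d\n",
              nrow(mat), ncol(mat)))
  cat(sprintf("  gap frac  : %.3f\n", ngap / length(mat)))
  cat(sprintf("  mean pairwise identity: %.3f\n", pairwise_identity(object)))
  invisible(object)
}

#' Write a multiple alignment
#'
#' Supported formats: `"fasta"` (aligned FASTA), `"clustal"` (60-column
#' blocks, no conservation line) and `"stockholm"` (carries the consensus
#' structure as a `#=GC SS_cons` line when present).  FASTA and Clustal
#' round-trip through [read_alignment()].
#'
#' @param aln an `rna_msa`.
#' @param path output file, or `NULL` to return the text.
#' @param format one of `"fasta"`, `"clustal"`, `"stockholm"`.
#' @return the formatted text, invisibly when written to `path`.
#' @export
write_alignment <- function(aln, path = NULL,
                            format = c("fasta", "clustal", "stockholm")) {
  stopifnot(inherits(aln, "rna_msa"))
  format <- match.arg(format)
  rows <- aln$rows
  ids <- names(rows)
  txt <- switch(format,
    fasta = paste0(paste0(">", ids, "\n", rows, collapse = "\n"), "\n"),
    clustal = {
      wid <- max(nchar(ids)) + 3
      n <- nchar(rows[1])
      blocks <- character(0)
      for (s in seq(1, n, by = 60)) {
        e <- min(s + 59, n)
        blocks <- c(blocks, paste0(sprintf("%-*s", wid, ids),
                                   substr(rows, s, e), collapse = "\n"), "")
      }
      paste0("CLUSTAL W multiple sequence alignment\n\n",
             paste(blocks, collapse = "\n"), "\n")
    },
    stockholm = {
      wid <- max(nchar(ids), nchar("#=GC SS_cons")) + 3
      body <- paste0(sprintf("%-*s", wid, ids), rows, collapse = "\n")
      ss <- if (!is.null(aln$structure))
        paste0("\n", sprintf("%-*s", wid, "#=GC SS_cons"), aln$structure)
      else ""
      paste0("# STOCKHOLM 1.0\n", body, ss, "\n//\n")
    })
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Read a multiple alignment
#'
#' @param path input file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return an `rna_msa`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(set) == 0) stop("no sequences in ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(set))
    rows <- as.character(set)
    names(rows) <- ids
    return(rna_msa(rows))
  }
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1]))
    stop("not a Clustal file: ", path, call. = FALSE)
  lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s", lines)]  # drop conservation lines if any
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s*$", lines))
  if (any(lengths(parts) != 3)) stop("malformed Clustal body in ", path, call. = FALSE)
  ids <- vapply(parts, `[`, character(1), 2)
  chunks <- vapply(parts, `[`, character(1), 3)
  uids <- unique(ids)
  rows <- vapply(uids, function(id)
    paste0(chunks[ids == id], collapse = ""), character(1))
  names(rows) <- uids
  rna_msa(rows)
}

#' Parse a dot-bracket secondary structure
#'
#' @param text string over `(`, `)`, `.`.
#' @param seq_length expected length (defaults to `nchar(text)`).
#' @return list with `length` and `pairs`, a two-column matrix of 1-based
#'   paired positions `(i, j)` with `i < j`.
#' @export
#' @examples
#' parse_dotbracket("((...))")$pairs
parse_dotbracket <- function(text, seq_length = nchar(text)) {
  if (nchar(text) != seq_length)
    stop("structure length ", nchar(text), " does not match sequence length ",
         seq_length, call. = FALSE)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad) > 0)
    stop("illegal structure character(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (length(stack) == 0)
        stop("unbalanced structure: unmatched ')' at position ", k, call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    stop("unbalanced structure: unmatched '(' at position ", stack[1], call. = FALSE)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  list(length = seq_length, pairs = pairs)
}

#' Render a pair set as a dot-bracket string
#'
#' @param pairs two-column matrix of 1-based pairs `(i, j)`, `i < j`, nested.
#' @param length sequence length.
#' @return dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs, length) {
  ch <- rep(".", length)
  if (NROW(pairs) > 0) {
    if (any(pairs < 1) || any(pairs > length) || any(pairs[, 1] >= pairs[, 2]))
      stop("invalid pair coordinates", call. = FALSE)
    if (anyDuplicated(c(pairs[, 1], pairs[, 2])))
      stop("a position participates in more than one pair", call. = FALSE)
    for (a in seq_len(nrow(pairs)))
      for (b in seq_len(nrow(pairs))) {
        i <- pairs[a, 1]; j <- pairs[a, 2]; k <- pairs[b, 1]; l <- pairs[b, 2]
        if (i < k && k < j && j < l)
          stop("pseudoknotted pair set cannot be rendered", call. = FALSE)
      }
    ch[pairs[, 1]] <- "("
    ch[pairs[, 2]] <- ")"
  }
  paste0(ch, collapse = "")
}
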