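## Sequence input/output.
##
## Protein records travel as tibbles with columns `id` and `seq`; an alignment
## is the same tibble shape whose sequences all have equal length (gap "-").
## Parsing of FASTA and Clustal files is delegated to Biostrings.

validate_residues <- function(seqs, ids, allow_gap = FALSE) {
  allowed <- if (allow_gap) AA_ALPHABET else setdiff(AA_ALPHABET, "-")
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0) {
      abort(sprintf(
        "record '%s' contains illegal residue character(s): %s",
        ids[[i]], paste(bad, collapse = ", ")
      ))
    }
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and validated against the amino-acid alphabet
#' (20 standard residues plus `X`; gaps are not allowed in plain FASTA input,
#' use [read_alignment()] for aligned input).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first word of the header) and `seq`.
#'   Record order is preserved. An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (file.size(path) == 0) return(tibble(id = character(), seq = character()))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0 && !startsWith(first, ">")) {
    abort(sprintf("'%s' is not FASTA: first line does not start with '>'", path))
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf(
      "empty sequence for record '%s'", ids[which(!nzchar(seqs))[1]]
    ))
  }
  validate_residues(seqs, ids, allow_gap = FALSE)
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  lines <- unlist(purrr::map2(records$id, records$seq, function(id, s) {
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein alignment
#'
#' Supports gapped FASTA and Clustal dialects (conservation lines in Clustal
#' files are ignored). Gap characters `.` are normalised to `-`.
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return An alignment tibble (`id`, `seq`) whose rows all have the same
#'   aligned length.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
    seqs <- as.character(set)
  } else {
    # minimal Clustal block parser: header line, then per-block
    # "<name> <chunk>" rows; conservation rows (leading whitespace) and
    # trailing column counts are ignored
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1])) {
      abort(sprintf("'%s' is not a Clustal alignment (missing CLUSTAL header)", path))
    }
    body <- lines[-1]
    body <- body[nzchar(trimws(body)) & !grepl("^\\s", body)]
    parts <- strsplit(trimws(body), "\\s+")
    ok <- vapply(parts, length, integer(1)) >= 2
    if (!all(ok)) abort(sprintf("malformed Clustal row in '%s'", path))
    ids_all <- vapply(parts, `[[`, character(1), 1L)
    chunks <- vapply(parts, `[[`, character(1), 2L)
    ids <- unique(ids_all)
    seqs <- vapply(ids, function(i) {
      paste(chunks[ids_all == i], collapse = "")
    }, character(1))
  }
  seqs <- chartr(".", "-", toupper(seqs))
  out <- tibble(id = unname(ids), seq = unname(seqs))
  as_alignment(out)
}

#' Validate an alignment tibble
#'
#' Checks equal aligned lengths and alphabet (gaps allowed), reporting the
#' offending record on failure.
#'
#' @param records Tibble with columns `id`, `seq`.
#' @return The validated tibble.
#' @export
as_alignment <- function(records) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  lens <- nchar(records$seq)
  if (nrow(records) > 0 && length(unique(lens)) != 1) {
    off <- records$id[which(lens != lens[1])[1]]
    abort(sprintf(
      "ragged alignment: record '%s' has length %d, expected %d",
      off, nchar(records$seq[records$id == off][1]), lens[1]
    ))
  }
  validate_residues(records$seq, records$id, allow_gap = TRUE)
  records
}

#' Remove gaps from an aligned sequence
#' @param seq Character vector of (aligned) sequences.
#' @return Sequences with all `-` removed.
#' @export
ungap <- function(seq) gsub("-", "", seq, fixed = TRUE)
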