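## Alignment-anchored residue extraction.
##
## A query is aligned globally to the annotated reference of its class
## (Needleman-Wunsch, affine gaps, BLOSUM62) and every named signature
## position is transferred through the alignment columns. Positions falling
## opposite a query gap degrade gracefully to residue "-" so downstream rule
## matching can flag them non-comparable instead of failing.

#' Global pairwise alignment of a query against a reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties, delegated to
#' Biostrings. The returned alignment has the reference as its first row,
#' which is the orientation [transfer_positions()] expects.
#'
#' @param query,reference Single-row record tibbles (`id`, `seq`) or plain
#'   named character vectors `c(id = seq)`.
#' @param substitution_table Scoring matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (default 10 / 0.5).
#' @return An alignment tibble (`id`, `seq`; reference first) with attribute
#'   `score`.
#' @export
global_align <- function(query, reference, substitution_table = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  q <- as_record(query)
  r <- as_record(reference)
  if (!nzchar(q$seq) || !nzchar(r$seq)) abort("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q$seq),
    subject = Biostrings::AAString(r$seq),
    type = "global",
    substitutionMatrix = substitution_table,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  out <- tibble(
    id = c(r$id, q$id),
    seq = c(
      as.character(Biostrings::alignedSubject(pa)),
      as.character(Biostrings::alignedPattern(pa))
    )
  )
  attr(out, "score") <- Biostrings::score(pa)
  as_alignment(out)
}

as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, all(c("id", "seq") %in% names(x)))
    list(id = x$id, seq = toupper(x$seq))
  } else if (is.character(x) && length(x) == 1) {
    list(id = if (is.null(names(x))) "query" else names(x), seq = toupper(unname(x)))
  } else {
    abort("expected a one-row record tibble or a single named character")
  }
}

#' Map reference coordinates to query coordinates through an alignment
#'
#' @param alignment Alignment tibble whose first row is the annotated
#'   reference (as produced by [global_align()]); second row the query.
#' @param annotation The `aqp_reference` the alignment was made against; used
#'   to verify that the alignment's reference row really is the annotated
#'   sequence.
#' @return A tibble with one row per reference residue: `ref_coord`,
#'   `query_coord` (`NA` when the query has a gap in that column) and
#'   `query_residue` (`"-"` for gaps).
#' @export
transfer_positions <- function(alignment, annotation) {
  stopifnot(nrow(alignment) >= 2)
  ref_row <- alignment$seq[1]
  qry_row <- alignment$seq[2]
  if (!identical(ungap(ref_row), annotation$seq)) {
    abort("alignment's first row does not match the annotated reference sequence")
  }
  ref_chars <- strsplit(ref_row, "")[[1]]
  qry_chars <- strsplit(qry_row, "")[[1]]
  ref_pos <- cumsum(ref_chars != "-")
  qry_pos <- cumsum(qry_chars != "-")
  keep <- ref_chars != "-"
  tibble(
    ref_coord = ref_pos[keep],
    query_coord = ifelse(qry_chars[keep] == "-", NA_integer_, qry_pos[keep]),
    query_residue = qry_chars[keep]
  )
}

#' Scan a sequence for NPA motifs
#'
#' @param seq A single amino-acid sequence.
#' @param variants Motif variants to accept; default strict `"NPA"`, the
#'   relaxed set `c("NPA", "NPS", "NPV", "NPT")` covers common substitutions.
#' @return Tibble `start` (1-based), `motif`, sorted left-to-right.
#' @export
scan_npa <- function(seq, variants = "NPA") {
  stopifnot(length(seq) == 1)
  seq <- ungap(toupper(seq))
  hits <- purrr::map(variants, function(v) {
    m <- gregexpr(paste0("(?=", v, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble(start = as.integer(m), motif = v)
  })
  out <- list_rbind(purrr::compact(hits))
  if (nrow(out) == 0) return(tibble(start = integer(), motif = character()))
  arrange(out, .data$start)
}

#' Extract residues at every named signature position
#'
#' Builds the full residue extraction for one query: NPA loop-B/loop-E
#' windows, the Ar/R selectivity filter, Froger P1-P5, the conserved loop-D
#' residue, the water-permeability pair (TM2, loop E), gating sites and the
#' per-substrate SDP residue vectors. Positions opposite a query gap carry
#' residue `"-"`.
#'
#' @param query One-row record tibble (`id`, `seq`), ungapped.
#' @param mapping Coordinate mapping from [transfer_positions()].
#' @param annotation The `aqp_reference` used for the mapping.
#' @return An object of class `aqp_extraction`: tibble with columns `query`,
#'   `view`, `name`, `ref_coord`, `query_coord`, `residue`, plus attributes
#'   `query_id` and `ref_class`. Grouped string views are available through
#'   [extraction_view()].
#' @export
extract_signature_residues <- function(query, mapping, annotation) {
  q <- as_record(query)
  lookup <- function(coords, names, view) {
    idx <- match(coords, mapping$ref_coord)
    if (anyNA(idx)) abort("mapping does not cover all annotated coordinates")
    tibble(
      query = q$id, view = view, name = names,
      ref_coord = as.integer(coords),
      query_coord = mapping$query_coord[idx],
      residue = mapping$query_residue[idx]
    )
  }
  npa <- annotation$npa
  bcoords <- seq(npa[["loopB_start"]], length.out = npa[["loopB_len"]])
  ecoords <- seq(npa[["loopE_start"]], length.out = npa[["loopE_len"]])
  rows <- list(
    lookup(bcoords, paste0("B", seq_along(bcoords)), "npa_loopB"),
    lookup(ecoords, paste0("E", seq_along(ecoords)), "npa_loopE"),
    lookup(annotation$arr, names(annotation$arr), "arr"),
    lookup(annotation$froger, names(annotation$froger), "froger"),
    lookup(annotation$positions[["loopD"]], "loopD", "loopD"),
    lookup(annotation$positions[c("perm_TM2", "perm_loopE")],
           c("perm_TM2", "perm_loopE"), "permeability")
  )
  if (nrow(annotation$gating) > 0) {
    rows <- c(rows, list(lookup(annotation$gating$coord, annotation$gating$site, "gating")))
  }
  for (sub in names(annotation$sdp)) {
    coords <- annotation$sdp[[sub]]
    rows <- c(rows, list(lookup(coords, as.character(coords), paste0("sdp_", sub))))
  }
  out <- list_rbind(rows)
  structure(out, query_id = q$id, ref_class = annotation$class,
            class = c("aqp_extraction", class(out)))
}

#' Grouped view of an extraction
#'
#' @param ext An `aqp_extraction`.
#' @param view View name (`"arr"`, `"froger"`, `"npa_loopB"`, `"npa_loopE"`,
#'   `"loopD"`, `"permeability"`, `"gating"`, `"sdp_<substrate>"`).
#' @param collapse If `TRUE` (default) return the residues pasted into one
#'   string (gap positions as `-`); otherwise the view's tibble rows.
#' @return A string or tibble.
#' @export
extraction_view <- function(ext, view, collapse = TRUE) {
  rows <- ext[ext$view == view, , drop = FALSE]
  if (nrow(rows) == 0) abort(sprintf("no view '%s' in extraction", view))
  if (collapse) paste(rows$residue, collapse = "") else as_tibble(rows)
}

#' @export
print.aqp_extraction <- function(x, ...) {
  cat(sprintf(
    "<aqp_extraction> %s vs %s reference: arr %s, froger %s\n",
    attr(x, "query_id"), attr(x, "ref_class"),
    extraction_view(x, "arr"), extraction_view(x, "froger")
  ))
  invisible(x)
}

#' Pick the best-scoring reference for a query
#'
#' Aligns the query against every shipped (or supplied) class reference and
#' returns the class with the highest global alignment score — the class hint
#' used to select extraction coordinates.
#'
#' @param query One-row record tibble.
#' @param references Named list of `aqp_reference` objects (default: shipped
#'   synthetic PIP and TIP references).
#' @return A list with `class`, `alignment`, `annotation`, `score`.
#' @export
choose_reference <- function(query, references = load_shipped_references()) {
  scored <- purrr::imap(references, function(ann, cls) {
    aln <- global_align(query, tibble(id = ann$reference_id, seq = ann$seq))
    list(class = cls, alignment = aln, annotation = ann, score = attr(aln, "score"))
  })
  best <- which.max(vapply(scored, `[[`, numeric(1), "score"))
  scored[[best]]
}
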