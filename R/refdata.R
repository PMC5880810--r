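## Reference annotation and signature rule tables.
##
## The reference annotation names every signature position (NPA windows, Ar/R
## filter, Froger P1-P5, SDP sets, permeability and gating sites) in 1-based
## coordinates on an annotated reference sequence. Rule tables give, per
## source (hove/azad), class and substrate, the residues expected at those
## positions. Both are plain text, user-editable, shipped under extdata.

SUBSTRATES <- c("h2o2", "urea", "boric_acid", "co2", "ammonia")
RULE_CLASSES <- c("PIP", "TIP")

# minimal INI reader: "[section]" headers, "key = value" entries,
# "#" comments; returns a named list of named character vectors
read_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) abort(sprintf("entry before any [section] in %s", path))
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      out[[section]][[key]] <- val
    } else {
      abort(sprintf("cannot parse config line '%s' in %s", ln, path))
    }
  }
  out
}

ini_coords <- function(section, keys, path) {
  missing <- setdiff(keys, names(section))
  if (length(missing) > 0) {
    abort(sprintf("missing key(s) %s in %s", paste(missing, collapse = ", "), path))
  }
  vals <- suppressWarnings(as.integer(section[keys]))
  if (any(is.na(vals))) abort(sprintf("non-integer coordinate in %s", path))
  setNames(vals, keys)
}

#' Load a reference annotation
#'
#' Reads the INI-style annotation config that maps named aquaporin signature
#' positions to 1-based, inclusive coordinates on an annotated reference
#' sequence (the numbering convention of the source alignment figures).
#' Mandatory blocks: `[meta]` (`reference_id`, `class`, `sequence_file`),
#' `[npa]` (`loopB_start`, `loopB_len`, `loopE_start`, `loopE_len`),
#' `[arr]` (`H2`, `H5`, `LE1`, `LE2`), `[froger]` (`P1`..`P5`),
#' `[positions]` (`loopD`, `perm_TM2`, `perm_loopE`), `[sdp]` (one key per
#' substrate, space-separated coordinates). Optional `[gating]` block entries
#' are `name = coord residue` (the conserved residue expected at that site).
#'
#' @param path Path to the config file.
#' @return An object of class `aqp_reference`: a list with elements
#'   `reference_id`, `class`, `seq`, `npa`, `arr`, `froger`, `positions`,
#'   `gating` (tibble `site`, `coord`, `expected`) and `sdp` (named list of
#'   integer coordinate vectors).
#' @export
load_reference_annotation <- function(path) {
  cfg <- read_ini(path)
  for (blk in c("meta", "npa", "arr", "froger", "positions", "sdp")) {
    if (is.null(cfg[[blk]])) abort(sprintf("missing mandatory block [%s] in %s", blk, path))
  }
  meta <- cfg$meta
  for (k in c("reference_id", "class", "sequence_file")) {
    if (is.null(meta[[k]]) || !nzchar(meta[[k]])) {
      abort(sprintf("missing meta key '%s' in %s", k, path))
    }
  }
  fasta <- file.path(dirname(path), meta[["sequence_file"]])
  ref <- read_fasta(fasta)
  if (nrow(ref) != 1) abort(sprintf("reference FASTA %s must hold one record", fasta))
  len <- nchar(ref$seq)

  npa <- ini_coords(cfg$npa, c("loopB_start", "loopB_len", "loopE_start", "loopE_len"), path)
  arr <- ini_coords(cfg$arr, c("H2", "H5", "LE1", "LE2"), path)
  if (length(cfg$froger) != 5) {
    abort(sprintf("[froger] must define exactly 5 positions (P1-P5), got %d in %s",
                  length(cfg$froger), path))
  }
  froger <- ini_coords(cfg$froger, paste0("P", 1:5), path)
  positions <- ini_coords(cfg$positions, c("loopD", "perm_TM2", "perm_loopE"), path)

  gating <- tibble(site = character(), coord = integer(), expected = character())
  if (!is.null(cfg$gating)) {
    parts <- strsplit(unname(cfg$gating), "\\s+")
    ok <- vapply(parts, length, integer(1)) == 2
    if (!all(ok)) abort(sprintf("[gating] entries must be 'name = coord residue' in %s", path))
    gating <- tibble(
      site = names(cfg$gating),
      coord = as.integer(vapply(parts, `[[`, character(1), 1L)),
      expected = vapply(parts, `[[`, character(1), 2L)
    )
  }

  sdp <- purrr::map(cfg$sdp, function(v) {
    out <- suppressWarnings(as.integer(strsplit(v, "\\s+")[[1]]))
    if (any(is.na(out))) abort(sprintf("non-integer SDP coordinate in %s", path))
    out
  })
  bad_sub <- setdiff(names(sdp), SUBSTRATES)
  if (length(bad_sub) > 0) {
    abort(sprintf("unknown substrate token(s) in [sdp]: %s", paste(bad_sub, collapse = ", ")))
  }

  all_coords <- c(
    npa[["loopB_start"]], npa[["loopB_start"]] + npa[["loopB_len"]] - 1L,
    npa[["loopE_start"]], npa[["loopE_start"]] + npa[["loopE_len"]] - 1L,
    arr, froger, positions, gating$coord, unlist(sdp)
  )
  if (any(all_coords < 1L) || any(all_coords > len)) {
    abort(sprintf(
      "coordinate out of range [1, %d] in %s (offending: %s)",
      len, path, paste(unique(all_coords[all_coords < 1 | all_coords > len]), collapse = ", ")
    ))
  }
  named <- c(names(arr), names(froger), names(positions), gating$site)
  if (anyDuplicated(named)) abort(sprintf("duplicate position names in %s", path))

  structure(
    list(
      reference_id = meta[["reference_id"]],
      class = meta[["class"]],
      seq = ref$seq,
      npa = npa, arr = arr, froger = froger,
      positions = positions, gating = gating, sdp = sdp
    ),
    class = "aqp_reference"
  )
}

#' @export
print.aqp_reference <- function(x, ...) {
  cat(sprintf(
    "<aqp_reference> %s (%s class, %d aa), %d SDP sets\n",
    x$reference_id, x$class, nchar(x$seq), length(x$sdp)
  ))
  invisible(x)
}

## Named SSSS/Ar-R/Froger position labels used by rule files and extractions:
## B1..B<loopB_len>, E1..E<loopE_len>, H2, H5, LE1, LE2, P1..P5.
ssss_position_names <- function(annotation) {
  c(
    paste0("B", seq_len(annotation$npa[["loopB_len"]])),
    paste0("E", seq_len(annotation$npa[["loopE_len"]])),
    names(annotation$arr), names(annotation$froger)
  )
}

#' Load a signature rule table
#'
#' Reads a tab-separated rule file with columns `source`, `type` (`ssss` or
#' `sdp`), `class`, `substrate`, `position`, `expected`. SSSS positions are
#' named (`B1`..`B10`, `E1`..`E11`, `H2`, `H5`, `LE1`, `LE2`, `P1`..`P5`);
#' SDP positions are 1-based reference coordinates. `expected` lists the
#' allowed residue(s), alternatives separated by `|`. A (class, substrate)
#' pair with no rows is *not defined* for that source; matching reports it as
#' such rather than as a mismatch.
#'
#' @param path Path to the rule file.
#' @return An object of class `aqp_rules`: a tibble of rules with attributes
#'   `source` and `type`.
#' @export
load_rules <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("source", "type", "class", "substrate", "position", "expected")
  if (!all(need %in% names(df))) {
    abort(sprintf("rule file %s must have columns %s", path, paste(need, collapse = ", ")))
  }
  df <- as_tibble(df)
  bad <- setdiff(unique(df$class), RULE_CLASSES)
  if (length(bad) > 0) abort(sprintf("unknown class token(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(df$substrate), SUBSTRATES)
  if (length(bad) > 0) abort(sprintf("unknown substrate token(s): %s", paste(bad, collapse = ", ")))
  if (length(unique(df$source)) != 1 || length(unique(df$type)) != 1) {
    abort(sprintf("rule file %s must carry a single source and type", path))
  }
  dup <- df |>
    dplyr::count(.data$source, .data$class, .data$substrate, .data$position) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate rule entry: (%s, %s, %s) position %s",
      dup$source[1], dup$class[1], dup$substrate[1], dup$position[1]
    ))
  }
  structure(
    df,
    source = df$source[1], type = df$type[1],
    class = c("aqp_rules", class(df))
  )
}

#' Check a rule table against a reference annotation
#'
#' Verifies that every rule position exists in the annotation: named SSSS
#' positions must be known labels, SDP coordinates must belong to the
#' annotation's SDP set for that substrate.
#'
#' @param rules An `aqp_rules` object.
#' @param annotation An `aqp_reference` (of the class the rules address).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_rules <- function(rules, annotation) {
  rel <- rules[rules$class == annotation$class, ]
  if (attr(rules, "type") == "ssss") {
    known <- ssss_position_names(annotation)
    bad <- setdiff(unique(rel$position), known)
    if (length(bad) > 0) {
      abort(sprintf("unknown SSSS position label(s): %s", paste(bad, collapse = ", ")))
    }
  } else {
    for (sub in unique(rel$substrate)) {
      coords <- suppressWarnings(as.integer(rel$position[rel$substrate == sub]))
      if (any(is.na(coords))) abort("SDP positions must be integer reference coordinates")
      extra <- setdiff(coords, annotation$sdp[[sub]])
      if (length(extra) > 0) {
        abort(sprintf(
          "SDP coordinate(s) %s for %s not in the annotation's set",
          paste(extra, collapse = ", "), sub
        ))
      }
    }
  }
  invisible(TRUE)
}

#' Load the shipped rule tables
#'
#' @return A named list of `aqp_rules`: `ssss_hove`, `ssss_azad`, `sdp_hove`.
#' @export
load_shipped_rules <- function() {
  list(
    ssss_hove = load_rules(aqp_example("ssss_hove.tsv")),
    ssss_azad = load_rules(aqp_example("ssss_azad.tsv")),
    sdp_hove = load_rules(aqp_example("sdp_hove.tsv"))
  )
}

#' Load the shipped synthetic reference annotations
#'
#' @return A named list of `aqp_reference` objects keyed by class
#'   (`PIP`, `TIP`).
#' @export
load_shipped_references <- function() {
  list(
    PIP = load_reference_annotation(aqp_example("pip_reference.cfg")),
    TIP = load_reference_annotation(aqp_example("tip_reference.cfg"))
  )
}
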