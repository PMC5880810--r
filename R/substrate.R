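## Substrate-specificity rule matching.
##
## A substrate matches a source's rule iff every defined position carries an
## allowed residue. Exactly one mismatching position is a near-miss — the
## "only one out of nine residues" situation the source alignments discuss —
## reported but never counted as a match. A gap at any rule position makes
## the verdict not-comparable, and a (class, substrate) pair the source never
## defined is not-defined. Hove and Azad rule sets are kept separate
## end-to-end; the consensus combines them under an explicit policy.

rule_class_of <- function(ext_class) {
  if (ext_class %in% c("PIP", "PIP1", "PIP2")) "PIP" else if (grepl("TIP", ext_class)) "TIP" else ext_class
}

match_rule_positions <- function(ext, rules_rows, named_views) {
  # residue lookup across the extraction's named (SSSS) or coordinate (SDP) keys
  ext_rows <- ext[ext$view %in% named_views, , drop = FALSE]
  key <- ext_rows$name
  residues <- setNames(ext_rows$residue, key)
  idx <- rules_rows$position
  missing <- setdiff(idx, names(residues))
  if (length(missing) > 0) {
    abort(sprintf("rule position(s) %s absent from extraction", paste(missing, collapse = ", ")))
  }
  obs <- residues[idx]
  allowed <- strsplit(rules_rows$expected, "|", fixed = TRUE)
  hit <- map_lgl(seq_along(obs), ~ obs[[.x]] %in% allowed[[.x]])
  tibble(position = idx, observed = unname(obs), expected = rules_rows$expected,
         ok = hit, gap = unname(obs) == "-")
}

verdict_from_checks <- function(checks) {
  if (any(checks$gap)) return(list(verdict = "not-comparable", mismatches = character()))
  bad <- checks$position[!checks$ok]
  verdict <- if (length(bad) == 0) "match" else if (length(bad) == 1) "near-miss" else "mismatch"
  list(verdict = verdict, mismatches = bad)
}

match_generic <- function(ext, rules, source, named_views) {
  if (!is.null(source) && attr(rules, "source") != source) {
    abort(sprintf("rule set carries source '%s', not '%s'", attr(rules, "source"), source))
  }
  cls <- rule_class_of(attr(ext, "ref_class"))
  rtype <- attr(rules, "type")
  purrr::map(SUBSTRATES, function(sub) {
    rows <- rules[rules$class == cls & rules$substrate == sub, , drop = FALSE]
    if (nrow(rows) == 0) {
      return(tibble(
        query = attr(ext, "query_id"), source = attr(rules, "source"),
        rule_type = rtype, substrate = sub, verdict = "not-defined",
        n_mismatch = NA_integer_, mismatch_positions = ""
      ))
    }
    checks <- match_rule_positions(ext, rows, named_views)
    v <- verdict_from_checks(checks)
    tibble(
      query = attr(ext, "query_id"), source = attr(rules, "source"),
      rule_type = rtype, substrate = sub, verdict = v$verdict,
      n_mismatch = if (v$verdict == "not-comparable") NA_integer_ else length(v$mismatches),
      mismatch_positions = paste(v$mismatches, collapse = ",")
    )
  }) |>
    list_rbind()
}

#' Match an extraction against an SSSS rule set
#'
#' The substrate-specific signature sequence covers the loop-B and loop-E
#' NPA windows, the Ar/R filter and the Froger P1-P5 positions.
#'
#' @param ext An `aqp_extraction`.
#' @param rules An `aqp_rules` object of type `ssss`.
#' @param source Optional source label to assert (`"hove"`, `"azad"`).
#' @return Tibble: `query`, `source`, `rule_type`, `substrate`, `verdict`
#'   (`match` / `near-miss` / `mismatch` / `not-defined` / `not-comparable`),
#'   `n_mismatch`, `mismatch_positions`.
#' @export
match_ssss <- function(ext, rules, source = NULL) {
  stopifnot(attr(rules, "type") == "ssss")
  match_generic(ext, rules, source,
                c("npa_loopB", "npa_loopE", "arr", "froger"))
}

#' Match an extraction against an SDP rule set
#'
#' Specificity-determining positions are additional residue positions outside
#' the NPA/Ar-R/Froger filters; positions are reference coordinates.
#'
#' @inheritParams match_ssss
#' @param rules An `aqp_rules` object of type `sdp`.
#' @return Same shape as [match_ssss()].
#' @export
match_sdp <- function(ext, rules, source = NULL) {
  stopifnot(attr(rules, "type") == "sdp")
  sdp_views <- unique(ext$view[startsWith(ext$view, "sdp_")])
  match_generic(ext, rules, source, sdp_views)
}

#' Consensus substrate prediction across rule sources
#'
#' Combines per-source verdicts into one substrate set. Policies:
#' * `"ssss-anchored"` (default): a substrate is predicted iff every SSSS
#'   source defines a rule for the class and calls `match`, and every SDP
#'   source that defines a rule calls `match` (an undefined SDP rule
#'   abstains). This is the full-correspondence reading under which signature
#'   coverage by both sequence-signature compilations is required, while the
#'   sparser SDP compilation cannot veto what it never characterised.
#' * `"strict-intersection"`: every source must define a rule and call
#'   `match`; any `not-defined` vetoes.
#' * `"lenient"`: any source without a defined rule abstains; a substrate is
#'   predicted iff all non-abstaining sources call `match`. A substrate on
#'   which every source abstains is never predicted.
#'
#' `near-miss`, `mismatch` and `not-comparable` always veto.
#'
#' @param verdicts Row-bound verdict tibbles from [match_ssss()] /
#'   [match_sdp()] for one query.
#' @param policy Consensus policy.
#' @return Tibble `query`, `substrate`, `consensus` (logical), `policy`.
#' @export
consensus_prediction <- function(verdicts,
                                 policy = c("ssss-anchored", "strict-intersection", "lenient")) {
  policy <- match.arg(policy)
  stopifnot(length(unique(verdicts$query)) == 1)
  per_sub <- verdicts |>
    group_by(.data$substrate) |>
    summarise(
      any_fail = any(!.data$verdict %in% c("match", "not-defined")),
      ssss_all_match = all(.data$verdict[.data$rule_type == "ssss"] == "match"),
      defined_all_match = {
        def <- .data$verdict != "not-defined"
        any(def) && all(.data$verdict[def] == "match")
      },
      all_defined_match = all(.data$verdict == "match"),
      sdp_defined_match = {
        sdp <- .data$rule_type == "sdp" & .data$verdict != "not-defined"
        all(.data$verdict[sdp] == "match")
      },
      .groups = "drop"
    )
  consensus <- switch(policy,
    "strict-intersection" = per_sub$all_defined_match,
    "lenient" = per_sub$defined_all_match & !per_sub$any_fail,
    "ssss-anchored" = per_sub$ssss_all_match & per_sub$sdp_defined_match &
      !per_sub$any_fail &
      map_lgl(per_sub$substrate, function(s) {
        any(verdicts$rule_type == "ssss" & verdicts$substrate == s &
              verdicts$verdict != "not-defined")
      })
  )
  tibble(
    query = verdicts$query[1],
    substrate = per_sub$substrate,
    consensus = consensus,
    policy = policy
  )
}

#' Water-permeability call from the TM2/loop-E residue pair
#'
#' Ala in TM2 with Ile in loop E is the low-permeability configuration seen
#' in all PIP1 sequences; Ile-or-Val in TM2 with Val in loop E the
#' high-permeability PIP2 configuration. Any other pair is undetermined.
#'
#' @param ext An `aqp_extraction`.
#' @return Tibble (one row): `query`, `tm2`, `loopE`, `verdict`.
#' @export
permeability_call <- function(ext) {
  perm <- extraction_view(ext, "permeability", collapse = FALSE)
  tm2 <- perm$residue[perm$name == "perm_TM2"]
  loopE <- perm$residue[perm$name == "perm_loopE"]
  verdict <- if (tm2 == "A" && loopE == "I") {
    "low-PIP1-like"
  } else if (tm2 %in% c("I", "V") && loopE == "V") {
    "high-PIP2-like"
  } else {
    "undetermined"
  }
  tibble(query = attr(ext, "query_id"), tm2 = tm2, loopE = loopE, verdict = verdict)
}

#' Gating-site profile
#'
#' Reports, per annotated gating site (loop-B phosphosite, C-terminal Ser,
#' loop-D His, blocking Leu, methylation Lys/Glu — whichever the class
#' annotation defines), whether the conserved residue is present, absent, or
#' opposite an alignment gap.
#'
#' @param ext An `aqp_extraction`.
#' @param annotation The `aqp_reference` used for the extraction (supplies
#'   the expected residues).
#' @return Tibble: `query`, `site`, `ref_coord`, `expected`, `observed`,
#'   `status` (`present`/`absent`/`gap`).
#' @export
gating_profile <- function(ext, annotation) {
  if (nrow(annotation$gating) == 0) {
    return(tibble(query = attr(ext, "query_id"), site = character(),
                  ref_coord = integer(), expected = character(),
                  observed = character(), status = character()))
  }
  obs <- extraction_view(ext, "gating", collapse = FALSE)
  annotation$gating |>
    left_join(select(obs, site = "name", observed = "residue"), by = "site") |>
    mutate(
      query = attr(ext, "query_id"),
      status = dplyr::case_when(
        .data$observed == "-" ~ "gap",
        .data$observed == .data$expected ~ "present",
        TRUE ~ "absent"
      )
    ) |>
    select("query", "site", ref_coord = "coord", "expected", "observed", "status")
}
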