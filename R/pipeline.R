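## End-to-end orchestration.
##
## `annotate_aquaporins()` runs the full sequence side: topology, NPA scan,
## reference choice, extraction, classification (residue rules and,
## optionally, clade placement), SSSS/SDP matching against every rule source,
## consensus, permeability and gating. `run_qpcr_analysis()` runs the full
## expression side: efficiencies, Cq, no-RT filter, geNorm, CNRQ and group
## statistics. Both return lists of tibbles ready for joining/plotting; both
## are deterministic given their inputs.

#' Annotate aquaporin protein sequences
#'
#' @param records Record tibble (`id`, `seq`), e.g. from [read_fasta()] or
#'   [make_group_records()].
#' @param references Named list of `aqp_reference` annotations (default: the
#'   shipped synthetic PIP/TIP references; supply your own to anchor on real
#'   reference translations).
#' @param rules List of `aqp_rules` (default: the shipped Hove/Azad SSSS and
#'   Hove SDP tables).
#' @param policy Consensus policy, see [consensus_prediction()].
#' @param panel Optional labelled panel tibble (`id`, `class`, `seq`) for
#'   clade-based classification; when given, an alignment of panel + queries
#'   is built by scaffold identity (equal lengths required) and
#'   [assign_by_clade()] runs on the neighbor-joining tree.
#' @param npa_variants Motif variants for [scan_npa()].
#' @return An object of class `aqp_annotation`: list of tibbles `topology`,
#'   `npa`, `extraction`, `classification`, `substrate`, `consensus`,
#'   `permeability`, `gating`, and `clade` (when a panel was supplied).
#' @export
annotate_aquaporins <- function(records,
                                references = load_shipped_references(),
                                rules = load_shipped_rules(),
                                policy = "ssss-anchored",
                                panel = NULL,
                                npa_variants = "NPA") {
  if (nrow(records) == 0) abort("no input sequences")
  per_query <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, c("id", "seq")]
    topo_warnings <- character()
    topo <- withCallingHandlers(
      tryCatch(
        predict_tm_helices(hydropathy_profile(rec$seq)),
        error = function(e) {
          topo_warnings <<- c(topo_warnings, conditionMessage(e))
          NULL
        }
      ),
      warning = function(w) {
        topo_warnings <<- c(topo_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    npa <- scan_npa(rec$seq, variants = npa_variants)
    npa_check <- NULL
    if (!is.null(topo)) {
      npa_check <- withCallingHandlers(
        locate_npa_in_topology(topo, npa),
        warning = function(w) {
          topo_warnings <<- c(topo_warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
    }
    ref <- choose_reference(rec, references)
    mapping <- transfer_positions(ref$alignment, ref$annotation)
    ext <- extract_signature_residues(rec, mapping, ref$annotation)
    cls <- classify_by_residues(ext)
    verdicts <- bind_rows(
      purrr::map(rules, function(r) {
        if (attr(r, "type") == "ssss") match_ssss(ext, r) else match_sdp(ext, r)
      })
    )
    cons <- consensus_prediction(verdicts, policy = policy)
    list(
      id = rec$id,
      topology = if (is.null(topo)) {
        tibble(id = rec$id, helix = integer(), start = integer(),
               end = integer(), mean_hydropathy = double(), n_helices = 0L)
      } else {
        mutate(topo$helices, id = rec$id, n_helices = nrow(topo$helices), .before = 1)
      },
      npa = mutate(npa, id = rec$id, .before = 1),
      npa_check = if (is.null(npa_check)) NULL else mutate(npa_check, id = rec$id, .before = 1),
      extraction = as_tibble(ext),
      classification = mutate(cls, reference_class = ref$class,
                              alignment_score = ref$score),
      substrate = verdicts,
      consensus = cons,
      permeability = permeability_call(ext),
      gating = gating_profile(ext, ref$annotation),
      warnings = topo_warnings
    )
  })
  out <- list(
    topology = list_rbind(purrr::map(per_query, "topology")),
    npa = list_rbind(purrr::map(per_query, "npa")),
    npa_check = list_rbind(purrr::compact(purrr::map(per_query, "npa_check"))),
    extraction = list_rbind(purrr::map(per_query, "extraction")),
    classification = list_rbind(purrr::map(per_query, "classification")),
    substrate = list_rbind(purrr::map(per_query, "substrate")),
    consensus = list_rbind(purrr::map(per_query, "consensus")),
    permeability = list_rbind(purrr::map(per_query, "permeability")),
    gating = list_rbind(purrr::map(per_query, "gating")),
    warnings = unlist(purrr::map(per_query, "warnings"))
  )
  if (!is.null(panel)) {
    aln <- as_alignment(bind_rows(
      select(panel, "id", "seq"), select(records, "id", "seq")
    ))
    d <- pdistance_matrix(aln)
    tree <- neighbor_joining(d)
    out$clade <- assign_by_clade(tree, select(panel, "id", "class"),
                                 queries = records$id)
    out$tree <- tree
  }
  structure(out, class = "aqp_annotation")
}

#' @export
print.aqp_annotation <- function(x, ...) {
  cat(sprintf("<aqp_annotation> %d queries\n", nrow(x$classification)))
  print(select(x$classification, "query", "class", "subtype"))
  cons <- x$consensus |>
    filter(.data$consensus) |>
    group_by(.data$query) |>
    summarise(substrates = paste(.data$substrate, collapse = ", "), .groups = "drop")
  if (nrow(cons) > 0) {
    cat("consensus substrates:\n")
    print(cons)
  }
  invisible(x)
}

#' Substrate verdict grid
#'
#' Wide per-query view of the per-source verdicts — the shape of the
#' published signature tables (one row per query, one column per
#' source/substrate pair).
#'
#' @param annotation An `aqp_annotation`.
#' @param rule_type `"ssss"` or `"sdp"`.
#' @return A wide tibble of verdicts.
#' @export
verdict_grid <- function(annotation, rule_type = "ssss") {
  annotation$substrate |>
    filter(.data$rule_type == !!rule_type) |>
    mutate(key = paste(.data$source, .data$substrate, sep = ".")) |>
    select("query", "key", "verdict") |>
    tidyr::pivot_wider(names_from = "key", values_from = "verdict")
}

#' Run the full RT-qPCR quantification pipeline
#'
#' Efficiency estimation from raw curves, Cq calling, the no-RT < `min_delta`
#' exclusion rule, geNorm selection among the designated reference
#' candidates, CNRQ computation, and per-target Brown-Forsythe + Scheffe
#' comparison of log10 CNRQ across tissue groups.
#'
#' @param curves Long curve tibble (`sample`, `target`, `well_type`, `cycle`,
#'   `fluorescence`).
#' @param design Sample design tibble (`sample`, `group`).
#' @param reference_candidates Targets eligible as references (>= 3 for
#'   geNorm; exactly the candidates you would assay for it). If fewer than 3
#'   are supplied the pipeline stops, mirroring geNorm's requirement.
#' @param efficiencies Optional known per-target efficiencies; default
#'   estimates them from the curves.
#' @param min_delta no-RT exclusion threshold in cycles (default 5).
#' @param threshold Cq threshold (default: derived from the noise band).
#' @param alpha Significance level for the post hoc tests.
#' @return An object of class `aqp_qpcr`: list with `efficiency`, `cq`,
#'   `nort_filter`, `genorm`, `cnrq`, `stats` (per-target tidy
#'   Brown-Forsythe results), `posthoc` (per-target Scheffe tables).
#' @export
run_qpcr_analysis <- function(curves, design, reference_candidates,
                              efficiencies = NULL, min_delta = 5,
                              threshold = NULL, alpha = 0.05) {
  stopifnot(all(c("sample", "group") %in% names(design)))
  if (length(reference_candidates) < 3) {
    abort("geNorm needs at least 3 candidate reference targets")
  }
  eff <- if (is.null(efficiencies)) estimate_efficiency(curves) else efficiencies
  eff_vec <- efficiency_vector(eff)
  cq <- compute_cq(curves, threshold = threshold)
  nort <- filter_nort(cq, min_delta = min_delta)
  kept <- nort |>
    filter(.data$keep) |>
    select("sample", "target", cq = "sample_cq")
  genorm <- genorm_stability(
    filter(kept, .data$target %in% reference_candidates), eff_vec
  )
  cnrq <- compute_cnrq(kept, eff_vec, reference_targets = genorm$selected)
  assay_targets <- setdiff(unique(kept$target), genorm$selected)
  per_target <- cnrq |>
    filter(.data$target %in% assay_targets, !is.na(.data$cnrq)) |>
    left_join(design, by = "sample")
  stats_tbl <- per_target |>
    group_by(.data$target) |>
    dplyr::group_map(function(df, key) {
      bf <- brown_forsythe(mutate(df, y = log10(.data$cnrq)), y, group)
      mutate(tidy(bf), target = key$target, .before = 1)
    }) |>
    list_rbind()
  posthoc <- per_target |>
    group_by(.data$target) |>
    dplyr::group_map(function(df, key) {
      sp <- scheffe_posthoc(mutate(df, y = log10(.data$cnrq)), y, group, alpha = alpha)
      mutate(tidy(sp), target = key$target, .before = 1)
    }) |>
    list_rbind()
  structure(
    list(efficiency = eff, cq = cq, nort_filter = nort, genorm = genorm,
         cnrq = cnrq, stats = stats_tbl, posthoc = posthoc, design = design),
    class = "aqp_qpcr"
  )
}

#' @export
print.aqp_qpcr <- function(x, ...) {
  cat(sprintf(
    "<aqp_qpcr> %d targets, %d samples; references: %s\n",
    length(unique(x$cq$target)), length(unique(x$cq$sample)),
    paste(x$genorm$selected, collapse = " + ")
  ))
  print(x$stats)
  invisible(x)
}

#' Write annotation reports to disk
#'
#' One TSV per report table plus a combined JSON, with a provenance header
#' comment (package version) in each TSV.
#'
#' @param annotation An `aqp_annotation`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_annotation_reports <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- purrr::keep(unclass(annotation), is.data.frame)
  header <- sprintf("# aquasig %s", as.character(utils::packageVersion("aquasig")))
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    writeLines(header, path)
    suppressWarnings(utils::write.table(
      tables[[nm]], path, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE
    ))
  }
  jsonlite::write_json(
    purrr::map(tables, ~ .x), file.path(dir, "annotation.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
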