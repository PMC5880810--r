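## Subfamily classification.
##
## Two independent routes: (i) conserved-residue rules — the PIP Ar/R filter
## is invariably FHTR while TIPs carry class-specific filters such as HIAR
## and HIGR; PIP1 vs PIP2 is decided by the TM2/loop-E water-permeability
## pair; (ii) neighbor-joining placement against a labelled reference panel.

TIP_ARR_REPERTOIRE <- c("HIAR", "HIGR")

#' Classify a query by conserved residues
#'
#' PIP iff the Ar/R filter reads FHTR, with subtype 1 vs 2 decided by the
#' (TM2, loop E) permeability pair — Ala/Ile marks the low-permeability PIP1
#' configuration, Ile-or-Val/Val the high-permeability PIP2 one. TIP iff the
#' filter belongs to the TIP repertoire. Everything else (NIP/SIP/XIP-like
#' filters) is `unknown`.
#'
#' @param ext An `aqp_extraction`.
#' @param tip_arr Accepted TIP Ar/R filters.
#' @return A tibble (one row): `query`, `class`, `subtype`, `method`,
#'   `evidence`.
#' @export
classify_by_residues <- function(ext, tip_arr = TIP_ARR_REPERTOIRE) {
  arr <- extraction_view(ext, "arr")
  perm <- extraction_view(ext, "permeability", collapse = FALSE)
  tm2 <- perm$residue[perm$name == "perm_TM2"]
  loopE <- perm$residue[perm$name == "perm_loopE"]
  evidence <- sprintf("arr=%s; perm=(%s,%s)", arr, tm2, loopE)
  cls <- "unknown"
  subtype <- "n/a"
  if (arr == "FHTR") {
    pc <- permeability_call(ext)
    if (pc$verdict == "low-PIP1-like") {
      cls <- "PIP1"
    } else if (pc$verdict == "high-PIP2-like") {
      cls <- "PIP2"
    } else {
      evidence <- paste0(evidence, "; FHTR filter but permeability pair inconclusive")
    }
  } else if (arr %in% tip_arr) {
    cls <- "TIP"
    loopB_site <- tryCatch(extraction_view(ext, "gating", collapse = FALSE),
                           error = function(e) NULL)
    if (!is.null(loopB_site)) {
      site <- loopB_site$residue[grepl("^loopB", loopB_site$name)]
      if (length(site) == 1 && !site %in% c("S", "T")) {
        evidence <- paste0(evidence, "; loop-B phosphosite absent")
      }
    }
    subtype <- "other"
  }
  tibble(
    query = attr(ext, "query_id"), class = cls, subtype = subtype,
    method = "residues", evidence = evidence
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TIP subtype from the loop-B phosphosite context
#'
#' The loop-B phosphorylation site sits in an `RXSXXR` motif in most
#' alpha-TIPs and in a `TXXR` motif in delta-TIPs; a conserved Ser/Thr whose
#' surroundings match neither marks another TIP type.
#'
#' @param context Residue window around the phosphosite.
#' @param site 1-based index of the phosphosite within `context` (default 3,
#'   the centre of a six-residue `site-2 .. site+3` window; pass 1 for a
#'   four-residue `TXXR` window).
#' @return `"alpha-TIP"`, `"delta-TIP"`, `"other"` or `"n/a"` (no conserved
#'   Ser/Thr at the site).
#' @export
tip_subtype <- function(context, site = 3) {
  context <- toupper(context)
  chars <- strsplit(context, "")[[1]]
  if (site < 1 || site > length(chars)) abort("site outside the context window")
  centre <- chars[site]
  if (centre == "S" && site >= 3 && site + 3 <= length(chars) &&
      chars[site - 2] == "R" && chars[site + 3] == "R") {
    return("alpha-TIP")
  }
  if (centre == "T" && site + 3 <= length(chars) && chars[site + 3] == "R") {
    return("delta-TIP")
  }
  if (centre %in% c("S", "T")) return("other")
  "n/a"
}

#' Pairwise p-distance matrix from an alignment
#'
#' p-distance = mismatches / compared columns, with pairwise deletion:
#' columns holding a gap in either row of the pair are skipped. A Poisson
#' correction `-log(1 - p)` is available behind a flag.
#'
#' @param alignment Alignment tibble (>= 3 rows).
#' @param correction `"none"` (default) or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
pdistance_matrix <- function(alignment, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  alignment <- as_alignment(alignment)
  if (nrow(alignment) < 3) abort("need at least 3 sequences")
  mat <- do.call(rbind, strsplit(alignment$seq, ""))
  rownames(mat) <- alignment$id
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(alignment$id, alignment$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        abort(sprintf("no comparable columns between '%s' and '%s'",
                      alignment$id[i], alignment$id[j]))
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      if (correction == "poisson") {
        if (p >= 1) abort(sprintf(
          "Poisson correction undefined at p = 1 for pair ('%s', '%s')",
          alignment$id[i], alignment$id[j]))
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (delegated to ape's implementation of the
#' Q-criterion agglomeration); negative branch lengths are clamped to zero.
#'
#' @param d Symmetric distance matrix with labelled rows (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (nrow(d) < 3) abort("need at least 3 taxa")
  if (is.null(rownames(d))) abort("distance matrix must have taxon labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) abort("distance matrix must be symmetric")
  if (any(!is.finite(d))) abort("distance matrix must be finite")
  tree <- ape::nj(as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Write a tree to a Newick string or file
#'
#' Branch lengths with fixed decimal formatting, no internal node labels.
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @param digits Decimal digits for branch lengths.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  tree$node.label <- NULL
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# descendant leaf sets of every node, taking the tree's stored rooting
# (for an unrooted NJ tree, the arbitrary basal multifurcation) as reference
tree_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  purrr::map(below[(n_tip + 1):n_node], ~ tree$tip.label[.x])
}

# deterministic outgroup-free rooting: place the root on the longest edge,
# the tree's deepest divergence (a midpoint-style convention)
root_longest_edge <- function(tree) {
  if (is.null(tree$edge.length) || nrow(tree$edge) == 0) return(tree)
  k <- which.max(tree$edge.length)
  child <- tree$edge[k, 2]
  n_tip <- length(tree$tip.label)
  out <- if (child <= n_tip) {
    tree$tip.label[child]
  } else {
    below <- tree_clades(tree)
    # tree_clades indexes internal nodes from n_tip+1
    below[[child - n_tip]]
  }
  if (length(out) == length(tree$tip.label)) return(tree)
  rooted <- try(ape::root(tree, outgroup = out, resolve.root = TRUE), silent = TRUE)
  if (inherits(rooted, "try-error")) tree else rooted
}

#' Assign class labels by clade placement
#'
#' The tree is first rooted on its longest edge (its deepest divergence — a
#' deterministic, outgroup-free convention). Each query is then labelled by
#' the smallest clade containing it that holds at least one panel leaf and is
#' label-pure among the panel leaves it holds; a query whose every
#' surrounding clade mixes panel classes — e.g. one attached outside the
#' whole panel by a long branch — stays `unknown`. Purity is judged over
#' panel leaves only, which makes the rule robust to other queries falling
#' into the same clade.
#'
#' @param tree A `phylo` whose leaves are panel taxa plus queries.
#' @param panel_labels Tibble `id`, `class` for the panel leaves.
#' @param queries Character vector of query leaf names; defaults to all
#'   leaves not in the panel.
#' @return Tibble `query`, `class`, `clade_size`, `method`.
#' @export
assign_by_clade <- function(tree, panel_labels, queries = NULL) {
  stopifnot(all(c("id", "class") %in% names(panel_labels)))
  if (is.null(queries)) queries <- setdiff(tree$tip.label, panel_labels$id)
  missing <- setdiff(queries, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("query leaf(s) absent from tree: %s", paste(missing, collapse = ", ")))
  }
  tree <- root_longest_edge(tree)
  clades <- tree_clades(tree)
  # never label from the all-leaf clade: it surrounds everything trivially
  clades <- purrr::discard(clades, ~ length(.x) == length(tree$tip.label))
  purrr::map(queries, function(q) {
    cand <- purrr::keep(clades, ~ q %in% .x)
    cand <- cand[order(vapply(cand, length, integer(1)))]
    for (side in cand) {
      members <- panel_labels$class[panel_labels$id %in% side]
      if (length(members) >= 1 && length(unique(members)) == 1) {
        return(tibble(query = q, class = unique(members),
                      clade_size = length(side), method = "clade"))
      }
    }
    tibble(query = q, class = "unknown", clade_size = NA_integer_, method = "clade")
  }) |>
    list_rbind()
}
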