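# shared fixtures, memoised so expensive pipeline runs happen once per suite

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

fixture_records <- function(seed = 1) {
  memo(paste0("records_", seed), make_group_records(seed = seed))
}

fixture_annotation <- function() {
  memo("annotation", annotate_aquaporins(fixture_records()))
}

fixture_references <- function() {
  memo("references", load_shipped_references())
}

fixture_rules <- function() {
  memo("rules", load_shipped_rules())
}

fixture_extraction <- function(group) {
  ann <- fixture_references()[[if (grepl("TIP", group)) "TIP" else "PIP"]]
  rec <- fixture_records()[fixture_records()$id == group, c("id", "seq")]
  aln <- global_align(rec, tibble::tibble(id = ann$reference_id, seq = ann$seq))
  extract_signature_residues(rec, transfer_positions(aln, ann), ann)
}

# verdicts for one group against all shipped rule sets
fixture_verdicts <- function(group) {
  ext <- fixture_extraction(group)
  rules <- fixture_rules()
  dplyr::bind_rows(
    match_ssss(ext, rules$ssss_hove),
    match_ssss(ext, rules$ssss_azad),
    match_sdp(ext, rules$sdp_hove)
  )
}

matched_substrates <- function(verdicts, src, type) {
  sort(verdicts$substrate[verdicts$source == src & verdicts$rule_type == type &
                            verdicts$verdict == "match"])
}

# write a temporary fasta and return its path
tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# exhaustive least-squares topology search: the independent oracle for NJ.
# Fits branch lengths of every unrooted topology on n taxa by unconstrained
# least squares on the path-indicator design matrix and returns the
# minimum-RSS tree.
ls_best_topology <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  pairs <- utils::combn(n, 2)
  rss_of <- function(tree) {
    tree$edge.length <- rep(1, nrow(tree$edge))
    # design matrix: rows = taxon pairs, cols = edges on the path
    X <- matrix(0, ncol(pairs), nrow(tree$edge))
    g <- tree$edge
    adj <- lapply(seq_len(max(g)), function(i) integer())
    for (e in seq_len(nrow(g))) {
      adj[[g[e, 1]]] <- c(adj[[g[e, 1]]], e)
      adj[[g[e, 2]]] <- c(adj[[g[e, 2]]], e)
    }
    edge_path <- function(from, to) {
      # BFS over nodes recording edges
      prev_edge <- rep(NA_integer_, max(g))
      prev_node <- rep(NA_integer_, max(g))
      visited <- rep(FALSE, max(g))
      queue <- from
      visited[from] <- TRUE
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        if (v == to) break
        for (e in adj[[v]]) {
          w <- if (g[e, 1] == v) g[e, 2] else g[e, 1]
          if (!visited[w]) {
            visited[w] <- TRUE
            prev_edge[w] <- e
            prev_node[w] <- v
            queue <- c(queue, w)
          }
        }
      }
      out <- integer()
      v <- to
      while (v != from) {
        out <- c(out, prev_edge[v])
        v <- prev_node[v]
      }
      out
    }
    y <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      X[p, edge_path(i, j)] <- 1
      y[p] <- d[labels[i], labels[j]]
    }
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss <- vapply(topos, rss_of, numeric(1))
  topos[[which.min(rss)]]
}

# random additive distance matrix from a random unrooted tree; returns both
random_additive <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.3, 1.5))
  tree$tip.label <- paste0("t", seq_len(n))
  list(tree = tree, d = cophenetic(tree))
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
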