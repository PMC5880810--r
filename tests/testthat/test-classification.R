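test_that("residue rules classify the fixtures into their intended classes", {
  ann <- fixture_annotation()
  cls <- ann$classification
  expect_equal(cls$class[cls$query == "FaPIP1.1"], "PIP1")
  expect_equal(cls$class[cls$query == "FaPIP1.3"], "PIP1")
  expect_equal(cls$class[cls$query == "FaPIP2.2"], "PIP2")
  expect_equal(cls$class[cls$query == "FaTIP.a"], "TIP")
  expect_equal(cls$class[cls$query == "FaTIP.b"], "TIP")
  # subtype is only ever set for TIPs
  expect_true(all(cls$subtype[cls$class != "TIP"] == "n/a"))
  # the shipped TIPs carry the conserved Thr but neither subtype motif
  expect_true(all(cls$subtype[cls$class == "TIP"] == "other"))
})

test_that("an unrecognised filter yields unknown", {
  # NIP-like W-V-A-R filter: mutate a PIP fixture's Ar/R positions
  ann <- fixture_references()$PIP
  rec <- fixture_records()[1, c("id", "seq")]
  chars <- strsplit(rec$seq, "")[[1]]
  chars[ann$arr] <- c("W", "V", "A", "R")
  mrec <- tibble::tibble(id = "nip_like", seq = paste(chars, collapse = ""))
  aln <- global_align(mrec, tibble::tibble(id = ann$reference_id, seq = ann$seq))
  ext <- extract_signature_residues(mrec, transfer_positions(aln, ann), ann)
  expect_equal(classify_by_residues(ext)$class, "unknown")
})

test_that("TIP subtype motifs are recognised", {
  expect_equal(tip_subtype("RKSTAR"), "alpha-TIP")
  expect_equal(tip_subtype("TEGR", site = 1), "delta-TIP")
  # conserved Thr with non-matching surroundings
  expect_equal(tip_subtype("AVTFKD"), "other")
  expect_equal(tip_subtype("AVAFKD"), "n/a")
})

test_that("p-distances follow the pairwise-deletion definition", {
  aln <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c("AAAA", "AAAT", "A-AA")
  )
  d <- pdistance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)
  # a vs c: 3 comparable columns, 0 mismatches; b vs c: 3 comparable, 1 mismatch
  expect_equal(d["a", "c"], 0)
  expect_equal(d["b", "c"], 1 / 3)
  expect_true(isSymmetric(d))

  # gap-only overlap errors with the pair named
  aln2 <- tibble::tibble(id = c("a", "b", "c"), seq = c("AA--", "--AA", "AAAA"))
  expect_error(pdistance_matrix(aln2), "'a' and 'b'")

  # Poisson correction applies -log(1 - p)
  dp <- pdistance_matrix(aln, correction = "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.25))
})

test_that("distance matrices are invariant to row order", {
  aln <- fixture_records()[, c("id", "seq")]
  d1 <- pdistance_matrix(aln)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  d2 <- pdistance_matrix(aln[perm, ])
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("neighbor joining matches closed forms on tiny cases", {
  # equidistant 3 taxa: star tree with branch lengths d/2
  d3 <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  t3 <- neighbor_joining(d3)
  expect_equal(sort(t3$tip.label), c("a", "b", "c"))
  expect_equal(unname(t3$edge.length), rep(0.2, 3))

  # additive 4-taxon matrix from (a:1,b:2,(c:3,d:1):1): exact recovery
  tr <- ape::read.tree(text = "(a:1,b:2,(c:3,d:1):1);")
  d4 <- cophenetic(tr)
  t4 <- neighbor_joining(d4)
  expect_true(same_topology(t4, tr))
  # branch lengths reproduce the additive metric exactly
  expect_equal(cophenetic(t4)[rownames(d4), colnames(d4)], d4)

  # duplicated taxon: zero-length cherry
  d5 <- cophenetic(tr)
  d5 <- rbind(cbind(d5, a2 = d5[, "a"]), a2 = c(d5["a", ], 0))
  t5 <- neighbor_joining(d5)
  m <- cophenetic(t5)
  expect_equal(m["a", "a2"], 0)
})

test_that("NJ recovers random additive topologies, LS oracle agrees (n <= 8)", {
  skip_if_not_installed("phangorn")
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      ra <- random_additive(n, seed = 1000 * n + rep)
      njt <- neighbor_joining(ra$d)
      expect_true(same_topology(njt, ra$tree))
      if (n <= 5) {
        oracle <- ls_best_topology(ra$d)
        expect_true(same_topology(oracle, ra$tree))
        expect_true(same_topology(njt, oracle))
      }
    }
  }
})

test_that("newick output round-trips through ape", {
  tr <- neighbor_joining(random_additive(5, seed = 11)$d)
  txt <- write_newick(tr)
  back <- ape::read.tree(text = txt)
  expect_true(same_topology(tr, back))
  expect_false(grepl("\\)[0-9]", txt)) # no internal labels
})

test_that("clade assignment follows the smallest label-pure surrounding clade", {
  # hand-built tree: query q1 nested in a PIP2 clade; q2 sister to everything
  txt <- "(((p2a:1,(p2b:1,q1:1):1):1,(p1a:1,p1b:1):1):1,(t1:1,t2:1):2,q2:6);"
  tree <- ape::read.tree(text = txt)
  panel <- tibble::tibble(
    id = c("p2a", "p2b", "p1a", "p1b", "t1", "t2"),
    class = c("PIP2", "PIP2", "PIP1", "PIP1", "TIP", "TIP")
  )
  res <- assign_by_clade(tree, panel)
  expect_equal(res$class[res$query == "q1"], "PIP2")
  expect_equal(res$class[res$query == "q2"], "unknown")
  expect_error(assign_by_clade(tree, panel, queries = "nope"), "absent")
})

test_that("clade and residue routes agree on the shipped fixtures", {
  panel <- make_reference_panel(n_per_class = 3, divergence = 0.05, seed = 7)
  expect_equal(nrow(panel), 9)
  recs <- fixture_records()
  aln <- as_alignment(dplyr::bind_rows(panel[, c("id", "seq")],
                                       recs[, c("id", "seq")]))
  tree <- neighbor_joining(pdistance_matrix(aln))
  clade <- assign_by_clade(tree, panel[, c("id", "class")], queries = recs$id)
  residues <- fixture_annotation()$classification
  cmp <- dplyr::left_join(residues[, c("query", "class")], clade, by = "query")
  expect_equal(cmp$class.y, cmp$class.x)
})
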