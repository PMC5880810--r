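# The substrate verdict grid is the package's primary surface: the shipped
# fixtures must reproduce the published signature tables cell for cell.

test_that("SSSS matching reproduces the published per-source substrate calls", {
  v11 <- fixture_verdicts("FaPIP1.1")
  # the E at P1 keeps these groups out of every signature (single mismatch)
  expect_equal(matched_substrates(v11, "hove", "ssss"), character(0))
  expect_equal(matched_substrates(v11, "azad", "ssss"), character(0))
  expect_true(all(v11$verdict[v11$rule_type == "ssss" & v11$source == "hove" &
                                v11$substrate != "ammonia"] == "near-miss"))
  expect_true(all(v11$mismatch_positions[v11$rule_type == "ssss" &
                                           v11$verdict == "near-miss"] == "P1"))

  v13 <- fixture_verdicts("FaPIP1.3")
  expect_equal(matched_substrates(v13, "hove", "ssss"),
               c("boric_acid", "co2", "h2o2", "urea"))
  expect_equal(matched_substrates(v13, "azad", "ssss"), c("co2", "h2o2"))

  v22 <- fixture_verdicts("FaPIP2.2")
  expect_equal(matched_substrates(v22, "hove", "ssss"), c("h2o2", "urea"))
  # boron and CO2 fail at exactly one loop-E signature position
  nm <- v22[v22$rule_type == "ssss" & v22$source == "hove" &
              v22$substrate %in% c("boric_acid", "co2"), ]
  expect_true(all(nm$verdict == "near-miss"))
  expect_true(all(nm$mismatch_positions == "E10"))

  va <- fixture_verdicts("FaTIP.a")
  expect_equal(matched_substrates(va, "hove", "ssss"), c("h2o2", "urea"))
  expect_equal(matched_substrates(va, "azad", "ssss"), character(0))
  vb <- fixture_verdicts("FaTIP.b")
  expect_equal(matched_substrates(vb, "hove", "ssss"), c("ammonia", "h2o2", "urea"))
  expect_equal(matched_substrates(vb, "azad", "ssss"), c("ammonia", "h2o2", "urea"))
})

test_that("SDP matching reproduces the published grid with its near-misses", {
  for (g in c("FaPIP1.1", "FaPIP1.2", "FaPIP1.3")) {
    v <- fixture_verdicts(g)
    expect_equal(matched_substrates(v, "hove", "sdp"),
                 c("boric_acid", "h2o2", "urea"))
  }
  for (g in c("FaPIP2.1a", "FaPIP2.1b")) {
    v <- fixture_verdicts(g)
    expect_equal(matched_substrates(v, "hove", "sdp"), c("h2o2", "urea"))
    # boric acid: exactly one of nine residues deviates
    ba <- v[v$rule_type == "sdp" & v$substrate == "boric_acid", ]
    expect_equal(ba$verdict, "near-miss")
    expect_equal(ba$n_mismatch, 1L)
  }
  v22 <- fixture_verdicts("FaPIP2.2")
  expect_equal(matched_substrates(v22, "hove", "sdp"), "urea")
  nm22 <- v22[v22$rule_type == "sdp" &
                v22$substrate %in% c("boric_acid", "co2", "h2o2"), ]
  expect_true(all(nm22$verdict == "near-miss"))
  expect_true(all(nm22$n_mismatch == 1L))

  for (g in c("FaTIP.a", "FaTIP.b")) {
    v <- fixture_verdicts(g)
    expect_equal(matched_substrates(v, "hove", "sdp"), "urea")
    # H2O2 is a one-of-nine near-miss; boric acid and CO2 are not defined
    expect_equal(v$verdict[v$rule_type == "sdp" & v$substrate == "h2o2"], "near-miss")
    expect_true(all(v$verdict[v$rule_type == "sdp" &
                                v$substrate %in% c("boric_acid", "co2")] == "not-defined"))
    expect_equal(v$verdict[v$rule_type == "sdp" & v$substrate == "ammonia"], "not-defined")
  }
})

test_that("consensus policies reproduce the published summary and nest properly", {
  expected_default <- list(
    FaPIP1.1 = character(0), FaPIP1.2 = character(0),
    FaPIP1.3 = "h2o2", FaPIP2.1a = "h2o2", FaPIP2.1b = "h2o2",
    FaPIP2.2 = character(0), FaTIP.a = character(0),
    FaTIP.b = c("ammonia", "urea")
  )
  for (g in names(expected_default)) {
    v <- fixture_verdicts(g)
    cons <- consensus_prediction(v, policy = "ssss-anchored")
    expect_equal(sort(cons$substrate[cons$consensus]), expected_default[[g]],
                 label = g)
    # nesting: strict subset of default subset of lenient
    strict <- consensus_prediction(v, policy = "strict-intersection")
    lenient <- consensus_prediction(v, policy = "lenient")
    expect_true(all(strict$substrate[strict$consensus] %in%
                      cons$substrate[cons$consensus]))
    expect_true(all(cons$substrate[cons$consensus] %in%
                      lenient$substrate[lenient$consensus]))
  }
  # strict intersection drops ammonia (no SDP rule defined for it)
  vb <- fixture_verdicts("FaTIP.b")
  strict_b <- consensus_prediction(vb, policy = "strict-intersection")
  expect_equal(sort(strict_b$substrate[strict_b$consensus]), "urea")

  # all sources undefined: empty consensus
  empty <- tibble::tibble(
    query = "q", source = c("hove", "azad"), rule_type = "ssss",
    substrate = "h2o2", verdict = "not-defined",
    n_mismatch = NA_integer_, mismatch_positions = ""
  )
  for (p in c("ssss-anchored", "strict-intersection", "lenient")) {
    expect_false(any(consensus_prediction(empty, policy = p)$consensus))
  }
})

test_that("single mutations move verdicts by at most one step", {
  # mutating one rule position can never turn mismatch into match
  rules <- fixture_rules()$ssss_hove
  ext <- fixture_extraction("FaPIP1.3")
  base <- match_ssss(ext, rules)
  rec <- fixture_records()[fixture_records()$id == "FaPIP1.3", c("id", "seq")]
  ann <- fixture_references()$PIP
  # mutate each Froger position in turn to a residue outside every rule
  for (coord in ann$froger) {
    chars <- strsplit(rec$seq, "")[[1]]
    chars[coord] <- "C"
    mrec <- tibble::tibble(id = "mut", seq = paste(chars, collapse = ""))
    aln <- global_align(mrec, tibble::tibble(id = ann$reference_id, seq = ann$seq))
    mext <- extract_signature_residues(mrec, transfer_positions(aln, ann), ann)
    mut <- match_ssss(mext, rules)
    for (s in base$substrate) {
      v0 <- base$verdict[base$substrate == s]
      v1 <- mut$verdict[mut$substrate == s]
      if (v0 == "match") expect_true(v1 %in% c("match", "near-miss"))
      if (v0 == "near-miss") expect_true(v1 %in% c("match", "near-miss", "mismatch"))
      if (v0 == "mismatch") expect_true(v1 != "match")
    }
  }
})

test_that("permeability calls follow the TM2/loop-E pair", {
  ann <- fixture_annotation()
  perm <- ann$permeability
  expect_equal(perm$verdict[perm$query == "FaPIP1.1"], "low-PIP1-like")
  expect_equal(perm$verdict[perm$query == "FaPIP1.3"], "low-PIP1-like")
  expect_equal(perm$verdict[perm$query == "FaPIP2.1a"], "high-PIP2-like")
  expect_equal(perm$verdict[perm$query == "FaPIP2.2"], "high-PIP2-like")
  # TIP pairs fall outside the PIP rule table
  expect_equal(perm$verdict[perm$query == "FaTIP.a"], "undetermined")
})

test_that("gating profiles report present/absent/gap per conserved site", {
  ann <- fixture_annotation()
  pip_gates <- ann$gating[ann$gating$query == "FaPIP1.1", ]
  expect_setequal(pip_gates$site,
                  c("loopB_S", "cterm_S", "loopD_H", "loopD_L", "meth_K", "meth_E"))
  expect_true(all(pip_gates$status == "present"))

  # mutate the loop-B phosphosite Ser to Ala: that site absent, others intact
  ref <- fixture_references()$PIP
  rec <- fixture_records()[1, c("id", "seq")]
  chars <- strsplit(rec$seq, "")[[1]]
  chars[ref$gating$coord[ref$gating$site == "loopB_S"]] <- "A"
  mrec <- tibble::tibble(id = "noS", seq = paste(chars, collapse = ""))
  aln <- global_align(mrec, tibble::tibble(id = ref$reference_id, seq = ref$seq))
  ext <- extract_signature_residues(mrec, transfer_positions(aln, ref), ref)
  gp <- gating_profile(ext, ref)
  expect_equal(gp$status[gp$site == "loopB_S"], "absent")
  expect_true(all(gp$status[gp$site != "loopB_S"] == "present"))

  # a deletion over the loop-D His reports a gap
  chars2 <- strsplit(rec$seq, "")[[1]]
  coordH <- ref$gating$coord[ref$gating$site == "loopD_H"]
  mut2 <- paste(chars2[-(coordH:(coordH + 3))], collapse = "")
  mrec2 <- tibble::tibble(id = "delH", seq = mut2)
  aln2 <- global_align(mrec2, tibble::tibble(id = ref$reference_id, seq = ref$seq))
  ext2 <- extract_signature_residues(mrec2, transfer_positions(aln2, ref), ref)
  gp2 <- gating_profile(ext2, ref)
  expect_equal(gp2$status[gp2$site == "loopD_H"], "gap")
})
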