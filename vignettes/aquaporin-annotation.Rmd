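---
title: "Annotating aquaporins and quantifying their expression with aquasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating aquaporins and quantifying their expression with aquasig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquasig)
library(dplyr)
```

## The problem

Plant aquaporins (major intrinsic proteins, MIPs) are six-transmembrane
channel proteins whose pore selectivity is carried by a small number of
highly conserved residues: the duplicated Asn-Pro-Ala (NPA) motifs in loops
B and E, the four-residue aromatic/Arginine (Ar/R) selectivity filter
(positions H2, H5, LE1, LE2), and the five Froger positions P1–P5. Plasma
membrane intrinsic proteins (PIP1, PIP2) and tonoplast intrinsic proteins
(TIP) can be told apart from these residues alone: the PIP filter is
invariably F-H-T-R, while TIPs carry class-specific filters such as HIAR or
HIGR. Beyond classification, published compilations associate *substrate
specific signature sequences* (SSSS: expected residues across the NPA
windows, the Ar/R filter and P1–P5) and additional *specificity-determining
positions* (SDPs) with transport of H₂O₂, urea, boric acid, CO₂ and
ammonia. Two such compilations — referred to here as the *hove* and *azad*
sources — disagree in places (the azad source defines no boron signature at
all and no urea signature for PIPs), and the package keeps them separate
end to end.

`aquasig` turns this annotation recipe into a pipeline: FASTA in,
tibbles out — topology, motif scan, residue extraction, classification by
two independent routes, per-source substrate verdicts, and a consensus.
A second, independent half of the package implements the RT-qPCR relative
quantification workflow that typically accompanies such a study.

## Sequence annotation

### Topology by hydropathy

`hydropathy_profile()` computes a sliding-window Kyte–Doolittle mean
(window 19 by default, the classic choice for transmembrane screening) and
`predict_tm_helices()` turns it into helix calls: maximal runs of score ≥
1.6, merged across dips of at most 3 residues, kept when at least 15
residues long. These defaults are calibration choices — the original study
used an external HMM tool whose parameters are not ours to reproduce — and
they are fixed so that the shipped six-helix fixtures yield exactly six
helices and five loops labelled A–E. Note one property that run-based
detectors do *not* have: helix count is not monotone in the threshold,
because lowering the threshold can merge two helices across a short loop.
What is monotone is the supra-threshold residue set, and that is what the
property tests assert.

Topology output is descriptive only. Residue extraction is anchored on the
reference alignment, never on predicted helix bounds: topology predictors
are known to misplace the conserved loop-D leucine into the following helix,
while its crystallographic location is loop D. `locate_npa_in_topology()`
therefore only *warns* when an NPA motif falls outside its expected loop.

### Alignment-anchored extraction

Each query is aligned globally (Needleman–Wunsch, affine gaps, BLOSUM62,
gap open 10, gap extend 0.5 — delegated to Biostrings' `pairwiseAlignment`)
against an annotated class reference, and every named coordinate is carried
through alignment columns (`transfer_positions()`). A query gap at a named
position degrades to residue `"-"`; rule matching then reports the affected
substrate as *not-comparable* rather than guessing. `choose_reference()`
picks the PIP or TIP reference by alignment score.

The shipped references are **synthetic**: six-helix scaffolds that carry
the published signature residues at the published alignment-figure
coordinates (e.g. the TM2/loop-E water-permeability pair at 103/249 in PIP
numbering, the loop-E NPA asparagine at 240). The true reference sequences
exist only in figures and an external archive; users with access to a real
annotated translation can re-anchor the pipeline by editing
`sequence_file` in the shipped `*.cfg` annotation configs — coordinates are
1-based and inclusive throughout.

### Classification

`classify_by_residues()` applies the conserved-residue rules: Ar/R = FHTR
makes a PIP, split into PIP1 (Ala in TM2, Ile in loop E: the low-water-
permeability configuration) versus PIP2 (Ile/Val in TM2, Val in loop E);
a filter in the TIP repertoire (HIAR, HIGR) makes a TIP, with
`tip_subtype()` reading the loop-B phosphosite context (RXSXXR → α-TIP,
TXXR → δ-TIP, conserved Ser/Thr alone → "other"). Anything else is
`unknown` — NIP/SIP/XIP rules are deliberately out of scope.

The independent route is distance-based: `pdistance_matrix()` (p-distance
with pairwise deletion; Poisson correction behind a flag) feeds
`neighbor_joining()` (Saitou–Nei via ape, negative branch lengths clamped
to zero) and `assign_by_clade()` labels each query by the smallest
label-pure clade around it. Because NJ output is unrooted and the stored
basal trifurcation is arbitrary — it can even sit on a query — the tree is
first rooted deterministically on its longest edge, a midpoint-style
convention that also makes a long-branch query attached outside the whole
panel come out `unknown` instead of inheriting a neighbour's label. The
distance model is an explicit stand-in: the original analysis used a GUI
program whose defaults are unstated.

### Substrate rules and consensus

Rule tables are data, not code (`inst/extdata/ssss_hove.tsv`,
`ssss_azad.tsv`, `sdp_hove.tsv`), so the hove/azad discrepancies co-exist
as separate sources and users can edit the transcription. A substrate
*matches* when every defined position carries an allowed residue; exactly
one failing position is a *near-miss* — reported, never counted as a match
— mirroring the "only one out of nine residues" discussions in the source
material; a `(class, substrate)` pair with no rule is *not-defined*.

One transcription caveat is important enough to state here: the published
SDP table marks mismatching residues typographically, and that markup does
not survive text extraction. The shipped SDP expected-residue sets are
therefore **reconstructed from the printed verdicts** (which groups fully
match, which are one-of-nine near-misses). Where several fully-matching
groups disagree at a position, the rule stores the alternatives
(e.g. boric-acid position 254 allows K, E, A or D); where no group matches
at all (CO₂), the expected residues are synthesized so that the printed
near-miss/mismatch pattern is reproduced exactly. The printed table is in
fact internally inconsistent for H₂O₂ (identical printed residues across
groups that the text assigns different verdicts); the shipped
transcription resolves this by placing SDP position 265 in the H₂O₂ set,
which reproduces every printed verdict. TIP ammonia SDPs are marked
not-defined: the source omits them as non-matching yet still predicts
ammonia transport for one TIP group, a tension the config preserves rather
than resolves.

`consensus_prediction()` offers three policies. The default,
`ssss-anchored`, requires every SSSS source to define a rule *and* match,
while an undefined SDP rule abstains. This asymmetry is the only reading
that reproduces the published full-correspondence summary: a source that
never compiled a urea signature for PIPs must veto (otherwise urea and
boron would leak into the PIP consensus), while the sparser SDP
compilation cannot veto a substrate it never characterised (otherwise the
TIP ammonia prediction would vanish). `strict-intersection` (any undefined
rule vetoes) and `lenient` (any undefined rule abstains) bracket the
default, and strict ⊆ default ⊆ lenient holds for every input.

```{r annotate}
records <- make_group_records(seed = 1)
ann <- annotate_aquaporins(records)
ann$classification |> select(query, class, subtype)
ann$consensus |> filter(consensus)
```

## RT-qPCR quantification

### Efficiency from raw curves

`estimate_efficiency()` reimplements the window-of-linearity idea behind
LinRegPCR, whose exact constants are proprietary: per well, baseline =
mean fluorescence of cycles 1–5 is subtracted; the exponential phase is
bounded below by the noise band (10 × the SD of cycles 1–5) and above by
half the plateau; among all windows of 4–6 consecutive cycles inside the
phase, the one maximising the R² of log₁₀(fluorescence) against cycle
wins, and E = 10^slope. Wells with no usable window are excluded with a
reason; R² < 0.99 flags a well without excluding it. On logistic curves
the estimator carries a small negative bias (the logistic bends away from
the exponential as the plateau nears, and the best window sits at a few
per cent of plateau); at the simulation's signal-to-noise this bias is
about 0.01–0.02, inside the ±0.03 recovery band the acceptance test
asserts.

### Cq, the no-RT rule, geNorm and CNRQ

`compute_cq()` places the threshold a fixed factor 10 above the noise band
(plate-wide median, so all wells share one threshold) and interpolates the
crossing log-linearly; wells that never cross are censored, and censoring
propagates — nothing is imputed. `filter_nort()` applies the contamination
rule verbatim: a sample is dropped when its no-RT control amplifies within
5 cycles of it; a censored no-RT keeps the sample.

`genorm_stability()` is classic geNorm: candidate j's M value is the mean
SD across samples of its pairwise log₂ ratios with every other candidate;
the highest-M candidate is dropped iteratively until the selected pair
remains. It requires ≥ 3 candidates and complete cases, and ties are
broken toward earlier input order.

`compute_cnrq()` uses the qBase conventions: RQ = E^(mean Cq − Cq) with
the target's mean Cq as calibrator, NRQ = RQ over the geometric mean of
the reference targets' RQ in the same sample, CNRQ = NRQ over the
per-target geometric mean across samples — so per-target CNRQ has
geometric mean exactly 1, an invariant asserted to 1e-9, and CNRQ is
invariant to any constant Cq shift of a target.

### Group comparison

With three biological replicates per tissue, variance homogeneity is not a
safe assumption, so `brown_forsythe()` implements the robust
equality-of-means form of the Brown–Forsythe test (variance-weighted F
with a Satterthwaite-type denominator df) — the parenthetical "robust test
of equality of means" names this variant rather than the Levene-median
location test — paired with `scheffe_posthoc()` at α = 0.05. Values enter
on the log scale; log₁₀ is used (the base is a documented choice — the
source only says "log-transformed" — and it does not affect any test
statistic). Degenerate inputs are pinned down: identical groups give
F* = 0 and p = 1; a group with fewer than two observations is an error.

```{r qpcr}
design <- qpcr_design(seed = 42)
curves <- simulate_qpcr_run(design)
res <- run_qpcr_analysis(
  curves, distinct(curves[, c("sample", "group")]),
  reference_candidates = c("clathrin", "CHP3", "FaPIP1.1", "FaTIP.a")
)
res$genorm$selected
res$stats |> select(target, statistic, p.value)
```

## The synthetic world, and what a green test establishes

The generators are the package's fixture factory and are themselves tested
code. `make_group_sequence()` assembles each expression group from a fixed
per-class backbone (helices from a strongly hydrophobic alphabet, loops
from a hydrophilic one), a deterministic per-lineage variant (PIP1, PIP2
and TIP backbones differ at ~12% of filler sites, because real subfamilies
differ family-wide, and distance trees could not separate them otherwise),
~8% seeded filler substitutions per record, and the group's published
signature residues at their reference coordinates. `qpcr_design()` fixes
the emulated study: seven tissue classes × three biological replicates,
eight targets with the published amplification efficiencies (1.786–2.081),
two reference genes at E = 1.911, logistic curves with 1% multiplicative
noise, clean (censored) no-RT controls by default. The tissue expression
profiles are invented ground truth chosen once to mirror the published
qualitative patterns — leaf-specific, constitutive, fruit-up, fruit-down —
not the real measurements, which are figure-only data and out of scope.

What green tests establish, therefore: the pipeline reproduces the
published signature tables cell-for-cell *given a faithful transcription
of the rules*, recovers known simulation parameters within stated bands,
and obeys its invariants. What they cannot establish: correctness of the
rule transcription beyond the printed verdicts (see the SDP caveat above),
behaviour on real sequences with indels, signal peptides or unusual length
(the synthetic scaffolds are gap-free relative to their reference), or
anything about real expression values.

## Known limitations

* Single-reference pairwise anchoring; no multiple-sequence alignment is
  constructed, and profile methods would outperform it for distant queries.
* No NIP/SIP/XIP rule sets; silicon is intentionally absent from the rule
  files (silicon transport is a NIP feature).
* No bootstrap support, no ML/Bayesian phylogenetics; NJ is the method the
  source analysis used and recovers additive topologies exactly, which the
  test suite verifies against an exhaustive least-squares oracle.
* The qPCR simulator models one amplicon per well with logistic kinetics;
  no melt curves, primer-dimer artefacts or inter-plate calibration.
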