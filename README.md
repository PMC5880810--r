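# aquasig

Sequence-level annotation of plant aquaporins (major intrinsic proteins)
and the RT-qPCR relative-quantification workflow that accompanies their
expression profiling — as one tidyverse-style R package.

## What it does, and for whom

Plant molecular biologists characterising new aquaporin coding sequences
ask the same questions every time: does the protein have the canonical
six-transmembrane topology with the two Asn-Pro-Ala (NPA) motifs in loops
B and E? Which subfamily does it belong to — PIP1, PIP2 or TIP? And which
small solutes is it likely to transport? `aquasig` answers these from
sequence alone:

* **Topology** — sliding-window Kyte–Doolittle hydropathy
  (`hydropathy_profile()`, `predict_tm_helices()`), with NPA motif
  placement checks.
* **Signature extraction** — global alignment (Needleman–Wunsch, affine
  gaps, BLOSUM62) against an annotated class reference, then transfer of
  every named position: the Ar/R selectivity filter (H2, H5, LE1, LE2),
  Froger positions P1–P5, NPA signature windows, gating and
  water-permeability sites, and all substrate-specificity-determining
  positions (SDPs).
* **Classification** — by conserved residues (PIP ⇔ Ar/R = FHTR, PIP1 vs
  PIP2 by the TM2/loop-E permeability pair; TIP filters HIAR/HIGR; α/δ-TIP
  by the loop-B RXSXXR / TXXR motifs) and independently by
  neighbor-joining placement against a labelled panel.
* **Substrate prediction** — matching against two published
  signature-sequence compilations ("hove", "azad") and an SDP table, with
  match / near-miss (exactly one mismatching residue) / mismatch /
  not-defined / not-comparable verdicts per source, combined into a
  consensus under an explicit policy.
* **Expression** — amplification-efficiency estimation from raw
  fluorescence curves (best-R² window of log-linearity), Cq calling, the
  "no-RT within 5 cycles" contamination filter, geNorm reference-gene
  selection, calibrated normalized relative quantities
  (CNRQ = E^ΔCq, normalized to the reference genes' geometric mean and
  calibrated so each target's CNRQ has geometric mean 1 across samples),
  and Brown–Forsythe + Scheffé group comparison of log-transformed CNRQ.

A synthetic-data module generates signature-bearing six-helix sequences,
labelled phylogeny panels and simulated qPCR plates with known ground
truth, so the whole pipeline is testable offline.

## Worked example

```r
library(aquasig)
library(dplyr)

records <- make_group_records(seed = 1)   # the eight expression-group fixtures
ann <- annotate_aquaporins(records)
ann
#> <aqp_annotation> 8 queries
#> # A tibble: 8 × 3
#>   query     class subtype
#>   <chr>     <chr> <chr>
#> 1 FaPIP1.1  PIP1  n/a
#> 2 FaPIP1.2  PIP1  n/a
#> 3 FaPIP1.3  PIP1  n/a
#> 4 FaPIP2.1a PIP2  n/a
#> 5 FaPIP2.1b PIP2  n/a
#> 6 FaPIP2.2  PIP2  n/a
#> 7 FaTIP.a   TIP   other
#> 8 FaTIP.b   TIP   other
#> consensus substrates:
#> # A tibble: 4 × 2
#>   query     substrates
#>   <chr>     <chr>
#> 1 FaPIP1.3  h2o2
#> 2 FaPIP2.1a h2o2
#> 3 FaPIP2.1b h2o2
#> 4 FaTIP.b   ammonia, urea
```

Reading this: all six PIP fixtures carry the invariant F-H-T-R selectivity
filter and are split into PIP1/PIP2 by their TM2/loop-E permeability pair;
the two TIPs carry HIAR/HIGR filters and a conserved loop-B Thr whose
surroundings match neither subtype motif ("other"). Under the default
consensus policy (every signature source must define a rule and match; an
undefined SDP rule abstains), H₂O₂ transport is predicted for FaPIP1.3 and
both FaPIP2.1 groups, and urea + ammonia for FaTIP.b — groups FaPIP1.1 and
FaPIP1.2 match nothing because their Froger P1 is Glu, a residue no
signature allows (each verdict is a near-miss at exactly that position:
see `ann$substrate`).

The expression side, end to end on a simulated plate:

```r
design <- qpcr_design(seed = 42)          # 7 tissues x 3 replicates, 10 targets
curves <- simulate_qpcr_run(design)
res <- run_qpcr_analysis(
  curves, distinct(curves[, c("sample", "group")]),
  reference_candidates = c("clathrin", "CHP3", "FaPIP1.1", "FaTIP.a")
)
res$genorm$selected
#> [1] "CHP3"     "clathrin"
tidy(res$genorm)      # geNorm M ranking
autoplot(res$cnrq, design = res$design)   # expression panels per target
```

geNorm drops the tissue-regulated candidates and keeps the two stable
reference genes; `res$stats` then holds one Brown–Forsythe test per target
across the seven tissue classes (on these simulated data every target is
significant except the constitutively expressed FaPIP1.2).

A thin command-line wrapper with `annotate`, `qpcr` and `simulate`
subcommands lives at `inst/scripts/aquasig.R`.

## Acceptance script

`scripts/acceptance.R` re-runs both pipelines from scratch — generating the
eight group fixtures and a labelled panel, annotating them (topology, NPA,
extraction, both classification routes, substrate verdicts, consensus),
then simulating the full qPCR plate and running efficiency estimation,
Cq calling, the no-RT filter, geNorm, CNRQ and the group statistics —
under a caller-supplied seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Shipped data

`inst/extdata/` holds the plain-text reference annotations
(`pip_reference.cfg`, `tip_reference.cfg`; coordinates are 1-based,
inclusive), the **synthetic** reference scaffolds they point at, and the
editable signature rule tables (`ssss_hove.tsv`, `ssss_azad.tsv`,
`sdp_hove.tsv`). To anchor on a real annotated reference translation,
point `sequence_file` at your own FASTA. See the vignette
(`vignettes/aquaporin-annotation.Rmd`) for the model, the parameter
choices and the transcription caveats.
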