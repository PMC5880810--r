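## Synthetic data generators.
##
## Real strawberry aquaporin sequences live in GenBank; to keep the test
## world offline and fully known, each RT-qPCR group is represented by a
## synthetic six-helix scaffold that carries the group's published signature
## residues (NPA windows, Ar/R filter, Froger positions, SDP residues,
## permeability and gating sites) at the reference coordinates of the
## published alignment numbering. Transmembrane segments are filled from a
## strongly hydrophobic alphabet and loops from a hydrophilic one, so the
## hydropathy predictor recovers exactly six helices. Everything is a pure
## function of (parameters, seed).

HYDROPHOBIC_FILL <- c("I", "L", "V", "F")
HYDROPHILIC_FILL <- c("S", "T", "N", "Q", "G", "E", "D", "K", "R", "P")

# evaluate code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# six-helix scaffold layouts (1-based inclusive segment bounds); the signature
# coordinates of each class's reference numbering dictate where loops must sit
scaffold_layout <- function(class) {
  if (class == "PIP") {
    tibble(
      segment = c("N-term", "TM1", "loopA", "TM2", "loopB", "TM3", "loopC",
                  "TM4", "loopD", "TM5", "loopE", "TM6", "C-term"),
      start = c(1, 15, 41, 79, 108, 136, 162, 178, 203, 214, 236, 262, 287),
      end   = c(14, 40, 78, 107, 135, 161, 177, 202, 213, 235, 261, 286, 295)
    )
  } else if (class == "TIP") {
    tibble(
      segment = c("N-term", "TM1", "loopA", "TM2", "loopB", "TM3", "loopC",
                  "TM4", "loopD", "TM5", "loopE", "TM6", "C-term"),
      start = c(1, 9, 35, 56, 82, 100, 126, 140, 166, 177, 198, 213, 241),
      end   = c(8, 34, 55, 81, 99, 125, 139, 165, 176, 197, 212, 240, 295)
    )
  } else {
    abort(sprintf("no scaffold for class '%s'", class))
  }
}

residue_map <- function(coords, residues) setNames(strsplit(residues, "")[[1]], coords)

pip_common <- function() {
  c(
    setNames(c("K", "E", "F"), c(4, 6, 95)),
    setNames(c("T", "I"), c(108, 111)),
    residue_map(112:121, "SGGHINPAVT"),
    setNames(c("F", "F"), c(122, 125)),
    setNames(c("V", "I", "A", "G", "V", "F"), c(136, 139, 146, 149, 153, 156)),
    setNames(c("E", "L", "H", "L"), c(186, 193, 203, 205)),
    setNames(c("I", "H", "L", "T", "P"), c(220, 222, 229, 231, 233)),
    residue_map(c(236:244, 246), "GTGINPARSG"),
    setNames(c("S", "A", "W", "W"), c(250, 251, 257, 261)),
    setNames(c("F", "W", "P", "S"), c(263, 264, 267, 287))
  )
}

tip_common <- function() {
  c(
    setNames(c("H", "F"), c(65, 68)),
    setNames("F", 92),
    setNames(c("A", "L", "V"), c(119, 123, 126)),
    setNames(c("T", "L", "I", "I", "I", "P"), c(150, 158, 175, 182, 185, 195)),
    setNames(c("A", "T"), c(210, 212)),
    setNames(c("Y", "W", "P"), c(222, 223, 226))
  )
}

#' Group templates for the eight aquaporin expression groups
#'
#' Each template records the group's class and the signature residues placed
#' at its class-reference coordinates: the published loop-B/loop-E NPA
#' decapeptide signatures, Ar/R filter, Froger P1-P5, conserved loop-D
#' residue, TM2/loop-E permeability pair, gating sites and all SDP residues.
#'
#' @return Named list of templates (`FaPIP1.1` ... `FaTIP.b`), each a list
#'   with `group`, `class`, `residues` (named character vector keyed by
#'   reference coordinate).
#' @export
aqp_group_templates <- function() {
  pip_groups <- list(
    # per-group variable positions: 103, 143, 199, 214, 226, 245, 249,
    # 254, 259, 260, 265
    FaPIP1.1  = c("A", "T", "E", "I", "L", "L", "I", "K", "D", "H", "V"),
    FaPIP1.2  = c("A", "T", "E", "I", "L", "L", "I", "E", "H", "H", "V"),
    FaPIP1.3  = c("A", "T", "Q", "I", "L", "L", "I", "A", "D", "Q", "V"),
    FaPIP2.1a = c("I", "S", "Q", "V", "M", "L", "V", "K", "D", "Q", "V"),
    FaPIP2.1b = c("I", "S", "Q", "V", "M", "L", "V", "K", "D", "Q", "V"),
    FaPIP2.2  = c("V", "S", "Q", "V", "M", "F", "V", "D", "D", "H", "L")
  )
  pip_var_coords <- c(103, 143, 199, 214, 226, 245, 249, 254, 259, 260, 265)
  pips <- purrr::imap(pip_groups, function(res, grp) {
    list(group = grp, class = "PIP",
         lineage = if (startsWith(grp, "FaPIP1")) "PIP1" else "PIP2",
         residues = c(pip_common(), setNames(res, pip_var_coords)))
  })
  tips <- list(
    FaTIP.a = list(group = "FaTIP.a", class = "TIP", lineage = "TIP", residues = c(
      tip_common(),
      residue_map(82:91, "SGGHVNPAVT"),
      setNames(c("L", "A", "H", "L"), c(95, 116, 219, 224)),
      residue_map(198:208, "GASMNPARAFG")
    )),
    FaTIP.b = list(group = "FaTIP.b", class = "TIP", lineage = "TIP", residues = c(
      tip_common(),
      residue_map(82:91, "SGGHLNPAVT"),
      setNames(c("A", "S", "N", "V"), c(95, 116, 219, 224)),
      residue_map(198:208, "GGSMNPARSFG")
    ))
  )
  c(pips, tips)
}

# fixed per-class base filler: all synthetic sequences of a class share this
# backbone, as homologous family members would, so reference alignments stay
# gap-free; seed-driven mutation then individualises each record
base_scaffold <- function(class) {
  layout <- scaffold_layout(class)
  with_seed(104729L + match(class, c("PIP", "TIP")), {
    out <- character(max(layout$end))
    for (i in seq_len(nrow(layout))) {
      idx <- layout$start[i]:layout$end[i]
      pool <- if (startsWith(layout$segment[i], "TM")) HYDROPHOBIC_FILL else HYDROPHILIC_FILL
      out[idx] <- sample(pool, length(idx), replace = TRUE)
    }
    out
  })
}

# deterministic per-lineage variant of the class backbone: PIP1, PIP2 and TIP
# are distinct clades, so their members must differ family-wide, not only at
# the handful of signature positions, for distance trees to separate them
LINEAGE_DIVERGENCE <- 0.12
lineage_scaffold <- function(class, lineage) {
  base <- base_scaffold(class)
  layout <- scaffold_layout(class)
  lineage_seed <- 7919L + sum(utf8ToInt(lineage))
  with_seed(lineage_seed, {
    for (i in seq_len(nrow(layout))) {
      idx <- layout$start[i]:layout$end[i]
      hit <- idx[runif(length(idx)) < LINEAGE_DIVERGENCE]
      if (length(hit) > 0) {
        pool <- if (startsWith(layout$segment[i], "TM")) HYDROPHOBIC_FILL else HYDROPHILIC_FILL
        base[hit] <- sample(pool, length(hit), replace = TRUE)
      }
    }
    base
  })
}

#' Generate a signature-bearing synthetic aquaporin sequence
#'
#' Assembles the class scaffold (six hydrophobic segments, hydrophilic loops)
#' from a fixed per-class base filler, substitutes non-signature filler sites
#' with probability `divergence` (within the segment's alphabet, so topology
#' is preserved), and overwrites every templated coordinate with the group's
#' signature residue. Deterministic given `(template, seed, divergence)`;
#' different seeds change only the untemplated filler residues.
#'
#' @param template One element of [aqp_group_templates()].
#' @param seed Integer seed.
#' @param id Record id (defaults to the template's group name).
#' @param divergence Per-site filler substitution probability (default 0.08,
#'   a realistic within-family divergence; 0 reproduces the base scaffold).
#' @return One-row tibble `id`, `class`, `seq`.
#' @export
make_group_sequence <- function(template, seed, id = template$group,
                                divergence = 0.08) {
  layout <- scaffold_layout(template$class)
  len <- max(layout$end)
  coords <- as.integer(names(template$residues))
  if (any(coords < 1 | coords > len)) {
    abort("template residue coordinate outside the class scaffold")
  }
  seq <- lineage_scaffold(template$class, template$lineage %||% template$class)
  if (divergence > 0) {
    seq <- with_seed(seed, {
      for (i in seq_len(nrow(layout))) {
        idx <- setdiff(layout$start[i]:layout$end[i], coords)
        hit <- idx[runif(length(idx)) < divergence]
        if (length(hit) > 0) {
          pool <- if (startsWith(layout$segment[i], "TM")) HYDROPHOBIC_FILL else HYDROPHILIC_FILL
          seq[hit] <- sample(pool, length(hit), replace = TRUE)
        }
      }
      seq
    })
  }
  seq[coords] <- unname(template$residues)
  tibble(id = id, class = template$class, seq = paste(seq, collapse = ""))
}

#' Generate the eight shipped group fixtures
#'
#' @param seed Integer seed for the filler residues.
#' @return Tibble `id`, `class`, `seq` — one row per expression group.
#' @export
make_group_records <- function(seed = 1) {
  templates <- aqp_group_templates()
  purrr::imap(templates, function(tpl, nm) make_group_sequence(tpl, seed, id = nm)) |>
    list_rbind()
}

#' Generate a labelled reference panel for clade assignment
#'
#' Per class (PIP1, PIP2, TIP), mutated copies of a class representative
#' (FaPIP1.1, FaPIP2.1a, FaTIP.a templates) are produced by substituting
#' non-signature sites with probability `divergence`; substitutions stay
#' within the segment's alphabet (hydrophobic in helices) so the scaffold
#' topology survives.
#'
#' @param n_per_class Copies per class (>= 2).
#' @param divergence Per-site substitution probability in `[0, 0.3]` (higher
#'   values would blur the class separation the panel exists to provide).
#' @param seed Integer seed.
#' @return Tibble `id`, `class`, `seq` with ids `<class>_panel_<i>`.
#' @export
make_reference_panel <- function(n_per_class = 3, divergence = 0.05, seed = 7) {
  if (n_per_class < 2) abort("n_per_class must be >= 2")
  if (divergence < 0 || divergence > 0.3) {
    abort("divergence must lie in [0, 0.3] to keep classes separable")
  }
  templates <- aqp_group_templates()
  reps <- list(PIP1 = templates$FaPIP1.1, PIP2 = templates$FaPIP2.1a,
               TIP = templates$FaTIP.a)
  with_seed(seed, {
    purrr::imap(reps, function(tpl, cls) {
      base <- make_group_sequence(tpl, seed = sample.int(1e6, 1))
      layout <- scaffold_layout(tpl$class)
      fixed <- as.integer(names(tpl$residues))
      purrr::map(seq_len(n_per_class), function(i) {
        chars <- strsplit(base$seq, "")[[1]]
        for (s in seq_len(nrow(layout))) {
          idx <- setdiff(layout$start[s]:layout$end[s], fixed)
          hit <- idx[runif(length(idx)) < divergence]
          if (length(hit) > 0) {
            pool <- if (startsWith(layout$segment[s], "TM")) HYDROPHOBIC_FILL else HYDROPHILIC_FILL
            chars[hit] <- sample(pool, length(hit), replace = TRUE)
          }
        }
        tibble(id = sprintf("%s_panel_%d", cls, i), class = cls,
               seq = paste(chars, collapse = ""))
      }) |>
        list_rbind()
    }) |>
      list_rbind()
  })
}

#' Default qPCR simulation design
#'
#' The emulated study design: seven tissue classes (young leaf Ly, mature
#' leaf Lm, petiole P, and four fruit stages sGF, lGF, WF, RF) in three
#' biological replicates; the eight aquaporin target groups with their
#' published amplification efficiencies plus two reference genes (clathrin,
#' CHP3) at E = 1.911. Tissue expression levels are fixed multiplicative
#' profiles chosen to mirror the published qualitative patterns
#' (leaf-specific, constitutive, fruit-regulated); they are the simulation's
#' known ground truth, not reproductions of the real data.
#'
#' @param tissue_groups Character vector of tissue class labels.
#' @param replicates Biological replicates per tissue class.
#' @param targets Tibble `target`, `efficiency`, `is_reference`.
#' @param expression Tibble `target`, one column per tissue class (levels),
#'   or `NULL` for the built-in profiles.
#' @param sigma Multiplicative (lognormal) fluorescence noise SD.
#' @param nort_offset Cycles by which no-RT contamination trails the sample
#'   (`Inf` = clean, censored noRT). Scalar or per-sample named vector.
#' @param cycles Number of PCR cycles.
#' @param baseline,plateau,c_half_base Curve shape parameters: additive
#'   baseline fluorescence, logistic plateau, and the half-plateau cycle of
#'   a level-1 template.
#' @param seed Integer seed (mandatory; the design is the stated world, the
#'   seed its only source of randomness).
#' @return A list of class `aqp_qpcr_design`.
#' @export
qpcr_design <- function(tissue_groups = c("Ly", "Lm", "P", "sGF", "lGF", "WF", "RF"),
                        replicates = 3,
                        targets = default_targets(),
                        expression = NULL,
                        sigma = 0.01,
                        nort_offset = Inf,
                        cycles = 40,
                        baseline = 0.05, plateau = 100, c_half_base = 28,
                        seed = 1) {
  if (is.null(expression)) expression <- default_expression(tissue_groups, targets)
  stopifnot(all(c("target", "efficiency", "is_reference") %in% names(targets)))
  if (any(targets$efficiency <= 1 | targets$efficiency > 2.2)) {
    abort("efficiencies must lie in (1, 2.2]")
  }
  lv <- as.matrix(expression[setdiff(names(expression), "target")])
  if (any(lv <= 0)) abort("expression levels must be positive")
  samples <- tibble(
    group = rep(tissue_groups, each = replicates),
    replicate = rep(seq_len(replicates), length(tissue_groups))
  ) |>
    mutate(sample = sprintf("%s_%d", .data$group, .data$replicate))
  structure(
    list(tissue_groups = tissue_groups, samples = samples, targets = targets,
         expression = expression, sigma = sigma, nort_offset = nort_offset,
         cycles = cycles, baseline = baseline, plateau = plateau,
         c_half_base = c_half_base, seed = seed),
    class = "aqp_qpcr_design"
  )
}

default_targets <- function() {
  tibble(
    target = c("FaPIP1.1", "FaPIP1.2", "FaPIP1.3", "FaPIP2.1a", "FaPIP2.1b",
               "FaPIP2.2", "FaTIP.a", "FaTIP.b", "clathrin", "CHP3"),
    efficiency = c(1.895, 1.902, 1.881, 1.786, 1.902, 1.897, 2.081, 1.903,
                   1.911, 1.911),
    is_reference = c(rep(FALSE, 8), TRUE, TRUE)
  )
}

default_expression <- function(tissue_groups, targets) {
  profiles <- tibble(
    target = c("FaPIP1.1", "FaPIP1.2", "FaPIP1.3", "FaPIP2.1a", "FaPIP2.1b",
               "FaPIP2.2", "FaTIP.a", "FaTIP.b", "clathrin", "CHP3"),
    Ly  = c(0.30, 1, 4.00, 0.50, 3.0, 2.0, 0.05, 0.10, 1, 1),
    Lm  = c(0.30, 1, 4.00, 0.50, 3.0, 2.0, 0.05, 0.10, 1, 1),
    P   = c(0.40, 1, 0.50, 0.70, 3.0, 2.0, 0.10, 1.00, 1, 1),
    sGF = c(2.00, 1, 0.30, 1.00, 0.8, 1.6, 3.00, 0.80, 1, 1),
    lGF = c(1.60, 1, 0.25, 1.50, 1.0, 1.2, 2.50, 1.00, 1, 1),
    WF  = c(1.20, 1, 0.20, 2.00, 1.3, 0.8, 2.00, 1.30, 1, 1),
    RF  = c(0.80, 1, 0.15, 2.50, 1.6, 0.5, 1.50, 1.60, 1, 1)
  )
  missing <- setdiff(targets$target, profiles$target)
  if (length(missing) > 0) {
    abort(sprintf("no default expression profile for target(s): %s; supply `expression`",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(tissue_groups, setdiff(names(profiles), "target"))
  if (length(extra) > 0) {
    abort(sprintf("no default levels for tissue group(s): %s; supply `expression`",
                  paste(extra, collapse = ", ")))
  }
  profiles[match(targets$target, profiles$target), c("target", tissue_groups)]
}

#' Simulate a qPCR run
#'
#' Per well a logistic amplification curve
#' `F(c) = baseline + plateau / (1 + exp(-k (c - c_half)))` with
#' `k = log(E)`, so the early exponential phase gains a fold-change of E per
#' cycle; `c_half` encodes the template amount
#' (`c_half_base - log(level) / log(E)`). Multiplicative lognormal noise of
#' SD `sigma` is applied to every reading. no-RT wells re-use the sample
#' curve delayed by `nort_offset` cycles (`Inf` gives a flat baseline well).
#'
#' @param design An [qpcr_design()] object.
#' @return Long tibble: `sample`, `group`, `target`, `well_type`
#'   (`sample` / `noRT`), `cycle`, `fluorescence`. Deterministic given the
#'   design's seed.
#' @export
simulate_qpcr_run <- function(design) {
  stopifnot(inherits(design, "aqp_qpcr_design"))
  lv <- design$expression
  level_of <- function(target, group) lv[[group]][match(target, lv$target)]
  offsets <- design$nort_offset
  offset_of <- function(sample) {
    if (length(offsets) == 1 && is.null(names(offsets))) offsets
    else if (!is.null(names(offsets)) && sample %in% names(offsets)) offsets[[sample]]
    else if (!is.null(names(offsets))) Inf
    else offsets
  }
  cyc <- seq_len(design$cycles)
  with_seed(design$seed, {
    grid <- tidyr::expand_grid(design$samples, target = design$targets$target)
    purrr::pmap(grid, function(group, replicate, sample, target) {
      eff <- design$targets$efficiency[design$targets$target == target]
      k <- log(eff)
      level <- level_of(target, group)
      c_half <- design$c_half_base - log(level) / k
      make_curve <- function(shift) {
        signal <- if (is.infinite(shift)) 0 else {
          design$plateau / (1 + exp(-k * (cyc - (c_half + shift))))
        }
        f <- design$baseline + signal
        if (design$sigma > 0) f <- f * exp(rnorm(length(cyc), 0, design$sigma))
        f
      }
      f_sample <- make_curve(0)
      f_nort <- make_curve(offset_of(sample))
      bind_rows(
        tibble(sample = sample, group = group, target = target,
               well_type = "sample", cycle = cyc, fluorescence = f_sample),
        tibble(sample = sample, group = group, target = target,
               well_type = "noRT", cycle = cyc, fluorescence = f_nort)
      )
    }) |>
      list_rbind()
  })
}
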