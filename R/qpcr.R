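## RT-qPCR relative quantification.
##
## The workflow mirrors standard practice: per-well amplification efficiency
## from the window of log-linearity (a LinRegPCR-style best-R2 sliding
## window), threshold-based Cq calling, exclusion of samples whose no-RT
## control amplifies within 5 cycles of the sample (genomic contamination),
## geNorm reference-gene stability, and qBase-style calibrated normalized
## relative quantities (CNRQ).

well_key <- function(curves) {
  if ("well" %in% names(curves)) curves$well
  else paste(curves$sample, curves$target, curves$well_type, sep = "|")
}

geomean <- function(x) exp(mean(log(x)))

#' Estimate amplification efficiency from raw curves
#'
#' Per well: the baseline (mean fluorescence of cycles 1-5) is subtracted,
#' the exponential phase is delimited by the noise band (10 x the SD of
#' cycles 1-5) below and half the plateau above, and the window of 4-6
#' consecutive cycles maximising the R-squared of log10(fluorescence) vs
#' cycle inside that phase gives the efficiency E = 10^slope (fold-change
#' per cycle; 2 is perfect doubling). Wells without a usable window are
#' excluded with a reason; wells with R-squared below `r2_flag` are kept but
#' flagged.
#'
#' @param curves Long tibble: `sample`, `target`, `well_type`, `cycle`,
#'   `fluorescence` (optionally `well`). Only `well_type == "sample"` wells
#'   are used.
#' @param window_len Candidate window lengths (default 4:6).
#' @param r2_flag R-squared below which a well is flagged (default 0.99).
#' @return An object of class `aqp_efficiency`: list with `wells` (per-well
#'   tibble: `target`, `sample`, `well`, `efficiency`, `window_start`,
#'   `window_len`, `r2`, `flagged`, `excluded`, `reason`) and `targets`
#'   (per-target tibble: `target`, `efficiency` = arithmetic mean over
#'   usable wells, `n_wells`).
#' @export
estimate_efficiency <- function(curves, window_len = 4:6, r2_flag = 0.99) {
  stopifnot(all(c("sample", "target", "well_type", "cycle", "fluorescence") %in% names(curves)))
  curves <- curves[curves$well_type == "sample", , drop = FALSE]
  if (nrow(curves) == 0) abort("no sample wells in input")
  curves$.well <- well_key(curves)

  wells <- curves |>
    group_by(.data$target, .data$sample, .data$.well) |>
    dplyr::group_map(function(df, key) {
      df <- arrange(df, .data$cycle)
      fit <- fit_efficiency_well(df$cycle, df$fluorescence, window_len)
      tibble(
        target = key$target, sample = key$sample, well = key$.well,
        efficiency = fit$efficiency, window_start = fit$window_start,
        window_len = fit$window_len, r2 = fit$r2,
        flagged = !is.na(fit$r2) && fit$r2 < r2_flag,
        excluded = fit$excluded, reason = fit$reason
      )
    }) |>
    list_rbind()

  targets <- wells |>
    filter(!.data$excluded) |>
    group_by(.data$target) |>
    summarise(efficiency = mean(.data$efficiency), n_wells = dplyr::n(), .groups = "drop")
  missing <- setdiff(unique(wells$target), targets$target)
  if (length(missing) > 0) {
    abort(sprintf("all wells excluded for target(s): %s", paste(missing, collapse = ", ")))
  }
  structure(list(wells = wells, targets = targets), class = "aqp_efficiency")
}

fit_efficiency_well <- function(cycle, f, window_len) {
  if (length(cycle) < 15) abort("fluorescence series must cover at least 15 cycles")
  base_idx <- cycle <= 5
  baseline <- mean(f[base_idx])
  noise <- stats::sd(f[base_idx])
  fs <- f - baseline
  plateau <- max(fs)
  lo <- 10 * noise
  in_phase <- fs > lo & fs < plateau / 2 & fs > 0
  excluded <- list(efficiency = NA_real_, window_start = NA_integer_,
                   window_len = NA_integer_, r2 = NA_real_,
                   excluded = TRUE, reason = "no exponential phase")
  if (sum(in_phase) < min(window_len)) return(excluded)

  best <- NULL
  for (len in window_len) {
    for (s in seq_len(length(cycle) - len + 1)) {
      idx <- s:(s + len - 1)
      if (!all(in_phase[idx])) next
      y <- log10(fs[idx])
      x <- cycle[idx]
      fit <- stats::lm.fit(cbind(1, x), y)
      res <- fit$residuals
      r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
      if (!is.finite(r2)) r2 <- -Inf
      if (is.null(best) || r2 > best$r2) {
        best <- list(efficiency = 10^fit$coefficients[[2]],
                     window_start = cycle[s], window_len = len, r2 = r2)
      }
    }
  }
  if (is.null(best)) return(excluded)
  c(best, list(excluded = FALSE, reason = ""))
}

#' @export
print.aqp_efficiency <- function(x, ...) {
  cat(sprintf("<aqp_efficiency> %d targets, %d wells (%d excluded)\n",
              nrow(x$targets), nrow(x$wells), sum(x$wells$excluded)))
  print(x$targets)
  invisible(x)
}

#' Call quantification cycles (Cq)
#'
#' Cq is the fractional cycle at which fluorescence first crosses the
#' threshold, log-linearly interpolated between the bracketing cycles. The
#' default policy places the threshold a fixed factor of 10 above the noise
#' band (per-well baseline mean + 10 SD of cycles 1-5; the plate-wide median
#' band is used so all wells share one threshold). Wells that never cross
#' are censored (`NA`).
#'
#' @param curves Long curve tibble (all well types).
#' @param threshold Numeric threshold on raw fluorescence; `NULL` (default)
#'   derives it from the noise band as described.
#' @return Tibble: `sample`, `target`, `well_type`, `well`, `cq`
#'   (`NA` = censored), plus attribute `threshold`.
#' @export
compute_cq <- function(curves, threshold = NULL) {
  stopifnot(all(c("sample", "target", "well_type", "cycle", "fluorescence") %in% names(curves)))
  curves$.well <- well_key(curves)
  if (is.null(threshold)) {
    bands <- curves |>
      filter(.data$cycle <= 5) |>
      group_by(.data$.well) |>
      summarise(band = mean(.data$fluorescence) + 10 * stats::sd(.data$fluorescence),
                .groups = "drop")
    threshold <- 10 * stats::median(bands$band)
  }
  out <- curves |>
    group_by(.data$sample, .data$target, .data$well_type, .data$.well) |>
    dplyr::group_map(function(df, key) {
      df <- arrange(df, .data$cycle)
      tibble(sample = key$sample, target = key$target,
             well_type = key$well_type, well = key$.well,
             cq = cq_one_well(df$cycle, df$fluorescence, threshold))
    }) |>
    list_rbind()
  attr(out, "threshold") <- threshold
  out
}

cq_one_well <- function(cycle, f, threshold) {
  over <- which(f >= threshold)
  if (length(over) == 0) return(NA_real_)
  i <- over[1]
  if (i == 1) return(cycle[1])
  f0 <- f[i - 1]; f1 <- f[i]
  if (f0 <= 0) {
    # cannot log-interpolate; fall back to linear
    return(cycle[i - 1] + (threshold - f0) / (f1 - f0) * (cycle[i] - cycle[i - 1]))
  }
  cycle[i - 1] + (log(threshold) - log(f0)) / (log(f1) - log(f0)) *
    (cycle[i] - cycle[i - 1])
}

#' Apply the no-RT contamination filter
#'
#' A sample/target measurement is dropped when the difference in Cq between
#' its no-RT control and the sample is smaller than `min_delta` cycles
#' (genomic DNA contamination non-negligible). A censored no-RT (no
#' amplification at all) keeps the sample; a censored sample Cq drops it.
#'
#' @param cq Cq tibble from [compute_cq()] containing `sample` and `noRT`
#'   well types.
#' @param min_delta Minimum acceptable Cq difference (default 5 cycles).
#' @return Tibble: `sample`, `target`, `sample_cq`, `nort_cq`, `delta`,
#'   `keep`, `reason`.
#' @export
filter_nort <- function(cq, min_delta = 5) {
  samples <- cq |>
    filter(.data$well_type == "sample") |>
    select("sample", "target", sample_cq = "cq")
  norts <- cq |>
    filter(.data$well_type == "noRT") |>
    select("sample", "target", nort_cq = "cq")
  samples |>
    left_join(norts, by = c("sample", "target")) |>
    mutate(
      delta = .data$nort_cq - .data$sample_cq,
      keep = dplyr::case_when(
        is.na(.data$sample_cq) ~ FALSE,
        is.na(.data$nort_cq) ~ TRUE,
        .data$delta >= min_delta ~ TRUE,
        TRUE ~ FALSE
      ),
      reason = dplyr::case_when(
        is.na(.data$sample_cq) ~ "sample Cq censored",
        is.na(.data$nort_cq) ~ "noRT censored (no amplification)",
        .data$delta >= min_delta ~ "",
        TRUE ~ sprintf("noRT within %.1f cycles of sample", .data$delta)
      )
    )
}

#' geNorm reference-gene stability
#'
#' Classic geNorm: for candidate *j*, the stability measure M_j is the mean,
#' over all other candidates *k*, of the standard deviation across samples of
#' log2(RQ_j / RQ_k). The least stable (highest M) candidate is dropped
#' iteratively until two remain — the selected reference pair.
#'
#' @param cq Tibble `sample`, `target`, `cq` restricted to the candidate
#'   reference targets (sample wells, post no-RT filter).
#' @param efficiencies Named numeric vector or tibble (`target`,
#'   `efficiency`) of per-target amplification efficiencies.
#' @return An object of class `aqp_genorm`: list with `ranking` (tibble
#'   `candidate`, `M`, `step`; step 0 = survived to the final pair, higher
#'   steps = dropped earlier in the order given), `selected` (character of
#'   length 2) and `m_initial` (all-candidate M values).
#' @export
genorm_stability <- function(cq, efficiencies) {
  eff <- efficiency_vector(efficiencies)
  cands <- unique(cq$target)
  if (length(cands) < 3) abort("geNorm needs at least 3 candidate references")
  wide <- cq |>
    select("sample", "target", "cq") |>
    tidyr::pivot_wider(names_from = "target", values_from = "cq")
  for (cand in cands) {
    if (!cand %in% names(wide) || anyNA(wide[[cand]])) {
      abort(sprintf("candidate '%s' is missing a sample value (complete-case policy)", cand))
    }
  }
  if (nrow(wide) < 2) abort("geNorm needs at least 2 samples")
  missing_eff <- setdiff(cands, names(eff))
  if (length(missing_eff) > 0) {
    abort(sprintf("no efficiency for candidate(s): %s", paste(missing_eff, collapse = ", ")))
  }
  rq <- purrr::map(cands, function(t) eff[[t]]^(mean(wide[[t]]) - wide[[t]]))
  names(rq) <- cands

  m_values <- function(active) {
    vapply(active, function(j) {
      mean(vapply(setdiff(active, j), function(k) {
        stats::sd(log2(rq[[j]] / rq[[k]]))
      }, numeric(1)))
    }, numeric(1))
  }

  active <- cands
  m_initial <- m_values(active)
  dropped <- character()
  m_at_drop <- numeric()
  while (length(active) > 2) {
    m <- m_values(active)
    # ties: drop the latest in input order so earlier candidates are preferred
    worst <- active[max(which(m == max(m)))]
    dropped <- c(dropped, worst)
    m_at_drop <- c(m_at_drop, max(m))
    active <- setdiff(active, worst)
  }
  ranking <- tibble(
    candidate = c(active, rev(dropped)),
    M = c(m_values(active), rev(m_at_drop)),
    step = c(0L, 0L, rev(seq_along(dropped)))
  )
  structure(
    list(ranking = ranking, selected = active,
         m_initial = setNames(m_initial, cands)),
    class = "aqp_genorm"
  )
}

efficiency_vector <- function(efficiencies) {
  if (is.data.frame(efficiencies)) {
    setNames(efficiencies$efficiency, efficiencies$target)
  } else if (inherits(efficiencies, "aqp_efficiency")) {
    setNames(efficiencies$targets$efficiency, efficiencies$targets$target)
  } else {
    efficiencies
  }
}

#' @export
print.aqp_genorm <- function(x, ...) {
  cat(sprintf("<aqp_genorm> selected pair: %s\n", paste(x$selected, collapse = " + ")))
  print(x$ranking)
  invisible(x)
}

#' Calibrated normalized relative quantities (CNRQ)
#'
#' qBase-style quantification: per (sample, target),
#' `RQ = E^(mean Cq_target - Cq)` (mean-Cq calibrator),
#' `NRQ = RQ / geometric mean of the reference targets' RQ in that sample`,
#' `CNRQ = NRQ / geometric mean of NRQ across samples for that target` —
#' so CNRQ has per-target geometric mean 1 across samples by construction.
#' A sample missing any reference Cq has its NRQ/CNRQ censored (`NA`); no
#' imputation.
#'
#' @param cq Tibble `sample`, `target`, `cq` (sample wells, post filter).
#' @param efficiencies Per-target efficiencies (named vector, tibble, or
#'   [estimate_efficiency()] result).
#' @param reference_targets Character vector (>= 1) of reference target ids.
#' @return An object of class `aqp_cnrq`: tibble `sample`, `target`, `cq`,
#'   `rq`, `nrq`, `cnrq` with attributes `reference_targets`, `efficiencies`
#'   and `calibration` (per-target geometric means divided out).
#' @export
compute_cnrq <- function(cq, efficiencies, reference_targets) {
  eff <- efficiency_vector(efficiencies)
  stopifnot(length(reference_targets) >= 1)
  missing_ref <- setdiff(reference_targets, unique(cq$target))
  if (length(missing_ref) > 0) {
    abort(sprintf("reference target(s) absent from Cq table: %s",
                  paste(missing_ref, collapse = ", ")))
  }
  missing_eff <- setdiff(unique(cq$target), names(eff))
  if (length(missing_eff) > 0) {
    abort(sprintf("no efficiency for target(s): %s", paste(missing_eff, collapse = ", ")))
  }
  tab <- cq |>
    filter(!is.na(.data$cq)) |>
    group_by(.data$target) |>
    mutate(rq = eff[.data$target[1]]^(mean(.data$cq) - .data$cq)) |>
    ungroup()

  norm <- tab |>
    filter(.data$target %in% reference_targets) |>
    group_by(.data$sample) |>
    summarise(nf = geomean(.data$rq), n_ref = dplyr::n(), .groups = "drop") |>
    mutate(nf = ifelse(.data$n_ref == length(reference_targets), .data$nf, NA_real_))

  tab <- tab |>
    left_join(select(norm, "sample", "nf"), by = "sample") |>
    mutate(nrq = .data$rq / .data$nf) |>
    group_by(.data$target) |>
    mutate(cnrq = .data$nrq / geomean(.data$nrq[!is.na(.data$nrq)])) |>
    ungroup()

  calib <- tab |>
    group_by(.data$target) |>
    summarise(calibration = geomean(.data$nrq[!is.na(.data$nrq)]), .groups = "drop")

  out <- select(tab, "sample", "target", "cq", "rq", "nrq", "cnrq")
  structure(out,
            reference_targets = reference_targets,
            efficiencies = eff[unique(cq$target)],
            calibration = calib,
            class = c("aqp_cnrq", class(out)))
}

#' Plot CNRQ expression levels
#'
#' @param object An `aqp_cnrq` table.
#' @param design Optional tibble `sample`, `group` to order/facet samples by
#'   tissue group.
#' @param ... Ignored.
#' @return A ggplot object (points + per-group geometric mean bars, one facet
#'   per target).
#' @exportS3Method ggplot2::autoplot
autoplot.aqp_cnrq <- function(object, design = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(design)) {
    df <- left_join(df, design, by = "sample")
  } else {
    df$group <- df$sample
  }
  summ <- df |>
    filter(!is.na(.data$cnrq)) |>
    group_by(.data$target, .data$group) |>
    summarise(cnrq = geomean(.data$cnrq), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$cnrq)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(data = filter(df, !is.na(.data$cnrq)), size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "CNRQ (non-log)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot geNorm stability ranking
#'
#' @param object An `aqp_genorm` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aqp_genorm <- function(object, ...) {
  df <- mutate(object$ranking,
               status = ifelse(.data$step == 0, "selected", "excluded"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$candidate, .data$M),
                                   y = .data$M, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "geNorm M") +
    ggplot2::theme_minimal()
}
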