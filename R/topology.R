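## Transmembrane topology by hydropathy.
##
## A sliding-window Kyte-Doolittle profile stands in for the HMM topology
## predictors usually run on aquaporins; defaults (window 19, threshold 1.6,
## minimum helix length 15) are the classic settings for transmembrane
## screening. Topology output is descriptive only: residue extraction is
## anchored on the reference alignment, never on predicted helix bounds,
## because topology software is known to misplace conserved loop-D residues.

# Kyte & Doolittle (1982) hydropathy index; X scores 0, gaps are stripped
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' @param seq A single amino-acid sequence (gaps are stripped first).
#' @param window Odd window size `>= 5`; the score at residue *i* is the mean
#'   Kyte-Doolittle index over the window centred at *i*, with shrunken
#'   windows at the ends so the profile has one value per residue.
#' @return A tibble with columns `pos`, `residue`, `score`.
#' @export
hydropathy_profile <- function(seq, window = 19) {
  stopifnot(length(seq) == 1)
  seq <- ungap(toupper(seq))
  n <- nchar(seq)
  if (n < 5) abort("sequence shorter than 5 residues")
  if (window < 5 || window %% 2 == 0) abort("window must be odd and >= 5")
  if (n < window) abort(sprintf("sequence length %d shorter than window %d", n, window))
  res <- strsplit(seq, "")[[1]]
  kd <- unname(KD_SCALE[res])
  if (anyNA(kd)) abort("sequence contains residues outside the amino-acid alphabet")
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, kd))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  score <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  tibble(pos = seq_len(n), residue = res, score = score)
}

#' Predict transmembrane helices from a hydropathy profile
#'
#' Maximal runs of score `>= threshold` are candidate helices; runs separated
#' by at most `merge_gap` sub-threshold residues are merged, and merged runs
#' shorter than `min_len` are discarded. When exactly six helices remain the
#' five connecting loops are labelled A-E (the aquaporin convention),
#' otherwise loops are numbered.
#'
#' @param profile Tibble from [hydropathy_profile()] (columns `pos`, `score`).
#' @param threshold Hydropathy threshold (default 1.6).
#' @param min_len Minimum helix length (default 15).
#' @param merge_gap Maximum gap merged between adjacent runs (default 3).
#' @return An object of class `aqp_topology`: list with `helices` (tibble
#'   `helix`, `start`, `end`, `mean_hydropathy`), `loops` (tibble `loop`,
#'   `start`, `end`), `states` (per-residue labels) and the `profile`.
#'   Zero helices is a valid result.
#' @export
predict_tm_helices <- function(profile, threshold = 1.6, min_len = 15, merge_gap = 3) {
  stopifnot(all(c("pos", "score") %in% names(profile)))
  n <- nrow(profile)
  above <- profile$score >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- tibble(start = starts, end = ends, above = runs$values) |> filter(.data$above)

  # merge runs separated by short dips
  if (nrow(seg) > 1) {
    merged <- list(c(seg$start[1], seg$end[1]))
    for (i in 2:nrow(seg)) {
      last <- merged[[length(merged)]]
      if (seg$start[i] - last[2] - 1L <= merge_gap) {
        merged[[length(merged)]] <- c(last[1], seg$end[i])
      } else {
        merged[[length(merged) + 1]] <- c(seg$start[i], seg$end[i])
      }
    }
    seg <- tibble(
      start = vapply(merged, `[[`, numeric(1), 1),
      end = vapply(merged, `[[`, numeric(1), 2)
    )
  }
  seg <- seg |>
    filter(.data$end - .data$start + 1L >= min_len) |>
    select("start", "end")

  helices <- seg |>
    mutate(
      helix = row_number(),
      mean_hydropathy = purrr::map2_dbl(
        .data$start, .data$end,
        ~ mean(profile$score[.x:.y])
      )
    ) |>
    select("helix", "start", "end", "mean_hydropathy")

  k <- nrow(helices)
  loops <- tibble(loop = character(), start = integer(), end = integer())
  if (k >= 2) {
    loop_names <- if (k == 6) LETTERS[1:5] else as.character(seq_len(k - 1))
    loops <- tibble(
      loop = loop_names,
      start = helices$end[-k] + 1L,
      end = helices$start[-1] - 1L
    )
  }

  states <- rep("N-term", n)
  if (k > 0) {
    for (i in seq_len(k)) {
      states[helices$start[i]:helices$end[i]] <- paste0("TM", i)
    }
    for (i in seq_len(nrow(loops))) {
      if (loops$start[i] <= loops$end[i]) {
        states[loops$start[i]:loops$end[i]] <- paste0("loop", loops$loop[i])
      }
    }
    if (helices$end[k] < n) states[(helices$end[k] + 1L):n] <- "C-term"
  }

  structure(
    list(helices = helices, loops = loops, states = states, profile = profile),
    class = "aqp_topology"
  )
}

#' @export
print.aqp_topology <- function(x, ...) {
  cat(sprintf("<aqp_topology> %d helices, %d loops over %d residues\n",
              nrow(x$helices), nrow(x$loops), nrow(x$profile)))
  if (nrow(x$helices) > 0) print(x$helices)
  invisible(x)
}

#' Check NPA motif placement against a predicted topology
#'
#' Reports whether the first NPA hit falls in loop B and the second in loop E.
#' A misplaced motif raises a warning, not an error: hydropathy topology is
#' known to shift loop boundaries relative to the crystallographic truth.
#'
#' @param topology An `aqp_topology`.
#' @param npa_hits Tibble from [scan_npa()] (columns `start`, `motif`).
#' @return A tibble with columns `motif`, `start`, `expected_loop`,
#'   `observed_state`, `ok`.
#' @export
locate_npa_in_topology <- function(topology, npa_hits) {
  expected <- c("loopB", "loopE")
  n_hit <- nrow(npa_hits)
  if (n_hit < 2) {
    warn(sprintf("expected 2 NPA motifs, found %d", n_hit))
  }
  take <- min(n_hit, 2L)
  out <- tibble(
    motif = npa_hits$motif[seq_len(take)],
    start = npa_hits$start[seq_len(take)],
    expected_loop = expected[seq_len(take)]
  ) |>
    mutate(
      observed_state = map_chr(.data$start, function(p) {
        if (p >= 1 && p <= length(topology$states)) topology$states[p] else "outside"
      }),
      ok = .data$observed_state == .data$expected_loop
    )
  if (take < 2) {
    out <- bind_rows(out, tibble(
      motif = NA_character_, start = NA_integer_,
      expected_loop = expected[(take + 1):2],
      observed_state = "missing", ok = FALSE
    ))
  }
  if (any(!out$ok & out$observed_state != "missing")) {
    warn(paste0(
      "NPA motif outside its expected loop: ",
      paste(sprintf("%s at %d in %s", out$motif[!out$ok], out$start[!out$ok],
                    out$observed_state[!out$ok]), collapse = "; ")
    ))
  }
  out
}

#' Topology report across records
#'
#' Convenience wrapper: hydropathy profile + helix prediction per record.
#'
#' @param records Tibble (`id`, `seq`).
#' @param window,threshold,min_len,merge_gap Passed through.
#' @return Tibble: `id`, `helix`, `start`, `end`, `mean_hydropathy`, and
#'   `n_helices` per record.
#' @export
topology_report <- function(records, window = 19, threshold = 1.6,
                            min_len = 15, merge_gap = 3) {
  purrr::map2(records$id, records$seq, function(id, s) {
    topo <- predict_tm_helices(hydropathy_profile(s, window),
                               threshold, min_len, merge_gap)
    if (nrow(topo$helices) == 0) {
      return(tibble(id = id, helix = integer(), start = integer(),
                    end = integer(), mean_hydropathy = double(),
                    n_helices = integer()))
    }
    mutate(topo$helices, id = id, n_helices = nrow(topo$helices),
           .before = 1)
  }) |>
    list_rbind()
}

#' @rdname autoplot.aqp_topology
#' @exportS3Method ggplot2::autoplot
autoplot.aqp_topology <- function(object, ...) {
  helices <- object$helices
  p <- ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$pos, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 1.6, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "residue", y = "Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
  if (nrow(helices) > 0) {
    p <- p + ggplot2::geom_rect(
      data = helices,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot a hydropathy profile with predicted helices
#'
#' @param object An `aqp_topology` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name autoplot.aqp_topology
NULL
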