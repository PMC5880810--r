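## Group comparison for expression data.
##
## With three biological replicates per tissue, variance homogeneity cannot
## be taken for granted, so the robust Brown-Forsythe equality-of-means test
## (variance-weighted F with Satterthwaite-type denominator df) replaces
## classic one-way ANOVA, paired with Scheffe post hoc contrasts — the
## combination SPSS offers for this situation. Values are expected on the
## log scale (log10 CNRQ).

# numeric core, used directly by Monte-Carlo loops
bf_stat <- function(values, groups) {
  groups <- as.factor(groups)
  n_i <- tapply(values, groups, length)
  if (any(n_i < 2)) abort("every group needs at least 2 observations")
  k <- nlevels(groups)
  if (k < 2) abort("need at least 2 groups")
  m_i <- tapply(values, groups, mean)
  v_i <- tapply(values, groups, var)
  N <- length(values)
  grand <- mean(values)
  num <- sum(n_i * (m_i - grand)^2)
  w_i <- (1 - n_i / N) * v_i
  den <- sum(w_i)
  if (den <= 0) {
    if (num <= 1e-300) {
      return(list(statistic = 0, df1 = k - 1, df2 = Inf, p.value = 1))
    }
    return(list(statistic = Inf, df1 = k - 1, df2 = Inf, p.value = 0))
  }
  fstar <- num / den
  c_i <- w_i / den
  df2 <- 1 / sum(c_i^2 / (n_i - 1))
  list(statistic = fstar, df1 = k - 1, df2 = df2,
       p.value = stats::pf(fstar, k - 1, df2, lower.tail = FALSE))
}

#' Brown-Forsythe robust test of equality of means
#'
#' @param data A data frame of per-sample values (e.g. log10 CNRQ).
#' @param value Column holding the response (unquoted).
#' @param group Column holding the group labels (unquoted).
#' @return An object of class `aqp_bf` with elements `statistic` (F*), `df1`,
#'   `df2` (Satterthwaite-type), `p.value`, `groups` (per-group summary) and
#'   `method`. Has [generics::tidy()] and [generics::glance()] methods.
#' @export
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
#' brown_forsythe(df, y, g)
brown_forsythe <- function(data, value, group) {
  values <- dplyr::pull(data, {{ value }})
  groups <- as.factor(dplyr::pull(data, {{ group }}))
  res <- bf_stat(values, groups)
  summary_tbl <- tibble(
    group = levels(groups),
    n = as.integer(tapply(values, groups, length)),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd))
  )
  structure(
    c(res, list(groups = summary_tbl,
                method = "Brown-Forsythe robust test of equality of means")),
    class = "aqp_bf"
  )
}

#' @export
print.aqp_bf <- function(x, ...) {
  cat(sprintf("%s\nF* = %.4g, df = (%d, %.2f), p = %.4g\n",
              x$method, x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname brown_forsythe
#' @param x An `aqp_bf` object.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.aqp_bf <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p.value, method = x$method)
}

#' @rdname brown_forsythe
#' @exportS3Method generics::glance
glance.aqp_bf <- function(x, ...) tidy(x)

#' @rdname genorm_stability
#' @param x An `aqp_genorm` object.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.aqp_genorm <- function(x, ...) x$ranking

#' @rdname genorm_stability
#' @exportS3Method generics::glance
glance.aqp_genorm <- function(x, ...) {
  tibble(selected_1 = x$selected[1], selected_2 = x$selected[2],
         n_candidates = length(x$m_initial))
}

#' Scheffe post hoc pairwise contrasts
#'
#' All pairwise group contrasts tested against the Scheffe critical value
#' `(k - 1) F(1 - alpha; k - 1, N - k)` on the pooled ANOVA mean square —
#' conservative for any number of (post hoc) contrasts.
#'
#' @inheritParams brown_forsythe
#' @param alpha Significance level (default 0.05).
#' @return An object of class `aqp_scheffe`: tibble `group1`, `group2`,
#'   `contrast` (mean difference), `f` (contrast F), `critical`,
#'   `significant`, with attributes `alpha`, `mse`, `df`.
#' @export
scheffe_posthoc <- function(data, value, group, alpha = 0.05) {
  values <- dplyr::pull(data, {{ value }})
  groups <- as.factor(dplyr::pull(data, {{ group }}))
  n_i <- tapply(values, groups, length)
  if (any(n_i < 2)) abort("every group needs at least 2 observations")
  k <- nlevels(groups)
  if (k < 2) abort("need at least 2 groups")
  N <- length(values)
  m_i <- tapply(values, groups, mean)
  v_i <- tapply(values, groups, var)
  mse <- sum((n_i - 1) * v_i) / (N - k)
  crit <- (k - 1) * stats::qf(1 - alpha, k - 1, N - k)
  pairs <- utils::combn(levels(groups), 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(p) {
    g1 <- pairs[1, p]; g2 <- pairs[2, p]
    diff <- m_i[[g1]] - m_i[[g2]]
    se2 <- mse * (1 / n_i[[g1]] + 1 / n_i[[g2]])
    f <- if (se2 > 0) diff^2 / se2 else if (abs(diff) > 0) Inf else 0
    tibble(group1 = g1, group2 = g2, contrast = diff, f = f,
           critical = crit, significant = f > crit)
  }) |>
    list_rbind()
  structure(out, alpha = alpha, mse = mse, df = c(k - 1, N - k),
            class = c("aqp_scheffe", class(out)))
}

#' @rdname scheffe_posthoc
#' @param x An `aqp_scheffe` object.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.aqp_scheffe <- function(x, ...) as_tibble(x)
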