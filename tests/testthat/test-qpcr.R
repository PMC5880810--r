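# helper: build a long curve tibble from one fluorescence vector
one_well <- function(f, sample = "s1", target = "t1", well_type = "sample") {
  tibble::tibble(sample = sample, target = target, well_type = well_type,
                 cycle = seq_along(f), fluorescence = f)
}

test_that("Cq calling inverts the doubling curve in closed form", {
  f <- pmin(0.01 * 2^(1:40), 0.01 * 2^30)
  cq <- compute_cq(one_well(f), threshold = 10.24)
  # 0.01 * 2^c = 10.24  =>  c = 10
  expect_equal(cq$cq, 10)

  # shift equivariance: delaying the curve by 2 cycles adds exactly 2
  f2 <- pmin(0.01 * 2^((1:40) - 2), 0.01 * 2^30)
  cq2 <- compute_cq(one_well(f2), threshold = 10.24)
  expect_equal(cq2$cq, 12)

  # fractional crossing is log-linearly interpolated
  cq3 <- compute_cq(one_well(f), threshold = 10.24 * sqrt(2))
  expect_equal(cq3$cq, 10.5)

  # a monotone-decreasing series never crosses: censored
  cqc <- compute_cq(one_well(rev(f)), threshold = 1e9)
  expect_true(is.na(cqc$cq))
})

test_that("efficiency estimation recovers E from clean and noisy curves", {
  # noise-free doubling, plateau-capped: E = 2.000 +- 0.001
  f <- pmin(0.01 * 2^(1:40), 0.01 * 2^30)
  est <- estimate_efficiency(one_well(f))
  expect_equal(est$targets$efficiency, 2, tolerance = 0.001 / 2)

  # simulated E = 1.90 with 1% multiplicative noise: recovered within 0.02
  des <- qpcr_design(
    tissue_groups = c("A", "B"), replicates = 3,
    targets = tibble::tibble(target = "g1", efficiency = 1.90, is_reference = FALSE),
    expression = tibble::tibble(target = "g1", A = 1, B = 1),
    sigma = 0.01, seed = 3
  )
  curves <- simulate_qpcr_run(des)
  est2 <- estimate_efficiency(curves)
  expect_equal(est2$targets$efficiency, 1.90, tolerance = 0.02 / 1.9)

  # flat curve: excluded with a reason, and all-excluded targets error
  flat <- one_well(rep(1, 40) + 1e-6 * sin(1:40))
  expect_error(estimate_efficiency(flat), "all wells excluded")
})

test_that("the no-RT exclusion rule drops contamination within 5 cycles", {
  cq <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2", "s3", "s3"),
    target = "g",
    well_type = rep(c("sample", "noRT"), 3),
    cq = c(22, 26, 22, 30, 22, NA)
  )
  res <- filter_nort(cq)
  expect_equal(res$keep[res$sample == "s1"], FALSE)   # delta 4 < 5
  expect_equal(res$keep[res$sample == "s2"], TRUE)    # delta 8
  expect_equal(res$keep[res$sample == "s3"], TRUE)    # censored noRT
  # censored sample Cq drops with its own reason
  cq2 <- tibble::tibble(sample = "s4", target = "g",
                        well_type = c("sample", "noRT"), cq = c(NA, 30))
  res2 <- filter_nort(cq2)
  expect_false(res2$keep)
  expect_match(res2$reason, "censored")
})

test_that("geNorm selects the co-stable pair and respects its preconditions", {
  # r1 and r2 perfectly proportional across samples, r3 noisy
  samples <- paste0("s", 1:6)
  cqs <- c(20, 21, 19, 22, 20.5, 21.5)
  cq <- dplyr::bind_rows(
    tibble::tibble(sample = samples, target = "r1", cq = cqs),
    tibble::tibble(sample = samples, target = "r2", cq = cqs + 2),
    tibble::tibble(sample = samples, target = "r3",
                   cq = cqs + c(0, 3, -2, 1, -1, 2))
  )
  eff <- c(r1 = 2, r2 = 2, r3 = 2)
  g <- genorm_stability(cq, eff)
  expect_setequal(g$selected, c("r1", "r2"))
  expect_equal(g$ranking$candidate[g$ranking$step == 1], "r3")
  # the proportional pair has log-ratio SD zero
  expect_equal(unname(g$ranking$M[g$ranking$candidate %in% c("r1", "r2")]), c(0, 0))

  # identical candidates: all M zero, input order breaks the tie
  cq_id <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(t) {
    tibble::tibble(sample = samples, target = t, cq = cqs)
  }))
  g2 <- genorm_stability(cq_id, c(a = 2, b = 2, c = 2))
  expect_equal(g2$selected, c("a", "b"))
  expect_true(all(g2$m_initial == 0))

  # missing sample value: complete-case error naming the candidate
  cq_miss <- cq[-2, ]
  expect_error(genorm_stability(cq_miss, eff), "r1.*missing|missing.*r1")
  expect_error(genorm_stability(cq[cq$target != "r3", ], eff), "at least 3")

  # exclusion order is stable under candidate input order (no ties here)
  g3 <- genorm_stability(cq[order(cq$target, decreasing = TRUE), ], eff)
  expect_setequal(g3$selected, c("r1", "r2"))
})

test_that("CNRQ follows its definition and calibration invariants", {
  # all Cq equal: every CNRQ is 1
  cq_flat <- tidyr::expand_grid(sample = paste0("s", 1:4),
                                target = c("g", "r1", "r2")) |>
    dplyr::mutate(cq = 25)
  eff <- c(g = 1.9, r1 = 1.911, r2 = 1.911)
  flat <- compute_cnrq(cq_flat, eff, reference_targets = c("r1", "r2"))
  expect_equal(flat$cnrq, rep(1, nrow(flat)))

  # one target, E = 2, one sample a cycle below the mean: RQ = 2
  cq1 <- tibble::tibble(sample = c("s1", "s2", "s3"), target = "g",
                        cq = c(24, 25, 26))
  r1 <- compute_cnrq(cq1, c(g = 2), reference_targets = "g")
  expect_equal(r1$rq[r1$sample == "s1"], 2)

  # calibration: per-target geometric CNRQ mean is 1 to 1e-9
  withr::with_seed(11, {
    cq_rand <- tidyr::expand_grid(sample = paste0("s", 1:6),
                                  target = c("g1", "g2", "r1", "r2")) |>
      dplyr::mutate(cq = runif(dplyr::n(), 18, 30))
  })
  eff4 <- c(g1 = 1.88, g2 = 2.05, r1 = 1.911, r2 = 1.911)
  res <- compute_cnrq(cq_rand, eff4, reference_targets = c("r1", "r2"))
  gm <- tapply(res$cnrq, res$target, function(x) exp(mean(log(x))))
  expect_true(all(abs(gm - 1) < 1e-9))

  # invariance to a constant Cq shift of one target
  shifted <- dplyr::mutate(cq_rand,
                           cq = cq + ifelse(target == "g1", 3.7, 0))
  res2 <- compute_cnrq(shifted, eff4, reference_targets = c("r1", "r2"))
  expect_equal(res2$cnrq, res$cnrq)

  # a sample missing a reference Cq is censored, not imputed
  cq_miss <- cq_rand[!(cq_rand$sample == "s1" & cq_rand$target == "r1"), ]
  res3 <- compute_cnrq(cq_miss, eff4, reference_targets = c("r1", "r2"))
  expect_true(all(is.na(res3$cnrq[res3$sample == "s1" & res3$target == "g1"])))
  expect_true(all(!is.na(res3$cnrq[res3$sample == "s2"])))
})

test_that("Brown-Forsythe reduces to ANOVA under equal sizes (k = 2) and is sane", {
  withr::with_seed(21, {
    df <- data.frame(y = c(rnorm(6, 0, 1), rnorm(6, 0.8, 1)),
                     g = rep(c("a", "b"), each = 6))
  })
  bf <- brown_forsythe(df, y, g)
  anova_f <- summary(stats::aov(y ~ g, data = df))[[1]]$`F value`[1]
  expect_equal(bf$statistic, anova_f)
  expect_equal(bf$df1, 1)

  # identical groups: F* = 0, p = 1
  df0 <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  df0$y <- rep(1.5, 9)
  bf0 <- brown_forsythe(df0, y, g)
  expect_equal(bf0$statistic, 0)
  expect_equal(bf0$p.value, 1)

  # a group of size 1 errors
  df1 <- data.frame(y = 1:4, g = c("a", "a", "a", "b"))
  expect_error(brown_forsythe(df1, y, g), "at least 2 observations")

  td <- tidy(bf)
  expect_named(td, c("statistic", "df1", "df2", "p.value", "method"))
})

test_that("Scheffe contrasts are conservative and detect separation", {
  # three identical groups: nothing significant
  df0 <- data.frame(y = rep(c(1, 1.1, 0.9), 3), g = rep(c("a", "b", "c"), each = 3))
  s0 <- scheffe_posthoc(df0, y, g)
  expect_false(any(s0$significant))

  # one group shifted by 10 SDs: both its pairs significant
  withr::with_seed(5, {
    df <- data.frame(
      y = c(rnorm(5), rnorm(5), rnorm(5, mean = 10)),
      g = rep(c("a", "b", "c"), each = 5)
    )
  })
  s1 <- scheffe_posthoc(df, y, g)
  expect_true(all(s1$significant[s1$group1 == "c" | s1$group2 == "c"]))
  expect_false(any(s1$significant[s1$group1 == "a" & s1$group2 == "b"]))

  # conservativeness: a Scheffe-significant pair is also significant by the
  # unadjusted pairwise F criterion, over random datasets
  withr::with_seed(99, {
    for (rep in 1:20) {
      d <- data.frame(y = rnorm(12, mean = rep(runif(3, 0, 2), each = 4)),
                      g = rep(c("a", "b", "c"), each = 4))
      sp <- scheffe_posthoc(d, y, g)
      crit_unadj <- stats::qf(0.95, 1, attr(sp, "df")[2])
      expect_true(all(!sp$significant | sp$f > crit_unadj))
    }
  })
})
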