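test_that("TMM factors are unity for proportional libraries", {
  counts <- tibble::tibble(
    acs_id = sprintf("a%02d", 1:20),
    s1 = rpois(20, 50) + 1
  )
  counts$s2 <- counts$s1
  expect_equal(unname(tmm_factors(counts)), c(1, 1))

  counts$s2 <- 2 * counts$s1 # pure depth difference
  expect_equal(unname(tmm_factors(counts)), c(1, 1))
})

test_that("TMM matches a direct hand computation on a toy table", {
  counts <- tibble::tibble(
    acs_id = c("a", "b", "c", "d"),
    s1 = c(10, 20, 30, 40),
    s2 = c(12, 26, 70, 50)
  )
  # independent spreadsheet-style computation against reference s1
  y1 <- counts$s1
  y2 <- counts$s2
  n1 <- sum(y1)
  n2 <- sum(y2)
  m <- log2((y2 / n2) / (y1 / n1))
  a <- 0.5 * log2((y2 / n2) * (y1 / n1))
  v <- (n2 - y2) / (n2 * y2) + (n1 - y1) / (n1 * y1)
  # n = 4: trim keeps M-ranks 2..3 and A-ranks 1..4
  keep <- rank(m) %in% 2:3
  f2 <- 2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  expected <- c(1, f2) / exp(mean(log(c(1, f2))))
  got <- tmm_factors(counts, ref_sample = "s1")
  expect_equal(unname(got), expected, tolerance = 1e-10)
})

test_that("TMM agrees with the established implementation", {
  skip_if_not_installed("edgeR")
  sim <- toy_counts(n_acs = 800, seed = 31, dispersion = 0.2,
    log2fc = c(rep(1.5, 150), rep(0, 650)))
  mat <- as.matrix(sim$counts[-1])
  mine <- tmm_factors(sim$counts)
  ref <- edgeR::calcNormFactors(mat, method = "TMM")
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("a sample of all zeros is rejected", {
  counts <- tibble::tibble(acs_id = c("a", "b"), s1 = c(1, 2), s2 = c(0, 0))
  expect_error(tmm_factors(counts), "all-zero")
})

test_that("common dispersion recovery brackets the simulation truth", {
  sim0 <- toy_counts(n_acs = 2000, seed = 41, dispersion = 0)
  expect_lte(estimate_common_dispersion(sim0$counts, sim0$samples), 0.02)

  sim4 <- toy_counts(n_acs = 2000, seed = 43, dispersion = 0.4)
  phi <- estimate_common_dispersion(sim4$counts, sim4$samples)
  expect_gte(phi, 0.3)
  expect_lte(phi, 0.5)

  # constant replicate columns: no excess variance, lower bound
  const <- tibble::tibble(
    acs_id = c("a", "b"), g1a = c(5, 9), g1b = c(5, 9),
    g2a = c(5, 9), g2b = c(5, 9)
  )
  samples <- tibble::tibble(
    sample = c("g1a", "g1b", "g2a", "g2b"),
    group = c("g1", "g1", "g2", "g2")
  )
  expect_warning(
    phi0 <- estimate_common_dispersion(const, samples),
    "constant"
  )
  expect_equal(phi0, 1e-6)
})

test_that("the exact test reduces to the conditional binomial at phi = 0", {
  # both groups all zero: the single outcome has p = 1
  expect_equal(nb_exact_test(matrix(0, 1, 3), matrix(0, 1, 3), 0.1), 1)

  # the conditional mode has p = 1 by the two-sided rule
  expect_equal(
    nb_exact_test(matrix(c(5, 5), 1), matrix(c(5, 5), 1), 0),
    1
  )

  # 1v1 split (30, 0): p = 2 * (1/2)^30
  expect_equal(
    nb_exact_test(matrix(30, 1, 1), matrix(0, 1, 1), 0),
    2 * 0.5^30,
    tolerance = 1e-12
  )

  # random splits match the binomial closed form
  set.seed(9)
  for (i in 1:25) {
    t_total <- sample(5:200, 1)
    a <- sample(0:t_total, 1)
    n_a <- sample(1:4, 1)
    n_b <- sample(1:4, 1)
    probs <- dbinom(0:t_total, t_total, n_a / (n_a + n_b))
    expected <- sum(probs[probs <= probs[a + 1] * (1 + 1e-10)])
    got <- nb_exact_test(
      matrix(c(a, rep(0, n_a - 1)), 1), matrix(c(t_total - a, rep(0, n_b - 1)), 1), 0
    )
    expect_equal(got, expected, tolerance = 1e-10)
  }

  expect_error(nb_exact_test(matrix(-1, 1, 1), matrix(0, 1, 1), 0), "negative")
})

test_that("exact-test p-values track the established implementation", {
  skip_if_not_installed("edgeR")
  sim <- toy_counts(n_acs = 500, seed = 55, dispersion = 0.15,
    log2fc = c(rep(c(-1, 1), each = 50), rep(0, 400)))
  res <- diff_accessibility(sim$counts, sim$samples)
  y <- edgeR::DGEList(
    counts = as.matrix(sim$counts[-1]),
    group = factor(sim$samples$group, levels = c("P10", "adult"))
  )
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y)
  ref_p <- et$table$PValue
  expect_gt(cor(log(res$p_value), log(ref_p), method = "spearman"), 0.97)
  expect_gt(cor(res$log2_fc, et$table$logFC), 0.99)
})

test_that("log2 fold-change uses prior-augmented normalised means", {
  sim <- toy_counts(n_acs = 30, seed = 61, dispersion = 0.05)
  lfc <- log2_fold_change(sim$counts, sim$samples)
  # identical group means in expectation: no systematic shift
  expect_lt(abs(mean(lfc)), 0.15)

  # direct formula: normalised means 20 vs 5, prior 0.5
  counts <- tibble::tibble(
    acs_id = "a",
    p1 = 20, p2 = 20, a1 = 5, a2 = 5
  )
  samples <- tibble::tibble(
    sample = c("p1", "p2", "a1", "a2"),
    group = c("P10", "P10", "adult", "adult")
  )
  lfc1 <- log2_fold_change(counts, samples,
    factors = setNames(rep(1, 4), samples$sample)
  )
  # all columns scale to the common library, giving means 20 and 5
  sc <- exp(mean(log(c(20, 20, 5, 5)))) / c(20, 20, 5, 5)
  m_p10 <- mean(20 * sc[1:2])
  m_adult <- mean(5 * sc[3:4])
  expect_equal(unname(lfc1), log2((m_adult + 0.5) / (m_p10 + 0.5)))

  # swapping the group labels negates the fold-change
  swapped <- samples
  swapped$group <- rev(samples$group)[c(2, 1, 4, 3)]
  lfc2 <- log2_fold_change(counts, swapped,
    factors = setNames(rep(1, 4), samples$sample)
  )
  expect_equal(unname(lfc1), -unname(lfc2))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (n in c(3, 17, 200, 1000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), brute_force_bh(p))
  }
})

test_that("classification applies both thresholds with the sign rule", {
  res <- tibble::tibble(
    acs_id = c("a", "b", "c"),
    log2_fc = c(1.2, -0.8, 2.0),
    p_value = c(0.01, 0.03, 0.20),
    fdr = c(0.10, 0.15, 0.50)
  )
  out <- classify_acs(res)
  expect_equal(out$class, c("Up", "Down", "Stable"))
  fr <- class_fractions(out)
  expect_equal(fr$fraction, rep(1 / 3, 3))
})

test_that("detection rate is monotone in the planted effect size", {
  # mostly-stable universe (as TMM assumes), effects planted on both signs
  set.seed(70)
  grid <- c(0.5, 1, 2)
  n_per <- 200
  lfc <- c(
    rep(0, 1400),
    sample(c(-1, 1), length(grid) * n_per, TRUE) * rep(grid, each = n_per)
  )
  sim <- simulate_counts(
    setNames(lfc, sprintf("acs%05d", seq_along(lfc))),
    dispersion = 0.1, baseline_logmean_sd = 0.5, seed = 71
  )
  res <- diff_accessibility(sim$counts, sim$samples)
  rate <- vapply(c(0, grid), function(g) {
    mean(res$class[abs(lfc) == g] != "Stable")
  }, numeric(1))
  expect_true(all(diff(rate) >= -0.03))
  expect_gt(rate[4], 0.9)
})
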