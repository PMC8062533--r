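test_that("PFM to PSSM conversion follows the pseudocount formula", {
  # uniform PFM against uniform background scores zero everywhere
  uni <- matrix(1, 4, 3, dimnames = list(c("A", "C", "G", "T")))
  expect_equal(max(abs(pfm_to_pssm(uni)$scores)), 0)

  # column (3,1,0,0), total 4, pseudocount 1, uniform background
  pfm <- matrix(c(3, 1, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  pssm <- pfm_to_pssm(pfm, pseudocount = 1)
  expect_equal(pssm$probs["A", 1], 3.25 / 5, ignore_attr = TRUE)
  expect_equal(pssm$scores["A", 1], log2(0.65 / 0.25), ignore_attr = TRUE)

  # point-mass PFM with zero pseudocount: consensus scores 2 bits
  pm <- matrix(c(4, 0, 0, 0), 4, 2, dimnames = list(c("A", "C", "G", "T")))
  pm[, 2] <- c(0, 0, 4, 0)
  s <- pfm_to_pssm(pm, pseudocount = 0)$scores
  expect_equal(s["A", 1], 2, ignore_attr = TRUE)
  expect_equal(s["G", 2], 2, ignore_attr = TRUE)
  expect_true(all(is.infinite(s[c(2, 3, 4), 1])))

  zero_col <- matrix(0, 4, 1, dimnames = list(c("A", "C", "G", "T")))
  expect_error(pfm_to_pssm(zero_col, pseudocount = 0), "zero column")
})

test_that("score distribution is an exact survival function", {
  # width-1 point-mass motif: p(consensus score) = background probability
  pm <- matrix(c(4, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  pssm <- pfm_to_pssm(pm, pseudocount = 1e-9)
  d <- pssm_score_distribution(pssm)
  expect_equal(score_pvalue(d, pssm$scores["A", 1]), 0.25)

  # survival-function shape: non-increasing, 1 at -Inf
  pwm <- sample_pwm(6, 1.2, seed = 4)
  pssm6 <- pfm_to_pssm(pwm)
  d6 <- pssm_score_distribution(pssm6)
  grid <- seq(sum(apply(pssm6$scores, 2, min)) - 1,
    sum(apply(pssm6$scores, 2, max)) + 1,
    length.out = 200
  )
  p <- score_pvalue(d6, grid)
  expect_true(all(diff(p) <= 1e-12))
  expect_equal(score_pvalue(d6, -Inf), 1)
})

test_that("DP p-values match exhaustive enumeration for short motifs", {
  set.seed(17)
  for (i in 1:4) {
    w <- sample(4:7, 1)
    bg <- rgamma(4, 5)
    bg <- bg / sum(bg)
    pssm <- pfm_to_pssm(random_count_pfm(w), background = bg)
    d <- pssm_score_distribution(pssm)
    smin <- sum(apply(pssm$scores, 2, min))
    smax <- sum(apply(pssm$scores, 2, max))
    query <- seq(smin, smax, length.out = 11)
    expect_equal(
      score_pvalue(d, query),
      enumerate_word_pvalue(pssm, query),
      tolerance = 1e-4, ignore_attr = TRUE
    )
  }
})

test_that("scanning reports mirrored matches on the reverse complement", {
  word <- "ACGTACGG"
  pssm <- consensus_pssm(word)
  seq_fwd <- paste0("TTT", word, "TTTTTTT")
  hit <- scan_sequence(pssm, seq_fwd, threshold_p = 1e-4)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$offset, 3L)
  expect_equal(hit$strand, "+")

  rc <- chromactivity:::reverse_complement(seq_fwd)
  hit_rc <- scan_sequence(pssm, rc, threshold_p = 1e-4)
  expect_equal(nrow(hit_rc), 1)
  expect_equal(hit_rc$strand, "-")
  expect_equal(hit_rc$offset, nchar(seq_fwd) - nchar(word) - 3L)
  expect_equal(hit_rc$score, hit$score)

  # windows containing N are skipped
  with_n <- paste0("TTT", substr(word, 1, 4), "N", substr(word, 6, 8), "TTT")
  expect_equal(nrow(scan_sequence(pssm, with_n, threshold_p = 1e-4)), 0)

  # sequences shorter than the motif give an empty result, not an error
  expect_equal(nrow(scan_sequence(pssm, "ACG")), 0)
})

test_that("match rate on background sequence matches 2 (L - w + 1) p", {
  set.seed(23)
  pwm <- sample_pwm(8, 1.0, seed = 19)
  pssm <- pfm_to_pssm(pwm)
  d <- pssm_score_distribution(pssm)
  # at threshold 1e-12 on 1 kb of background, zero matches expected
  bg_seq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  expect_equal(nrow(scan_sequence(pssm, bg_seq, 1e-12, dist = d)), 0)

  # at a permissive threshold the empirical rate is near 2 (L - w + 1) p
  thr <- 1e-3
  n_hits <- 0
  n_windows <- 0
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    n_hits <- n_hits + nrow(scan_sequence(pssm, s, thr, dist = d))
    n_windows <- n_windows + 2 * (500 - 8 + 1)
  }
  expected <- n_windows * thr
  expect_lt(abs(n_hits - expected), 4 * sqrt(expected) + 5)
})

test_that("the match matrix recovers planted instances", {
  # detectability at threshold 1e-4 needs the expected instance score
  # (~ IC x width bits) comfortably above log2(1/1e-4) ~ 13.3 bits
  motifs <- sample_motif_set(5,
    width_range = c(10, 14),
    information_content = 1.6, seed = 29
  )
  planting <- tibble::tibble(
    motif_id = motifs$motif_id, prob = 0.4, activity = 0
  )
  acs <- simulate_acs_set(120, motifs, planting, seed = 31)
  mm <- build_match_matrix(acs$sequences, motifs, threshold_p = 1e-4)
  mat <- chromactivity:::match_matrix_to_matrix(mm)
  expect_true(all(mat %in% c(0, 1)))
  planted <- acs$truth$match_truth == 1
  recall <- sum(mat[planted] == 1) / sum(planted)
  expect_gte(recall, 0.95)

  # count mode stores at least as many entries as binary
  mmc <- build_match_matrix(acs$sequences[1:10, ], motifs,
    threshold_p = 1e-3, mode = "count"
  )
  matc <- chromactivity:::match_matrix_to_matrix(mmc)
  expect_true(all(matc >= 0))

  dup <- acs$sequences[c(1, 1), ]
  expect_error(build_match_matrix(dup, motifs), "duplicate")
})
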