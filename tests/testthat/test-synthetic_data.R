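test_that("sample_pwm hits the requested information content", {
  # maximal IC forces point-mass columns
  pm <- sample_pwm(4, 2, seed = 1)
  expect_true(all(apply(pm, 2, max) == 1))
  expect_equal(colSums(pm), rep(1, 4), tolerance = 1e-9)

  # determinism
  expect_identical(sample_pwm(6, 1, seed = 7), sample_pwm(6, 1, seed = 7))

  # empirical IC close to request
  pm8 <- sample_pwm(8, 1, seed = 3)
  ic <- apply(pm8, 2, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  expect_gte(mean(ic), 0.8)
  expect_lte(mean(ic), 1.2)

  expect_error(sample_pwm(3, 1), "width")
  expect_error(sample_pwm(30, 1), "width")
})

test_that("simulate_acs_set plants instances consistently with its truth", {
  motifs <- sample_motif_set(4, width_range = c(8, 10), seed = 5)
  planting <- tibble::tibble(
    motif_id = motifs$motif_id, prob = c(0.3, 0.3, 0, 0),
    activity = c(1, -1, 0, 0)
  )
  acs <- simulate_acs_set(100, motifs, planting, seed = 11)

  # zero planting probability gives an all-zero truth column
  expect_true(all(acs$truth$match_truth[, 3:4] == 0))

  # planted column sums within 3 binomial SDs of n * p
  sds <- sqrt(100 * 0.3 * 0.7)
  expect_true(all(abs(colSums(acs$truth$match_truth[, 1:2]) - 30) <= 3 * sds))

  # the linear activity model holds exactly
  expect_equal(
    unname(acs$truth$acs_log2fc_true),
    unname(drop(acs$truth$match_truth %*% c(1, -1, 0, 0)) + acs$truth$epsilon)
  )

  # with point-mass motifs the planted instance is the consensus word and
  # must occur verbatim (or reverse-complemented) in the sequence
  sharp <- sample_motif_set(2,
    width_range = c(8, 8),
    information_content = 2, seed = 13
  )
  sharp_plant <- tibble::tibble(
    motif_id = sharp$motif_id, prob = 0.5, activity = 0
  )
  acs_sharp <- simulate_acs_set(60, sharp, sharp_plant, seed = 14)
  for (m in 1:2) {
    consensus <- paste(
      rownames(sharp$matrix[[m]])[apply(sharp$matrix[[m]], 2, which.max)],
      collapse = ""
    )
    rc <- chromactivity:::reverse_complement(consensus)
    planted <- acs_sharp$truth$match_truth[, m] == 1
    found <- grepl(consensus, acs_sharp$sequences$seq, fixed = TRUE) |
      grepl(rc, acs_sharp$sequences$seq, fixed = TRUE)
    expect_true(all(found[planted]))
  }

  # same seed reproduces byte-identical FASTA and BED
  acs2 <- simulate_acs_set(100, motifs, planting, seed = 11)
  d <- withr::local_tempdir()
  write_fasta(acs$sequences, file.path(d, "a.fa"))
  write_fasta(acs2$sequences, file.path(d, "b.fa"))
  write_bed(acs$regions, file.path(d, "a.bed"))
  write_bed(acs2$regions, file.path(d, "b.bed"))
  expect_identical(
    readLines(file.path(d, "a.fa")),
    readLines(file.path(d, "b.fa"))
  )
  expect_identical(
    readLines(file.path(d, "a.bed")),
    readLines(file.path(d, "b.bed"))
  )

  # motif wider than the shortest sequence is rejected
  expect_error(
    simulate_acs_set(10, motifs, planting, length_range = c(8, 20)),
    "wider"
  )
})

test_that("simulate_counts follows the NB mean-variance model", {
  # Poisson limit at equal library sizes: pooled index of dispersion near 1
  sim0 <- simulate_counts(
    setNames(rep(0, 2000), sprintf("acs%04d", 1:2000)),
    dispersion = 0, lib_size_range = c(1, 1), seed = 21
  )
  mat <- as.matrix(sim0$counts[-1])
  p10 <- mat[, sim0$samples$sample[sim0$samples$group == "P10"]]
  idx <- apply(p10, 1, var) / pmax(rowMeans(p10), 1e-9)
  expect_gte(mean(idx), 0.9)
  expect_lte(mean(idx), 1.1)

  # log2fc = 1 doubles the adult group mean
  sim1 <- toy_counts(n_acs = 4000, seed = 22, dispersion = 0.05, log2fc = rep(1, 4000))
  m1 <- as.matrix(sim1$counts[-1])
  adult <- rowSums(m1[, sim1$samples$group == "adult"]) / sum(sim1$rel_lib[sim1$samples$group == "adult"])
  p10m <- rowSums(m1[, sim1$samples$group == "P10"]) / sum(sim1$rel_lib[sim1$samples$group == "P10"])
  expect_equal(sum(adult) / sum(p10m), 2, tolerance = 0.05)

  # method-of-moments dispersion recovery: var = mu + phi mu^2
  sim4 <- simulate_counts(
    setNames(rep(0, 5000), sprintf("acs%04d", 1:5000)),
    n_per_group = 10,
    dispersion = 0.4, lib_size_range = c(1, 1), seed = 23
  )
  m4 <- as.matrix(sim4$counts[-1])[, sim4$samples$group == "P10"]
  mu <- rowMeans(m4)
  v <- apply(m4, 1, var)
  keep <- mu > 5
  phi_hat <- sum((v[keep] - mu[keep]) * mu[keep]^2) / sum(mu[keep]^4)
  expect_gte(phi_hat, 0.3)
  expect_lte(phi_hat, 0.5)
})

test_that("simulate_expression controls enhancer/repressor concordance", {
  tss <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
    strand = "+", tss = seq(1000, by = 5000, length.out = 100)
  )
  links <- tibble::tibble(acs_id = sprintf("a%03d", 1:100), gene_id = tss$gene_id)
  acs_fc <- setNames(rnorm(100, 0, 1), links$acs_id)

  enh <- simulate_expression(tss, links, acs_fc,
    role_fractions = c(1, 0),
    noise_sd = 0, seed = 1
  )
  expect_equal(cor(acs_fc, enh$genes$log2fc[match(links$gene_id, enh$genes$gene_id)]), 1)

  rep_ <- simulate_expression(tss, links, acs_fc,
    role_fractions = c(0, 1),
    noise_sd = 0, seed = 1
  )
  expect_equal(cor(acs_fc, rep_$genes$log2fc[match(links$gene_id, rep_$genes$gene_id)]), -1)

  bad_links <- tibble::tibble(acs_id = "a001", gene_id = "nope")
  expect_error(simulate_expression(tss, bad_links, acs_fc), "key not found")
})

test_that("synthetic truth serialisation round-trips losslessly", {
  motifs <- sample_motif_set(3, seed = 2)
  planting <- tibble::tibble(
    motif_id = motifs$motif_id, prob = 0.2,
    activity = c(0.5, -0.5, 0)
  )
  acs <- simulate_acs_set(40, motifs, planting, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(acs$truth, path)
  back <- read_truth(path)
  expect_equal(back$match_truth, acs$truth$match_truth)
  expect_equal(back$acs_log2fc_true, acs$truth$acs_log2fc_true)
  expect_equal(back$epsilon, acs$truth$epsilon)
  expect_equal(back$true_activity, acs$truth$true_activity)
  expect_equal(back$noise_sd, acs$truth$noise_sd)
  expect_equal(back$seed, acs$truth$seed)
})
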