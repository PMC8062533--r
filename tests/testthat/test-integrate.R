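test_that("nearest TSS linking uses midpoint distance with a stable tie-break", {
  tss <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "+"),
    tss = c(1000L, 9000L)
  )
  acs <- tibble::tibble(
    chrom = "chr1", start = 2900L, end = 3100L, id = "mid3000"
  )
  link <- nearest_tss(acs, tss)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$signed_distance, 2000)

  # midpoint exactly at a TSS
  at <- nearest_tss(
    tibble::tibble(chrom = "chr1", start = 900L, end = 1100L, id = "x"), tss
  )
  expect_equal(at$signed_distance, 0)
  expect_equal(at$location_class, "TSS")

  # equidistant: lexicographically smaller gene id wins
  tss_tie <- tibble::tibble(
    gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
    tss = c(2000L, 4000L)
  )
  tie <- nearest_tss(
    tibble::tibble(chrom = "chr1", start = 2950L, end = 3050L, id = "t"), tss_tie
  )
  expect_equal(tie$gene_id, "gA")

  # minus-strand genes flip the sign (positive = downstream of the TSS)
  tss_minus <- tibble::tibble(
    gene_id = "gM", chrom = "chr1", strand = "-", tss = 5000L
  )
  minus <- nearest_tss(
    tibble::tibble(chrom = "chr1", start = 3900L, end = 4100L, id = "m"), tss_minus
  )
  expect_equal(minus$signed_distance, 1000)

  # a chromosome with no TSS leaves the site unlinked, with a warning
  expect_warning(
    un <- nearest_tss(
      tibble::tibble(chrom = "chrX", start = 0L, end = 100L, id = "u"), tss
    ),
    "unlinked"
  )
  expect_true(is.na(un$gene_id))
})

test_that("location classes follow the 1 kb / 10 kb boundaries", {
  expect_equal(location_class(500), "TSS")
  expect_equal(location_class(-5000), "proximal")
  expect_equal(location_class(50000), "distal")
  # boundaries belong to the smaller class
  expect_equal(location_class(c(1000, -1000)), c("TSS", "TSS"))
  expect_equal(location_class(c(10000, -10000)), c("proximal", "proximal"))
  expect_equal(location_class(c(1001, 10001)), c("proximal", "distal"))
})

test_that("regulatory roles encode fold-change concordance", {
  diff_res <- tibble::tibble(
    acs_id = c("a1", "a2", "a3", "a4"),
    log2_fc = c(1.2, 1.2, 1.2, 0.1),
    class = c("Up", "Up", "Up", "Stable")
  )
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(0.8, -0.8, 0.8, 0.9),
    fdr = c(0.01, 0.01, 0.30, 0.01)
  )
  links <- tibble::tibble(
    acs_id = c("a1", "a2", "a3", "a4"),
    gene_id = c("g1", "g2", "g3", "g4")
  )
  out <- classify_regulatory_role(links, diff_res, genes)
  expect_equal(out$role, c("enhancer", "repressor", "unlinked", "unlinked"))

  # negating both fold-change conventions leaves roles unchanged
  flipped <- classify_regulatory_role(
    links,
    dplyr::mutate(diff_res, log2_fc = -log2_fc,
      class = dplyr::recode(class, Up = "Down", Down = "Up")),
    dplyr::mutate(genes, log2fc = -log2fc)
  )
  expect_equal(flipped$role, out$role)
})

test_that("role recovery is perfect at zero noise and high at sd 0.2", {
  n <- 500
  tss <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), chrom = "chr1", strand = "+",
    tss = seq(1000, by = 4000, length.out = n)
  )
  links <- tibble::tibble(acs_id = sprintf("a%03d", 1:n), gene_id = tss$gene_id)
  acs_fc <- setNames(rnorm(n, 0, 1.2), links$acs_id)
  diff_res <- tibble::tibble(
    acs_id = links$acs_id, log2_fc = unname(acs_fc),
    class = ifelse(acs_fc > 0, "Up", "Down")
  )
  for (noise in c(0, 0.2)) {
    expr <- simulate_expression(tss, links, acs_fc,
      role_fractions = c(0.5, 0.5), noise_sd = noise, seed = 67
    )
    out <- classify_regulatory_role(links, diff_res, expr$genes)
    truth <- expr$roles$role_true
    informative <- truth %in% c("enhancer", "repressor")
    rate <- mean(out$role[informative] == truth[informative])
    if (noise == 0) expect_equal(rate, 1) else expect_gte(rate, 0.9)
  }
})

test_that("motif target enrichment counts genes and reaches significance", {
  # a motif with no matching sites is trivially unenriched
  mm <- tibble::tibble(acs_id = c("a1", "a2"), m0 = c(0L, 0L))
  links <- tibble::tibble(acs_id = c("a1", "a2"), gene_id = c("g1", "g2"))
  none <- motif_target_enrichment(mm, links, "g1", c("g1", "g2"))
  expect_equal(none$k, 0)
  expect_equal(none$K, 0)
  expect_equal(none$p_value, 1)

  # toy counts k=4, K=5, n=4, N=10
  mm2 <- tibble::tibble(acs_id = sprintf("a%02d", 1:5), m = 1L)
  links2 <- tibble::tibble(
    acs_id = sprintf("a%02d", 1:5), gene_id = sprintf("g%02d", 1:5)
  )
  toy <- motif_target_enrichment(
    mm2, links2, sprintf("g%02d", c(1:4)), sprintf("g%02d", 1:10)
  )
  expect_equal(toy$K, 5)
  expect_equal(toy$k, 4)
  expect_equal(toy$p_value, 5 / 210, tolerance = 1e-12)

  # planted association: motif sites linked almost only to DE genes
  set.seed(71)
  n_genes <- 600
  genes <- sprintf("g%03d", seq_len(n_genes))
  de <- genes[1:120]
  acs_ids <- sprintf("a%03d", seq_len(n_genes))
  carrier <- c(rbinom(120, 1, 0.7), rbinom(n_genes - 120, 1, 0.03))
  mm3 <- tibble::tibble(acs_id = acs_ids, planted = as.integer(carrier))
  links3 <- tibble::tibble(acs_id = acs_ids, gene_id = genes)
  res <- motif_target_enrichment(mm3, links3, de, genes)
  expect_lt(res$p_value, 1e-6)

  expect_error(motif_target_enrichment(mm2, links2, "g01", character()), "empty")
})

test_that("fold-change correlation reproduces the t-transform", {
  perfect <- foldchange_correlation(
    setNames(c(1, 2, 3), c("a", "b", "c")),
    setNames(c(3, 2, 1), c("a", "b", "c"))
  )
  expect_equal(perfect$r, -1)

  hand <- foldchange_correlation(
    setNames(c(1, 2, 3, 4), letters[1:4]),
    setNames(c(2, 1, 4, 3), letters[1:4])
  )
  expect_equal(hand$r, 0.6)
  expect_equal(hand$statistic, 0.6 * sqrt(2) / sqrt(1 - 0.36), tolerance = 1e-9)
  expect_equal(hand$p_value, 0.4, tolerance = 1e-9)

  expect_error(
    foldchange_correlation(
      setNames(c(1, 1, 1), letters[1:3]),
      setNames(c(1, 2, 3), letters[1:3])
    ),
    "zero variance"
  )
  expect_error(
    foldchange_correlation(
      setNames(1:2, c("a", "b")), setNames(1:2, c("a", "b"))
    ),
    "3 shared"
  )
})
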