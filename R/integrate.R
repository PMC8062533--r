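# Linking accessible sites to genes. Each site is assigned its nearest
# transcription start site (by midpoint distance, strand-oriented sign), a
# location class (TSS within 1 kb, proximal to 10 kb, distal beyond), and a
# regulatory role: enhancer when the site's accessibility change is
# sign-concordant with the nearby gene's expression change, repressor when
# anti-concordant.

#' Link each site to its nearest transcription start site
#'
#' Distance is measured from the site midpoint (`floor((start + end) / 2)`)
#' to the TSS; the gene with minimal absolute distance wins, ties going to
#' the lexicographically smallest gene id. The sign is oriented by gene
#' strand (positive = downstream of the TSS). Sites on chromosomes with no
#' TSS are reported unlinked with a warning.
#'
#' @param acs Region tibble (`chrom`, `start`, `end`, `id`).
#' @param tss_table Gene table (`gene_id`, `chrom`, `strand`, `tss`).
#' @return A tibble `acs_id`, `gene_id`, `signed_distance`,
#'   `location_class` (NA fields for unlinked sites).
#' @export
nearest_tss <- function(acs, tss_table) {
  check_columns(acs, c("chrom", "start", "end", "id"), "acs")
  check_columns(tss_table, c("gene_id", "chrom", "strand", "tss"), "tss_table")
  if (nrow(tss_table) == 0) abort("`tss_table` must be non-empty")
  mid <- floor((acs$start + acs$end) / 2)
  out <- tibble(
    acs_id = acs$id, gene_id = NA_character_,
    signed_distance = NA_real_
  )
  for (chr in unique(acs$chrom)) {
    rows <- which(acs$chrom == chr)
    genes <- tss_table[tss_table$chrom == chr, , drop = FALSE]
    if (nrow(genes) == 0) next
    # tie-break: among equal |distance|, the lexicographically smallest id
    genes <- genes[order(genes$tss, genes$gene_id), , drop = FALSE]
    for (i in rows) {
      d <- mid[i] - genes$tss
      best <- abs(d) == min(abs(d))
      pick <- which(best)[order(genes$gene_id[best])][1]
      signed <- d[pick]
      if (genes$strand[pick] == "-") signed <- -signed
      out$gene_id[i] <- genes$gene_id[pick]
      out$signed_distance[i] <- signed
    }
  }
  unlinked <- is.na(out$gene_id)
  if (any(unlinked)) {
    warn(paste0(
      sum(unlinked), " site(s) on chromosome(s) with no TSS left unlinked"
    ))
  }
  out$location_class <- ifelse(is.na(out$signed_distance), NA_character_,
    location_class(out$signed_distance)
  )
  out
}

#' Location class from a signed TSS distance
#'
#' `|d| <= 1000` bp is `TSS`, `1000 < |d| <= 10000` is `proximal`,
#' `|d| > 10000` is `distal`; boundaries belong to the smaller class.
#'
#' @param signed_distance Numeric vector of signed distances in bp.
#' @param tss_bound,proximal_bound Class boundaries in bp.
#' @return Character vector of classes.
#' @export
location_class <- function(signed_distance, tss_bound = 1000,
                           proximal_bound = 10000) {
  d <- abs(signed_distance)
  dplyr::case_when(
    d <= tss_bound ~ "TSS",
    d <= proximal_bound ~ "proximal",
    TRUE ~ "distal"
  )
}

#' Call enhancer / repressor roles for linked sites
#'
#' A linked site is an `enhancer` when it changes accessibility (class not
#' `Stable`), its gene is significantly differentially expressed, and the
#' accessibility and expression log2 fold-changes share their sign;
#' `repressor` when the signs are opposite; `unlinked` otherwise.
#'
#' @param links Link tibble (`acs_id`, `gene_id`) as from [nearest_tss()].
#' @param diff_results Differential accessibility table (`acs_id`,
#'   `log2_fc`, `class`).
#' @param genes Gene table (`gene_id`, `log2fc`, `fdr`).
#' @param gene_fdr_threshold Gene significance cutoff (default 0.05).
#' @return `links` with `role` added (`enhancer`, `repressor`, `unlinked`).
#' @export
classify_regulatory_role <- function(links, diff_results, genes,
                                     gene_fdr_threshold = 0.05) {
  check_columns(links, c("acs_id", "gene_id"), "links")
  check_columns(diff_results, c("acs_id", "log2_fc", "class"), "diff_results")
  check_columns(genes, c("gene_id", "log2fc", "fdr"), "genes")
  out <- links |>
    dplyr::left_join(
      dplyr::select(diff_results, "acs_id",
        acs_log2fc = "log2_fc", acs_class = "class"
      ),
      by = "acs_id"
    ) |>
    dplyr::left_join(
      dplyr::select(genes, "gene_id",
        gene_log2fc = "log2fc", gene_fdr = "fdr"
      ),
      by = "gene_id"
    ) |>
    dplyr::mutate(
      role = dplyr::case_when(
        is.na(.data$gene_id) | is.na(.data$acs_class) |
          is.na(.data$gene_log2fc) ~ "unlinked",
        .data$acs_class == "Stable" ~ "unlinked",
        .data$gene_fdr >= gene_fdr_threshold ~ "unlinked",
        .data$acs_log2fc * .data$gene_log2fc > 0 ~ "enhancer",
        .data$acs_log2fc * .data$gene_log2fc < 0 ~ "repressor",
        TRUE ~ "unlinked"
      )
    ) |>
    dplyr::select(-"acs_log2fc", -"acs_class", -"gene_log2fc", -"gene_fdr")
  out
}

#' Hypergeometric enrichment of motif-carrying sites near DE genes
#'
#' For each motif: the universe is the supplied gene universe (size `N`),
#' the successes are genes with at least one linked site carrying the motif
#' (`K`), the draws are the differentially expressed genes (`n`), and `k`
#' is their intersection; the p-value is the exact upper tail.
#'
#' @param match_matrix Match-matrix tibble (`acs_id` + motif columns).
#' @param links Link tibble (`acs_id`, `gene_id`).
#' @param de_gene_ids Differentially expressed gene ids (subset of the
#'   universe).
#' @param universe_gene_ids The gene universe.
#' @param motif_ids Motifs to test (default: all columns).
#' @return A tibble `motif_id`, `k`, `K`, `n`, `N`, `p_value`.
#' @export
motif_target_enrichment <- function(match_matrix, links, de_gene_ids,
                                    universe_gene_ids, motif_ids = NULL) {
  if (length(universe_gene_ids) == 0) abort("empty gene universe")
  if (!all(de_gene_ids %in% universe_gene_ids)) {
    abort("`de_gene_ids` must be a subset of `universe_gene_ids`")
  }
  mat <- match_matrix_to_matrix(match_matrix)
  motif_ids <- motif_ids %||% colnames(mat)
  links <- links[!is.na(links$gene_id) &
    links$gene_id %in% universe_gene_ids, , drop = FALSE]
  n_draw <- length(unique(de_gene_ids))
  n_universe <- length(unique(universe_gene_ids))
  purrr::map_dfr(motif_ids, function(m) {
    carriers <- rownames(mat)[mat[, m] > 0]
    target_genes <- unique(links$gene_id[links$acs_id %in% carriers])
    k_obs <- length(intersect(target_genes, de_gene_ids))
    tibble(
      motif_id = m,
      k = k_obs, K = length(target_genes),
      n = n_draw, N = n_universe,
      p_value = hypergeom_test(k_obs, length(target_genes), n_draw, n_universe)
    )
  })
}

#' Pearson correlation between two gene fold-change tables
#'
#' Two-sided test via the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' on `n - 2` degrees of freedom, over genes shared between the two tables.
#'
#' @param fc_a,fc_b Named numeric vectors, or tibbles with `gene_id` and
#'   `log2fc` columns.
#' @return A tibble `r`, `statistic`, `df`, `p_value`, `n`.
#' @export
foldchange_correlation <- function(fc_a, fc_b) {
  as_vec <- function(x, name) {
    if (is.data.frame(x)) {
      check_columns(x, c("gene_id", "log2fc"), name)
      setNames(x$log2fc, x$gene_id)
    } else {
      if (is.null(names(x))) abort(paste0("`", name, "` must be named"))
      x
    }
  }
  a <- as_vec(fc_a, "fc_a")
  b <- as_vec(fc_b, "fc_b")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) abort("need at least 3 shared genes")
  a <- a[shared]
  b <- b[shared]
  if (sd(a) == 0 || sd(b) == 0) abort("zero variance in a fold-change vector")
  ct <- cor.test(a, b, method = "pearson")
  tibble(
    r = unname(ct$estimate), statistic = unname(ct$statistic),
    df = unname(ct$parameter), p_value = ct$p.value, n = length(shared)
  )
}
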