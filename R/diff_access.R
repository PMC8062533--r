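# Differential accessibility between two groups of replicated insertion
# count profiles. The model is the standard one for replicated count data:
# counts are negative binomial with variance mu + phi * mu^2, samples are
# made comparable by TMM normalisation, a single common dispersion phi is
# estimated by profile likelihood, and each site is tested with the
# conditional NB exact test ("sum of outcomes no more likely than the
# observed one", not a doubled tail).

counts_to_matrix <- function(counts, samples = NULL) {
  check_columns(counts, "acs_id", "counts")
  mat <- as.matrix(counts[setdiff(names(counts), "acs_id")])
  rownames(mat) <- counts$acs_id
  storage.mode(mat) <- "double"
  if (!is.null(samples)) {
    check_columns(samples, c("sample", "group"), "samples")
    missing <- setdiff(samples$sample, colnames(mat))
    if (length(missing) > 0) {
      abort(paste0(
        "sample(s) absent from the counts table: ",
        paste(missing, collapse = ", ")
      ))
    }
    mat <- mat[, samples$sample, drop = FALSE]
  }
  mat
}

#' TMM normalisation factors
#'
#' Weighted trimmed mean of M-values: for each sample against a reference,
#' per-site log2 ratios (M) and average log intensities (A) are computed on
#' library-size-scaled counts, the most extreme 30% of M values and 5% of A
#' values are trimmed on each side, and the remaining M values are averaged
#' with inverse asymptotic variance weights. Factors are rescaled to
#' geometric mean 1. The reference defaults to the sample whose
#' upper-quartile count fraction is closest to the mean upper quartile.
#'
#' @param counts Count tibble (`acs_id` + sample columns) or numeric matrix.
#' @param ref_sample Optional reference sample name.
#' @return Named vector of positive normalisation factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  mat <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  if (ncol(mat) < 2) abort("TMM needs at least two samples")
  lib <- colSums(mat)
  if (any(lib == 0)) {
    abort(paste0(
      "sample(s) with all-zero counts: ",
      paste(colnames(mat)[lib == 0], collapse = ", ")
    ))
  }
  f75 <- vapply(
    seq_len(ncol(mat)),
    function(j) quantile(mat[, j] / lib[j], 0.75, names = FALSE),
    numeric(1)
  )
  ref <- if (is.null(ref_sample)) {
    which.min(abs(f75 - mean(f75)))
  } else {
    match(ref_sample, colnames(mat))
  }
  if (is.na(ref)) abort("`ref_sample` not found among samples")
  yr <- mat[, ref]
  nr <- lib[ref]
  factors <- vapply(seq_len(ncol(mat)), function(j) {
    y <- mat[, j]
    n <- lib[j]
    keep <- y > 0 & yr > 0
    if (!any(keep)) {
      return(1)
    }
    m <- log2((y[keep] / n) / (yr[keep] / nr))
    a <- 0.5 * log2((y[keep] / n) * (yr[keep] / nr))
    # delta-method variance of M; weights are its inverse
    v <- (n - y[keep]) / (n * y[keep]) + (nr - yr[keep]) / (nr * yr[keep])
    k <- length(m)
    lo_m <- floor(k * 0.3) + 1
    hi_m <- k + 1 - lo_m
    lo_a <- floor(k * 0.05) + 1
    hi_a <- k + 1 - lo_a
    rm_ <- rank(m)
    ra_ <- rank(a)
    use <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(use) || sum(1 / v[use]) == 0) {
      return(1)
    }
    fj <- sum(m[use] / v[use]) / sum(1 / v[use])
    if (!is.finite(fj) || abs(fj) < 1e-6) fj <- 0
    2^fj
  }, numeric(1))
  names(factors) <- colnames(mat)
  factors / geometric_mean(factors)
}

# Profiled NB log-likelihood at dispersion phi: per-site per-group means
# are replaced by their MLE (Newton on the score, vectorised over sites),
# with the Cox-Reid adjustment -(1/2) log I(m) per profiled mean; without
# it the dispersion would be biased low by the (n - groups)/n df factor.
profiled_nb_loglik <- function(mat, group_index, offsets, phi) {
  s <- exp(offsets)
  total <- 0
  for (g in unique(group_index)) {
    cols <- which(group_index == g)
    y <- mat[, cols, drop = FALSE]
    sg <- s[cols]
    m <- rowSums(y) / sum(sg)
    pos <- m > 0
    if (any(pos)) {
      mp <- m[pos]
      yp <- y[pos, , drop = FALSE]
      for (it in 1:25) {
        score <- 0
        dscore <- 0
        for (j in seq_along(sg)) {
          denom <- 1 + phi * sg[j] * mp
          score <- score + (yp[, j] - sg[j] * mp) / denom
          dscore <- dscore - sg[j] * (1 + phi * yp[, j]) / denom^2
        }
        step <- score / dscore
        mp_new <- pmax(mp - step, mp / 10)
        if (max(abs(mp_new - mp) / pmax(mp, 1e-8)) < 1e-8) {
          mp <- mp_new
          break
        }
        mp <- mp_new
      }
      m[pos] <- mp
    }
    size <- 1 / phi
    for (j in seq_along(sg)) {
      mu <- sg[j] * m
      ll <- ifelse(mu > 0,
        lgamma(y[, j] + size) - lgamma(size) - lgamma(y[, j] + 1) +
          y[, j] * log(mu / (mu + size)) + size * log(size / (size + mu)),
        ifelse(y[, j] == 0, 0, -Inf)
      )
      total <- total + sum(ll)
    }
    # Cox-Reid: expected information of the profiled mean
    if (any(pos)) {
      info <- Reduce(`+`, lapply(seq_along(sg), function(j) {
        sg[j] / (m[pos] * (1 + phi * sg[j] * m[pos]))
      }))
      total <- total - 0.5 * sum(log(info))
    }
  }
  total
}

#' Estimate a common NB dispersion by profile likelihood
#'
#' Maximises, over phi in `[1e-6, 10]`, the sum across sites of the NB
#' log-likelihood with per-site group means profiled out, using offsets
#' `log(lib_size * factor)`. The search is golden-section on log phi with
#' tolerance 1e-4.
#'
#' @param counts Count tibble or matrix.
#' @param samples Sample sheet (`sample`, `group`).
#' @param factors TMM factors (defaults to [tmm_factors()]).
#' @return The common dispersion estimate (a single number).
#' @export
estimate_common_dispersion <- function(counts, samples, factors = NULL) {
  mat <- if (is.matrix(counts)) counts else counts_to_matrix(counts, samples)
  if (is.null(factors)) factors <- tmm_factors(mat)
  group_index <- match(samples$group, unique(samples$group))
  offsets <- log(colSums(mat) * factors[colnames(mat)])
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0) {
    warn("no non-zero features; returning the dispersion lower bound")
    return(1e-6)
  }
  grp_var <- vapply(unique(group_index), function(g) {
    sum(apply(mat[, group_index == g, drop = FALSE], 1, var))
  }, numeric(1))
  if (all(grp_var == 0)) {
    warn("all features constant within groups; dispersion at lower bound")
    return(1e-6)
  }
  obj <- function(lphi) profiled_nb_loglik(mat, group_index, offsets, 10^lphi)
  lo <- log10(1e-6)
  hi <- log10(10)
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- obj(x1)
  f2 <- obj(x2)
  while (hi - lo > 1e-4) {
    if (f1 < f2) {
      lo <- x1
      x1 <- x2
      f1 <- f2
      x2 <- lo + gr * (hi - lo)
      f2 <- obj(x2)
    } else {
      hi <- x2
      x2 <- x1
      f2 <- f1
      x1 <- hi - gr * (hi - lo)
      f1 <- obj(x1)
    }
  }
  10^((lo + hi) / 2)
}

# Scale each sample's counts to the geometric-mean effective library and
# round to the nearest integer (the documented approximation standing in
# for full quantile adjustment).
equalize_counts <- function(mat, eff_lib) {
  common <- geometric_mean(eff_lib)
  out <- sweep(mat, 2, common / eff_lib, `*`)
  round(out)
}

# Conditional two-sided exact NB p-value for one site: given group sums
# (a, b) with n_a, n_b samples of equal effective library and common
# dispersion phi, sum the probabilities of all splits of t = a + b that are
# no more likely than the observed split.
nb_exact_pvalue_single <- function(a, b, n_a, n_b, phi) {
  if (a < 0 || b < 0) abort("negative counts in exact test")
  t <- a + b
  if (t == 0) {
    return(1)
  }
  k <- 0:t
  if (phi <= 1e-10) {
    logp <- dbinom(k, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    r1 <- n_a / phi
    r2 <- n_b / phi
    logp <- lchoose(k + r1 - 1, k) + lchoose(t - k + r2 - 1, t - k)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  obs <- logp[a + 1]
  min(1, sum(exp(logp[logp <= obs + 1e-10])))
}

#' Conditional NB exact test over all sites
#'
#' @param counts_a,counts_b Matrices of library-equalised counts, one
#'   column per sample, rows aligned.
#' @param phi Common NB dispersion.
#' @return Vector of two-sided p-values in (0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b, phi) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (any(counts_a < 0) || any(counts_b < 0)) {
    abort("negative counts in exact test")
  }
  a <- rowSums(counts_a)
  b <- rowSums(counts_b)
  vapply(
    seq_along(a),
    function(i) {
      nb_exact_pvalue_single(a[i], b[i], ncol(counts_a), ncol(counts_b), phi)
    },
    numeric(1)
  )
}

#' Per-site log2 fold-change of normalised group means
#'
#' Counts are scaled to a common effective library; the fold-change is
#' `log2((mean_alt + prior) / (mean_ref + prior))` so that positive values
#' mean more accessible in the alternative (adult) group.
#'
#' @param counts Count tibble or matrix.
#' @param samples Sample sheet (`sample`, `group`).
#' @param factors TMM factors.
#' @param group_ref,group_alt Group labels (reference and alternative).
#' @param prior_count Prior count added to each group mean (default 0.5 at
#'   the common library scale).
#' @return Named vector of log2 fold-changes (alt minus ref).
#' @export
log2_fold_change <- function(counts, samples, factors = NULL,
                             group_ref = "P10", group_alt = "adult",
                             prior_count = 0.5) {
  mat <- if (is.matrix(counts)) counts else counts_to_matrix(counts, samples)
  if (is.null(factors)) factors <- tmm_factors(mat)
  check_number(prior_count, "prior_count", lower = 1e-12)
  eff <- colSums(mat) * factors[colnames(mat)]
  scaled <- sweep(mat, 2, geometric_mean(eff) / eff, `*`)
  idx_ref <- samples$sample[samples$group == group_ref]
  idx_alt <- samples$sample[samples$group == group_alt]
  if (length(idx_ref) == 0 || length(idx_alt) == 0) {
    abort("both groups must be non-empty")
  }
  m_ref <- rowMeans(scaled[, idx_ref, drop = FALSE])
  m_alt <- rowMeans(scaled[, idx_alt, drop = FALSE])
  setNames(log2((m_alt + prior_count) / (m_ref + prior_count)), rownames(mat))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment, capped at 1.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Classify sites as Up / Down / Stable
#'
#' A site is `Up` when its log2FC is positive, its p-value is below
#' `p_threshold` and its FDR below `fdr_threshold`; `Down` symmetrically for
#' negative log2FC; otherwise `Stable`.
#'
#' @param results Tibble with `log2_fc`, `p_value`, `fdr`.
#' @param p_threshold,fdr_threshold Significance cutoffs (defaults 0.05 and
#'   0.2).
#' @return `results` with a `class` column added.
#' @export
classify_acs <- function(results, p_threshold = 0.05, fdr_threshold = 0.2) {
  check_columns(results, c("log2_fc", "p_value", "fdr"), "results")
  check_number(p_threshold, "p_threshold", lower = 0, upper = 1)
  check_number(fdr_threshold, "fdr_threshold", lower = 0, upper = 1)
  sig <- results$p_value < p_threshold & results$fdr < fdr_threshold
  dplyr::mutate(results, class = dplyr::case_when(
    sig & .data$log2_fc > 0 ~ "Up",
    sig & .data$log2_fc < 0 ~ "Down",
    TRUE ~ "Stable"
  ))
}

#' Fractions of Up / Down / Stable sites
#'
#' @param results A classified differential table (with a `class` column).
#' @return A tibble `class`, `n`, `fraction` over the three classes.
#' @export
class_fractions <- function(results) {
  check_columns(results, "class", "results")
  tibble(class = c("Up", "Down", "Stable")) |>
    dplyr::left_join(
      dplyr::count(results, .data$class),
      by = "class"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      fraction = .data$n / sum(.data$n)
    )
}

#' Differential accessibility analysis
#'
#' Full two-group chain: TMM factors, common dispersion by profile
#' likelihood, library equalisation, conditional NB exact test per site,
#' prior-augmented log2 fold-change, BH adjustment and Up/Down/Stable
#' classification.
#'
#' @param counts Count tibble (`acs_id` + one column per sample).
#' @param samples Sample sheet tibble (`sample`, `group`).
#' @param group_ref,group_alt Reference (P10) and alternative (adult) group
#'   labels; positive log2FC means more accessible in `group_alt`.
#' @param p_threshold,fdr_threshold Classification cutoffs.
#' @param prior_count Fold-change prior count.
#' @param dispersion Optional known dispersion; estimated when `NULL`.
#' @return A `diff_access` tibble: `acs_id`, `log2_fc`, `p_value`, `fdr`,
#'   `class`, with normalisation state (`lib_sizes`, `tmm_factors`,
#'   `dispersion`, thresholds) in attributes; see [glance.diff_access()].
#' @export
diff_accessibility <- function(counts, samples,
                               group_ref = "P10", group_alt = "adult",
                               p_threshold = 0.05, fdr_threshold = 0.2,
                               prior_count = 0.5, dispersion = NULL) {
  mat <- counts_to_matrix(counts, samples)
  groups <- setNames(samples$group, samples$sample)
  if (!all(c(group_ref, group_alt) %in% groups)) {
    abort("`group_ref` and `group_alt` must both appear in `samples$group`")
  }
  factors <- tmm_factors(mat)
  phi <- dispersion %||%
    estimate_common_dispersion(mat, samples, factors)
  eff <- colSums(mat) * factors[colnames(mat)]
  eq <- equalize_counts(mat, eff)
  cols_ref <- samples$sample[samples$group == group_ref]
  cols_alt <- samples$sample[samples$group == group_alt]
  p <- nb_exact_test(
    eq[, cols_alt, drop = FALSE],
    eq[, cols_ref, drop = FALSE], phi
  )
  lfc <- log2_fold_change(mat, samples, factors,
    group_ref = group_ref, group_alt = group_alt, prior_count = prior_count
  )
  res <- tibble(
    acs_id = rownames(mat),
    log2_fc = unname(lfc),
    p_value = p,
    fdr = bh_adjust(p)
  )
  res <- classify_acs(res, p_threshold, fdr_threshold)
  structure(res,
    class = c("diff_access", class(res)),
    lib_sizes = colSums(mat),
    tmm_factors = factors,
    dispersion = phi,
    p_threshold = p_threshold,
    fdr_threshold = fdr_threshold
  )
}

#' @importFrom rlang %||%
NULL
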