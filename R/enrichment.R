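# Preranked set enrichment over sites ranked by accessibility log2
# fold-change. The enrichment score is the signed extremum of a weighted
# Kolmogorov-Smirnov running sum; significance comes from a permutation
# null of random equal-size member sets drawn from the same ranking, with
# BH adjustment across sets.

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking down the ranking, member hits add `|r_i|^w / sum_members(|r|^w)`
#' and misses subtract `1 / (n - n_members)`; the enrichment score is the
#' signed extremum of the walk (when the maximum and the negated minimum
#' tie exactly, the positive extremum is reported).
#'
#' @param ranked_values Numeric vector sorted in decreasing order.
#' @param membership 0/1 (or logical) vector aligned with `ranked_values`.
#' @param weight_exponent Weight exponent `w` (0 gives the classic
#'   unweighted statistic).
#' @return A list with `es` (in `[-1, 1]`), `position` (1-based rank of the
#'   extremum) and `leading_edge_size`.
#' @export
enrichment_score <- function(ranked_values, membership, weight_exponent = 1) {
  membership <- as.logical(membership)
  n <- length(ranked_values)
  if (length(membership) != n) {
    abort("`membership` must align with `ranked_values`")
  }
  k <- sum(membership)
  if (k == 0 || k == n) {
    abort("the set must have at least one member and one non-member")
  }
  res <- es_from_positions(
    which(membership),
    abs(ranked_values)^weight_exponent, n
  )
  members_at <- cumsum(membership)
  leading <- if (res$es >= 0) {
    members_at[res$position]
  } else {
    k - (if (res$position > 1) members_at[res$position - 1] else 0L)
  }
  list(es = res$es, position = res$position, leading_edge_size = leading)
}

# Fast ES from sorted member positions. `absw` is the |r|^w vector for the
# whole ranking. The walk's extrema can only occur at hit positions (just
# after a hit for the maximum, just before for the minimum).
es_from_positions <- function(pos, absw, n) {
  k <- length(pos)
  hit_w <- absw[pos]
  nr <- sum(hit_w)
  inc <- if (nr > 0) hit_w / nr else rep(1 / k, k)
  cum_hit <- cumsum(inc)
  miss_step <- 1 / (n - k)
  i <- seq_len(k)
  after <- cum_hit - (pos - i) * miss_step
  before <- c(0, cum_hit[-k]) - (pos - i) * miss_step
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) {
    list(es = hi, position = pos[which.max(after)])
  } else {
    list(es = lo, position = pos[which.min(before)])
  }
}

#' Preranked permutation GSEA over motif (or annotation) sets
#'
#' The null for each set is the enrichment score of random member sets of
#' the same size drawn from the same ranking. P-values are one-sided on the
#' sign of the observed score: `(1 + same-sign exceedances) /
#' (1 + same-sign permutations)`, the convention that keeps null p-values
#' uniform; they are never zero. The normalised score (NES) divides the
#' observed score by the mean absolute null score of the same sign. Ties in
#' the ranking are broken by stable input order.
#'
#' @param ranking Tibble with columns `id` and `stat`, or a named numeric
#'   vector; ranked internally in decreasing `stat` order.
#' @param sets Named list mapping `set_id` to member ids.
#' @param n_perm Number of permutations.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranking.
#' @param weight_exponent Hit weight exponent.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A `gsea_result` tibble: `set_id`, `size`, `es`, `nes`,
#'   `p_value`, `adj_p`, `leading_edge_size`, sorted by `p_value`. Sets
#'   empty after intersection are dropped with a warning.
#' @export
gsea_prerank <- function(ranking, sets, n_perm = 1000, min_size = 5,
                         max_size = 5000, weight_exponent = 1, seed = NULL) {
  if (is.numeric(ranking)) {
    ranking <- tibble(id = names(ranking), stat = unname(ranking))
  }
  check_columns(ranking, c("id", "stat"), "ranking")
  check_number(n_perm, "n_perm", lower = 1, integer = TRUE)
  ord <- order(ranking$stat, decreasing = TRUE)
  ids <- ranking$id[ord]
  absw <- abs(ranking$stat[ord])^weight_exponent
  n <- length(ids)
  rank_of <- setNames(seq_len(n), ids)

  set_pos <- purrr::map(sets, function(members) {
    sort(unname(rank_of[intersect(unique(members), ids)]))
  })
  empty <- lengths(set_pos) == 0
  if (any(empty)) {
    warn(paste0(
      "dropping ", sum(empty),
      " set(s) empty after intersection with the ranking: ",
      paste(head(names(set_pos)[empty], 5), collapse = ", ")
    ))
  }
  keep <- lengths(set_pos) >= max(min_size, 1) &
    lengths(set_pos) <= min(max_size, n - 1)
  set_pos <- set_pos[keep & !empty]
  if (length(set_pos) == 0) {
    abort("no set passes the size bounds after intersection with the ranking")
  }
  obs <- purrr::map(set_pos, function(pos) {
    es_from_positions(pos, absw, n)
  })
  obs_es <- purrr::map_dbl(obs, "es")
  sizes <- lengths(set_pos)
  uniq_sizes <- sort(unique(sizes))
  size_index <- match(sizes, uniq_sizes)

  exceed <- numeric(length(set_pos))
  null_sum_pos <- setNames(numeric(length(uniq_sizes)), uniq_sizes)
  null_n_pos <- null_sum_pos
  null_sum_neg <- null_sum_pos
  null_n_neg <- null_sum_pos
  null_es_by_size <- matrix(0, n_perm, length(uniq_sizes))
  with_local_seed(seed, {
    kmax <- max(uniq_sizes)
    for (b in seq_len(n_perm)) {
      draw <- sample.int(n, kmax)
      for (si in seq_along(uniq_sizes)) {
        k <- uniq_sizes[si]
        null_es_by_size[b, si] <-
          es_from_positions(sort(draw[seq_len(k)]), absw, n)$es
      }
    }
  })
  for (si in seq_along(uniq_sizes)) {
    es_null <- null_es_by_size[, si]
    null_sum_pos[si] <- sum(es_null[es_null >= 0])
    null_n_pos[si] <- sum(es_null >= 0)
    null_sum_neg[si] <- sum(abs(es_null[es_null < 0]))
    null_n_neg[si] <- sum(es_null < 0)
  }
  p <- numeric(length(set_pos))
  nes <- numeric(length(set_pos))
  for (s in seq_along(set_pos)) {
    es_null <- null_es_by_size[, size_index[s]]
    if (obs_es[s] >= 0) {
      p[s] <- (1 + sum(es_null >= obs_es[s] & es_null >= 0)) /
        (1 + null_n_pos[size_index[s]])
      denom <- null_sum_pos[size_index[s]] /
        max(null_n_pos[size_index[s]], 1)
    } else {
      p[s] <- (1 + sum(es_null <= obs_es[s])) /
        (1 + null_n_neg[size_index[s]])
      denom <- null_sum_neg[size_index[s]] /
        max(null_n_neg[size_index[s]], 1)
    }
    nes[s] <- if (denom > 0) obs_es[s] / denom else NA_real_
  }
  out <- tibble(
    set_id = names(set_pos),
    size = as.integer(sizes),
    es = unname(obs_es),
    nes = unname(nes),
    p_value = unname(p),
    adj_p = bh_adjust(unname(p)),
    leading_edge_size = purrr::map_int(seq_along(set_pos), function(s) {
      pos <- set_pos[[s]]
      ext <- obs[[s]]$position
      if (obs_es[s] >= 0) {
        sum(pos <= ext)
      } else {
        sum(pos >= ext)
      }
    })
  ) |>
    dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$nes)))
  structure(out, class = c("gsea_result", class(out)))
}

#' One-sided hypergeometric over-representation test
#'
#' Exact upper-tail probability `P(X >= k)` of drawing at least `k`
#' successes in `n` draws without replacement from a universe of size `N`
#' containing `K` successes.
#'
#' @param k Observed successes among the draws.
#' @param K Successes in the universe.
#' @param n Number of draws.
#' @param N Universe size.
#' @return The exact tail probability.
#' @export
hypergeom_test <- function(k, K, n, N) {
  check_number(k, "k", lower = 0, integer = TRUE)
  check_number(K, "K", lower = 0, integer = TRUE)
  check_number(n, "n", lower = 0, integer = TRUE)
  check_number(N, "N", lower = 1, integer = TRUE)
  if (K > N || n > N || k > min(n, K)) {
    abort("inconsistent hypergeometric arguments: need k <= min(n, K) and n, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
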