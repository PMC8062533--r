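# Independent brute-force oracles used to pin down expected values. These
# deliberately share no code with the implementations they check.

# Direct running-sum enrichment score (the definition, step by step; the
# documented tie rule reports the positive extremum when |max| == |min|).
brute_force_es <- function(values, membership, w = 1) {
  membership <- as.logical(membership)
  n <- length(values)
  nr <- sum(abs(values[membership])^w)
  walk <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(n)) {
    if (membership[i]) {
      walk <- walk + if (nr > 0) abs(values[i])^w / nr else 1 / sum(membership)
    } else {
      walk <- walk - 1 / (n - sum(membership))
    }
    hi <- max(hi, walk)
    lo <- min(lo, walk)
  }
  if (hi >= -lo) hi else lo
}

# Exact PSSM match p-values by exhaustive enumeration of all 4^w words.
enumerate_word_pvalue <- function(pssm, query_scores) {
  w <- pssm$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  lp <- numeric(nrow(words))
  for (j in seq_len(w)) {
    sc <- sc + pssm$scores[cbind(words[, j], j)]
    lp <- lp + log(pssm$background[words[, j]])
  }
  pr <- exp(lp)
  vapply(query_scores, function(s) sum(pr[sc >= s - 1e-9]), numeric(1))
}

# Step-up BH from the definition.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Hypergeometric upper tail from binomial coefficients.
brute_force_hyper <- function(k, K, n, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# A deterministic toy counts fixture: 2 groups x n_per replicates.
toy_counts <- function(n_acs = 50, n_per = 3, seed = 42, dispersion = 0.1,
                       log2fc = rep(0, n_acs)) {
  sim <- simulate_counts(
    setNames(log2fc, sprintf("acs%03d", seq_len(n_acs))),
    n_per_group = n_per, dispersion = dispersion, seed = seed
  )
  sim
}

# A generic random count PFM (JASPAR-like: smooth, no tied score levels).
random_count_pfm <- function(width) {
  m <- matrix(rgamma(4 * width, shape = 2) * 25, 4, width,
    dimnames = list(c("A", "C", "G", "T"))
  )
  m
}

# A consensus-only PSSM for a fixed word (very high scores on the word).
consensus_pssm <- function(word, id = "cons") {
  codes <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  pfm <- matrix(0, 4, length(codes), dimnames = list(c("A", "C", "G", "T")))
  pfm[cbind(codes, seq_along(codes))] <- 100
  pfm_to_pssm(pfm, pseudocount = 0.01, motif_id = id)
}
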