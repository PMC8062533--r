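# PWM scanning with exact match p-values. A PFM is converted to a log-odds
# PSSM against a mononucleotide background; the null distribution of the
# window score for a random background word is computed exactly by dynamic
# programming over discretised per-column scores, and every window of each
# sequence (both strands) whose score p-value passes the threshold is
# reported. Windows containing N are excluded.

#' Convert a position frequency matrix to a log-odds PSSM
#'
#' Probabilities are `(count + pseudocount * background) / (total +
#' pseudocount)` per column; scores are `log2(prob / background)`.
#'
#' @param pfm 4 x width non-negative matrix (rows A, C, G, T), counts or
#'   probabilities.
#' @param background Length-4 positive base composition (normalised
#'   internally).
#' @param pseudocount Total pseudocount per column, distributed
#'   proportionally to the background; must be positive unless the PFM has
#'   no zero entries.
#' @param motif_id Optional identifier carried through to matches.
#' @return A `pssm` object (list with `motif_id`, `scores`, `probs`,
#'   `background`, `pseudocount`, `width`).
#' @export
pfm_to_pssm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.1,
                        motif_id = NULL) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4 || any(pfm < 0)) {
    abort("`pfm` must be a non-negative 4 x width matrix (rows A,C,G,T)")
  }
  if (any(background <= 0) || length(background) != 4) {
    abort("`background` must be 4 strictly positive frequencies")
  }
  background <- background / sum(background)
  check_number(pseudocount, "pseudocount", lower = 0)
  totals <- colSums(pfm)
  if (pseudocount == 0 && any(pfm == 0)) {
    if (any(totals == 0)) {
      abort("zero column total with zero pseudocount")
    }
  }
  if (any(totals == 0) && pseudocount == 0) {
    abort("zero column total with zero pseudocount")
  }
  probs <- sweep(pfm, 2, totals, function(x, tot) {
    x / ifelse(tot > 0, tot, 1)
  })
  probs <- sweep(probs, 2, totals / (totals + pseudocount), `*`) +
    (pseudocount / rep(totals + pseudocount, each = 4)) * background
  scores <- log2(probs / background)
  rownames(scores) <- rownames(probs) <- DNA_ALPHABET
  structure(
    list(
      motif_id = motif_id %||% "motif", scores = scores, probs = probs,
      background = background, pseudocount = pseudocount, width = ncol(pfm)
    ),
    class = "pssm"
  )
}

# Reverse-complement view of a PSSM score matrix: a minus-strand match at a
# window equals the plus-strand score of this matrix at the same window.
revcomp_scores <- function(scores) {
  scores[4:1, rev(seq_len(ncol(scores))), drop = FALSE]
}

#' Exact null distribution of PSSM window scores
#'
#' The distribution of the total score of a random background word is
#' obtained by convolving the per-column score distributions. For motifs
#' of width at most `exact_width` the convolution runs on the exact score
#' support (at most `4^width` values), making p-values exact; wider motifs
#' fall back to a discretised convolution on an integer grid with `n_bins`
#' levels across the widest column's score span. Letters with `-Inf` score
#' (possible only at zero pseudocount) contribute an excluded probability
#' mass rather than a finite score.
#'
#' @param pssm A `pssm` object.
#' @param n_bins Number of discretisation steps across the widest column's
#'   score span (wide motifs only).
#' @param exact_width Largest width for which the exact-support convolution
#'   is used.
#' @return A `pssm_dist` object with the survival function of the score.
#' @export
pssm_score_distribution <- function(pssm, n_bins = 10000, exact_width = 9) {
  stopifnot(inherits(pssm, "pssm"))
  s <- pssm$scores
  w <- ncol(s)
  finite <- is.finite(s)
  if (w <= exact_width) {
    # exact support: accumulate column sums in scan order so window scores
    # reproduce support values bit for bit
    support <- 0
    prob <- 1
    excluded <- 0
    for (j in seq_len(w)) {
      vals <- s[, j]
      keep <- finite[, j]
      excluded <- excluded + sum(prob) * sum(pssm$background[!keep])
      support <- rep(support, each = sum(keep)) + vals[keep]
      prob <- rep(prob, each = sum(keep)) * pssm$background[keep]
      ord <- order(support)
      support <- support[ord]
      prob <- prob[ord]
      dup <- c(diff(support) < 1e-12, FALSE)
      if (any(dup)) {
        grp <- cumsum(!c(FALSE, dup[-length(dup)]))
        prob <- as.numeric(rowsum(prob, grp))
        support <- support[!c(FALSE, dup[-length(dup)])]
      }
    }
    return(structure(
      list(
        type = "exact", support = support,
        tail_p = rev(cumsum(rev(prob))),
        excluded_mass = excluded, width = w
      ),
      class = "pssm_dist"
    ))
  }
  col_min <- apply(s, 2, function(x) min(x[is.finite(x)]))
  col_max <- apply(s, 2, function(x) max(x[is.finite(x)]))
  span <- max(col_max - col_min)
  g <- if (span > 0) span / n_bins else 1
  ints <- round(sweep(s, 2, col_min) / g)
  max_int <- sum(apply(ints, 2, function(x) max(x[is.finite(x)])))
  dist <- numeric(max_int + 1)
  dist[1] <- 1
  excluded <- 0
  for (j in seq_len(w)) {
    new <- numeric(max_int + 1)
    for (b in 1:4) {
      if (!finite[b, j]) {
        excluded <- excluded + sum(dist) * pssm$background[b]
        next
      }
      k <- ints[b, j]
      p <- pssm$background[b]
      if (k == 0) {
        new <- new + dist * p
      } else {
        n <- length(dist)
        new[(k + 1):n] <- new[(k + 1):n] + dist[1:(n - k)] * p
      }
    }
    dist <- new
  }
  tail_p <- rev(cumsum(rev(dist)))
  structure(
    list(
      type = "grid",
      base = sum(col_min), granularity = g, tail_p = tail_p,
      excluded_mass = excluded, width = w, int_scores = ints
    ),
    class = "pssm_dist"
  )
}

#' Match p-values for PSSM scores
#'
#' `p(s)` is the probability that a random background word of the motif's
#' width scores at least `s`. Non-increasing in `s`; `p(-Inf) = 1`.
#'
#' @param dist A `pssm_dist` object.
#' @param scores Numeric vector of window scores (may include `-Inf`).
#' @return P-values in `(0, 1]`.
#' @export
score_pvalue <- function(dist, scores) {
  stopifnot(inherits(dist, "pssm_dist"))
  if (identical(dist$type, "exact")) {
    # first support value >= s (with a small tolerance for float noise)
    idx <- findInterval(scores - 1e-9, dist$support) + 1
    n <- length(dist$support)
    p <- numeric(length(scores))
    low <- !is.finite(scores) & scores < 0
    p[low] <- 1
    mid <- !low & idx <= n
    p[mid] <- dist$tail_p[idx[mid]]
    p[!low & idx > n] <- 0
    return(pmax(p, 0))
  }
  k <- round((scores - dist$base) / dist$granularity)
  n <- length(dist$tail_p)
  p <- numeric(length(scores))
  low <- !is.finite(scores) | k < 0
  p[low] <- 1
  mid <- !low & k < n
  p[mid] <- dist$tail_p[k[mid] + 1]
  # above the maximum achievable score nothing can match
  p[!low & k >= n] <- 0
  pmax(p, 0)
}

# Window scores of an encoded sequence (integer codes, NA for N) against a
# score matrix; windows containing N score NA.
window_scores <- function(codes, scores) {
  w <- ncol(scores)
  n_win <- length(codes) - w + 1
  if (n_win < 1) {
    return(numeric(0))
  }
  total <- numeric(n_win)
  for (j in seq_len(w)) {
    total <- total + scores[cbind(codes[j:(j + n_win - 1)], j)]
  }
  total
}

#' Scan one sequence with a PSSM on both strands
#'
#' @param pssm A `pssm` object.
#' @param sequence A single ACGTN string.
#' @param threshold_p Report windows with match p-value at or below this.
#' @param dist Optional precomputed [pssm_score_distribution()].
#' @return A tibble `offset` (0-based, plus-strand coordinate of the window
#'   start), `strand` (`+`/`-`), `score`, `p`, ordered by offset. Sequences
#'   shorter than the motif give an empty result.
#' @export
scan_sequence <- function(pssm, sequence, threshold_p = 1e-4, dist = NULL) {
  stopifnot(inherits(pssm, "pssm"), length(sequence) == 1)
  check_number(threshold_p, "threshold_p", lower = 0, upper = 1)
  if (is.null(dist)) dist <- pssm_score_distribution(pssm)
  codes <- encode_sequence(sequence)
  out <- purrr::map(c("+", "-"), function(strand) {
    mat <- if (strand == "+") pssm$scores else revcomp_scores(pssm$scores)
    sc <- window_scores(codes, mat)
    if (length(sc) == 0) {
      return(NULL)
    }
    ok <- which(is.finite(sc))
    if (length(ok) == 0) {
      return(NULL)
    }
    if (identical(dist$type, "exact")) {
      p <- score_pvalue(dist, sc[ok])
    } else {
      # wide motifs: p-value from the integer score on the DP's own grid,
      # so the reported p is exactly the DP tail of the observed window
      imat <- if (strand == "+") {
        dist$int_scores
      } else {
        revcomp_scores(dist$int_scores)
      }
      isc <- window_scores(codes, imat)[ok]
      n_tail <- length(dist$tail_p)
      p <- ifelse(isc >= n_tail, 0, dist$tail_p[pmin(isc, n_tail - 1) + 1])
    }
    hit <- p <= threshold_p
    if (!any(hit)) {
      return(NULL)
    }
    tibble(
      offset = ok[hit] - 1L, strand = strand,
      score = sc[ok][hit], p = p[hit]
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(
      offset = integer(), strand = character(),
      score = numeric(), p = numeric()
    ))
  }
  dplyr::arrange(res, .data$offset, .data$strand)
}

# Empirical mononucleotide composition of a sequence set (N ignored).
empirical_background <- function(sequences) {
  counts <- numeric(4)
  for (s in sequences) {
    codes <- encode_sequence(s)
    counts <- counts + tabulate(codes[!is.na(codes)], nbins = 4)
  }
  if (sum(counts) == 0) {
    return(rep(0.25, 4))
  }
  pmax(counts / sum(counts), 1e-6)
}

# Build PSSMs (+ score distributions) for a motif tibble.
prepare_pssms <- function(motifs, background, pseudocount) {
  check_columns(motifs, c("motif_id", "matrix"), "motifs")
  purrr::map2(motifs$matrix, motifs$motif_id, function(m, id) {
    pssm <- pfm_to_pssm(m,
      background = background, pseudocount = pseudocount,
      motif_id = id
    )
    list(pssm = pssm, dist = pssm_score_distribution(pssm))
  })
}

#' Scan a sequence set against a motif set
#'
#' @param sequences Sequence tibble (`id`, `seq`).
#' @param motifs Motif tibble (`motif_id`, `matrix`), counts or
#'   probabilities.
#' @param threshold_p Match p-value threshold (FIMO-style default 1e-4).
#' @param background `"empirical"` (mononucleotide composition of the
#'   scanned set, the default), `"uniform"`, or a length-4 vector.
#' @param pseudocount Per-column pseudocount for the PSSM.
#' @return A match tibble: `acs_id`, `motif_id`, `offset`, `strand`,
#'   `score`, `p`.
#' @export
scan_sequences <- function(sequences, motifs, threshold_p = 1e-4,
                           background = "empirical", pseudocount = 0.1) {
  check_columns(sequences, c("id", "seq"), "sequences")
  bg <- resolve_background(background, sequences$seq)
  pssms <- prepare_pssms(motifs, bg, pseudocount)
  res <- purrr::map(pssms, function(pd) {
    hits <- purrr::map2(sequences$id, sequences$seq, function(id, s) {
      h <- scan_sequence(pd$pssm, s, threshold_p = threshold_p, dist = pd$dist)
      if (nrow(h) == 0) {
        return(NULL)
      }
      dplyr::bind_cols(tibble(acs_id = id, motif_id = pd$pssm$motif_id), h)
    })
    dplyr::bind_rows(hits)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(
      acs_id = character(), motif_id = character(), offset = integer(),
      strand = character(), score = numeric(), p = numeric()
    ))
  }
  out
}

resolve_background <- function(background, seqs) {
  if (is.numeric(background)) {
    if (length(background) != 4) abort("numeric background must have length 4")
    return(background / sum(background))
  }
  switch(match.arg(background, c("empirical", "uniform")),
    empirical = empirical_background(seqs),
    uniform = rep(0.25, 4)
  )
}

#' Build the ACS x motif match matrix
#'
#' @param sequences Sequence tibble (`id`, `seq`); ids must be unique.
#' @param motifs Motif tibble (`motif_id`, `matrix`).
#' @param threshold_p Match p-value threshold.
#' @param mode `"binary"` (default; 1 iff at least one match) or `"count"`
#'   (number of matches).
#' @inheritParams scan_sequences
#' @return A `motif_match_matrix` tibble: `acs_id` plus one integer column
#'   per motif, with `threshold_p` and `mode` stored as attributes.
#' @export
build_match_matrix <- function(sequences, motifs, threshold_p = 1e-4,
                               mode = c("binary", "count"),
                               background = "empirical", pseudocount = 0.1) {
  mode <- match.arg(mode)
  check_columns(sequences, c("id", "seq"), "sequences")
  if (anyDuplicated(sequences$id)) {
    abort("duplicate ACS ids in `sequences`")
  }
  bg <- resolve_background(background, sequences$seq)
  pssms <- prepare_pssms(motifs, bg, pseudocount)
  mat <- matrix(0L, nrow(sequences), length(pssms),
    dimnames = list(sequences$id, motifs$motif_id)
  )
  for (m in seq_along(pssms)) {
    pd <- pssms[[m]]
    for (i in seq_len(nrow(sequences))) {
      hits <- scan_sequence(pd$pssm, sequences$seq[i],
        threshold_p = threshold_p, dist = pd$dist
      )
      mat[i, m] <- if (mode == "binary") {
        as.integer(nrow(hits) > 0)
      } else {
        nrow(hits)
      }
    }
  }
  structure(
    dplyr::bind_cols(tibble(acs_id = sequences$id), as_tibble(mat)),
    class = c("motif_match_matrix", class(tibble())),
    threshold_p = threshold_p, mode = mode
  )
}

# Numeric matrix view of a match-matrix tibble.
match_matrix_to_matrix <- function(match_matrix) {
  check_columns(match_matrix, "acs_id", "match_matrix")
  m <- as.matrix(match_matrix[setdiff(names(match_matrix), "acs_id")])
  rownames(m) <- match_matrix$acs_id
  storage.mode(m) <- "double"
  m
}
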