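# Synthetic data with planted ground truth. The generator emulates the
# statistical structure of an ATAC-seq maturation study: a few-vs-few
# replicate design of negative binomial insertion counts over accessible
# chromatin sites (ACS), site sequences carrying planted PWM instances whose
# presence drives the accessibility log2 fold-change through a linear
# activity model, and gene fold-change tables with controlled
# enhancer/repressor concordance to nearby sites.

#' Sample a random position weight matrix of given information content
#'
#' Each column is a mixture `(1 - t) * 1/4 + t * e_b` of the uniform
#' background and a point mass on a randomly chosen consensus letter, with
#' `t` solved per column so the column's information content
#' (`2 + sum(p * log2(p))` bits) equals the request.
#'
#' @param width Motif width in bp (4 to 25).
#' @param information_content Target per-column information content in bits,
#'   in (0, 2]. `2` forces point-mass columns.
#' @param seed Integer seed; the same seed always returns the same matrix.
#' @return A 4 x `width` probability matrix with rows A, C, G, T; columns
#'   sum to 1.
#' @export
sample_pwm <- function(width, information_content, seed = NULL) {
  check_number(width, "width", lower = 4, upper = 25, integer = TRUE)
  check_number(information_content, "information_content",
    lower = 1e-6, upper = 2
  )
  with_local_seed(seed, {
    consensus <- sample.int(4, width, replace = TRUE)
    cols <- vapply(seq_len(width), function(j) {
      ic_of <- function(t) {
        p <- rep((1 - t) / 4, 4)
        p[consensus[j]] <- p[consensus[j]] + t
        2 + sum(ifelse(p > 0, p * log2(p), 0))
      }
      t <- if (information_content >= 2 - 1e-12) {
        1
      } else {
        stats::uniroot(function(t) ic_of(t) - information_content,
          c(0, 1 - 1e-12),
          tol = 1e-10
        )$root
      }
      p <- rep((1 - t) / 4, 4)
      p[consensus[j]] <- p[consensus[j]] + t
      p
    }, numeric(4))
    rownames(cols) <- DNA_ALPHABET
    cols
  })
}

#' Sample a set of random motifs
#'
#' @param n_motifs Number of motifs.
#' @param width_range Integer range of motif widths, inclusive.
#' @param information_content Per-column information content in bits.
#' @param seed Integer seed.
#' @return A motif tibble (`motif_id`, `name`, `matrix`) compatible with
#'   [parse_jaspar_pfm()] output; matrices hold probabilities.
#' @export
sample_motif_set <- function(n_motifs, width_range = c(8, 14),
                             information_content = 1.3, seed = NULL) {
  check_number(n_motifs, "n_motifs", lower = 1, integer = TRUE)
  with_local_seed(seed, {
    wopts <- seq(width_range[1], width_range[2])
    widths <- wopts[sample.int(length(wopts), n_motifs, replace = TRUE)]
    seeds <- sample.int(.Machine$integer.max, n_motifs)
    tibble(
      motif_id = sprintf("SM%03d", seq_len(n_motifs)),
      name = sprintf("synthetic_motif_%03d", seq_len(n_motifs)),
      matrix = purrr::map2(widths, seeds, function(w, s) {
        sample_pwm(w, information_content, seed = s)
      })
    )
  })
}

# Draw one motif instance (a string) from a PWM's column distributions.
draw_motif_instance <- function(pwm) {
  paste(DNA_ALPHABET[apply(pwm, 2, function(p) sample.int(4, 1, prob = p))],
    collapse = ""
  )
}

#' Generate a synthetic ACS universe with planted motif instances
#'
#' Background letters are i.i.d. with the requested GC content. For each
#' (site, motif) pair an instance is planted with the motif's planting
#' probability, at a uniform position on a uniform strand, rejecting
#' positions that would overwrite a previously planted instance. The true
#' accessibility log2 fold-change of each site is the linear activity model
#' `match_truth %*% activity + rnorm(n, 0, noise_sd)`.
#'
#' @param n_acs Number of accessible sites.
#' @param motifs Motif tibble (`motif_id`, `matrix`), e.g. from
#'   [sample_motif_set()].
#' @param planting Tibble with columns `motif_id`, `prob` (per-site planting
#'   probability) and `activity` (true per-match log2FC contribution).
#' @param length_range Site length range in bp, inclusive.
#' @param gc GC content of the background, in (0, 1).
#' @param noise_sd Standard deviation of the Gaussian residual on the true
#'   log2 fold-change.
#' @param n_chrom Number of synthetic chromosomes the sites are laid out on.
#' @param gap_range Range of inter-site gaps in bp.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list with `sequences` (tibble `id`, `seq`), `regions` (tibble
#'   `chrom`, `start`, `end`, `id`) and `truth`, a `synthetic_truth` object
#'   holding `match_truth`, `true_activity`, `epsilon` and
#'   `acs_log2fc_true`.
#' @export
simulate_acs_set <- function(n_acs, motifs, planting,
                             length_range = c(200, 500), gc = 0.45,
                             noise_sd = 0.25, n_chrom = 2,
                             gap_range = c(2000, 8000), seed = NULL) {
  check_number(n_acs, "n_acs", lower = 1, integer = TRUE)
  check_number(gc, "gc", lower = 1e-6, upper = 1 - 1e-6)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_columns(motifs, c("motif_id", "matrix"), "motifs")
  check_columns(planting, c("motif_id", "prob", "activity"), "planting")
  if (!all(planting$motif_id %in% motifs$motif_id)) {
    abort("`planting` names motif_id(s) absent from `motifs`")
  }
  widths <- purrr::map_int(motifs$matrix, ncol)
  if (any(widths >= length_range[1])) {
    abort("motif wider than the minimum ACS length")
  }
  planting <- dplyr::left_join(
    tibble(motif_id = motifs$motif_id),
    planting,
    by = "motif_id"
  ) |>
    dplyr::mutate(
      prob = dplyr::coalesce(.data$prob, 0),
      activity = dplyr::coalesce(.data$activity, 0)
    )
  n_motifs <- nrow(motifs)
  base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  with_local_seed(seed, {
    lopts <- seq(length_range[1], length_range[2])
    lens <- lopts[sample.int(length(lopts), n_acs, replace = TRUE)]
    acs_ids <- sprintf("acs%05d", seq_len(n_acs))
    match_truth <- matrix(0L, n_acs, n_motifs,
      dimnames = list(acs_ids, motifs$motif_id)
    )
    seqs <- character(n_acs)
    for (i in seq_len(n_acs)) {
      chars <- sample(DNA_ALPHABET, lens[i], replace = TRUE, prob = base_probs)
      occupied <- logical(lens[i])
      plant <- runif(n_motifs) < planting$prob
      for (m in which(plant)) {
        w <- widths[m]
        placed <- FALSE
        for (try in seq_len(50)) {
          pos <- sample.int(lens[i] - w + 1, 1)
          if (!any(occupied[pos:(pos + w - 1)])) {
            inst <- draw_motif_instance(motifs$matrix[[m]])
            if (runif(1) < 0.5) inst <- reverse_complement(inst)
            chars[pos:(pos + w - 1)] <- strsplit(inst, "")[[1]]
            occupied[pos:(pos + w - 1)] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (placed) match_truth[i, m] <- 1L
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    epsilon <- rnorm(n_acs, 0, noise_sd)
    acs_log2fc_true <- drop(match_truth %*% planting$activity) + epsilon

    chrom <- paste0("chr", rep_len(seq_len(n_chrom), n_acs))
    start <- integer(n_acs)
    cursor <- setNames(rep(0L, n_chrom), paste0("chr", seq_len(n_chrom)))
    gopts <- seq(gap_range[1], gap_range[2])
    gaps <- gopts[sample.int(length(gopts), n_acs, replace = TRUE)]
    for (i in seq_len(n_acs)) {
      start[i] <- cursor[chrom[i]] + gaps[i]
      cursor[chrom[i]] <- start[i] + lens[i]
    }
    regions <- tibble(
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + lens), id = acs_ids
    )
    truth <- structure(
      list(
        motif_ids = motifs$motif_id,
        true_activity = setNames(planting$activity, motifs$motif_id),
        planting_prob = setNames(planting$prob, motifs$motif_id),
        match_truth = match_truth,
        epsilon = epsilon,
        acs_log2fc_true = setNames(acs_log2fc_true, acs_ids),
        noise_sd = noise_sd,
        gc = gc,
        seed = seed
      ),
      class = "synthetic_truth"
    )
    list(
      sequences = tibble(id = acs_ids, seq = seqs),
      regions = regions,
      truth = truth
    )
  })
}

#' Simulate a replicated negative binomial count matrix
#'
#' Counts follow `NB(mean = lib_j * mu_i * 2^(x_j * log2fc_i), dispersion)`
#' with variance `mu + dispersion * mu^2`, where `x_j` is 1 for adult
#' samples and 0 for P10, so a positive log2FC means more accessible in
#' adult. `dispersion = 0` gives Poisson counts.
#'
#' @param log2fc_true Per-ACS true log2 fold-change (named vector, or a
#'   `synthetic_truth` object).
#' @param n_per_group Replicates per group.
#' @param mean_count Median baseline expected count per site.
#' @param baseline_logmean_sd SD of the log-normal spread of per-site
#'   baseline means.
#' @param dispersion NB dispersion phi (>= 0).
#' @param lib_size_range Relative library-size range samples are drawn from.
#' @param group_labels Two group names, reference first.
#' @param seed Integer seed.
#' @return A list with `counts` (tibble: `acs_id` + one column per sample),
#'   `samples` (tibble: `sample`, `group`) and `mu` (baseline means).
#' @export
simulate_counts <- function(log2fc_true, n_per_group = 3, mean_count = 100,
                            baseline_logmean_sd = 0.8, dispersion = 0.1,
                            lib_size_range = c(0.7, 1.3),
                            group_labels = c("P10", "adult"), seed = NULL) {
  if (inherits(log2fc_true, "synthetic_truth")) {
    log2fc_true <- log2fc_true$acs_log2fc_true
  }
  check_number(n_per_group, "n_per_group", lower = 1, integer = TRUE)
  check_number(dispersion, "dispersion", lower = 0)
  check_number(mean_count, "mean_count", lower = 1e-9)
  n_acs <- length(log2fc_true)
  acs_ids <- names(log2fc_true)
  if (is.null(acs_ids)) acs_ids <- sprintf("acs%05d", seq_len(n_acs))
  n_samples <- 2 * n_per_group
  sample_ids <- c(
    sprintf("%s_%d", group_labels[1], seq_len(n_per_group)),
    sprintf("%s_%d", group_labels[2], seq_len(n_per_group))
  )
  groups <- rep(group_labels, each = n_per_group)
  with_local_seed(seed, {
    mu <- mean_count * exp(rnorm(n_acs, 0, baseline_logmean_sd))
    rel_lib <- runif(n_samples, lib_size_range[1], lib_size_range[2])
    x <- as.numeric(groups == group_labels[2])
    counts <- matrix(0L, n_acs, n_samples,
      dimnames = list(acs_ids, sample_ids)
    )
    for (j in seq_len(n_samples)) {
      mean_j <- rel_lib[j] * mu * 2^(x[j] * log2fc_true)
      counts[, j] <- if (dispersion <= 0) {
        rpois(n_acs, mean_j)
      } else {
        rnbinom(n_acs, size = 1 / dispersion, mu = mean_j)
      }
    }
    list(
      counts = dplyr::bind_cols(
        tibble(acs_id = acs_ids),
        as_tibble(counts)
      ),
      samples = tibble(sample = sample_ids, group = groups),
      mu = setNames(mu, acs_ids),
      rel_lib = setNames(rel_lib, sample_ids)
    )
  })
}

#' Simulate a gene fold-change table concordant with linked ACS
#'
#' Each ACS-to-gene link is assigned a regulatory role: enhancer links give
#' the gene `+concordance * acs_log2fc + noise`, repressor links the
#' negated value, and unlinked genes pure noise. Genes driven through a link
#' are marked significant (small FDR); undriven genes receive FDR above the
#' default significance cutoff, so that role recovery is identifiable.
#'
#' @param tss_table Gene table with `gene_id` (other columns ignored).
#' @param links Tibble with `acs_id`, `gene_id`; every `gene_id` must exist
#'   in `tss_table`.
#' @param acs_log2fc Named per-ACS log2 fold-change vector.
#' @param role_fractions Length-2 vector `c(enhancer, repressor)` of link
#'   role probabilities; the remainder is unlinked.
#' @param concordance Positive scaling from ACS log2FC to gene log2FC.
#' @param noise_sd SD of the Gaussian noise on gene log2FC.
#' @param seed Integer seed.
#' @return A list with `genes` (tibble: `gene_id`, `log2fc`, `fdr`) and
#'   `roles` (tibble: `acs_id`, `gene_id`, `role_true`).
#' @export
simulate_expression <- function(tss_table, links, acs_log2fc,
                                role_fractions = c(0.4, 0.2),
                                concordance = 1, noise_sd = 0.2,
                                seed = NULL) {
  check_columns(links, c("acs_id", "gene_id"), "links")
  check_columns(tss_table, "gene_id", "tss_table")
  check_number(concordance, "concordance", lower = 1e-9)
  check_number(noise_sd, "noise_sd", lower = 0)
  unknown <- setdiff(links$gene_id, tss_table$gene_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "key not found: link gene_id(s) absent from tss_table: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  missing_acs <- setdiff(links$acs_id, names(acs_log2fc))
  if (length(missing_acs) > 0) {
    abort(paste0(
      "key not found: link acs_id(s) absent from acs_log2fc: ",
      paste(head(missing_acs, 5), collapse = ", ")
    ))
  }
  with_local_seed(seed, {
    roles <- sample(c("enhancer", "repressor", "none"),
      nrow(links),
      replace = TRUE,
      prob = c(role_fractions, max(0, 1 - sum(role_fractions)))
    )
    link_fc <- acs_log2fc[links$acs_id]
    signed <- dplyr::case_when(
      roles == "enhancer" ~ concordance * link_fc,
      roles == "repressor" ~ -concordance * link_fc,
      TRUE ~ 0
    )
    gene_signal <- tibble(gene_id = links$gene_id, signal = signed) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(signal = sum(.data$signal), .groups = "drop")
    genes <- tibble(gene_id = tss_table$gene_id) |>
      dplyr::left_join(gene_signal, by = "gene_id") |>
      dplyr::mutate(
        signal = dplyr::coalesce(.data$signal, 0),
        log2fc = .data$signal + rnorm(dplyr::n(), 0, noise_sd),
        driven = .data$gene_id %in% links$gene_id[roles != "none"],
        fdr = ifelse(.data$driven, runif(dplyr::n(), 0, 0.04),
          runif(dplyr::n(), 0.06, 1)
        )
      ) |>
      dplyr::select("gene_id", "log2fc", "fdr")
    list(
      genes = genes,
      roles = tibble(
        acs_id = links$acs_id, gene_id = links$gene_id,
        role_true = roles
      )
    )
  })
}

#' Simulate per-sample Tn5 fragment intervals over a region set
#'
#' Fragment sizes are drawn from a two-component normal mixture
#' (sub-nucleosomal and mono-nucleosomal modes, as in a typical ATAC-seq
#' fragment-size profile) and fragment midpoints uniformly within a region.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, `id`).
#' @param fragments_per_region Mean number of fragments per region (Poisson).
#' @param size_modes,size_sds,size_weights Mixture component means, SDs and
#'   weights for fragment size in bp.
#' @param seed Integer seed.
#' @return A fragment tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @export
simulate_fragments <- function(regions, fragments_per_region = 20,
                               size_modes = c(80, 260),
                               size_sds = c(15, 30),
                               size_weights = c(0.65, 0.35), seed = NULL) {
  check_columns(regions, c("chrom", "start", "end"), "regions")
  with_local_seed(seed, {
    n_frag <- rpois(nrow(regions), fragments_per_region)
    idx <- rep(seq_len(nrow(regions)), n_frag)
    total <- length(idx)
    comp <- sample.int(length(size_modes), total,
      replace = TRUE,
      prob = size_weights
    )
    sizes <- pmax(20, round(rnorm(total, size_modes[comp], size_sds[comp])))
    mid <- regions$start[idx] +
      floor(runif(total) * (regions$end[idx] - regions$start[idx]))
    start <- pmax(0, mid - floor(sizes / 2))
    tibble(
      chrom = regions$chrom[idx],
      start = as.integer(start),
      end = as.integer(start + sizes)
    )
  })
}

#' Serialise a synthetic truth object to JSON
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- list(
    motif_ids = truth$motif_ids,
    acs_ids = names(truth$acs_log2fc_true),
    true_activity = unname(truth$true_activity),
    planting_prob = unname(truth$planting_prob),
    match_truth = unname(truth$match_truth),
    epsilon = truth$epsilon,
    acs_log2fc_true = unname(truth$acs_log2fc_true),
    noise_sd = truth$noise_sd,
    gc = truth$gc,
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a serialised synthetic truth object
#' @param path Path written by [write_truth()].
#' @return A `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  acs_ids <- raw$acs_ids
  match_truth <- matrix(as.integer(as.matrix(raw$match_truth)),
    nrow = length(acs_ids),
    dimnames = list(acs_ids, raw$motif_ids)
  )
  structure(
    list(
      motif_ids = raw$motif_ids,
      true_activity = setNames(raw$true_activity, raw$motif_ids),
      planting_prob = setNames(raw$planting_prob, raw$motif_ids),
      match_truth = match_truth,
      epsilon = raw$epsilon,
      acs_log2fc_true = setNames(raw$acs_log2fc_true, acs_ids),
      noise_sd = raw$noise_sd,
      gc = raw$gc,
      seed = raw$seed
    ),
    class = "synthetic_truth"
  )
}
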