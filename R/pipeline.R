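# End-to-end orchestration: simulate -> (quantify) -> diff -> scan ->
# enrich -> activity -> integrate, driven by a validated key-value (YAML)
# config, with one global seed fanned out to per-stage seeds and a JSON
# run manifest recording parameters and output checksums.

pipeline_defaults <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    # inputs (used when simulate = FALSE)
    simulate = TRUE,
    acs_bed = NULL, acs_fasta = NULL, counts_tsv = NULL, samples_tsv = NULL,
    fragments_bed = NULL, motifs_pfm = NULL, tss_tsv = NULL, genes_tsv = NULL,
    # simulation scale
    n_acs = 500L, n_motifs = 15L, n_active = 4L, n_repressor = 2L,
    planting_prob = 0.12, activity_scale = 0.8, noise_sd = 0.25,
    n_per_group = 3L, mean_count = 100, dispersion = 0.1,
    genes_per_chrom = 60L,
    # thresholds
    p = 0.05, fdr = 0.2, scan_p = 1e-4, alpha = 0.5,
    lambda_rule = "min", gene_fdr = 0.05,
    tss_bound = 1000, proximal_bound = 10000,
    gsea_n_perm = 1000L, min_set_size = 5L, max_set_size = 5000L,
    rank_all_acs = FALSE,
    min_matches = 10L
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path; fills documented defaults,
#' rejects unknown keys (suggesting the closest known one), checks
#' threshold ranges and that referenced input files exist.
#'
#' @param config A named list of settings, or the path to a YAML file.
#' @return A fully-defaulted `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or a file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    suggestions <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(defaults))
      names(defaults)[which.min(d)]
    }, character(1))
    abort(paste0(
      "unknown config key(s): ",
      paste(sprintf("`%s` (did you mean `%s`?)", unknown, suggestions),
        collapse = ", "
      )
    ))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) abort("config key `out_dir` is required")
  check_number(cfg$p, "p", lower = 0, upper = 1)
  check_number(cfg$fdr, "fdr", lower = 0, upper = 1)
  check_number(cfg$scan_p, "scan_p", lower = 0, upper = 1)
  check_number(cfg$alpha, "alpha", lower = 0, upper = 1)
  check_number(cfg$gene_fdr, "gene_fdr", lower = 0, upper = 1)
  check_number(cfg$seed, "seed", integer = TRUE)
  check_number(cfg$gsea_n_perm, "gsea_n_perm", lower = 1, integer = TRUE)
  if (!cfg$lambda_rule %in% c("min", "1se")) {
    abort("`lambda_rule` must be \"min\" or \"1se\"")
  }
  if (!isTRUE(cfg$simulate)) {
    required <- c("acs_bed", "acs_fasta", "counts_tsv", "samples_tsv",
      "motifs_pfm", "tss_tsv", "genes_tsv")
    for (key in required) {
      if (is.null(cfg[[key]])) {
        abort(paste0("config key `", key, "` is required when simulate is off"))
      }
    }
  }
  for (key in c("acs_bed", "acs_fasta", "counts_tsv", "samples_tsv",
    "fragments_bed", "motifs_pfm", "tss_tsv", "genes_tsv")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(paste0("input path for `", key, "` does not exist: ", cfg[[key]]))
    }
  }
  structure(cfg, class = "pipeline_config")
}

# Synthetic-input stage: motifs, ACS sequences/regions, counts, TSS and
# gene tables, all written under out_dir with the stage seed.
stage_simulate <- function(cfg, paths) {
  seed <- stage_seed(cfg$seed, "simulate")
  motifs <- sample_motif_set(cfg$n_motifs, seed = seed)
  n_act <- min(cfg$n_active, cfg$n_motifs)
  n_rep <- min(cfg$n_repressor, n_act)
  activity <- rep(0, cfg$n_motifs)
  signs <- c(rep(-1, n_rep), rep(1, n_act - n_rep))
  activity[seq_len(n_act)] <- signs * cfg$activity_scale
  planting <- tibble(
    motif_id = motifs$motif_id,
    prob = cfg$planting_prob,
    activity = activity
  )
  acs <- simulate_acs_set(cfg$n_acs, motifs, planting,
    noise_sd = cfg$noise_sd, seed = seed + 1
  )
  sim <- simulate_counts(acs$truth,
    n_per_group = cfg$n_per_group,
    mean_count = cfg$mean_count, dispersion = cfg$dispersion,
    seed = seed + 2
  )
  # genes laid out along each chromosome; links from nearest TSS
  tss <- with_local_seed(seed + 3, {
    purrr::map_dfr(split(acs$regions, acs$regions$chrom), function(reg) {
      n_genes <- min(cfg$genes_per_chrom, nrow(reg))
      span <- range(c(reg$start, reg$end))
      tibble(
        chrom = reg$chrom[1],
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        tss = as.integer(sort(round(runif(n_genes, span[1], span[2]))))
      )
    })
  })
  tss$gene_id <- sprintf("gene%04d", seq_len(nrow(tss)))
  tss <- tss[, c("gene_id", "chrom", "strand", "tss")]
  links <- nearest_tss(acs$regions, tss)
  expr <- simulate_expression(
    tss, links[!is.na(links$gene_id), c("acs_id", "gene_id")],
    acs$truth$acs_log2fc_true,
    seed = seed + 4
  )
  write_jaspar_pfm(
    dplyr::mutate(motifs, matrix = purrr::map(matrix, function(m) round(m * 100))),
    paths$motifs_pfm
  )
  write_fasta(acs$sequences, paths$acs_fasta)
  write_bed(acs$regions, paths$acs_bed)
  readr::write_tsv(sim$counts, paths$counts_tsv)
  readr::write_tsv(sim$samples, paths$samples_tsv)
  readr::write_tsv(tss, paths$tss_tsv)
  readr::write_tsv(expr$genes, paths$genes_tsv)
  readr::write_tsv(expr$roles, paths$roles_tsv)
  write_truth(acs$truth, paths$truth_json)
  invisible(NULL)
}

pipeline_paths <- function(cfg) {
  out <- cfg$out_dir
  p <- list(
    motifs_pfm = cfg$motifs_pfm, acs_fasta = cfg$acs_fasta,
    acs_bed = cfg$acs_bed, counts_tsv = cfg$counts_tsv,
    samples_tsv = cfg$samples_tsv, tss_tsv = cfg$tss_tsv,
    genes_tsv = cfg$genes_tsv
  )
  if (isTRUE(cfg$simulate)) {
    p <- list(
      motifs_pfm = file.path(out, "motifs.pfm"),
      acs_fasta = file.path(out, "acs.fasta"),
      acs_bed = file.path(out, "acs.bed"),
      counts_tsv = file.path(out, "counts.tsv"),
      samples_tsv = file.path(out, "samples.tsv"),
      tss_tsv = file.path(out, "tss.tsv"),
      genes_tsv = file.path(out, "genes.tsv")
    )
  }
  c(p, list(
    roles_tsv = file.path(out, "roles_true.tsv"),
    truth_json = file.path(out, "truth.json"),
    differential_tsv = file.path(out, "differential.tsv"),
    fractions_tsv = file.path(out, "class_fractions.tsv"),
    match_matrix_tsv = file.path(out, "match_matrix.tsv"),
    enrichment_tsv = file.path(out, "enrichment.tsv"),
    activity_tsv = file.path(out, "activity.tsv"),
    cv_tsv = file.path(out, "activity_cv.tsv"),
    links_tsv = file.path(out, "links.tsv"),
    target_tsv = file.path(out, "target_enrichment.tsv"),
    manifest_json = file.path(out, "manifest.json")
  ))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing one TSV per result plus
#' a JSON manifest (package version, seed, applied thresholds, output
#' checksums). Every threshold actually applied is logged to `stderr`.
#' With `resume = TRUE`, stages whose outputs already exist are skipped. A
#' failing stage leaves a `<stage>.failed` marker and raises an error.
#'
#' @param config A `pipeline_config`, a named list, or a YAML file path.
#' @param resume Skip stages whose outputs are already present.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(cfg)
  log_msg <- function(...) message("[chromactivity] ", ...)
  run_stage <- function(name, outputs, fun) {
    marker <- file.path(cfg$out_dir, paste0(name, ".failed"))
    if (resume && all(file.exists(unlist(outputs)))) {
      log_msg("stage ", name, ": outputs present, skipped (resume)")
      return(invisible(NULL))
    }
    ok <- tryCatch(
      {
        fun()
        if (file.exists(marker)) file.remove(marker)
        TRUE
      },
      error = function(e) {
        writeLines(conditionMessage(e), marker)
        abort(paste0("pipeline stage `", name, "` failed: ",
          conditionMessage(e)))
      }
    )
    log_msg("stage ", name, ": done")
    invisible(ok)
  }

  if (isTRUE(cfg$simulate)) {
    run_stage("simulate",
      paths[c("motifs_pfm", "acs_fasta", "acs_bed", "counts_tsv",
        "samples_tsv", "tss_tsv", "genes_tsv", "truth_json")],
      function() stage_simulate(cfg, paths)
    )
  }

  if (!is.null(cfg$fragments_bed)) {
    run_stage("quantify", paths["counts_tsv"], function() {
      fragments <- read_bed(cfg$fragments_bed)
      acs <- read_bed(paths$acs_bed)
      counts <- count_insertions(fragments, acs)
      readr::write_tsv(counts, paths$counts_tsv)
    })
  }

  diff_res <- NULL
  run_stage("diff", paths[c("differential_tsv", "fractions_tsv")], function() {
    log_msg("diff thresholds: p < ", cfg$p, ", FDR < ", cfg$fdr)
    counts <- read_counts(paths$counts_tsv)
    samples <- read_typed_tsv(paths$samples_tsv,
      schema = c(sample = "c", group = "c")
    )
    res <- diff_accessibility(counts, samples,
      p_threshold = cfg$p, fdr_threshold = cfg$fdr
    )
    readr::write_tsv(as_tibble(res), paths$differential_tsv)
    readr::write_tsv(class_fractions(res), paths$fractions_tsv)
  })

  run_stage("scan", paths["match_matrix_tsv"], function() {
    log_msg("scan threshold: match p <= ", cfg$scan_p)
    sequences <- read_fasta(paths$acs_fasta)
    motifs <- read_jaspar_pfm(paths$motifs_pfm)
    mm <- build_match_matrix(sequences, motifs, threshold_p = cfg$scan_p)
    readr::write_tsv(as_tibble(mm), paths$match_matrix_tsv)
  })

  run_stage("enrich", paths["enrichment_tsv"], function() {
    diff_tbl <- readr::read_tsv(paths$differential_tsv,
      col_types = "cdddc", progress = FALSE
    )
    mm <- read_counts(paths$match_matrix_tsv)
    ranked <- if (isTRUE(cfg$rank_all_acs)) {
      diff_tbl
    } else {
      diff_tbl[diff_tbl$class != "Stable", , drop = FALSE]
    }
    mat <- match_matrix_to_matrix(mm)
    sets <- purrr::map(
      setNames(colnames(mat), colnames(mat)),
      function(m) rownames(mat)[mat[, m] > 0]
    )
    res <- gsea_prerank(
      tibble(id = ranked$acs_id, stat = ranked$log2_fc),
      sets,
      n_perm = cfg$gsea_n_perm, min_size = cfg$min_set_size,
      max_size = cfg$max_set_size,
      seed = stage_seed(cfg$seed, "enrich")
    )
    readr::write_tsv(as_tibble(res), paths$enrichment_tsv)
  })

  run_stage("activity", paths[c("activity_tsv", "cv_tsv")], function() {
    log_msg("activity: alpha = ", cfg$alpha, ", lambda rule = ",
      cfg$lambda_rule)
    diff_tbl <- readr::read_tsv(paths$differential_tsv,
      col_types = "cdddc", progress = FALSE
    )
    mm <- read_counts(paths$match_matrix_tsv)
    fit <- suppressWarnings(motif_activity(
      mm, setNames(diff_tbl$log2_fc, diff_tbl$acs_id),
      alpha = cfg$alpha, rule = cfg$lambda_rule,
      min_matches = cfg$min_matches,
      seed = stage_seed(cfg$seed, "activity")
    ))
    out <- dplyr::mutate(tidy(fit),
      lambda = fit$lambda, alpha = fit$alpha
    )
    readr::write_tsv(out, paths$activity_tsv)
    cv_tab <- if (!is.null(fit$cv)) fit$cv$cv_table else {
      tibble(lambda = numeric(), cv_mse = numeric(), cv_se = numeric())
    }
    readr::write_tsv(cv_tab, paths$cv_tsv)
  })

  run_stage("integrate", paths[c("links_tsv", "target_tsv")], function() {
    log_msg("integrate: gene FDR < ", cfg$gene_fdr, ", TSS bound ",
      cfg$tss_bound, " bp, proximal bound ", cfg$proximal_bound, " bp")
    acs <- read_bed(paths$acs_bed)
    tss <- read_tss_table(paths$tss_tsv)
    genes <- read_gene_fc_table(paths$genes_tsv)
    diff_tbl <- readr::read_tsv(paths$differential_tsv,
      col_types = "cdddc", progress = FALSE
    )
    mm <- read_counts(paths$match_matrix_tsv)
    links <- nearest_tss(acs, tss)
    links$location_class <- ifelse(
      is.na(links$signed_distance), NA_character_,
      location_class(links$signed_distance, cfg$tss_bound, cfg$proximal_bound)
    )
    links <- classify_regulatory_role(links, diff_tbl, genes,
      gene_fdr_threshold = cfg$gene_fdr
    )
    readr::write_tsv(links, paths$links_tsv)
    de_genes <- genes$gene_id[!is.na(genes$fdr) & genes$fdr < cfg$gene_fdr]
    target <- motif_target_enrichment(
      mm, links[!is.na(links$gene_id), c("acs_id", "gene_id")],
      de_genes, genes$gene_id
    )
    readr::write_tsv(target, paths$target_tsv)
  })

  outputs <- unlist(paths[purrr::map_lgl(paths, function(p) {
    !is.null(p) && file.exists(p)
  })])
  manifest <- list(
    package = "chromactivity",
    version = as.character(utils::packageVersion("chromactivity")),
    seed = cfg$seed,
    stage_seeds = purrr::map(
      setNames(
        c("simulate", "quantify", "diff", "scan", "enrich", "activity",
          "integrate"),
        c("simulate", "quantify", "diff", "scan", "enrich", "activity",
          "integrate")
      ),
      function(s) stage_seed(cfg$seed, s)
    ),
    thresholds = cfg[c("p", "fdr", "scan_p", "alpha", "lambda_rule",
      "gene_fdr", "tss_bound", "proximal_bound", "gsea_n_perm")],
    checksums = as.list(tools::md5sum(outputs[names(outputs) != "manifest_json"]))
  )
  jsonlite::write_json(manifest, paths$manifest_json,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
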