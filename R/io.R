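# Readers and writers for the plain-text formats the pipeline touches:
# FASTA sequences, BED3/BED4 intervals, JASPAR PFM motif files and
# tab-separated tables with a header row. All coordinates follow the BED
# convention (0-based, half-open) and are never silently rebased.

#' Parse FASTA text into a tibble of sequences
#'
#' @param text A character vector of FASTA lines, or a single string
#'   containing newlines.
#' @return A tibble with columns `id` and `seq` (upper-cased, `N` allowed),
#'   in file order.
#' @examples
#' parse_fasta(c(">acs1", "ACGT", ">acs2", "ttga"))
#' @export
parse_fasta <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(id = character(), seq = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    abort("FASTA format error: sequence data before the first '>' header")
  }
  rec <- cumsum(is_header)
  ids <- sub("^>", "", trimws(lines[is_header]))
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!is_header], rec[!is_header]), paste,
    character(1),
    collapse = ""
  )
  # headers with no sequence lines become empty strings
  all_seqs <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  all_seqs[names(seqs)] <- seqs
  out <- tibble(id = ids, seq = toupper(unname(all_seqs)))
  bad <- grepl("[^ACGTN]", out$seq)
  if (any(bad)) {
    abort(paste0(
      "FASTA format error: non-ACGTN letters in record(s): ",
      paste(head(out$id[bad], 5), collapse = ", ")
    ))
  }
  out
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  parse_fasta(readr::read_lines(path))
}

#' Write sequences to a FASTA file
#'
#' @param sequences A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  check_columns(sequences, c("id", "seq"), "sequences")
  lines <- unlist(purrr::map2(sequences$id, sequences$seq, function(id, s) {
    starts <- seq(1, max(nchar(s), 1), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Parse BED text into a tibble of regions
#'
#' Intervals are kept 0-based, half-open exactly as in the file. A fourth
#' column, when present, supplies the region id; otherwise ids are
#' autogenerated as `"chrom:start-end"`.
#'
#' @param text Character vector of BED lines (or one string with newlines).
#' @return A tibble with columns `chrom`, `start`, `end`, `id`.
#' @export
parse_bed <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      id = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(paste0(
      "BED format error: fewer than 3 tab-separated columns at line ",
      which(n_fields < 3)[1]
    ))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(paste0(
      "BED format error: non-numeric start/end at line ",
      which(is.na(start) | is.na(end))[1]
    ))
  }
  bad <- end <= start | start < 0
  if (any(bad)) {
    abort(paste0(
      "BED format error: end <= start (or negative start) at line ",
      which(bad)[1]
    ))
  }
  id <- ifelse(
    n_fields >= 4, vapply(fields, function(f) f[min(4, length(f))], character(1)),
    paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE), "-",
      format(end, scientific = FALSE, trim = TRUE))
  )
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end), id = id)
}

#' Read a BED file of regions
#' @param path Path to a BED3/BED4 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `id`.
#' @export
read_bed <- function(path) {
  parse_bed(readr::read_lines(path))
}

#' Write regions to a BED file
#' @param regions A data frame with columns `chrom`, `start`, `end` and
#'   optionally `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  check_columns(regions, c("chrom", "start", "end"), "regions")
  cols <- c("chrom", "start", "end")
  if ("id" %in% names(regions)) cols <- c(cols, "id")
  readr::write_tsv(regions[cols], path, col_names = FALSE)
  invisible(path)
}

#' Parse JASPAR PFM text into a motif tibble
#'
#' Accepts the JASPAR 2016 text dialect: a `>ID name` header followed by four
#' rows labelled A, C, G, T whose numbers may be wrapped in square brackets.
#' Row order in the file is irrelevant; the stored matrix rows are always
#' A, C, G, T.
#'
#' @param text Character vector of PFM lines (or one string with newlines).
#' @return A tibble with columns `motif_id`, `name` and a list-column
#'   `matrix` of 4 x width count matrices (rows A, C, G, T).
#' @examples
#' parse_jaspar_pfm(c(">M1 T", "A [4 0]", "C [0 4]", "G [0 0]", "T [0 0]"))
#' @export
parse_jaspar_pfm <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(motif_id = character(), name = character(), matrix = list()))
  }
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0 || headers[1] != 1) {
    abort("JASPAR PFM format error: file must start with a '>' header")
  }
  bounds <- c(headers, length(lines) + 1)
  records <- purrr::map(seq_along(headers), function(i) {
    hdr <- trimws(sub("^>", "", lines[headers[i]]))
    parts <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else parts[1]
    body <- lines[seq(bounds[i] + 1, bounds[i + 1] - 1)]
    if (length(body) != 4) {
      abort(paste0(
        "JASPAR PFM format error: motif ", motif_id,
        " must have exactly 4 base rows, found ", length(body)
      ))
    }
    labels <- toupper(sub("^\\s*([ACGTacgt]).*$", "\\1", body))
    if (!setequal(labels, DNA_ALPHABET)) {
      abort(paste0(
        "JASPAR PFM format error: motif ", motif_id,
        " is missing base row(s): ",
        paste(setdiff(DNA_ALPHABET, labels), collapse = ", ")
      ))
    }
    rows <- purrr::map(body, function(line) {
      nums <- sub("^\\s*[ACGTacgt]\\s*", "", line)
      nums <- gsub("\\[|\\]", " ", nums)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) {
        abort(paste0(
          "JASPAR PFM format error: non-numeric count in motif ", motif_id
        ))
      }
      vals
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1) {
      abort(paste0(
        "JASPAR PFM format error: rows of unequal width in motif ", motif_id
      ))
    }
    mat <- do.call(rbind, rows[order(match(labels, DNA_ALPHABET))])
    rownames(mat) <- DNA_ALPHABET
    if (any(mat < 0)) {
      abort(paste0("JASPAR PFM format error: negative count in motif ", motif_id))
    }
    if (any(colSums(mat) == 0)) {
      abort(paste0(
        "JASPAR PFM format error: all-zero column in motif ", motif_id
      ))
    }
    list(motif_id = motif_id, name = name, matrix = mat)
  })
  tibble(
    motif_id = purrr::map_chr(records, "motif_id"),
    name = purrr::map_chr(records, "name"),
    matrix = purrr::map(records, "matrix")
  )
}

#' Read a JASPAR PFM motif file
#' @param path Path to a JASPAR text PFM file.
#' @return A motif tibble as from [parse_jaspar_pfm()].
#' @export
read_jaspar_pfm <- function(path) {
  parse_jaspar_pfm(readr::read_lines(path))
}

#' Write motifs to a JASPAR PFM file
#' @param motifs A motif tibble with `motif_id`, `name`, `matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  check_columns(motifs, c("motif_id", "name", "matrix"), "motifs")
  lines <- unlist(purrr::pmap(motifs, function(motif_id, name, matrix, ...) {
    c(
      paste0(">", motif_id, " ", name),
      vapply(DNA_ALPHABET, function(b) {
        paste0(b, " [", paste(format(matrix[b, ], trim = TRUE), collapse = " "), "]")
      }, character(1))
    )
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a typed tab-separated table with validation
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Named character vector mapping required column names to
#'   readr-style types: `"c"` (character), `"d"` (double), `"i"` (integer).
#'   Columns absent from the schema are read as-is; columns named in the
#'   schema must be present unless listed in `optional`.
#' @param id_col Optional name of a column whose values must be unique.
#' @param optional Character vector of schema columns allowed to be missing.
#' @return A tibble.
#' @export
read_typed_tsv <- function(path, schema, id_col = NULL, optional = character()) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- setdiff(names(schema), optional)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "table format error: missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  for (col in intersect(names(schema), names(df))) {
    type <- schema[[col]]
    if (type %in% c("d", "i")) {
      vals <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(vals) && !all(is.na(df[[col]]) == is.na(vals))) {
        abort(paste0(
          "table format error: non-numeric value in numeric column `", col, "`"
        ))
      }
      df[[col]] <- if (type == "i") as.integer(round(vals)) else vals
    }
  }
  if (!is.null(id_col) && id_col %in% names(df)) {
    dup <- df[[id_col]][duplicated(df[[id_col]])]
    if (length(dup) > 0) {
      abort(paste0(
        "table format error: duplicated id(s) in `", id_col, "`: ",
        paste(unique(head(dup, 5)), collapse = ", ")
      ))
    }
  }
  df
}

#' Read a counts table (rows = ACS, columns = samples)
#'
#' @param path TSV with first column `acs_id` followed by one numeric column
#'   per sample.
#' @return A tibble with `acs_id` and numeric sample columns.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      acs_id = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE
  )
  check_columns(df, "acs_id", "counts")
  if (anyDuplicated(df$acs_id)) {
    abort("table format error: duplicated acs_id in counts table")
  }
  num <- df[setdiff(names(df), "acs_id")]
  if (any(vapply(num, function(x) any(!is.finite(x) | x < 0), logical(1)))) {
    abort("counts table must be finite and non-negative")
  }
  df
}

#' Read a TSS annotation table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `strand` (+/-), `tss`
#'   (0-based coordinate of the transcription start site).
#' @return A typed tibble, one row per gene.
#' @export
read_tss_table <- function(path) {
  df <- read_typed_tsv(
    path,
    schema = c(gene_id = "c", chrom = "c", strand = "c", tss = "i"),
    id_col = "gene_id"
  )
  bad <- !df$strand %in% c("+", "-")
  if (any(bad)) {
    abort("TSS table format error: strand must be '+' or '-'")
  }
  df
}

#' Read a gene log2 fold-change table
#'
#' @param path TSV with columns `gene_id`, `log2fc` and optionally `fdr`.
#' @return A typed tibble, one row per gene.
#' @export
read_gene_fc_table <- function(path) {
  read_typed_tsv(
    path,
    schema = c(gene_id = "c", log2fc = "d", fdr = "d"),
    id_col = "gene_id", optional = "fdr"
  )
}
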