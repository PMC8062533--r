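# Tn5 insertion counting. Each sequenced fragment implies two transposase
# insertion events, one at each end; a fragment therefore contributes its
# 5' coordinate (`start`) and its final covered base (`end - 1`) as
# insertion points, and can add 0, 1 or 2 counts to any given site.
# Overlapping sites each receive an insertion falling inside them.

insertion_points <- function(fragments, shift = FALSE) {
  start <- fragments$start
  end <- fragments$end
  if (shift) {
    # +4/-5 Tn5 duplication-site shift for raw (unshifted) intervals
    start <- start + 4L
    end <- end - 5L
    keep <- end > start
    start <- start[keep]
    end <- end[keep]
    chrom <- fragments$chrom[keep]
  } else {
    chrom <- fragments$chrom
  }
  tibble(
    chrom = rep(chrom, 2L),
    pos = c(start, end - 1L)
  )
}

#' Count Tn5 insertions per accessible site per sample
#'
#' An insertion point `p` is counted for site `[start, end)` iff
#' `start <= p < end`. Fragments are assumed Tn5-shifted already; set
#' `shift = TRUE` to apply the +4/-5 shift to raw intervals.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`), 0-based
#'   half-open, with an optional `sample` column; without one, a single
#'   sample named `"sample1"` is assumed.
#' @param acs Region tibble (`chrom`, `start`, `end`, `id`).
#' @param shift Apply the +4/-5 Tn5 shift before counting.
#' @return A count tibble: `acs_id` plus one non-negative integer column per
#'   sample, rows in `acs` order. Fragments on chromosomes absent from
#'   `acs` are skipped with a warning stating how many.
#' @export
count_insertions <- function(fragments, acs, shift = FALSE) {
  check_columns(fragments, c("chrom", "start", "end"), "fragments")
  check_columns(acs, c("chrom", "start", "end"), "acs")
  if (!"id" %in% names(acs)) {
    acs$id <- paste0(acs$chrom, ":", acs$start, "-", acs$end)
  }
  if (!"sample" %in% names(fragments)) {
    fragments$sample <- "sample1"
  }
  known_chroms <- unique(acs$chrom)
  unknown <- !fragments$chrom %in% known_chroms
  if (any(unknown)) {
    warn(paste0(
      "skipping ", sum(unknown),
      " fragment(s) on chromosome(s) absent from the ACS set: ",
      paste(unique(fragments$chrom[unknown]), collapse = ", ")
    ))
    fragments <- fragments[!unknown, , drop = FALSE]
  }
  sample_ids <- unique(fragments$sample)
  if (length(sample_ids) == 0) sample_ids <- "sample1"
  out <- matrix(0L, nrow(acs), length(sample_ids),
    dimnames = list(acs$id, sample_ids)
  )
  for (s in sample_ids) {
    pts <- insertion_points(fragments[fragments$sample == s, , drop = FALSE],
      shift = shift
    )
    for (chr in intersect(known_chroms, unique(pts$chrom))) {
      p <- sort(pts$pos[pts$chrom == chr])
      on_chr <- which(acs$chrom == chr)
      # points in [start, end): rank of end-1 minus rank of start-1
      out[on_chr, s] <- findInterval(acs$end[on_chr] - 0.5, p) -
        findInterval(acs$start[on_chr] - 0.5, p)
    }
  }
  dplyr::bind_cols(tibble(acs_id = acs$id), as_tibble(out))
}

#' Fragment-size histogram for ATAC-seq quality control
#'
#' Sizes are `end - start`; bins are left-closed `[b, b + bin_width)`. A
#' typical ATAC-seq library shows a sub-nucleosomal mode (< 100 bp) and
#' nucleosome-spaced modes near 200 and 400 bp.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`).
#' @param bin_width Bin width in bp (>= 1).
#' @return A tibble `bin_start`, `bin_end`, `count` covering only occupied
#'   and intervening bins; total count equals the number of fragments.
#' @export
fragment_size_histogram <- function(fragments, bin_width = 10) {
  check_columns(fragments, c("start", "end"), "fragments")
  check_number(bin_width, "bin_width", lower = 1, integer = TRUE)
  sizes <- fragments$end - fragments$start
  if (length(sizes) == 0) {
    return(tibble(
      bin_start = integer(), bin_end = integer(),
      count = integer()
    ))
  }
  bin <- floor(sizes / bin_width) * bin_width
  grid <- seq(min(bin), max(bin), by = bin_width)
  counts <- tabulate(match(bin, grid), nbins = length(grid))
  tibble(
    bin_start = as.integer(grid),
    bin_end = as.integer(grid + bin_width),
    count = as.integer(counts)
  )
}
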