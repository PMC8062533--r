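#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom rpois rnbinom rlnorm quantile
#'   optimize p.adjust phyper dbinom cor.test sd var median setNames
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

# Run `code` under a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Fan a single pipeline seed out to per-stage seeds deterministically.
# Kept below 2^31 so the result is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stages <- c(
    simulate = 1L, quantify = 2L, diff = 3L, scan = 4L,
    enrich = 5L, activity = 6L, integrate = 7L
  )
  if (!stage %in% names(stages)) {
    abort(paste0("unknown pipeline stage: ", stage))
  }
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * stages[[stage]]) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(paste0("`", name, "` must not be NULL"))
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  if (integer && x != round(x)) {
    abort(paste0("`", name, "` must be an integer"))
  }
  if (x < lower || x > upper) {
    abort(paste0(
      "`", name, "` must be in [", lower, ", ", upper, "], got ", x
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "`", name, "` is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Reverse complement of an ACGTN string (vectorised over characters).
reverse_complement <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(seq, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    paste(rev(unname(comp[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Convert an ACGTN string to integer codes (A=1 ... T=4, N=NA).
encode_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, DNA_ALPHABET)
  bad <- is.na(codes) & chars != "N"
  if (any(bad)) {
    abort(paste0(
      "sequence contains letters outside ACGTN: ",
      paste(unique(chars[bad]), collapse = ", ")
    ))
  }
  codes
}

geometric_mean <- function(x) exp(mean(log(x)))
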