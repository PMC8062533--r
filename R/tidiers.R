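# broom-style accessors for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a motif activity fit
#'
#' @param x A `motif_activity` object.
#' @param ... Unused.
#' @return A tibble `motif_id`, `activity`, `n_matches`, `selected`,
#'   sorted by decreasing absolute activity.
#' @export
tidy.motif_activity <- function(x, ...) {
  x$activities
}

#' One-row summary of a motif activity fit
#'
#' @param x A `motif_activity` object.
#' @param ... Unused.
#' @return A tibble with `n_acs`, `n_motifs`, `n_selected`, `alpha`,
#'   `lambda`, `rule`, `cv_mse`.
#' @export
glance.motif_activity <- function(x, ...) {
  cv_mse <- if (!is.null(x$cv)) {
    x$cv$cvm[which.min(abs(x$cv$lambda - x$lambda))]
  } else {
    NA_real_
  }
  tibble(
    n_acs = x$n_acs, n_motifs = x$n_motifs,
    n_selected = sum(x$activities$selected),
    alpha = x$alpha, lambda = x$lambda, rule = x$rule, cv_mse = cv_mse
  )
}

#' One-row summary of a differential accessibility result
#'
#' @param x A `diff_access` tibble from [diff_accessibility()].
#' @param ... Unused.
#' @return A tibble with the dispersion estimate, thresholds and class
#'   fractions.
#' @export
glance.diff_access <- function(x, ...) {
  fr <- class_fractions(x)
  tibble(
    n_acs = nrow(x),
    dispersion = attr(x, "dispersion"),
    p_threshold = attr(x, "p_threshold"),
    fdr_threshold = attr(x, "fdr_threshold"),
    frac_up = fr$fraction[fr$class == "Up"],
    frac_down = fr$fraction[fr$class == "Down"],
    frac_stable = fr$fraction[fr$class == "Stable"]
  )
}

#' Normalisation state of a differential accessibility result
#'
#' @param x A `diff_access` tibble.
#' @return A tibble `sample`, `lib_size`, `tmm_factor`.
#' @export
normalization_state <- function(x) {
  stopifnot(inherits(x, "diff_access"))
  lib <- attr(x, "lib_sizes")
  tibble(
    sample = names(lib), lib_size = unname(lib),
    tmm_factor = unname(attr(x, "tmm_factors")[names(lib)])
  )
}
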