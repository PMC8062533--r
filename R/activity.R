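# Motif activity by penalised regression: accessibility log2 fold-changes
# of all sites are regressed on the site x motif match matrix with an
# elastic-net penalty, solved by cyclic coordinate descent with
# soft-thresholding. A positive activity means the motif's presence is
# associated with sites opening in adult; a negative activity with sites
# closing (the repressor-like pattern).

soft_threshold <- function(z, gamma) {
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Elastic-net linear regression by cyclic coordinate descent
#'
#' Minimises `(1/2n) ||y - b0 - X b||^2 +
#' lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)`.
#' Predictors are standardised internally (population SD) and coefficients
#' returned on the original scale; constant columns are dropped with a
#' warning and get coefficient zero.
#'
#' @param x Numeric matrix (n x p).
#' @param y Numeric response of length n.
#' @param lambda Penalty strength (>= 0).
#' @param alpha Elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param standardize Standardise columns before fitting.
#' @param tol Convergence tolerance on the maximum (standardised)
#'   coefficient change per sweep.
#' @param max_iter Maximum number of coordinate sweeps.
#' @param beta_init Optional warm-start coefficients on the standardised
#'   scale (used internally along the CV path).
#' @return A list with `beta` (named, original scale), `intercept`,
#'   `iterations`, `converged`, and `beta_std`/`scale_info` for warm starts.
#' @export
elastic_net_fit <- function(x, y, lambda, alpha = 0.5, standardize = TRUE,
                            tol = 1e-7, max_iter = 1e5, beta_init = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite")
  }
  n <- nrow(x)
  if (n < 2 || length(y) != n) {
    abort("need at least two observations and matching `y`")
  }
  check_number(lambda, "lambda", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  p <- ncol(x)
  cn <- colnames(x) %||% paste0("x", seq_len(p))
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  xs <- if (standardize) sqrt(colMeans(xc^2)) else rep(1, p)
  keep <- xs > 1e-12
  if (!all(keep)) {
    warn(paste0(
      "dropping ", sum(!keep), " constant column(s): ",
      paste(head(cn[!keep], 5), collapse = ", ")
    ))
  }
  xz <- sweep(xc[, keep, drop = FALSE], 2, xs[keep], `/`)
  ym <- mean(y)
  yc <- y - ym
  pk <- ncol(xz)
  beta <- if (!is.null(beta_init)) beta_init else numeric(pk)
  r <- yc - drop(xz %*% beta)
  denom_j <- colMeans(xz^2) + lambda * (1 - alpha)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    max_delta <- 0
    for (j in seq_len(pk)) {
      bj <- beta[j]
      z <- sum(xz[, j] * r) / n + colMeans_xz2_j(denom_j, j, lambda, alpha) * bj
      bj_new <- soft_threshold(z, lambda * alpha) / denom_j[j]
      delta <- bj_new - bj
      if (delta != 0) {
        r <- r - xz[, j] * delta
        beta[j] <- bj_new
        max_delta <- max(max_delta, abs(delta))
      }
    }
    if (max_delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0(
      "coordinate descent did not converge in ", it, " sweeps"
    ))
  }
  # snap numerically-zero coefficients so the selected set is meaningful
  beta[abs(beta) < 1e-10] <- 0
  beta_full <- numeric(p)
  beta_full[keep] <- beta / xs[keep]
  intercept <- ym - sum(beta_full * xm)
  list(
    beta = setNames(beta_full, cn), intercept = intercept,
    iterations = it, converged = converged,
    beta_std = beta, keep = keep
  )
}

# Partial-residual coefficient for column j: with unit-variance columns the
# quadratic coefficient is colMeans(xz^2)[j]; the ridge part of denom_j is
# removed so the update sees x_j' x_j / n only.
colMeans_xz2_j <- function(denom_j, j, lambda, alpha) {
  denom_j[j] - lambda * (1 - alpha)
}

# Smallest lambda with an all-zero solution (alpha > 0), on the
# standardised scale.
lambda_max_value <- function(xz, yc, alpha) {
  n <- nrow(xz)
  max(abs(crossprod(xz, yc)) / n) / max(alpha, 1e-3)
}

#' Cross-validated elastic-net penalty path
#'
#' Fits a geometric grid of `n_lambda` penalties from `lambda_max` (the
#' smallest all-zero penalty) down to `lambda_max * lambda_min_ratio`, with
#' warm starts, and estimates out-of-fold MSE by seeded k-fold CV.
#'
#' @inheritParams elastic_net_fit
#' @param n_folds Number of CV folds.
#' @param n_lambda Grid size.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @param seed Integer seed controlling fold assignment.
#' @return A list with `lambda` (grid), `cvm`, `cvsd`, `lambda_min`,
#'   `lambda_1se`, `n_folds` and `cv_table` (tibble).
#' @export
cv_lambda_path <- function(x, y, alpha = 0.5, n_folds = 10, n_lambda = 100,
                           lambda_min_ratio = 1e-4, standardize = TRUE,
                           tol = 1e-7, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  check_number(n_folds, "n_folds", lower = 2, integer = TRUE)
  if (n < n_folds) abort("need at least as many observations as folds")
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  xs <- if (standardize) sqrt(colMeans(xc^2)) else rep(1, ncol(x))
  keep <- xs > 1e-12
  xz <- sweep(xc[, keep, drop = FALSE], 2, xs[keep], `/`)
  yc <- y - mean(y)
  lmax <- lambda_max_value(xz, yc, alpha)
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
    length.out = n_lambda
  ))
  folds <- with_local_seed(seed, {
    sample(rep_len(seq_len(n_folds), n))
  })
  path_fit <- function(xmat, yvec) {
    beta <- numeric(sum(keep))
    purrr::map(lambda, function(l) {
      # constant-column warnings inside folds are expected for sparse
      # binary predictors and would only repeat per lambda
      fit <- suppressWarnings(elastic_net_fit(xmat, yvec,
        lambda = l, alpha = alpha,
        standardize = standardize, tol = tol, beta_init = beta
      ))
      beta <<- fit$beta_std
      fit
    })
  }
  fold_errors <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    fits <- path_fit(x[!test, , drop = FALSE], y[!test])
    for (l in seq_along(lambda)) {
      pred <- fits[[l]]$intercept +
        drop(x[test, , drop = FALSE] %*% fits[[l]]$beta)
      fold_errors[f, l] <- mean((y[test] - pred)^2)
    }
  }
  cvm <- colMeans(fold_errors)
  cvsd <- apply(fold_errors, 2, sd) / sqrt(n_folds)
  i_min <- which.min(cvm)
  ok_1se <- which(cvm <= cvm[i_min] + cvsd[i_min])
  i_1se <- min(ok_1se) # largest lambda within one SE
  list(
    lambda = lambda, cvm = cvm, cvsd = cvsd,
    lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
    n_folds = n_folds,
    cv_table = tibble(lambda = lambda, cv_mse = cvm, cv_se = cvsd)
  )
}

#' Infer per-motif activity from the match matrix and site fold-changes
#'
#' Elastic-net regression of per-site accessibility log2 fold-change on
#' motif presence, with the penalty chosen by k-fold cross-validation.
#' Motifs matching fewer sites than `min_matches` are dropped with a
#' warning. Results are sorted by decreasing absolute activity.
#'
#' @param match_matrix A match-matrix tibble (`acs_id` + one column per
#'   motif) as from [build_match_matrix()].
#' @param log2fc Per-site log2 fold-change: a named vector or a tibble with
#'   `acs_id` and `log2_fc` columns (e.g. a [diff_accessibility()] result).
#' @param alpha Elastic-net mixing parameter.
#' @param rule Penalty choice: `"min"` (CV-minimising) or `"1se"`.
#' @param min_matches Minimum number of matched sites per motif.
#' @param n_folds,n_lambda CV settings.
#' @param seed Integer seed for fold assignment.
#' @return A `motif_activity` object; [tidy()] gives the per-motif activity
#'   table, [glance()] the fit summary.
#' @export
motif_activity <- function(match_matrix, log2fc, alpha = 0.5,
                           rule = c("min", "1se"), min_matches = 10,
                           n_folds = 10, n_lambda = 100, seed = NULL) {
  rule <- match.arg(rule)
  x <- match_matrix_to_matrix(match_matrix)
  if (is.data.frame(log2fc)) {
    check_columns(log2fc, c("acs_id", "log2_fc"), "log2fc")
    log2fc <- setNames(log2fc$log2_fc, log2fc$acs_id)
  }
  if (is.null(names(log2fc))) {
    if (length(log2fc) != nrow(x)) {
      abort("unnamed `log2fc` must match the match-matrix rows")
    }
    names(log2fc) <- rownames(x)
  }
  missing <- setdiff(rownames(x), names(log2fc))
  extra <- setdiff(names(log2fc), rownames(x))
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "ACS index mismatch between match matrix and log2fc; e.g. ",
      paste(head(c(missing, extra), 5), collapse = ", ")
    ))
  }
  y <- unname(log2fc[rownames(x)])
  n_match <- colSums(x > 0)
  drop <- n_match < min_matches
  if (any(drop)) {
    warn(paste0(
      "dropping ", sum(drop), " motif(s) matching fewer than ", min_matches,
      " sites: ", paste(head(colnames(x)[drop], 5), collapse = ", ")
    ))
    x <- x[, !drop, drop = FALSE]
  }
  if (ncol(x) == 0) abort("no motif passes `min_matches`")
  if (all(y == 0)) {
    # degenerate response: every activity is exactly zero
    cv <- NULL
    lambda_chosen <- 0
    beta <- setNames(numeric(ncol(x)), colnames(x))
    intercept <- 0
  } else {
    cv <- cv_lambda_path(x, y,
      alpha = alpha, n_folds = n_folds,
      n_lambda = n_lambda, seed = seed
    )
    lambda_chosen <- if (rule == "min") cv$lambda_min else cv$lambda_1se
    fit <- elastic_net_fit(x, y, lambda = lambda_chosen, alpha = alpha)
    beta <- fit$beta
    intercept <- fit$intercept
  }
  activities <- tibble(
    motif_id = colnames(x),
    activity = unname(beta),
    n_matches = unname(n_match[colnames(x)]),
    selected = unname(beta != 0)
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$activity)))
  structure(
    list(
      activities = activities, lambda = lambda_chosen, alpha = alpha,
      rule = rule, intercept = intercept, cv = cv,
      n_acs = nrow(x), n_motifs = ncol(x)
    ),
    class = "motif_activity"
  )
}

#' @export
print.motif_activity <- function(x, ...) {
  cat(
    "Motif activity fit:", x$n_motifs, "motifs over", x$n_acs, "sites\n",
    "alpha =", x$alpha, ", lambda (", x$rule, ") =",
    format(x$lambda, digits = 4), "\n",
    sum(x$activities$selected), "motifs selected\n"
  )
  print(head(x$activities, 10))
  invisible(x)
}
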