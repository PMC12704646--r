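# Summary-data Mendelian randomization estimators, implemented from scratch.
#
# All estimators consume a harmonized instrument table (one row per variant;
# columns beta_exp, se_exp, beta_out, se_out, see harmonize()) and return an
# `mr_estimate` object. Per-variant Wald ratios are weighted by
# w_j = beta_exp_j^2 / se_out_j^2, the first-order (fixed-effects) weights
# that ignore exposure-side uncertainty; the fixed-effects IVW estimate is
# then exactly weighted least squares of outcome effects on exposure effects
# through the origin.

new_mr_estimate <- function(beta, se, pvalue, method, n_instruments,
                            diagnostics = list()) {
  structure(
    list(beta = beta, se = se, pvalue = pvalue, method = method,
         n_instruments = n_instruments, diagnostics = diagnostics),
    class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g, se = %.4g, p = %.3g (%d instrument%s)\n",
              x$method, x$beta, x$se, x$pvalue, x$n_instruments,
              if (x$n_instruments == 1) "" else "s"))
  if (!is.null(x$diagnostics$q)) {
    cat(sprintf("  Cochran Q = %.3g on %d df (p = %.3g)\n",
                x$diagnostics$q, x$diagnostics$q_df, x$diagnostics$q_p))
  }
  if (!is.null(x$diagnostics$global_p)) {
    cat(sprintf("  global test p = %.3g; outliers flagged: %s\n",
                x$diagnostics$global_p,
                if (length(x$diagnostics$outlier_indices) == 0) "none" else
                  paste(x$diagnostics$outlier_indices, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `n_instruments`.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(method = x$method, estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$pvalue,
         n_instruments = x$n_instruments)
}

#' Diagnostics of an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble of method-specific diagnostics (heterogeneity Q
#'   for IVW; global-test and distortion p-values plus outlier count for
#'   MR-PRESSO).
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    method = x$method,
    n_instruments = x$n_instruments,
    q = d$q %||% NA_real_,
    q_df = d$q_df %||% NA_integer_,
    q_p = d$q_p %||% NA_real_,
    global_rss = d$global_rss %||% NA_real_,
    global_p = d$global_p %||% NA_real_,
    n_outliers = if (is.null(d$outlier_indices)) NA_integer_ else
      length(d$outlier_indices),
    distortion = d$distortion %||% NA_real_,
    distortion_p = d$distortion_p %||% NA_real_
  )
}

check_pairs <- function(pairs, min_n, method) {
  req <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(req, names(pairs))
  if (length(missing) > 0) {
    abort(paste0("instrument table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "trialmr_validation_error")
  }
  if (nrow(pairs) < min_n) {
    abort(paste0(method, " requires at least ", min_n,
                 " instruments, got ", nrow(pairs)),
          class = "trialmr_insufficient_instruments")
  }
  if (any(pairs$se_out <= 0) || any(pairs$se_exp < 0, na.rm = TRUE)) {
    abort("standard errors must be positive",
          class = "trialmr_validation_error")
  }
  invisible(pairs)
}

wald_z_p <- function(beta, se) 2 * pnorm(-abs(beta / se))

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`, with the first-order delta-method standard
#' error `se_out / |beta_exp|` (exposure-side uncertainty ignored, matching
#' the fixed-effects IVW weights). Set `second_order = TRUE` for the
#' second-order delta-method correction that propagates `se_exp`.
#'
#' @param pairs One-row harmonized instrument table.
#' @param second_order Use the second-order delta-method standard error.
#' @return An `mr_estimate` with `method = "wald"`.
#' @export
mr_wald_ratio <- function(pairs, second_order = FALSE) {
  check_pairs(pairs, 1, "wald ratio")
  pairs <- pairs[1, , drop = FALSE]
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out
  if (bx == 0) {
    abort("Wald ratio undefined: exposure beta is zero",
          class = "trialmr_undefined_ratio")
  }
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    sy / abs(bx)
  }
  new_mr_estimate(beta, se, wald_z_p(beta, se), "wald", 1L)
}

#' Fixed-effects inverse-variance weighted estimate
#'
#' The precision-weighted combination of per-variant Wald ratios,
#' `beta = sum(bx * by / sy^2) / sum(bx^2 / sy^2)` with
#' `se = sum(bx^2 / sy^2)^(-1/2)`: exactly the weighted-least-squares fit of
#' outcome effects on exposure effects through the origin with weights
#' `1/sy^2`. Reduces to the Wald ratio for a single instrument. Cochran's Q
#' heterogeneity statistic is reported in the diagnostics.
#'
#' @param pairs Harmonized instrument table (>= 1 row).
#' @return An `mr_estimate` with `method = "ivw_fixed"`.
#' @export
mr_ivw <- function(pairs) {
  check_pairs(pairs, 1, "fixed-effects IVW")
  bx <- pairs$beta_exp; by <- pairs$beta_out; sy <- pairs$se_out
  w <- 1 / sy^2
  denom <- sum(w * bx^2)
  if (denom == 0) {
    abort("IVW undefined: all exposure betas are zero",
          class = "trialmr_undefined_ratio")
  }
  # single instrument: the exact Wald ratio (avoids last-ulp differences
  # between (w*bx*by)/(w*bx^2) and by/bx)
  beta <- if (nrow(pairs) == 1) by / bx else sum(w * bx * by) / denom
  se <- sqrt(1 / denom)
  q <- sum(w * (by - beta * bx)^2)
  q_df <- nrow(pairs) - 1L
  diagnostics <- list(q = q, q_df = q_df,
                      q_p = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE)
                            else NA_real_)
  new_mr_estimate(beta, se, wald_z_p(beta, se), "ivw_fixed",
                  nrow(pairs), diagnostics)
}

# weighted median of ratios r with weights w (normalized); cumulative
# standardized weight crosses 0.5 with linear interpolation between ratios
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  k <- max(which(s <= 0.5))
  if (s[k] == 0.5) return(r[k])
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

ratio_weights <- function(pairs) {
  list(r = pairs$beta_out / pairs$beta_exp,
       w = pairs$beta_exp^2 / pairs$se_out^2)
}

bootstrap_se <- function(pairs, reps, seed, point_fun) {
  if (reps <= 0) return(NA_real_)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(pairs)
  est <- vapply(seq_len(reps), function(b) {
    bx <- rnorm(n, pairs$beta_exp, pairs$se_exp)
    by <- rnorm(n, pairs$beta_out, pairs$se_out)
    point_fun(bx, by, pairs$se_out)
  }, numeric(1))
  sd(est)
}

#' Weighted median estimate
#'
#' Consistent when instruments contributing more than half of the weight are
#' valid. The point estimate is the weighted median of per-variant Wald
#' ratios with weights `beta_exp^2 / se_out^2`; the standard error comes
#' from a parametric bootstrap that resamples each variant's exposure and
#' outcome effects from their normal sampling distributions.
#'
#' @param pairs Harmonized instrument table (>= 3 rows).
#' @param bootstrap_reps Bootstrap replicates for the standard error
#'   (default 1000; 0 skips the bootstrap and returns `se = NA`).
#' @param seed Optional seed for the bootstrap.
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(pairs, bootstrap_reps = 1000, seed = NULL) {
  check_pairs(pairs, 3, "weighted median")
  rw <- ratio_weights(pairs)
  beta <- weighted_median_point(rw$r, rw$w)
  se <- bootstrap_se(pairs, bootstrap_reps, seed, function(bx, by, sy) {
    weighted_median_point(by / bx, bx^2 / sy^2)
  })
  p <- if (is.na(se)) NA_real_ else wald_z_p(beta, se)
  new_mr_estimate(beta, se, p, "weighted_median", nrow(pairs),
                  list(seed = seed, bootstrap_reps = bootstrap_reps))
}

# argmax of the weighted normal-kernel density over ratio estimates;
# MAD-based rule-of-thumb bandwidth
weighted_mode_point <- function(r, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  h <- bandwidth_factor * 0.9 * mad(r) * length(r)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    h <- bandwidth_factor * 0.9 * sd(r) * length(r)^(-1 / 5)
  }
  if (!is.finite(h) || h <= 0) return(r[which.max(w)])
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - r) / h)) / h, numeric(1))
  }
  fx <- dens(grid)
  i <- which.max(fx)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(dens, c(lo, hi), maximum = TRUE)
  opt$maximum
}

#' Weighted mode estimate
#'
#' Consistent when the largest cluster of instruments is valid
#' (plurality-valid assumption). The point estimate is the maximizer of a
#' weighted normal-kernel density over per-variant Wald ratios; the
#' bandwidth is `bandwidth_factor` times a median-absolute-deviation
#' rule-of-thumb (`0.9 * mad(r) * n^(-1/5)`). Standard error by parametric
#' bootstrap as in [mr_weighted_median()].
#'
#' @param pairs Harmonized instrument table (>= 3 rows).
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth
#'   (default 1).
#' @param bootstrap_reps,seed See [mr_weighted_median()].
#' @return An `mr_estimate` with `method = "weighted_mode"`.
#' @export
mr_weighted_mode <- function(pairs, bandwidth_factor = 1,
                             bootstrap_reps = 1000, seed = NULL) {
  check_pairs(pairs, 3, "weighted mode")
  rw <- ratio_weights(pairs)
  beta <- weighted_mode_point(rw$r, rw$w, bandwidth_factor)
  se <- bootstrap_se(pairs, bootstrap_reps, seed, function(bx, by, sy) {
    weighted_mode_point(by / bx, bx^2 / sy^2, bandwidth_factor)
  })
  p <- if (is.na(se)) NA_real_ else wald_z_p(beta, se)
  new_mr_estimate(beta, se, p, "weighted_mode", nrow(pairs),
                  list(seed = seed, bootstrap_reps = bootstrap_reps,
                       bandwidth_factor = bandwidth_factor))
}

#' Run every estimator an instrument count permits
#'
#' Primary estimator is fixed-effects IVW (the Wald ratio when only one
#' instrument is available); weighted median and mode require at least 3
#' instruments and MR-PRESSO at least 4. Estimators whose requirements are
#' not met are recorded as absent, never treated as failures.
#'
#' @param pairs Harmonized instrument table.
#' @param bootstrap_reps,seed Passed to the bootstrap-based estimators.
#' @param presso_sims Simulations for the MR-PRESSO null distribution.
#' @return A list of `mr_estimate` objects keyed by method name.
#' @export
mr_all_estimators <- function(pairs, bootstrap_reps = 1000,
                              presso_sims = 1000, seed = NULL) {
  n <- nrow(pairs)
  out <- list()
  out$primary <- if (n == 1) mr_wald_ratio(pairs) else mr_ivw(pairs)
  if (n >= 3) {
    out$weighted_median <- mr_weighted_median(pairs, bootstrap_reps, seed)
    out$weighted_mode <- mr_weighted_mode(pairs, 1, bootstrap_reps, seed)
  }
  if (n >= 4) {
    out$mr_presso <- mr_presso(pairs, n_simulations = presso_sims,
                               seed = seed)
  }
  out
}
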