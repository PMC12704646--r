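# Wald ratio, IVW, weighted median and weighted mode.

test_that("Wald ratio matches hand arithmetic and both delta orders", {
  pairs <- make_pairs(beta_exp = 0.4, beta_out = 0.1,
                      se_exp = 0.05, se_out = 0.02)
  est <- mr_wald_ratio(pairs)
  expect_equal(est$beta, 0.25)
  expect_equal(est$se, 0.02 / 0.4)
  expect_equal(est$pvalue, 2 * pnorm(-abs(est$beta / est$se)))
  est2 <- mr_wald_ratio(pairs, second_order = TRUE)
  expect_equal(est2$se, sqrt(0.02^2 / 0.4^2 + 0.1^2 * 0.05^2 / 0.4^4))
  expect_gt(est2$se, est$se)
  expect_error(mr_wald_ratio(make_pairs(0, 0.1)),
               class = "trialmr_undefined_ratio")
})

test_that("IVW equals the WLS-through-origin oracle on random sets", {
  withr::local_seed(101)
  for (rep in 1:100) {
    n <- sample(2:15, 1)
    pairs <- make_pairs(beta_exp = runif(n, -0.5, 0.5),
                        beta_out = rnorm(n, 0, 0.1),
                        se_out = runif(n, 0.01, 0.1))
    est <- mr_ivw(pairs)
    fit <- lm(beta_out ~ 0 + beta_exp, data = pairs,
              weights = 1 / pairs$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
    # fixed-effects se uses the analytic weights, not the residual scale
    expect_equal(est$se, sqrt(1 / sum(pairs$beta_exp^2 / pairs$se_out^2)),
                 tolerance = 1e-12)
  }
})

test_that("single-instrument IVW reduces exactly to the Wald ratio", {
  pairs <- make_pairs(0.3, 0.12, se_out = 0.04)
  ivw <- mr_ivw(pairs)
  wald <- mr_wald_ratio(pairs)
  expect_identical(ivw$beta, wald$beta)
  expect_equal(ivw$se, wald$se)
  expect_equal(ivw$pvalue, wald$pvalue)
})

test_that("duplicating every instrument shrinks the IVW se by sqrt(2)", {
  pairs <- make_pairs(c(0.3, 0.4), c(0.03, 0.05))
  doubled <- dplyr::bind_rows(pairs, pairs)
  expect_equal(mr_ivw(doubled)$beta, mr_ivw(pairs)$beta)
  expect_equal(mr_ivw(doubled)$se, mr_ivw(pairs)$se / sqrt(2))
})

test_that("Cochran's Q is zero for perfectly collinear instruments", {
  pairs <- make_pairs(c(0.2, 0.3, 0.4), c(0.1, 0.15, 0.2))
  est <- mr_ivw(pairs)
  expect_equal(est$beta, 0.5)
  expect_equal(est$diagnostics$q, 0)
  expect_equal(est$diagnostics$q_df, 2L)
})

test_that("weighted median interpolates the cumulative-weight crossing", {
  # equal weights, three ratios: the middle ratio exactly
  pairs <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.5))
  est <- mr_weighted_median(pairs, bootstrap_reps = 0)
  expect_equal(est$beta, 0.2)
  expect_true(is.na(est$se))
  # a dominant-weight instrument pulls the median to itself:
  # weights are beta_exp^2/se_out^2, so a large beta_exp dominates
  pairs2 <- make_pairs(c(10, 1, 1), c(3, 0.1, 0.5))
  expect_equal(mr_weighted_median(pairs2, bootstrap_reps = 0)$beta, 0.3)
  # the estimate always lies within the range of the ratios
  withr::local_seed(5)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    p <- make_pairs(runif(n, 0.1, 0.5), rnorm(n, 0, 0.2),
                    se_out = runif(n, 0.01, 0.1))
    r <- p$beta_out / p$beta_exp
    b <- mr_weighted_median(p, bootstrap_reps = 0)$beta
    expect_gte(b, min(r)); expect_lte(b, max(r))
  }
})

test_that("weighted median resists up to half the weight being invalid", {
  # 3 of 7 equally weighted instruments grossly wrong: median unaffected
  pairs <- make_pairs(rep(0.3, 7),
                      c(rep(0.3 * 0.2, 4), rep(0.9, 3)),
                      se_out = 0.01)
  expect_equal(mr_weighted_median(pairs, bootstrap_reps = 0)$beta, 0.2)
  # IVW on the same set is dragged far from 0.2
  expect_gt(mr_ivw(pairs)$beta, 0.5)
})

test_that("bootstrap se is deterministic under a fixed seed and positive", {
  withr::local_seed(12)
  pairs <- random_pairs(6, slope = 0.2)
  a <- mr_weighted_median(pairs, bootstrap_reps = 200, seed = 99)
  b <- mr_weighted_median(pairs, bootstrap_reps = 200, seed = 99)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
  expect_equal(a$pvalue, 2 * pnorm(-abs(a$beta / a$se)))
})

test_that("weighted mode finds the plurality cluster", {
  # 4 instruments near ratio 0.2, 2 outliers near 1.0, equal weights
  pairs <- make_pairs(rep(0.3, 6),
                      0.3 * c(0.19, 0.2, 0.2, 0.21, 1.0, 1.05),
                      se_out = 0.01)
  est <- mr_weighted_mode(pairs, bootstrap_reps = 0)
  expect_equal(est$beta, 0.2, tolerance = 0.05)
  # a degenerate set with identical ratios returns that ratio
  same <- make_pairs(c(0.2, 0.3, 0.4), c(0.1, 0.15, 0.2))
  expect_equal(mr_weighted_mode(same, bootstrap_reps = 0)$beta, 0.5,
               tolerance = 1e-6)
})

test_that("mode estimate is stable across nearby bandwidth factors", {
  withr::local_seed(8)
  pairs <- random_pairs(10, slope = 0.3, se_out = 0.01)
  b1 <- mr_weighted_mode(pairs, bandwidth_factor = 0.9,
                         bootstrap_reps = 0)$beta
  b2 <- mr_weighted_mode(pairs, bandwidth_factor = 1.1,
                         bootstrap_reps = 0)$beta
  expect_equal(b1, b2, tolerance = 0.05)
})

test_that("estimators are sign- and scale-equivariant", {
  withr::local_seed(21)
  pairs <- random_pairs(8, slope = 0.25)
  for (fit in list(function(p) mr_ivw(p)$beta,
                   function(p) mr_weighted_median(p, bootstrap_reps = 0)$beta,
                   function(p) mr_weighted_mode(p, bootstrap_reps = 0)$beta)) {
    b <- fit(pairs)
    flipped <- pairs; flipped$beta_out <- -flipped$beta_out
    expect_equal(fit(flipped), -b, tolerance = 1e-6)
    scaled <- pairs
    scaled$beta_out <- 3 * scaled$beta_out
    scaled$se_out <- 3 * scaled$se_out
    expect_equal(fit(scaled), 3 * b, tolerance = 1e-6)
  }
})

test_that("estimators validate their inputs with classed conditions", {
  pairs <- make_pairs(c(0.3, 0.4), c(0.1, 0.2))
  expect_error(mr_weighted_median(pairs),
               class = "trialmr_insufficient_instruments")
  expect_error(mr_weighted_mode(pairs),
               class = "trialmr_insufficient_instruments")
  expect_error(mr_ivw(dplyr::select(pairs, -"se_out")),
               class = "trialmr_validation_error")
  bad <- pairs; bad$se_out <- c(0.02, -0.01)
  expect_error(mr_ivw(bad), class = "trialmr_validation_error")
})

test_that("mr_all_estimators respects instrument-count requirements", {
  one <- make_pairs(0.3, 0.1)
  expect_named(mr_all_estimators(one), "primary")
  expect_equal(mr_all_estimators(one)$primary$method, "wald")
  three <- make_pairs(c(0.2, 0.3, 0.4), c(0.05, 0.1, 0.1))
  ests3 <- mr_all_estimators(three, bootstrap_reps = 20, seed = 1)
  expect_setequal(names(ests3),
                  c("primary", "weighted_median", "weighted_mode"))
  four <- make_pairs(c(0.2, 0.3, 0.4, 0.5), c(0.05, 0.1, 0.1, 0.12))
  ests4 <- mr_all_estimators(four, bootstrap_reps = 20, presso_sims = 100,
                             seed = 1)
  expect_true("mr_presso" %in% names(ests4))
})

test_that("tidy and glance return one-row method summaries", {
  est <- mr_ivw(make_pairs(c(0.3, 0.4), c(0.1, 0.12)))
  td <- tidy(est)
  expect_equal(nrow(td), 1)
  expect_named(td, c("method", "estimate", "std.error", "statistic",
                     "p.value", "n_instruments"))
  expect_equal(td$statistic, td$estimate / td$std.error)
  gl <- glance(est)
  expect_equal(gl$q_df, 1L)
  expect_output(print(est), "ivw_fixed")
})
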