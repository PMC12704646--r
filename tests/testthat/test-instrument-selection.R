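# Instrument selection chain: cis significance, clumping, two-study split,
# F filter, cross-protein pleiotropy filter, aptamer resolution.

test_that("cis selection uses a closed window and a strict p cut-off", {
  gene_start <- 1e6; gene_end <- 1.1e6; win <- 5e5
  assocs <- make_assocs(
    6,
    pos = c(gene_start - win,       # exactly on the lower edge: kept
            gene_start - win - 1,   # one bp outside: dropped
            gene_end + win,         # exactly on the upper edge: kept
            gene_end + win + 1,     # one bp outside: dropped
            gene_start, gene_start),
    p = c(1e-9, 1e-9, 1e-9, 1e-9,
          5e-8,                     # exactly at the threshold: dropped
          4.9e-8))                  # strictly below: kept
  sel <- select_cis_variants(assocs, "1", gene_start, gene_end,
                             cis_window_bp = win)
  expect_setequal(sel$variant_id, c("rs001", "rs003", "rs006"))
})

test_that("variants on another chromosome are never cis", {
  assocs <- make_assocs(2, chrom = c("1", "2"), pos = 1e6, p = 1e-9)
  sel <- select_cis_variants(assocs, "1", 9e5, 1.1e6)
  expect_equal(sel$variant_id, "rs001")
})

test_that("ld_clump keeps the smallest-p variant of a correlated pair", {
  assocs <- make_assocs(3, pos = c(100, 200, 300) + 1e6,
                        p = c(1e-10, 1e-12, 1e-9))
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.8
  dimnames(m) <- list(assocs$variant_id, assocs$variant_id)
  kept <- ld_clump(assocs, ld_matrix(m), r2_threshold = 0.001)
  expect_setequal(kept$variant_id, c("rs002", "rs003"))
  # r2 exactly at the threshold is not independent (strict inequality)
  m2 <- diag(3); m2[1, 2] <- m2[2, 1] <- 0.001
  dimnames(m2) <- list(assocs$variant_id, assocs$variant_id)
  kept2 <- ld_clump(assocs, ld_matrix(m2), r2_threshold = 0.001)
  expect_setequal(kept2$variant_id, c("rs002", "rs003"))
})

test_that("clumping ties break by position, then variant id", {
  assocs <- make_assocs(2, pos = c(2e6, 1e6), p = c(1e-9, 1e-9))
  m <- matrix(c(1, 0.9, 0.9, 1), 2,
              dimnames = list(assocs$variant_id, assocs$variant_id))
  kept <- ld_clump(assocs, ld_matrix(m))
  expect_equal(kept$variant_id, "rs002")   # same p, smaller position wins
})

test_that("clumped sets are valid and maximal against a brute-force check", {
  # property: every kept pair is independent; every dropped variant
  # conflicts with some kept variant of smaller or equal rank
  withr::local_seed(7)
  for (rep in 1:10) {
    n <- 8
    assocs <- make_assocs(n, pos = 1e6 + sort(sample.int(5000, n)),
                          p = runif(n, 1e-12, 1e-8))
    m <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- sample(c(0, 0.5), 1)
    }
    dimnames(m) <- list(assocs$variant_id, assocs$variant_id)
    ld <- ld_matrix(m)
    kept <- ld_clump(assocs, ld, r2_threshold = 0.1)
    ki <- match(kept$variant_id, assocs$variant_id)
    if (length(ki) > 1) {
      expect_true(all(m[ki, ki][upper.tri(diag(length(ki)))] < 0.1))
    }
    for (d in setdiff(seq_len(n), ki)) {
      expect_true(any(m[d, ki] >= 0.1))
    }
    # row-order invariance
    shuffled <- assocs[sample.int(n), ]
    expect_equal(ld_clump(shuffled, ld, r2_threshold = 0.1), kept)
  }
})

test_that("split_sample_effects swaps to estimation effects and logs absences", {
  disc <- make_assocs(3, beta = 0.5)
  est <- make_assocs(2, beta = 0.2)
  out <- split_sample_effects(disc, est, quiet = TRUE)
  expect_equal(out$beta, c(0.2, 0.2))        # estimation, not discovery
  expect_equal(dropped_records(out)$variant_id, "rs003")
  expect_equal(dropped_records(out)$reason, "absent_from_estimation_study")
})

test_that("selection on discovery plus estimation-side effects avoids winner's curse", {
  # small discovery study selects on noisy effects; conditional on
  # selection, |discovery beta| is inflated while the independent
  # estimation beta is unbiased
  withr::local_seed(11)
  beta_true <- 0.08; se_disc <- 0.03; se_est <- 0.03
  reps <- 400
  sel_disc <- c(); sel_est <- c()
  for (r in seq_len(reps)) {
    b_d <- beta_true + rnorm(20, 0, se_disc)
    b_e <- beta_true + rnorm(20, 0, se_est)
    hit <- which((b_d / se_disc)^2 > 9)      # selection on discovery only
    sel_disc <- c(sel_disc, b_d[hit])
    sel_est <- c(sel_est, b_e[hit])
  }
  expect_gt(mean(sel_disc), beta_true + 2 * sd(sel_disc) / sqrt(length(sel_disc)))
  expect_lt(abs(mean(sel_est) - beta_true),
            3 * sd(sel_est) / sqrt(length(sel_est)))
})

test_that("f_statistic matches the published worked value", {
  # beta 0.057, se 0.0049 gives F about 135
  expect_equal(f_statistic(0.057, 0.0049), (0.057 / 0.0049)^2)
  expect_equal(round(f_statistic(0.057, 0.0049)), 135)
  expect_error(f_statistic(0.1, 0), regexp = "se")
})

test_that("the weak-instrument filter keeps F exactly at the threshold", {
  se <- 0.1
  assocs <- make_assocs(3, beta = c(sqrt(10) * se,        # F = 10: kept
                                    sqrt(10) * se - 1e-9, # F < 10: dropped
                                    1), se = se)
  out <- filter_weak_instruments(assocs, f_min = 10, quiet = TRUE)
  expect_setequal(out$variant_id, c("rs001", "rs003"))
  expect_equal(out$f_stat, f_statistic(out$beta, out$se))
  expect_equal(dropped_records(out)$reason, "weak_instrument")
})

test_that("pleiotropy filter removes on strictly smaller other-protein p, keeps ties", {
  assocs <- make_assocs(3, p = c(1e-8, 1e-8, 1e-8))
  others <- tibble::tibble(
    protein = c("T", "B", "B", "B"),
    variant_id = c("rs001", "rs001", "rs002", "rs003"),
    p = c(1e-8, 1e-9, 1e-8, 1e-7))
  out <- cross_protein_pleiotropy_filter(assocs, "T", others, quiet = TRUE)
  # rs001: other protein strictly stronger -> removed
  # rs002: tie -> retained; rs003: weaker -> retained
  expect_setequal(out$variant_id, c("rs002", "rs003"))
  expect_equal(dropped_records(out)$reason, "stronger_other_protein")
  expect_error(
    cross_protein_pleiotropy_filter(assocs, "MISSING", others, quiet = TRUE),
    class = "trialmr_validation_error")
})

test_that("aptamer resolution keeps the smallest-p aptamer per protein", {
  trial <- tibble::tibble(
    uniprot_id = c("P1", "P1", "P2"),
    gene_symbol = c("G1", "G1", "G2"),
    seq_id = c("10_1", "11_1", "12_1"),
    log2_fold_change = c(0.1, 0.2, -0.1), fdr_p = 0.01)
  minp <- tibble::tibble(seq_id = c("10_1", "11_1"), p = c(1e-6, 1e-9))
  out <- resolve_aptamers(trial, minp)
  # G1 resolves to the stronger aptamer; G2 has no pQTL but is retained
  expect_setequal(out$seq_id, c("11_1", "12_1"))
  # tie breaks by lexicographic seq_id
  minp2 <- tibble::tibble(seq_id = c("10_1", "11_1"), p = c(1e-9, 1e-9))
  expect_true("10_1" %in% resolve_aptamers(trial, minp2)$seq_id)
})

test_that("build_instruments records exact stage-wise conservation", {
  withr::local_seed(3)
  sim <- simulate_study(simulation_scenario(n_proteins = 3,
                                            variants_per_protein = 4,
                                            seed = 3))
  gene <- sim$genes[sim$genes$protein == "PROT02", ]
  inst <- build_instruments(
    dplyr::filter(sim$discovery, protein == "PROT02"),
    dplyr::filter(sim$estimation, protein == "PROT02"),
    gene, sim$ld, all_protein_stats = sim$discovery,
    target_protein = "PROT02")
  prov <- attr(inst, "provenance")
  expect_equal(prov$n_in, prov$n_kept + prov$n_dropped)
  # consecutive stages chain: kept of one stage is input of the next
  expect_equal(prov$n_in[-1], prov$n_kept[-nrow(prov)])
  expect_equal(prov$n_kept[nrow(prov)], nrow(inst))
  # the per-variant drop log agrees with the stage counts
  expect_equal(nrow(attr(inst, "dropped")), sum(prov$n_dropped))
})
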