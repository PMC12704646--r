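# Readers, validation and harmonization.

test_that("read_summary_stats resolves GWAS-catalog-style headers", {
  raw <- tibble::tibble(
    SNP = c("rs1", "rs2"), CHR = "2", BP = c(100, 200),
    effect_allele = c("a", "t"), other_allele = c("g", "c"),
    b = c(0.1, -0.2), standard_error = c(0.02, 0.03),
    pval = c(6e-7, 3e-11), freq = c(0.3, 0.4), samplesize = 5000)
  path <- write_tmp_tsv(raw)
  x <- read_summary_stats(path, quiet = TRUE)
  expect_named(x, c("variant_id", "chrom", "pos", "ea", "oa", "beta",
                    "se", "p", "eaf", "n"))
  expect_equal(x$variant_id, c("rs1", "rs2"))
  expect_equal(x$ea, c("A", "T"))           # alleles uppercased
  expect_equal(x$beta, c(0.1, -0.2))
  expect_equal(nrow(dropped_records(x)), 0)
})

test_that("invalid rows are dropped with counted reasons, never silently", {
  raw <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5", ""),
    ea = c("A", "A", "A", "A", "A", "A"),
    oa = c("G", "G", "A", "G", "G", "G"),
    beta = c("0.1", "abc", "0.1", "0.1", "0.1", "0.1"),
    se = c("0.02", "0.02", "0.02", "0", "0.02", "0.02"),
    p = c(NA, NA, NA, NA, "1.5", NA))
  x <- as_summary_stats(raw, quiet = TRUE)
  d <- dropped_records(x)
  expect_equal(nrow(x), 1)
  expect_equal(nrow(d), 5)
  expect_setequal(d$reason, c("non_numeric_beta", "identical_alleles",
                              "nonpositive_se", "p_out_of_range",
                              "missing_variant_id"))
  # conservation: kept + dropped = input
  expect_equal(nrow(x) + nrow(d), nrow(raw))
})

test_that("missing p is imputed from the two-sided normal oracle", {
  raw <- tibble::tibble(variant_id = "rs1", ea = "A", oa = "G",
                        beta = 0.1, se = 0.02)
  x <- as_summary_stats(raw, quiet = TRUE)
  expect_equal(x$p, 2 * pnorm(-abs(0.1 / 0.02)))
})

test_that("p grossly inconsistent with the Wald z is rejected", {
  raw <- tibble::tibble(variant_id = c("rs1", "rs2"), ea = "A", oa = "G",
                        beta = 0.1, se = 0.02,
                        p = c(2 * pnorm(-5), 0.9))
  x <- as_summary_stats(raw, quiet = TRUE)
  expect_equal(x$variant_id, "rs1")
  expect_equal(dropped_records(x)$reason, "p_inconsistent_with_z")
})

test_that("a missing required column raises a config error naming it", {
  raw <- tibble::tibble(variant_id = "rs1", ea = "A", oa = "G", beta = 0.1)
  expect_error(as_summary_stats(raw, quiet = TRUE),
               class = "trialmr_config_error", regexp = "se")
})

test_that("harmonize keeps aligned variants unchanged and flips swapped ones", {
  exposure <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = 1:3,
    ea = c("A", "A", "A"), oa = c("G", "G", "G"),
    beta = c(0.2, 0.2, 0.2), se = 0.02, p = 1e-9, eaf = 0.3, n = 1e4)
  outcome <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    ea = c("A", "G", "A"), oa = c("G", "A", "C"),   # direct, swap, mismatch
    beta = c(0.1, 0.1, 0.1), se = 0.01, p = 0.5, eaf = c(0.3, 0.7, 0.3),
    n = 1e5)
  h <- harmonize(exposure, outcome, quiet = TRUE)
  expect_equal(h$variant_id, c("rs1", "rs2"))
  expect_equal(h$beta_out, c(0.1, -0.1))        # swap flips the sign
  expect_equal(h$eaf_out, c(0.3, 0.3))          # and complements the eaf
  expect_equal(dropped_records(h),
               tibble::tibble(variant_id = "rs3",
                              reason = "allele_mismatch"))
})

test_that("strand-complement alleles are reconciled for non-palindromic variants", {
  exposure <- tibble::tibble(variant_id = "rs1", chrom = "1", pos = 1,
                             ea = "A", oa = "G", beta = 0.2, se = 0.02,
                             p = 1e-9, eaf = 0.3, n = 1e4)
  # T/C is the strand complement of A/G: same orientation, no flip
  outcome <- tibble::tibble(variant_id = "rs1", ea = "T", oa = "C",
                            beta = 0.1, se = 0.01, p = 0.5, eaf = 0.3,
                            n = 1e5)
  h <- harmonize(exposure, outcome, quiet = TRUE)
  expect_equal(h$beta_out, 0.1)
  # C/T (complement of the swap) flips
  outcome2 <- outcome
  outcome2$ea <- "C"; outcome2$oa <- "T"
  h2 <- harmonize(exposure, outcome2, quiet = TRUE)
  expect_equal(h2$beta_out, -0.1)
})

test_that("palindromic variants resolve only with unambiguous, agreeing frequencies", {
  mk_exp <- function(eaf) tibble::tibble(
    variant_id = "rs1", chrom = "1", pos = 1, ea = "A", oa = "T",
    beta = 0.2, se = 0.02, p = 1e-9, eaf = eaf, n = 1e4)
  mk_out <- function(eaf) tibble::tibble(
    variant_id = "rs1", ea = "A", oa = "T", beta = 0.1, se = 0.01,
    p = 0.5, eaf = eaf, n = 1e5)
  # both clearly on the same side of 0.5: kept
  expect_equal(nrow(harmonize(mk_exp(0.2), mk_out(0.25), quiet = TRUE)), 1)
  # inside the ambiguity band [0.42, 0.58]: dropped
  h <- harmonize(mk_exp(0.5), mk_out(0.5), quiet = TRUE)
  expect_equal(nrow(h), 0)
  expect_equal(dropped_records(h)$reason, "palindromic_ambiguous")
  # boundary: exactly at the band edge counts as ambiguous
  expect_equal(nrow(harmonize(mk_exp(0.42), mk_out(0.3), quiet = TRUE)), 0)
  # opposite sides of 0.5: dropped even though both are outside the band
  expect_equal(nrow(harmonize(mk_exp(0.2), mk_out(0.8), quiet = TRUE)), 0)
  # missing frequency: dropped with its own reason
  h2 <- harmonize(mk_exp(NA), mk_out(0.2), quiet = TRUE)
  expect_equal(dropped_records(h2)$reason, "palindromic_missing_eaf")
})

test_that("harmonization conserves counts: shared = kept + dropped", {
  withr::local_seed(42)
  n <- 50
  exposure <- make_assocs(n, beta = runif(n, -0.5, 0.5))
  # randomly swap alleles on the outcome side
  swap <- runif(n) < 0.5
  outcome <- exposure
  outcome$ea <- ifelse(swap, exposure$oa, exposure$ea)
  outcome$oa <- ifelse(swap, exposure$ea, exposure$oa)
  outcome$beta <- ifelse(swap, -exposure$beta, exposure$beta)
  h <- harmonize(exposure, outcome, quiet = TRUE)
  expect_equal(nrow(h) + nrow(dropped_records(h)), n)
  # double harmonization is the identity on the harmonized table:
  # the outcome is already aligned to the exposure alleles
  expect_equal(h$beta_out, exposure$beta)
})

test_that("trial-effects reader derives directions and rejects duplicates", {
  raw <- tibble::tibble(uniprot = c("P1", "P2"), gene = c("A1", "B1"),
                        seqid = c("1_1", "2_2"),
                        log2fc = c(0.2, -0.3), fdr = c(0.01, 0.02))
  path <- write_tmp_tsv(raw)
  tr <- read_trial_effects(path)
  expect_equal(tr$direction, c("Up", "Down"))
  raw2 <- raw; raw2$seqid <- c("1_1", "1_1")
  expect_error(read_trial_effects(write_tmp_tsv(raw2)),
               class = "trialmr_validation_error", regexp = "1_1")
})

test_that("outcome-direction reader maps blanks to Unobserved", {
  raw <- tibble::tibble(outcome = c("a", "b", "c"),
                        direction = c("Up", "", "Down"))
  x <- read_outcome_directions(write_tmp_tsv(raw))
  expect_equal(x$direction, c("Up", "Unobserved", "Down"))
  expect_equal(unique(x$outcome_type), "continuous")
})

test_that("LD matrix round-trips through disk in both layouts", {
  ids <- c("rs1", "rs2", "rs3")
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.5
  dimnames(m) <- list(ids, ids)
  ld <- ld_matrix(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  back <- read_ld_matrix(path)
  expect_equal(unclass(back), unclass(ld))
  # invalid matrices are rejected
  bad <- m; bad[1, 1] <- 0.9
  expect_error(ld_matrix(bad), class = "trialmr_validation_error")
})
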