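# Summary-level simulation of two-sample MR inputs with known ground truth:
# a discovery and an estimation pQTL study, outcome GWAS under configurable
# pleiotropy regimes, a trial protein-change table, a block LD structure and
# lipid-MR results for the on-target exclusion step. Effects are per-allele
# in trait SD units; standard errors follow the single-variant regression
# calibration se = 1 / sqrt(n * 2 f (1 - f)), so F-statistics scale
# linearly with sample size and the F >= 10 filter behaves realistically.

#' Define a simulation scenario
#'
#' The scenario plus its seed fully determine every simulated table.
#' Defaults mirror the study conditions of the motivating analysis: a
#' discovery pQTL study of 7,213 (ARIC-like), an estimation study of 35,559
#' (deCODE-like), large outcome GWAS, and cis-pQTL effects in the
#' 0.15-0.5 SD-per-allele range.
#'
#' @param n_proteins Number of simulated proteins (default 20).
#' @param variants_per_protein Cis variants per protein (default 5).
#' @param n_outcomes Number of health outcomes (default 3).
#' @param pqtl_effect_range Range of true per-allele pQTL effects, SD units
#'   (default `c(0.15, 0.5)`; effect alleles are coded protein-increasing).
#' @param discovery_n,estimation_n,outcome_n GWAS sample sizes governing
#'   standard-error magnitudes.
#' @param true_causal_effects Matrix (`n_proteins` x `n_outcomes`) of true
#'   protein-on-outcome effects; defaults to cycling
#'   `c(0, 0.1, -0.1, 0.3, -0.3)`.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"outliers"`: the horizontal-pleiotropy regime placed on the outcome
#'   path.
#' @param pleiotropy_magnitude Scale of the pleiotropic effects (outcome
#'   units per allele).
#' @param pleiotropy_fraction Fraction of each protein's variants carrying
#'   pleiotropy (balanced/directional/outliers regimes).
#' @param ld_block_r2 Within-protein pairwise r-squared (between-protein 0).
#' @param lipid_effect_fraction Probability that a protein carries a true
#'   lipid effect (the on-target exclusion simulation).
#' @param trial_log2fc Optional per-protein log2-fold changes; drawn as
#'   `sign * U(0.05, 0.3)` when `NULL`.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(n_proteins = 20, variants_per_protein = 5,
                                n_outcomes = 3,
                                pqtl_effect_range = c(0.15, 0.5),
                                discovery_n = 7213, estimation_n = 35559,
                                outcome_n = 1e5,
                                true_causal_effects = NULL,
                                pleiotropy = c("none", "balanced",
                                               "directional", "outliers"),
                                pleiotropy_magnitude = 0,
                                pleiotropy_fraction = 0.4,
                                ld_block_r2 = 0,
                                lipid_effect_fraction = 0,
                                trial_log2fc = NULL,
                                seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(discovery_n >= 100, estimation_n >= 100, outcome_n >= 100,
            n_proteins >= 1, variants_per_protein >= 1, n_outcomes >= 1,
            length(pqtl_effect_range) == 2,
            pqtl_effect_range[1] <= pqtl_effect_range[2],
            ld_block_r2 >= 0, ld_block_r2 <= 1,
            lipid_effect_fraction >= 0, lipid_effect_fraction <= 1)
  if (is.null(true_causal_effects)) {
    true_causal_effects <- matrix(
      rep_len(c(0, 0.1, -0.1, 0.3, -0.3), n_proteins * n_outcomes),
      nrow = n_proteins)
  }
  stopifnot(nrow(true_causal_effects) == n_proteins,
            ncol(true_causal_effects) == n_outcomes)
  structure(
    list(n_proteins = n_proteins,
         variants_per_protein = variants_per_protein,
         n_outcomes = n_outcomes,
         pqtl_effect_range = pqtl_effect_range,
         discovery_n = discovery_n, estimation_n = estimation_n,
         outcome_n = outcome_n,
         true_causal_effects = true_causal_effects,
         pleiotropy = pleiotropy,
         pleiotropy_magnitude = pleiotropy_magnitude,
         pleiotropy_fraction = pleiotropy_fraction,
         ld_block_r2 = ld_block_r2,
         lipid_effect_fraction = lipid_effect_fraction,
         trial_log2fc = trial_log2fc,
         seed = as.integer(seed)),
    class = "simulation_scenario")
}

protein_names <- function(scenario) {
  sprintf("PROT%02d", seq_len(scenario$n_proteins))
}

outcome_names <- function(scenario) {
  sprintf("outcome_%02d", seq_len(scenario$n_outcomes))
}

se_calibrated <- function(n, eaf) 1 / sqrt(n * 2 * eaf * (1 - eaf))

#' Simulate discovery and estimation pQTL studies
#'
#' Each protein receives `variants_per_protein` cis variants with true
#' per-allele effects drawn from `pqtl_effect_range`; the discovery and
#' estimation studies observe independent noisy realizations with standard
#' errors calibrated to their sample sizes.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with canonical association tibbles `discovery` and
#'   `estimation` (long format with a `protein` column), a `genes` tibble
#'   (`protein`, `chrom`, `start`, `end`) and a `truth` tibble of
#'   per-variant true effects.
#' @export
simulate_pqtl_studies <- function(scenario) {
  withr::local_seed(scenario$seed)
  P <- scenario$n_proteins; V <- scenario$variants_per_protein
  prot <- protein_names(scenario)
  genes <- tibble(protein = prot, chrom = "1",
                  start = 2e6 * seq_len(P), end = 2e6 * seq_len(P) + 1e5)
  idx <- rep(seq_len(P), each = V)
  pos <- genes$start[idx] + 1000 * (rep(seq_len(V), P) - 1)
  eaf <- runif(P * V, 0.05, 0.95)
  beta_true <- runif(P * V, scenario$pqtl_effect_range[1],
                     scenario$pqtl_effect_range[2])
  allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                         ncol = 2, byrow = TRUE)
  pair <- allele_pairs[sample.int(4, P * V, replace = TRUE), , drop = FALSE]
  truth <- tibble(
    protein = prot[idx],
    variant_id = sprintf("%s_v%02d", prot[idx], rep(seq_len(V), P)),
    chrom = "1", pos = pos, ea = pair[, 1], oa = pair[, 2],
    eaf = eaf, beta_true = beta_true)

  realize <- function(n) {
    se <- se_calibrated(n, truth$eaf)
    beta <- truth$beta_true + rnorm(nrow(truth), 0, se)
    tibble(variant_id = truth$variant_id, chrom = truth$chrom,
           pos = truth$pos, ea = truth$ea, oa = truth$oa,
           beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
           eaf = truth$eaf, n = n, protein = truth$protein)
  }
  list(discovery = realize(scenario$discovery_n),
       estimation = realize(scenario$estimation_n),
       genes = genes, truth = truth)
}

#' Simulate outcome GWAS under a pleiotropy regime
#'
#' Per variant j (of protein p) and outcome k the outcome effect is
#' `beta_Y = theta[p, k] * beta_X_true[j] + alpha[j, k] + noise`, where
#' `alpha` is zero for valid instruments, zero-mean for balanced
#' pleiotropy, positive-mean for directional pleiotropy, and a large shift
#' for the outlier regime, applied to `pleiotropy_fraction` of each
#' protein's variants.
#'
#' @param scenario A [simulation_scenario()].
#' @param truth Per-variant truth tibble from [simulate_pqtl_studies()].
#' @return List with `outcomes` (named list of canonical association
#'   tibbles) and `pleiotropy` (long tibble of the alpha draws).
#' @export
simulate_outcome_stats <- function(scenario, truth) {
  withr::local_seed(scenario$seed + 1L)
  theta <- scenario$true_causal_effects
  prot <- protein_names(scenario)
  ocs <- outcome_names(scenario)
  J <- nrow(truth)
  se_y <- se_calibrated(scenario$outcome_n, truth$eaf)
  p_idx <- match(truth$protein, prot)

  alpha_tab <- list()
  outcomes <- list()
  for (k in seq_along(ocs)) {
    alpha <- numeric(J)
    if (scenario$pleiotropy != "none" && scenario$pleiotropy_magnitude != 0) {
      sel <- as.logical(stats::ave(
        seq_len(J), truth$protein,
        FUN = function(ix) {
          m <- length(ix)
          hit <- rep(FALSE, m)
          n_hit <- round(scenario$pleiotropy_fraction * m)
          if (n_hit > 0) hit[sample.int(m, n_hit)] <- TRUE
          hit
        }))
      m <- scenario$pleiotropy_magnitude
      alpha[sel] <- switch(scenario$pleiotropy,
        balanced = rnorm(sum(sel), 0, m),
        directional = m * runif(sum(sel), 0.5, 1.5),
        outliers = m)
    }
    beta_y <- theta[cbind(p_idx, k)] * truth$beta_true + alpha +
      rnorm(J, 0, se_y)
    outcomes[[ocs[k]]] <- tibble(
      variant_id = truth$variant_id, chrom = truth$chrom, pos = truth$pos,
      ea = truth$ea, oa = truth$oa, beta = beta_y, se = se_y,
      p = 2 * pnorm(-abs(beta_y / se_y)), eaf = truth$eaf,
      n = scenario$outcome_n)
    alpha_tab[[k]] <- tibble(variant_id = truth$variant_id,
                             outcome = ocs[k], alpha = alpha)
  }
  list(outcomes = outcomes, pleiotropy = bind_rows(alpha_tab))
}

#' Simulate the trial protein-change table and outcome directions
#'
#' Log2-fold changes follow the scenario's rule (or `sign * U(0.05, 0.3)`);
#' each outcome's trial direction is the sign of the truth-implied aggregate
#' `sum_p theta[p, k] * sign(log2fc_p)`, `Unobserved` when that sum is zero.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `trial_effects` and `outcome_directions` tibbles.
#' @export
simulate_trial_table <- function(scenario) {
  withr::local_seed(scenario$seed + 2L)
  P <- scenario$n_proteins
  prot <- protein_names(scenario)
  lfc <- scenario$trial_log2fc %||%
    (sample(c(-1, 1), P, replace = TRUE) * runif(P, 0.05, 0.3))
  trial <- tibble(
    uniprot_id = sprintf("SYNP%02d", seq_len(P)),
    gene_symbol = prot,
    seq_id = sprintf("%d_%d", 1000 + seq_len(P), seq_len(P)),
    log2_fold_change = lfc,
    fdr_p = runif(P, 1e-6, 0.049),
    direction = trial_direction(lfc))
  agg <- as.numeric(sign(lfc) %*% scenario$true_causal_effects)
  dirs <- tibble(
    outcome = outcome_names(scenario),
    direction = ifelse(agg > 0, "Up", ifelse(agg < 0, "Down", "Unobserved")),
    outcome_type = "continuous")
  list(trial_effects = trial, outcome_directions = dirs)
}

#' Simulate the block LD structure
#'
#' Block-diagonal r-squared: within a protein's variant block the pairwise
#' r-squared is `ld_block_r2`, between blocks 0, with a unit diagonal.
#'
#' @param scenario A [simulation_scenario()].
#' @param truth Per-variant truth tibble from [simulate_pqtl_studies()].
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(scenario, truth) {
  J <- nrow(truth)
  m <- matrix(0, J, J, dimnames = list(truth$variant_id, truth$variant_id))
  for (p in unique(truth$protein)) {
    ix <- which(truth$protein == p)
    m[ix, ix] <- scenario$ld_block_r2
  }
  diag(m) <- 1
  ld_matrix(m)
}

#' Simulate lipid-on-protein MR results for the on-target exclusion
#'
#' A `lipid_effect_fraction` share of proteins (Bernoulli draws) receives a
#' true lipid effect; affected lipid-protein tests get a strong signal,
#' unaffected ones a null draw.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `lipid_mr` (tibble `lipid`, `protein`, `beta`, `se`,
#'   `p`) and `lipid_affected` (logical truth per protein).
#' @export
simulate_lipid_mr <- function(scenario) {
  withr::local_seed(scenario$seed + 3L)
  prot <- protein_names(scenario)
  P <- length(prot)
  affected <- runif(P) < scenario$lipid_effect_fraction
  lipids <- c("LDL", "HDL", "triglycerides")
  se <- 0.01
  rows <- lapply(lipids, function(l) {
    beta <- ifelse(affected, 0.15, 0) + rnorm(P, 0, se)
    tibble(lipid = l, protein = prot, beta = beta, se = se,
           p = 2 * pnorm(-abs(beta / se)))
  })
  list(lipid_mr = bind_rows(rows), lipid_affected =
         tibble(protein = prot, lipid_affected = affected))
}

#' Simulate the full study bundle
#'
#' Runs every generator of the scenario in a fixed order and returns all
#' inputs the pipeline consumes plus the truth records. The same scenario
#' and seed always yield identical output.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `mr_sim_bundle` list: `discovery`, `estimation`, `outcomes`,
#'   `genes`, `ld`, `trial_effects`, `outcome_directions`, `lipid_mr`,
#'   `truth` (list of `variants`, `theta`, `pleiotropy`, `lipid_affected`),
#'   `scenario`.
#' @export
simulate_study <- function(scenario) {
  pq <- simulate_pqtl_studies(scenario)
  oc <- simulate_outcome_stats(scenario, pq$truth)
  tr <- simulate_trial_table(scenario)
  li <- simulate_lipid_mr(scenario)
  theta_long <- as_tibble(scenario$true_causal_effects,
                          .name_repair = ~outcome_names(scenario)) %>%
    mutate(protein = protein_names(scenario)) %>%
    tidyr::pivot_longer(-"protein", names_to = "outcome",
                        values_to = "theta")
  structure(
    list(discovery = pq$discovery, estimation = pq$estimation,
         outcomes = oc$outcomes, genes = pq$genes,
         ld = simulate_ld(scenario, pq$truth),
         trial_effects = tr$trial_effects,
         outcome_directions = tr$outcome_directions,
         lipid_mr = li$lipid_mr,
         truth = list(variants = pq$truth, theta = theta_long,
                      pleiotropy = oc$pleiotropy,
                      lipid_affected = li$lipid_affected),
         scenario = scenario),
    class = "mr_sim_bundle")
}
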