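# Orchestration of the full inference chain: exclusion of lipid-mediated
# (on-target) proteins, forward MR over all protein-outcome pairs,
# orientation of estimates to the trial-observed protein direction,
# Bonferroni correction over the estimates actually produced, concordance
# classification against trial-observed trait changes, reverse MR, and the
# mediator / downstream-consequence classification.

#' Partition proteins into on-target (lipid-mediated) and off-target
#'
#' A protein is on-target iff any lipid's MR effect on it is significant at
#' the Bonferroni level `alpha / n`, with `n` the number of lipid-protein
#' tests supplied. Proteins absent from `lipid_mr_results` are placed
#' off-target with a warning.
#'
#' @param proteins Trial protein-change tibble (see [read_trial_effects()]).
#' @param lipid_mr_results Tibble with columns `lipid`, `protein`
#'   (gene symbol) and `p`, the IVW MR p-value of each lipid's effect on
#'   each protein.
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @return List with tibbles `on_target` and `off_target` (an exhaustive,
#'   disjoint partition of `proteins`) and the `threshold` used.
#' @export
exclude_lipid_mediated <- function(proteins, lipid_mr_results, alpha = 0.05) {
  threshold <- bonferroni_threshold(nrow(lipid_mr_results), alpha)
  hit <- lipid_mr_results %>%
    group_by(.data$protein) %>%
    summarise(lipid_mediated = any(.data$p < threshold), .groups = "drop")
  merged <- left_join(proteins, hit, by = c(gene_symbol = "protein"))
  absent <- is.na(merged$lipid_mediated)
  if (any(absent)) {
    warn(paste0(sum(absent), " protein(s) absent from lipid MR results, ",
                "treated as off-target"))
    merged$lipid_mediated[absent] <- FALSE
  }
  list(on_target = proteins[merged$lipid_mediated, , drop = FALSE],
       off_target = proteins[!merged$lipid_mediated, , drop = FALSE],
       threshold = threshold)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests actually performed (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Orient an MR estimate to the trial-observed protein direction
#'
#' MR estimates are computed per SD *increase* in protein level; trial
#' reporting expresses them per SD change *in the direction observed in the
#' trial*. For proteins that rose on treatment the estimate is unchanged;
#' for proteins that fell it is sign-flipped (standard error and p-value
#' unchanged). A zero log2-fold change has no direction and raises an error.
#'
#' @param x An `mr_estimate`, or a numeric vector of betas.
#' @param log2_fold_change Trial-observed log2-fold change(s).
#' @return Same type as `x`, with oriented beta(s).
#' @export
orient_to_trial <- function(x, log2_fold_change) {
  UseMethod("orient_to_trial")
}

#' @export
orient_to_trial.mr_estimate <- function(x, log2_fold_change) {
  x$beta <- orient_to_trial(x$beta, log2_fold_change)
  x
}

#' @export
orient_to_trial.numeric <- function(x, log2_fold_change) {
  if (any(log2_fold_change == 0)) {
    abort("orientation undefined for a zero log2-fold change",
          class = "trialmr_orientation_error")
  }
  ifelse(log2_fold_change < 0, -x, x)
}

#' Concordance of an oriented MR estimate with the trial trait change
#'
#' An estimate is concordant (1) when its oriented direction matches the
#' trait change observed in the trial's active arm, discordant (0)
#' otherwise, and `NA` when the trait was not annotated in the trial
#' (`"Unobserved"`).
#'
#' @param oriented_beta Numeric vector of trial-oriented MR estimates.
#' @param trial_direction Character vector: `"Up"`, `"Down"` or
#'   `"Unobserved"`.
#' @return Integer vector of 1, 0, `NA`.
#' @export
classify_concordance <- function(oriented_beta, trial_direction) {
  case_when(
    trial_direction == "Unobserved" | is.na(trial_direction) ~ NA_integer_,
    trial_direction == "Up" & oriented_beta > 0 ~ 1L,
    trial_direction == "Down" & oriented_beta < 0 ~ 1L,
    TRUE ~ 0L
  )
}

# run the primary estimator (IVW; Wald when single-instrument) for every
# exposure-outcome pair; exposures and outcomes are named lists of canonical
# association tibbles
mr_all_pairs <- function(exposures, outcomes, palindrome_eaf_limit = 0.42) {
  rows <- list()
  excluded <- list()
  for (ex in names(exposures)) {
    instr <- exposures[[ex]]
    if (is.null(instr) || nrow(instr) == 0) {
      excluded[[length(excluded) + 1]] <-
        tibble(exposure = ex, outcome = NA_character_,
               reason = "no_instruments")
      next
    }
    for (oc in names(outcomes)) {
      pairs <- harmonize(instr, outcomes[[oc]], palindrome_eaf_limit,
                         quiet = TRUE)
      if (nrow(pairs) == 0) {
        excluded[[length(excluded) + 1]] <-
          tibble(exposure = ex, outcome = oc,
                 reason = "no_harmonized_variants")
        next
      }
      est <- tryCatch(
        if (nrow(pairs) == 1) mr_wald_ratio(pairs) else mr_ivw(pairs),
        error = function(e) NULL)
      if (is.null(est)) {
        excluded[[length(excluded) + 1]] <-
          tibble(exposure = ex, outcome = oc, reason = "estimator_failure")
        next
      }
      f <- f_statistic(pairs$beta_exp, pairs$se_exp)
      rows[[length(rows) + 1]] <- tidy(est) %>%
        mutate(exposure = ex, outcome = oc,
               f_mean = mean(f), f_min = min(f), .before = 1)
    }
  }
  list(results = if (length(rows)) bind_rows(rows) else
         tibble(exposure = character(), outcome = character(),
                f_mean = double(), f_min = double(), method = character(),
                estimate = double(), std.error = double(),
                statistic = double(), p.value = double(),
                n_instruments = integer()),
       excluded = if (length(excluded)) bind_rows(excluded) else
         tibble(exposure = character(), outcome = character(),
                reason = character()))
}

#' Forward MR over all protein-outcome pairs
#'
#' For every protein with at least one instrument and every outcome, runs
#' the primary estimator (fixed-effects IVW; Wald ratio when a single
#' instrument survives harmonization), applies the Bonferroni correction
#' over the estimates actually produced, orients significant estimates to
#' the trial-observed protein direction, and classifies concordance with
#' the trial-observed trait change. Sensitivity estimators (weighted
#' median, weighted mode, MR-PRESSO) run on significant pairs where
#' instrument counts permit and are summarized by [sensitivity_consistency()].
#'
#' @param trial_effects Trial protein-change tibble; `gene_symbol` must
#'   match the names of `instruments`.
#' @param instruments Named list (by protein) of estimation-study exposure
#'   association tibbles (post instrument selection).
#' @param outcome_stats Named list (by outcome) of outcome GWAS association
#'   tibbles.
#' @param outcome_directions Tibble with `outcome`, `direction`,
#'   `outcome_type` (see [read_outcome_directions()]); outcomes absent from
#'   it are treated as `"Unobserved"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @param sensitivity Run sensitivity estimators on significant pairs.
#' @param bootstrap_reps,presso_sims,seed Sensitivity-estimator settings.
#' @return An object of class `mr_forward`: list with `results` (all
#'   primary estimates), `concordance` (significant, oriented, classified),
#'   `sensitivity`, `excluded`, `threshold`, `n_tests`, `alpha`, `seed`.
#' @export
run_forward_mr <- function(trial_effects, instruments, outcome_stats,
                           outcome_directions = NULL, alpha = 0.05,
                           palindrome_eaf_limit = 0.42, sensitivity = TRUE,
                           bootstrap_reps = 1000, presso_sims = 1000,
                           seed = NULL) {
  undirected <- trial_effects$gene_symbol[trial_effects$log2_fold_change == 0]
  if (length(undirected) > 0) {
    warn(paste0("excluding protein(s) with zero log2-fold change (no ",
                "direction): ", paste(undirected, collapse = ", ")))
    trial_effects <- trial_effects %>%
      filter(.data$log2_fold_change != 0)
    instruments <- instruments[setdiff(names(instruments), undirected)]
  }
  instruments <- instruments[intersect(trial_effects$gene_symbol,
                                       names(instruments))]

  scan <- mr_all_pairs(instruments, outcome_stats, palindrome_eaf_limit)
  results <- scan$results
  n_tests <- nrow(results)
  threshold <- if (n_tests > 0) bonferroni_threshold(n_tests, alpha) else NA_real_

  sig <- results %>% filter(.data$p.value < threshold)
  conc <- sig %>%
    inner_join(trial_effects %>%
                 select("gene_symbol", "seq_id", "log2_fold_change"),
               by = c(exposure = "gene_symbol"))
  if (nrow(conc) > 0) {
    conc <- conc %>%
      mutate(oriented_beta = orient_to_trial(.data$estimate,
                                             .data$log2_fold_change))
  } else {
    conc$oriented_beta <- double(0)
  }
  dirs <- outcome_directions %||%
    tibble(outcome = character(), direction = character(),
           outcome_type = character())
  conc <- conc %>%
    left_join(dirs, by = "outcome") %>%
    mutate(
      direction = ifelse(is.na(.data$direction), "Unobserved",
                         .data$direction),
      outcome_type = ifelse(is.na(.data$outcome_type), "continuous",
                            .data$outcome_type),
      concordant = classify_concordance(.data$oriented_beta,
                                        .data$direction)) %>%
    select(protein = "exposure", "seq_id", "outcome",
           n_inst = "n_instruments", f_mean = "f_mean", f_min = "f_min",
           "log2_fold_change", trial_direction = "direction",
           beta = "oriented_beta", se = "std.error", p = "p.value",
           "concordant", "outcome_type")

  sens <- NULL
  if (sensitivity && nrow(sig) > 0) {
    sens_rows <- purrr::pmap(
      list(sig$exposure, sig$outcome),
      function(ex, oc) {
        pairs <- harmonize(instruments[[ex]], outcome_stats[[oc]],
                           palindrome_eaf_limit, quiet = TRUE)
        ests <- mr_all_estimators(pairs, bootstrap_reps, presso_sims, seed)
        report <- bind_rows(lapply(ests, tidy)) %>%
          mutate(protein = ex, outcome = oc, .before = 1)
        cons <- sensitivity_consistency(ests$primary, ests[-1])
        report$consistent <- cons$consistent
        report
      })
    sens <- bind_rows(sens_rows)
  }

  structure(
    list(results = results, concordance = conc, sensitivity = sens,
         excluded = scan$excluded, threshold = threshold, n_tests = n_tests,
         alpha = alpha, seed = seed),
    class = "mr_forward")
}

#' @export
print.mr_forward <- function(x, ...) {
  cat("<mr_forward> ", x$n_tests, " protein-outcome estimates; threshold p < ",
      format(x$threshold, digits = 3), "\n", sep = "")
  cat("  significant pairs: ", nrow(x$concordance),
      " (", n_distinct(x$concordance$protein), " protein(s))\n", sep = "")
  invisible(x)
}

#' @method tidy mr_forward
#' @export
tidy.mr_forward <- function(x, ...) x$concordance

#' @method glance mr_forward
#' @export
glance.mr_forward <- function(x, ...) {
  tibble(n_tests = x$n_tests, threshold = x$threshold,
         n_significant = nrow(x$concordance),
         n_proteins = n_distinct(x$concordance$protein),
         n_concordant = n_distinct(
           x$concordance$protein[x$concordance$concordant %in% 1L]),
         n_excluded = nrow(x$excluded))
}

#' Reverse MR of outcomes on the proteome
#'
#' Estimates the effect of each health outcome (exposure side, genome-wide
#' instruments) on each protein (outcome side) with the primary estimator
#' and Bonferroni correction over the estimates produced, then summarizes
#' per-outcome significant-protein sets and their intersections.
#'
#' @param outcome_instruments Named list (by outcome) of genome-wide
#'   significant, clumped instrument tibbles.
#' @param protein_stats Named list (by protein) of protein GWAS association
#'   tibbles (estimation study).
#' @param alpha Family-wise error rate (default 0.05).
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @return An object of class `mr_reverse`: list with `results`,
#'   `significant`, `sets` (per-outcome protein vectors), `counts` (see
#'   [intersection_counts()]), `threshold`, `n_tests`, `excluded`.
#' @export
run_reverse_mr <- function(outcome_instruments, protein_stats, alpha = 0.05,
                           palindrome_eaf_limit = 0.42) {
  scan <- mr_all_pairs(outcome_instruments, protein_stats,
                       palindrome_eaf_limit)
  results <- scan$results
  n_tests <- nrow(results)
  threshold <- if (n_tests > 0) bonferroni_threshold(n_tests, alpha) else NA_real_
  sig <- results %>% filter(.data$p.value < threshold)
  sets <- lapply(setNames(names(outcome_instruments),
                          names(outcome_instruments)),
                 function(oc) sort(unique(sig$outcome[sig$exposure == oc])))
  structure(
    list(results = results, significant = sig, sets = sets,
         counts = intersection_counts(sig, exposure_col = "exposure",
                                      member_col = "outcome"),
         threshold = threshold, n_tests = n_tests, excluded = scan$excluded),
    class = "mr_reverse")
}

#' @export
print.mr_reverse <- function(x, ...) {
  cat("<mr_reverse> ", x$n_tests, " outcome-protein estimates; threshold p < ",
      format(x$threshold, digits = 3), "\n", sep = "")
  cat("  proteins influenced by at least one outcome: ",
      n_distinct(x$significant$outcome), "\n", sep = "")
  invisible(x)
}

#' @method tidy mr_reverse
#' @export
tidy.mr_reverse <- function(x, ...) x$significant

#' Per-exposure and intersection counts of significant hits
#'
#' Summarizes a significant-results table the way an upset plot does: how
#' many members (e.g. proteins) each exposure (e.g. health outcome) hits,
#' and how many members fall in each exact combination of exposures.
#'
#' @param sig Tibble of significant pairs.
#' @param exposure_col,member_col Column names for the set-defining exposure
#'   and the set members.
#' @return List with tibbles `per_exposure` (`exposure`, `n`),
#'   `combinations` (`combination`, `n`) and the scalar `n_union`.
#' @export
intersection_counts <- function(sig, exposure_col = "exposure",
                                member_col = "outcome") {
  ex <- sig[[exposure_col]]; mem <- sig[[member_col]]
  per_exposure <- tibble(exposure = ex, member = mem) %>%
    distinct() %>%
    group_by(.data$exposure) %>%
    summarise(n = n(), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n), .data$exposure)
  combos <- tibble(exposure = ex, member = mem) %>%
    distinct() %>%
    group_by(.data$member) %>%
    summarise(combination = paste(sort(unique(.data$exposure)),
                                  collapse = "+"),
              .groups = "drop") %>%
    group_by(.data$combination) %>%
    summarise(n = n(), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n), .data$combination)
  list(per_exposure = per_exposure, combinations = combos,
       n_union = n_distinct(mem))
}

#' Classify proteins as upstream mediators or downstream consequences
#'
#' Combines forward-significance (protein affects at least one outcome) and
#' reverse-significance (at least one outcome affects the protein):
#' forward-only proteins are upstream mediators, both-directions proteins
#' are bidirectional, reverse-only proteins are downstream consequences,
#' and proteins significant in neither direction are unclassified.
#'
#' @param forward An `mr_forward` object, or a character vector of
#'   forward-significant proteins.
#' @param reverse An `mr_reverse` object, or a character vector of
#'   reverse-significant proteins.
#' @param proteins Optional character vector of all proteins to classify;
#'   defaults to the union of the two significant sets.
#' @return Tibble with `protein`, `forward_significant`,
#'   `reverse_significant`, `class`.
#' @export
classify_mediators <- function(forward, reverse, proteins = NULL) {
  fwd <- if (inherits(forward, "mr_forward"))
    unique(forward$concordance$protein) else unique(forward)
  rev <- if (inherits(reverse, "mr_reverse"))
    unique(reverse$significant$outcome) else unique(reverse)
  proteins <- proteins %||% sort(union(fwd, rev))
  tibble(protein = proteins) %>%
    mutate(
      forward_significant = .data$protein %in% fwd,
      reverse_significant = .data$protein %in% rev,
      class = case_when(
        .data$forward_significant & !.data$reverse_significant ~
          "upstream_mediator",
        .data$forward_significant & .data$reverse_significant ~
          "bidirectional",
        !.data$forward_significant & .data$reverse_significant ~
          "downstream_consequence",
        TRUE ~ "unclassified"))
}

#' Consistency of the primary estimate across sensitivity estimators
#'
#' Consistent iff every alternate estimator shares the primary estimate's
#' sign and its confidence interval overlaps the primary's.
#'
#' @param primary An `mr_estimate` (the IVW / Wald primary).
#' @param alternates List of `mr_estimate` objects (may be empty; an
#'   absent alternate is never treated as inconsistency).
#' @param level Confidence level for the interval-overlap rule
#'   (default 0.95).
#' @return List with `consistent` (logical) and a `report` tibble listing
#'   every estimator's beta, se, p and agreement flags.
#' @export
sensitivity_consistency <- function(primary, alternates, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- function(e) c(e$beta - z * e$se, e$beta + z * e$se)
  p_ci <- ci(primary)
  rows <- list(tidy(primary) %>%
                 mutate(same_sign = TRUE, ci_overlaps = TRUE))
  consistent <- TRUE
  for (alt in alternates) {
    same_sign <- sign(alt$beta) == sign(primary$beta)
    a_ci <- ci(alt)
    overlaps <- is.na(alt$se) ||
      (a_ci[1] <= p_ci[2] && p_ci[1] <= a_ci[2])
    consistent <- consistent && same_sign && overlaps
    rows[[length(rows) + 1]] <- tidy(alt) %>%
      mutate(same_sign = same_sign, ci_overlaps = overlaps)
  }
  list(consistent = consistent, report = bind_rows(rows))
}
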