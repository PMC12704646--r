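# Per-protein instrument construction: cis-region restriction and genome-wide
# significance, greedy LD clumping, the discovery/estimation two-study split
# that guards against winner's curse, the instrument-strength (F) filter and
# the cross-protein pleiotropy filter. Filters compose in a fixed order and
# every exclusion is logged so stage-wise bookkeeping is exact.

#' Select genome-wide significant cis variants for a gene
#'
#' Retains associations on the gene's chromosome whose position falls in the
#' closed interval `[gene_start - cis_window_bp, gene_end + cis_window_bp]`
#' and whose p-value is strictly below `p_threshold`.
#'
#' @param assocs Canonical association tibble.
#' @param gene_chrom,gene_start,gene_end Gene body coordinates (1-based).
#' @param cis_window_bp Flanking window in base pairs (default 500 kb).
#' @param p_threshold Significance cut-off, strict inequality
#'   (default 5e-8).
#' @return The retained rows of `assocs`.
#' @export
select_cis_variants <- function(assocs, gene_chrom, gene_start, gene_end,
                                cis_window_bp = 5e5, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1, cis_window_bp >= 0)
  lo <- gene_start - cis_window_bp
  hi <- gene_end + cis_window_bp
  assocs %>%
    filter(.data$chrom == gene_chrom,
           .data$pos >= lo, .data$pos <= hi,
           .data$p < p_threshold)
}

#' Greedy LD clumping to approximately independent variants
#'
#' Variants are visited in order of ascending p-value (ties broken by
#' ascending position then lexicographic variant id) and a variant is kept
#' iff its r-squared with every previously kept variant within `window_kb`
#' is strictly below `r2_threshold`. Variants absent from the LD matrix are
#' treated as independent with a warning. The result is returned sorted by
#' position, and is invariant to the input row order.
#'
#' @param assocs Canonical association tibble.
#' @param ld An [ld_matrix()] (or named square matrix) covering the variants.
#' @param r2_threshold Independence threshold on r-squared (default 0.001,
#'   strict inequality).
#' @param window_kb Pairwise distance in kilobases within which LD is
#'   considered (default 10,000 kb); more distant pairs are treated as
#'   independent.
#' @return The retained rows of `assocs`, sorted by position.
#' @export
ld_clump <- function(assocs, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(assocs) == 0) return(assocs)
  ids <- rownames(ld)
  missing <- setdiff(assocs$variant_id, ids)
  if (length(missing) > 0) {
    warn(paste0(length(missing),
                " variant(s) absent from LD matrix treated as independent"))
  }
  ord <- order(assocs$p, assocs$pos, assocs$variant_id)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      within <- !is.na(assocs$pos[i]) && !is.na(assocs$pos[k]) &&
        abs(assocs$pos[i] - assocs$pos[k]) <= window_kb * 1000
      if (!within) next
      vi <- assocs$variant_id[i]; vk <- assocs$variant_id[k]
      r2 <- if (vi %in% ids && vk %in% ids) ld[vi, vk] else 0
      if (r2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  assocs[kept, , drop = FALSE] %>% arrange(.data$pos, .data$variant_id)
}

#' Swap discovery-selected variants to estimation-study effects
#'
#' Discovery-study effect sizes are used only to select variants; effect
#' estimation uses an independent study, which removes winner's-curse
#' inflation. Returns the estimation-study association for every selected
#' variant; variants absent from the estimation study are dropped with a
#' logged reason.
#'
#' @param discovery_selection Selected (and clumped) discovery associations.
#' @param estimation_stats Canonical association tibble from the estimation
#'   study.
#' @param quiet Suppress the drop message.
#' @return Estimation-study rows for the selected variants; attribute
#'   `dropped` logs variants missing from the estimation study.
#' @export
split_sample_effects <- function(discovery_selection, estimation_stats,
                                 quiet = FALSE) {
  sel <- discovery_selection$variant_id
  out <- estimation_stats %>% filter(.data$variant_id %in% sel)
  missing <- setdiff(sel, out$variant_id)
  if (length(missing) > 0 && !quiet) {
    inform(paste0(length(missing),
                  " selected variant(s) absent from estimation study, dropped"))
  }
  attr(out, "dropped") <- tibble(variant_id = missing,
                                 reason = rep("absent_from_estimation_study",
                                              length(missing)))
  out
}

#' Single-variant instrument-strength F-statistic
#'
#' The squared Wald z-statistic, `(beta/se)^2`, equivalent to the partial
#' F-statistic of a single-variant regression on summary data.
#'
#' @param beta,se Per-variant effect and standard error (vectorized).
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0, na.rm = TRUE))
  (beta / se)^2
}

#' Drop weak instruments
#'
#' Removes variants whose F-statistic is strictly below `f_min`; an F of
#' exactly `f_min` is retained.
#'
#' @param assocs Canonical association tibble (exposure side).
#' @param f_min Minimum instrument strength (default 10).
#' @param quiet Suppress the drop message.
#' @return Retained rows with an added `f_stat` column; attribute `dropped`
#'   logs removed variants.
#' @export
filter_weak_instruments <- function(assocs, f_min = 10, quiet = FALSE) {
  stopifnot(f_min >= 0)
  f <- f_statistic(assocs$beta, assocs$se)
  keep <- f >= f_min
  out <- assocs[keep, , drop = FALSE]
  out$f_stat <- f[keep]
  dropped <- tibble(variant_id = assocs$variant_id[!keep],
                    reason = rep("weak_instrument", sum(!keep)))
  if (nrow(dropped) > 0 && !quiet) {
    inform(paste0("dropped ", nrow(dropped), " weak instrument(s) (F < ",
                  f_min, ")"))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Remove variants more strongly associated with another protein
#'
#' A variant is removed iff any other protein's association p-value at that
#' variant is strictly smaller than the target protein's p-value there; ties
#' are retained.
#'
#' @param assocs Target-protein association tibble (the candidate
#'   instruments, with their p-values).
#' @param target_protein Name of the target protein.
#' @param all_protein_stats Long tibble with columns `protein`,
#'   `variant_id`, `p` covering associations of all proteins (including the
#'   target) at the candidate variants.
#' @param quiet Suppress the drop message.
#' @return Retained rows; attribute `dropped` logs removed variants.
#' @export
cross_protein_pleiotropy_filter <- function(assocs, target_protein,
                                            all_protein_stats,
                                            quiet = FALSE) {
  if (!target_protein %in% all_protein_stats$protein) {
    abort("all_protein_stats must contain the target protein",
          class = "trialmr_validation_error")
  }
  other_best <- all_protein_stats %>%
    filter(.data$protein != target_protein,
           .data$variant_id %in% assocs$variant_id,
           !is.na(.data$p)) %>%
    arrange(.data$p) %>%
    distinct(.data$variant_id, .keep_all = TRUE) %>%
    select("variant_id", best_other_p = "p")
  merged <- left_join(assocs, other_best, by = "variant_id")
  remove <- !is.na(merged$best_other_p) & merged$best_other_p < merged$p
  out <- assocs[!remove, , drop = FALSE]
  dropped <- tibble(variant_id = assocs$variant_id[remove],
                    reason = rep("stronger_other_protein", sum(remove)))
  if (nrow(dropped) > 0 && !quiet) {
    inform(paste0("dropped ", nrow(dropped),
                  " variant(s) more strongly associated with another protein"))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Resolve multiple aptamers mapping to one protein
#'
#' When several aptamers target the same protein, the aptamer with the
#' smallest discovery-study pQTL p-value is kept; ties break by
#' lexicographic SeqID.
#'
#' @param trial_effects Trial protein-change tibble
#'   (see [read_trial_effects()]).
#' @param aptamer_min_p Tibble with columns `seq_id` and `p`, the smallest
#'   discovery-study pQTL p-value per aptamer; aptamers absent from it are
#'   treated as having no pQTL (p = 1).
#' @return The trial-effects rows retained after resolution.
#' @export
resolve_aptamers <- function(trial_effects, aptamer_min_p) {
  trial_effects %>%
    left_join(aptamer_min_p, by = "seq_id") %>%
    mutate(p = ifelse(is.na(.data$p), 1, .data$p)) %>%
    group_by(.data$uniprot_id) %>%
    arrange(.data$p, .data$seq_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"p") %>%
    arrange(.data$gene_symbol, .data$seq_id)
}

#' Build the full instrument set for one protein
#'
#' Composes the selection chain in the fixed order cis-window and p-value
#' selection (discovery study), LD clumping, estimation-study effect swap,
#' weak-instrument filter, and cross-protein pleiotropy filter. Every stage's
#' input, retained and excluded counts are recorded in the `provenance`
#' attribute; identical inputs yield identical provenance.
#'
#' @param discovery Discovery-study associations for the protein.
#' @param estimation Estimation-study associations for the protein.
#' @param gene One-row tibble/list with `chrom`, `start`, `end`.
#' @param ld An [ld_matrix()] covering the candidate variants.
#' @param all_protein_stats Optional long tibble (`protein`, `variant_id`,
#'   `p`) for the cross-protein pleiotropy filter; skipped when `NULL`.
#' @param target_protein Protein name used by the pleiotropy filter.
#' @param p_threshold,cis_window_bp,r2_threshold,window_kb,f_min Stage
#'   parameters, see the individual filters.
#' @param quiet Suppress per-stage messages.
#' @return Estimation-study instrument tibble with `f_stat`; attributes
#'   `provenance` (stage-wise counts) and `dropped` (per-variant log).
#' @export
build_instruments <- function(discovery, estimation, gene, ld,
                              all_protein_stats = NULL,
                              target_protein = NULL,
                              p_threshold = 5e-8, cis_window_bp = 5e5,
                              r2_threshold = 0.001, window_kb = 10000,
                              f_min = 10, quiet = TRUE) {
  log_rows <- list()
  note <- function(stage, n_in, kept) {
    tibble(stage = stage, n_in = n_in, n_kept = kept,
           n_dropped = n_in - kept)
  }
  drops <- list()

  cis <- select_cis_variants(discovery, gene$chrom, gene$start, gene$end,
                             cis_window_bp, p_threshold)
  log_rows$cis <- note("cis_significance", nrow(discovery), nrow(cis))
  drops$cis <- tibble(
    variant_id = setdiff(discovery$variant_id, cis$variant_id),
    reason = "failed_cis_or_significance")

  clumped <- ld_clump(cis, ld, r2_threshold, window_kb)
  log_rows$clump <- note("ld_clump", nrow(cis), nrow(clumped))
  drops$clump <- tibble(
    variant_id = setdiff(cis$variant_id, clumped$variant_id),
    reason = "ld_clumped")

  est <- split_sample_effects(clumped, estimation, quiet = quiet)
  log_rows$split <- note("estimation_split", nrow(clumped), nrow(est))
  drops$split <- dropped_records(est) %>% select("variant_id", "reason")

  strong <- filter_weak_instruments(est, f_min, quiet = quiet)
  log_rows$f <- note("f_filter", nrow(est), nrow(strong))
  drops$f <- dropped_records(strong)

  out <- strong
  if (!is.null(all_protein_stats)) {
    out <- cross_protein_pleiotropy_filter(strong, target_protein,
                                           all_protein_stats, quiet = quiet)
    log_rows$pleio <- note("cross_protein_pleiotropy", nrow(strong),
                           nrow(out))
    drops$pleio <- dropped_records(out)
  }

  attr(out, "provenance") <- bind_rows(log_rows)
  attr(out, "dropped") <- bind_rows(drops)
  out
}
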