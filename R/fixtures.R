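# Packaged reference data.

#' Published torcetrapib proteogenomic concordance results
#'
#' The reported protein-outcome concordance table from the torcetrapib
#' (ILLUMINATE) proteogenomic analysis: for every protein-outcome pair that
#' survived multiple-testing correction, the instrument count and
#' F-statistic, the trial-observed log2-fold change, the trait change in the
#' trial's active arm (blank cells become `"Unobserved"`), the
#' trial-oriented MR estimate with its standard error and p-value, the
#' printed concordance flag, and the outcome type.
#'
#' Betas are expressed per SD change in protein level *in the direction of
#' the observed protein effect*; binary-outcome betas are log odds ratios.
#'
#' @return A 32-row tibble.
#' @export
torcetrapib_concordance <- function() {
  path <- system.file("extdata", "torcetrapib_concordance.tsv",
                      package = "trialmr", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(),
    seq_id = readr::col_character(),
    outcome = readr::col_character(),
    n_inst = readr::col_integer(),
    f_statistic = readr::col_double(),
    log2_fold_change = readr::col_double(),
    trait_direction = readr::col_character(),
    beta = readr::col_double(),
    se = readr::col_double(),
    p = readr::col_double(),
    concordant = readr::col_integer(),
    outcome_type = readr::col_character()
  ), progress = FALSE) %>%
    mutate(trait_direction = ifelse(is.na(.data$trait_direction),
                                    "Unobserved", .data$trait_direction))
}

#' Replay the concordance classification on the packaged table
#'
#' Recovers the raw per-SD-increase MR estimate from each printed oriented
#' beta, re-applies [orient_to_trial()] and [classify_concordance()], and
#' returns the table with recomputed `oriented_beta` and
#' `concordant_replayed` columns for comparison against the printed flags.
#'
#' @param tbl The table from [torcetrapib_concordance()]; loaded when
#'   omitted.
#' @return The input tibble with `oriented_beta` and `concordant_replayed`.
#' @export
replay_concordance <- function(tbl = torcetrapib_concordance()) {
  raw_beta <- ifelse(tbl$log2_fold_change < 0, -tbl$beta, tbl$beta)
  oriented <- orient_to_trial(raw_beta, tbl$log2_fold_change)
  tbl %>%
    mutate(oriented_beta = oriented,
           concordant_replayed = classify_concordance(oriented,
                                                      tbl$trait_direction))
}
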