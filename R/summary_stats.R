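# Reading, validating and harmonizing GWAS / pQTL summary statistics and the
# trial protein-change tables. All functions return tibbles in the canonical
# column order (variant_id, chrom, pos, ea, oa, beta, se, p, eaf, n); rows that
# fail validation are counted and attached, never silently discarded.

default_column_map <- function() {
  list(
    variant_id = c("variant_id", "snp", "rsid", "id", "markername", "variant"),
    chrom      = c("chrom", "chr", "chromosome"),
    pos        = c("pos", "position", "bp", "base_pair_location"),
    ea         = c("ea", "effect_allele", "a1", "alt", "allele1"),
    oa         = c("oa", "other_allele", "a2", "ref", "allele2",
                   "non_effect_allele"),
    beta       = c("beta", "b", "effect", "effect_size"),
    se         = c("se", "standard_error", "stderr", "sebeta"),
    p          = c("p", "pval", "pvalue", "p_value"),
    eaf        = c("eaf", "effect_allele_frequency", "freq", "af", "maf"),
    n          = c("n", "samplesize", "sample_size", "n_samples"),
    protein    = c("protein", "trait", "phenotype", "exposure")
  )
}

resolve_columns <- function(header, column_map) {
  defaults <- default_column_map()
  if (!is.null(column_map)) {
    column_map <- as.list(column_map)
    for (nm in names(column_map)) defaults[[nm]] <- column_map[[nm]]
  }
  lower <- tolower(header)
  out <- list()
  for (canon in names(defaults)) {
    hit <- match(tolower(defaults[[canon]]), lower)
    hit <- hit[!is.na(hit)]
    if (length(hit) > 0) out[[canon]] <- header[hit[1]]
  }
  out
}

complement_alleles <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

is_palindromic <- function(ea, oa) {
  nchar(ea) == 1L & nchar(oa) == 1L & oa == complement_alleles(ea)
}

#' Read GWAS or pQTL summary statistics
#'
#' Reads a delimited summary-statistics file into the canonical association
#' table. Column names are resolved through `column_map` (GWAS-catalog-style
#' headers are recognized by default). Rows failing validation (non-numeric
#' effect or standard error, `se <= 0`, identical alleles, p outside
#' \[0, 1\], or a p-value grossly inconsistent with the Wald z-statistic) are
#' dropped, counted, and reported via the `"dropped"` attribute (see
#' [dropped_records()]). Missing p-values are imputed from the two-sided
#' normal approximation `2 * pnorm(-|beta/se|)`.
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param column_map Optional named list/character vector mapping canonical
#'   names (`variant_id`, `chrom`, `pos`, `ea`, `oa`, `beta`, `se`, `p`,
#'   `eaf`, `n`, `protein`) to source column names.
#' @param delim Field delimiter; guessed from the first line when `NULL`.
#' @param quiet Suppress the dropped-row message.
#' @return A tibble with columns `variant_id, chrom, pos, ea, oa, beta, se,
#'   p, eaf, n` (plus `protein` when present), attribute `dropped` holding a
#'   tibble of rejected rows with `row` index and `reason`.
#' @export
read_summary_stats <- function(path, column_map = NULL, delim = NULL,
                               quiet = FALSE) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  as_summary_stats(raw, column_map = column_map, quiet = quiet)
}

#' Coerce a data frame to the canonical summary-statistics table
#'
#' Workhorse behind [read_summary_stats()]; usable directly on in-memory
#' data frames.
#'
#' @inheritParams read_summary_stats
#' @param data A data frame with one row per variant association.
#' @return See [read_summary_stats()].
#' @export
as_summary_stats <- function(data, column_map = NULL, quiet = FALSE) {
  cols <- resolve_columns(names(data), column_map)
  required <- c("variant_id", "ea", "oa", "beta", "se")
  missing <- setdiff(required, names(cols))
  if (length(missing) > 0) {
    abort(paste0("required column(s) not found in input: ",
                 paste(missing, collapse = ", "),
                 "; supply them via `column_map`"),
          class = "trialmr_config_error")
  }

  num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  chr <- function(x) as.character(x)
  get <- function(canon) if (canon %in% names(cols)) data[[cols[[canon]]]] else
    rep(NA, nrow(data))

  out <- tibble(
    variant_id = chr(get("variant_id")),
    chrom      = chr(get("chrom")),
    pos        = num(get("pos")),
    ea         = toupper(chr(get("ea"))),
    oa         = toupper(chr(get("oa"))),
    beta       = num(get("beta")),
    se         = num(get("se")),
    p          = num(get("p")),
    eaf        = num(get("eaf")),
    n          = num(get("n"))
  )
  if ("protein" %in% names(cols)) out$protein <- chr(get("protein"))

  raw_beta <- chr(get("beta")); raw_se <- chr(get("se"))
  reason <- rep(NA_character_, nrow(out))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(is.na(out$variant_id) | out$variant_id == "",
                 "missing_variant_id")
  reason <- flag(is.na(out$beta) & !is.na(raw_beta) & raw_beta != "",
                 "non_numeric_beta")
  reason <- flag(is.na(out$se) & !is.na(raw_se) & raw_se != "",
                 "non_numeric_se")
  reason <- flag(is.na(out$beta), "missing_beta")
  reason <- flag(is.na(out$se), "missing_se")
  reason <- flag(out$se <= 0, "nonpositive_se")
  reason <- flag(!grepl("^[ACGT]+$", out$ea) | !grepl("^[ACGT]+$", out$oa),
                 "invalid_alleles")
  reason <- flag(out$ea == out$oa, "identical_alleles")
  reason <- flag(!is.na(out$p) & (out$p < 0 | out$p > 1), "p_out_of_range")
  # impute p from the Wald z when absent, then screen gross inconsistencies
  pz <- 2 * pnorm(-abs(out$beta / out$se))
  out$p <- ifelse(is.na(out$p), pz, out$p)
  inconsistent <- !is.na(out$p) & !is.na(pz) & out$p > 1e-300 & pz > 1e-300 &
    abs(log10(out$p) - log10(pz)) > 2
  reason <- flag(inconsistent, "p_inconsistent_with_z")

  keep <- is.na(reason)
  dropped <- tibble(row = which(!keep), reason = reason[!keep])
  if (nrow(dropped) > 0 && !quiet) {
    tab <- table(dropped$reason)
    inform(paste0("dropped ", nrow(dropped), " of ", nrow(out),
                  " rows failing validation: ",
                  paste(names(tab), tab, sep = "=", collapse = ", ")))
  }
  res <- out[keep, , drop = FALSE]
  attr(res, "dropped") <- dropped
  res
}

#' Dropped-record log of a reader or harmonizer result
#'
#' @param x A tibble returned by [read_summary_stats()], [harmonize()] or
#'   related functions.
#' @return A tibble describing rows removed during validation, with a
#'   `reason` column.
#' @export
dropped_records <- function(x) {
  d <- attr(x, "dropped")
  if (is.null(d)) tibble(reason = character()) else d
}

#' Write summary statistics in the canonical column order
#'
#' @param x Canonical association tibble.
#' @param path Output path; tab-delimited.
#' @export
write_summary_stats <- function(x, path) {
  keep <- c(SUMSTAT_COLS, intersect("protein", names(x)))
  readr::write_tsv(x[, intersect(keep, names(x)), drop = FALSE], path,
                   progress = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure's effect allele for every
#' variant shared between the two tables. The outcome beta is sign-flipped
#' (and its allele frequency complemented) when its effect allele matches the
#' exposure's other allele, directly or after strand complementation.
#' Palindromic variants (A/T or C/G) are resolvable only through allele
#' frequency: they are retained when, after alignment, both frequencies fall
#' on the same side of 0.5 and outside the ambiguity band
#' `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`; otherwise they are
#' dropped with a logged reason, as are palindromic variants with a missing
#' frequency and variants whose alleles cannot be reconciled at all.
#'
#' @param exposure,outcome Canonical association tibbles
#'   (see [read_summary_stats()]) keyed by `variant_id`.
#' @param palindrome_eaf_limit Lower edge of the ambiguity band
#'   (default 0.42, a common harmonization convention).
#' @param quiet Suppress the summary message.
#' @return A tibble of paired associations with exposure columns
#'   `beta_exp, se_exp, p_exp, eaf_exp, n_exp` and outcome columns
#'   `beta_out, se_out, p_out, eaf_out, n_out`, alleles as coded in the
#'   exposure; attribute `dropped` logs removed variants and reasons.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                      quiet = FALSE) {
  stopifnot(palindrome_eaf_limit > 0, palindrome_eaf_limit < 0.5)
  exp_t <- as_tibble(exposure)
  out_t <- as_tibble(outcome)
  shared <- inner_join(
    exp_t, out_t,
    by = "variant_id", suffix = c("_exp", "_out"),
    relationship = "one-to-one"
  )
  if (nrow(shared) == 0) {
    if (!quiet) warn("no shared variants between exposure and outcome")
    res <- shared
    attr(res, "dropped") <- tibble(variant_id = character(),
                                   reason = character())
    return(res)
  }

  pick <- function(col, side = "_exp") {
    suff <- paste0(col, side)
    if (suff %in% names(shared)) shared[[suff]]
    else if (col %in% names(shared)) shared[[col]]
    else rep(NA_real_, nrow(shared))
  }
  ea_e <- shared$ea_exp; oa_e <- shared$oa_exp
  ea_o <- shared$ea_out; oa_o <- shared$oa_out
  pal <- is_palindromic(ea_e, oa_e)

  direct      <- ea_o == ea_e & oa_o == oa_e
  swapped     <- ea_o == oa_e & oa_o == ea_e
  strand      <- !pal & complement_alleles(ea_o) == ea_e &
                        complement_alleles(oa_o) == oa_e
  strand_swap <- !pal & complement_alleles(ea_o) == oa_e &
                        complement_alleles(oa_o) == ea_e

  flip <- (swapped | strand_swap) & !direct
  matched <- direct | swapped | strand | strand_swap

  eaf_e <- pick("eaf"); eaf_o_raw <- pick("eaf", "_out")
  beta_out <- ifelse(flip, -pick("beta", "_out"), pick("beta", "_out"))
  eaf_out <- ifelse(flip & !is.na(eaf_o_raw), 1 - eaf_o_raw, eaf_o_raw)

  reason <- rep(NA_character_, nrow(shared))
  reason[!matched] <- "allele_mismatch"
  pal_missing <- matched & pal & (is.na(eaf_e) | is.na(eaf_out))
  reason[pal_missing] <- "palindromic_missing_eaf"
  lo <- palindrome_eaf_limit; hi <- 1 - palindrome_eaf_limit
  outside_band <- function(f) f < lo | f > hi
  pal_check <- matched & pal & !pal_missing
  ambiguous <- pal_check &
    !(outside_band(eaf_e) & outside_band(eaf_out) &
        sign(eaf_e - 0.5) == sign(eaf_out - 0.5))
  reason[ambiguous] <- "palindromic_ambiguous"

  keep <- is.na(reason)
  res <- tibble(
    variant_id = shared$variant_id,
    chrom = pick("chrom"),
    pos = pick("pos"),
    ea = ea_e, oa = oa_e,
    beta_exp = pick("beta"), se_exp = pick("se"),
    p_exp = pick("p"), eaf_exp = eaf_e, n_exp = pick("n"),
    beta_out = beta_out, se_out = pick("se", "_out"),
    p_out = pick("p", "_out"), eaf_out = eaf_out, n_out = pick("n", "_out")
  )[keep, , drop = FALSE]

  dropped <- tibble(variant_id = shared$variant_id[!keep],
                    reason = reason[!keep])
  unshared <- sum(nrow(exp_t) - nrow(shared))
  if (!quiet && (nrow(dropped) > 0 || unshared > 0)) {
    tab <- table(dropped$reason)
    inform(paste0("harmonized ", nrow(res), "/", nrow(exp_t),
                  " exposure variants (", unshared, " absent from outcome",
                  if (nrow(dropped) > 0)
                    paste0("; dropped: ",
                           paste(names(tab), tab, sep = "=", collapse = ", ")),
                  ")"))
  }
  attr(res, "dropped") <- dropped
  res
}

#' Direction of a trial-observed protein change
#'
#' @param log2_fold_change Numeric vector of log2-fold changes.
#' @return Character vector: `"Up"` for positive, `"Down"` for negative,
#'   `NA` for an exact zero (no direction is defined).
#' @export
trial_direction <- function(log2_fold_change) {
  ifelse(log2_fold_change > 0, "Up",
         ifelse(log2_fold_change < 0, "Down", NA_character_))
}

#' Read a trial protein-change table
#'
#' One row per aptamer: UniProt ID, gene symbol, aptamer SeqID, log2-fold
#' change between baseline and on-treatment measurements, and FDR p-value.
#'
#' @param path Delimited file with columns resolvable to `uniprot_id`,
#'   `gene_symbol`, `seq_id`, `log2_fold_change`, `fdr_p`.
#' @param delim Field delimiter; guessed when `NULL`.
#' @return A tibble with those columns plus `direction`
#'   (see [trial_direction()]).
#' @export
read_trial_effects <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  syn <- list(uniprot_id = c("uniprot_id", "uniprot"),
              gene_symbol = c("gene_symbol", "gene", "symbol"),
              seq_id = c("seq_id", "seqid", "aptamer"),
              log2_fold_change = c("log2_fold_change", "log2fc", "l2fc",
                                   "logfc"),
              fdr_p = c("fdr_p", "fdr", "qvalue", "padj"))
  cols <- resolve_columns(names(raw), syn)
  missing <- setdiff(names(syn), names(cols))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "trialmr_config_error")
  }
  out <- tibble(
    uniprot_id = as.character(raw[[cols$uniprot_id]]),
    gene_symbol = as.character(raw[[cols$gene_symbol]]),
    seq_id = as.character(raw[[cols$seq_id]]),
    log2_fold_change = as.numeric(raw[[cols$log2_fold_change]]),
    fdr_p = as.numeric(raw[[cols$fdr_p]])
  )
  dup <- unique(out$seq_id[duplicated(out$seq_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate seq_id(s) in trial table: ",
                 paste(dup, collapse = ", ")),
          class = "trialmr_validation_error")
  }
  if (any(!is.finite(out$log2_fold_change))) {
    abort("non-finite log2_fold_change in trial table",
          class = "trialmr_validation_error")
  }
  out$direction <- trial_direction(out$log2_fold_change)
  out
}

#' Read trial outcome-direction annotations
#'
#' @param path Delimited file with columns `outcome`, `direction`
#'   (Up/Down/Unobserved; blank cells become Unobserved) and optionally
#'   `outcome_type` (continuous/binary).
#' @param delim Field delimiter; guessed when `NULL`.
#' @return A tibble with `outcome`, `direction`, `outcome_type`.
#' @export
read_outcome_directions <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  nm <- tolower(names(raw))
  oc <- raw[[which(nm %in% c("outcome", "outcome_name", "trait"))[1]]]
  dir <- raw[[which(nm %in% c("direction", "trait_direction", "trait_change"))[1]]]
  dir <- ifelse(is.na(dir) | dir == "", "Unobserved", dir)
  bad <- setdiff(unique(dir), c("Up", "Down", "Unobserved"))
  if (length(bad) > 0) {
    abort(paste0("invalid outcome direction(s): ", paste(bad, collapse = ", ")),
          class = "trialmr_validation_error")
  }
  type <- if (any(nm %in% c("outcome_type", "type")))
    raw[[which(nm %in% c("outcome_type", "type"))[1]]] else
      rep("continuous", nrow(raw))
  out <- tibble(outcome = as.character(oc), direction = dir,
                outcome_type = as.character(type))
  dup <- unique(out$outcome[duplicated(out$outcome)])
  if (length(dup) > 0) {
    abort(paste0("duplicate outcome(s) in direction table: ",
                 paste(dup, collapse = ", ")),
          class = "trialmr_validation_error")
  }
  out
}
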