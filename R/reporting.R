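# Configuration handling, the three pipeline entry points (simulate,
# forward, reverse) and structured run manifests. Every effective parameter,
# input checksum and stage-wise inclusion/exclusion count is echoed into the
# manifest so a run is fully auditable and reproducible.

default_params <- function() {
  list(p_instrument = 5e-8, clump_r2 = 0.001, clump_window_kb = 10000,
       cis_window_bp = 5e5, f_min = 10, alpha = 0.05,
       palindrome_eaf_limit = 0.42, seed = 1L, bootstrap_reps = 1000,
       presso_sims = 1000, sensitivity = TRUE)
}

#' Read a pipeline configuration file
#'
#' YAML with two blocks: `inputs` (file paths) and `params` (thresholds and
#' seeds; missing keys take package defaults).
#'
#' @param path Path to a YAML configuration, or an already-parsed list.
#' @param required_inputs Character vector of input keys that must resolve.
#' @return List with `inputs` and `params`.
#' @export
read_config <- function(path, required_inputs = character()) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  config$params <- modifyList(default_params(), config$params %||% list())
  missing <- setdiff(required_inputs, names(config$inputs %||% list()))
  if (length(missing) > 0) {
    abort(paste0("configuration is missing required input key(s): ",
                 paste(missing, collapse = ", ")),
          class = "trialmr_config_error")
  }
  for (key in required_inputs) {
    p <- config$inputs[[key]]
    paths <- if (is.list(p)) unlist(p) else p
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0) {
      abort(paste0("input file(s) for `", key, "` not found: ",
                   paste(absent, collapse = ", ")),
            class = "trialmr_config_error")
    }
  }
  config
}

flatten_config <- function(x, prefix = NULL) {
  out <- character()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste0(prefix, ".", nm)
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, flatten_config(v, key))
    else out <- c(out, setNames(paste(format(v, digits = 15), collapse = ","),
                                key))
  }
  out
}

#' Write a run manifest
#'
#' Key-value text: the effective configuration, md5 checksums of every
#' input, seeds, stage-wise inclusion/exclusion counts, and a timestamp
#' (last line, so byte-comparisons of reruns can exclude it).
#'
#' @param path Output file.
#' @param config Configuration list (already resolved).
#' @param input_paths Named character vector of input files to checksum.
#' @param counts Tibble with columns `stage`, `n_in`, `n_kept`, `n_dropped`.
#' @param extra Named list of additional scalar entries.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, input_paths = character(),
                           counts = NULL, extra = list()) {
  lines <- c(paste0("config.", names(flatten_config(config)), "=",
                    unname(flatten_config(config))))
  if (length(input_paths) > 0) {
    sums <- tools::md5sum(input_paths)
    lines <- c(lines, paste0("input.", names(input_paths), ".md5=",
                             unname(sums)))
  }
  if (!is.null(counts) && nrow(counts) > 0) {
    lines <- c(lines,
               paste0("count.", counts$stage, ".in=", counts$n_in),
               paste0("count.", counts$stage, ".kept=", counts$n_kept),
               paste0("count.", counts$stage, ".dropped=", counts$n_dropped))
  }
  for (nm in names(extra)) {
    lines <- c(lines, paste0(nm, "=", format(extra[[nm]], digits = 15)))
  }
  lines <- c(lines, paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a manifest back into a named character vector
#'
#' @param path Manifest file written by [write_manifest()].
#' @return Named character vector.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
           vapply(kv, `[[`, character(1), 1))
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(paste0("output directory ", out_dir,
                 " is not empty; use force = TRUE to overwrite"),
          class = "trialmr_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' Simulate a full synthetic dataset bundle to disk
#'
#' Writes discovery/estimation pQTL tables, per-outcome GWAS tables, the LD
#' matrix, gene annotation, trial tables, lipid-MR results and truth
#' records in the delimited formats the readers consume, plus a manifest.
#'
#' @param config Configuration list or YAML path; scenario parameters live
#'   under the `scenario` key (see [simulation_scenario()]); a `--seed`
#'   style override can be given via `seed`.
#' @param out_dir Target directory.
#' @param force Overwrite a non-empty target.
#' @param seed Optional seed overriding the scenario's.
#' @return The bundle (invisibly), after writing.
#' @export
cmd_simulate <- function(config = list(), out_dir, force = FALSE,
                         seed = NULL) {
  config <- if (is.character(config)) yaml::read_yaml(config) else config
  prepare_out_dir(out_dir, force)
  sc_args <- config$scenario %||% list()
  if (!is.null(seed)) sc_args$seed <- seed
  scenario <- do.call(simulation_scenario, sc_args)
  bundle <- simulate_study(scenario)

  fp <- function(name) file.path(out_dir, name)
  write_summary_stats(bundle$discovery, fp("discovery.tsv"))
  write_summary_stats(bundle$estimation, fp("estimation.tsv"))
  for (oc in names(bundle$outcomes)) {
    write_summary_stats(bundle$outcomes[[oc]], fp(paste0(oc, ".tsv")))
  }
  write_ld_matrix(bundle$ld, fp("ld.tsv"))
  readr::write_tsv(bundle$genes, fp("genes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$trial_effects %>% select(-"direction"),
                   fp("trial_effects.tsv"), progress = FALSE)
  readr::write_tsv(bundle$outcome_directions, fp("outcome_directions.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$lipid_mr, fp("lipid_mr.tsv"), progress = FALSE)
  readr::write_tsv(bundle$truth$variants, fp("truth_variants.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$truth$theta, fp("truth_theta.tsv"),
                   progress = FALSE)
  write_manifest(fp("manifest.txt"),
                 list(scenario = scenario[setdiff(names(scenario),
                                                  "true_causal_effects")]),
                 counts = NULL,
                 extra = list(n_variants = nrow(bundle$truth$variants)))
  invisible(bundle)
}

read_long_stats <- function(path) {
  x <- read_summary_stats(path, quiet = TRUE)
  if (!"protein" %in% names(x)) {
    abort(paste0("expected a `protein` column in ", path),
          class = "trialmr_config_error")
  }
  x
}

#' Run the forward pipeline from a configuration
#'
#' Instrument selection (cis significance, clumping, estimation-study swap,
#' F and cross-protein pleiotropy filters) for every off-target protein,
#' forward MR over all protein-outcome pairs, orientation, Bonferroni
#' correction, concordance classification, and Table-style outputs plus a
#' manifest with full stage accounting.
#'
#' @param config YAML path or list; required inputs: `discovery`,
#'   `estimation` (long tables with a `protein` column), `outcomes` (named
#'   map of outcome GWAS paths), `genes`, `ld`, `trial_effects`; optional:
#'   `outcome_directions`, `lipid_mr`.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty target.
#' @param seed Optional override of `params$seed`.
#' @return The `mr_forward` object (invisibly), after writing
#'   `results.tsv`, `concordance.tsv`, `sensitivity.tsv`, `exclusions.tsv`
#'   and `manifest.txt`.
#' @export
cmd_forward <- function(config, out_dir, force = FALSE, seed = NULL) {
  config <- read_config(config, required_inputs =
                          c("discovery", "estimation", "outcomes", "genes",
                            "ld", "trial_effects"))
  if (!is.null(seed)) config$params$seed <- seed
  prm <- config$params
  prepare_out_dir(out_dir, force)

  discovery <- read_long_stats(config$inputs$discovery)
  estimation <- read_long_stats(config$inputs$estimation)
  outcome_stats <- lapply(config$inputs$outcomes, read_summary_stats,
                          quiet = TRUE)
  genes <- readr::read_tsv(config$inputs$genes,
                           col_types = readr::cols(), progress = FALSE)
  ld <- read_ld_matrix(config$inputs$ld)
  trial <- read_trial_effects(config$inputs$trial_effects)
  dirs <- if (!is.null(config$inputs$outcome_directions))
    read_outcome_directions(config$inputs$outcome_directions) else NULL

  counts <- list()
  if (!is.null(config$inputs$lipid_mr)) {
    lipid_mr <- readr::read_tsv(config$inputs$lipid_mr,
                                col_types = readr::cols(), progress = FALSE)
    part <- exclude_lipid_mediated(trial, lipid_mr, prm$alpha)
    counts$lipid <- tibble(stage = "lipid_exclusion", n_in = nrow(trial),
                           n_kept = nrow(part$off_target),
                           n_dropped = nrow(part$on_target))
    trial <- part$off_target
  }

  all_p <- discovery %>% select("protein", "variant_id", "p")
  instruments <- list()
  prov <- list()
  for (pr in intersect(trial$gene_symbol, genes$protein)) {
    gene <- genes[genes$protein == pr, , drop = FALSE]
    inst <- build_instruments(
      discovery %>% filter(.data$protein == pr),
      estimation %>% filter(.data$protein == pr),
      gene, ld, all_protein_stats = all_p, target_protein = pr,
      p_threshold = prm$p_instrument, cis_window_bp = prm$cis_window_bp,
      r2_threshold = prm$clump_r2, window_kb = prm$clump_window_kb,
      f_min = prm$f_min, quiet = TRUE)
    instruments[[pr]] <- inst
    prov[[pr]] <- attr(inst, "provenance")
  }
  stage_counts <- bind_rows(prov) %>%
    group_by(.data$stage) %>%
    summarise(n_in = sum(.data$n_in), n_kept = sum(.data$n_kept),
              n_dropped = sum(.data$n_dropped), .groups = "drop")
  counts$stages <- stage_counts

  fwd <- withCallingHandlers(
    run_forward_mr(trial, instruments, outcome_stats, dirs,
                   alpha = prm$alpha,
                   palindrome_eaf_limit = prm$palindrome_eaf_limit,
                   sensitivity = isTRUE(prm$sensitivity),
                   bootstrap_reps = prm$bootstrap_reps,
                   presso_sims = prm$presso_sims, seed = prm$seed),
    warning = function(w) invokeRestart("muffleWarning"))

  fp <- function(name) file.path(out_dir, name)
  readr::write_tsv(fwd$results, fp("results.tsv"), progress = FALSE)
  readr::write_tsv(fwd$concordance, fp("concordance.tsv"), progress = FALSE)
  if (!is.null(fwd$sensitivity)) {
    readr::write_tsv(fwd$sensitivity, fp("sensitivity.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(fwd$excluded, fp("exclusions.tsv"), progress = FALSE)

  inputs <- unlist(config$inputs)
  write_manifest(fp("manifest.txt"), config, setNames(inputs, names(inputs)),
                 counts = bind_rows(counts),
                 extra = list(n_tests = fwd$n_tests,
                              threshold = fwd$threshold,
                              n_significant = nrow(fwd$concordance),
                              seed = prm$seed))
  invisible(fwd)
}

#' Run the reverse pipeline from a configuration
#'
#' Genome-wide significant instruments for each health outcome (no cis
#' restriction), clumped with the same parameters as the forward run, then
#' reverse MR of every outcome on every protein with Bonferroni correction;
#' writes per-outcome significant-protein sets and the intersection-count
#' table behind upset-style summaries.
#'
#' @param config YAML path or list; required inputs: `outcomes` (named
#'   map), `estimation` (long protein table), `ld`.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty target.
#' @param seed Optional override of `params$seed`.
#' @return The `mr_reverse` object (invisibly), after writing
#'   `reverse_results.tsv`, `reverse_sets.tsv`, `intersections.tsv` and
#'   `manifest.txt`.
#' @export
cmd_reverse <- function(config, out_dir, force = FALSE, seed = NULL) {
  config <- read_config(config, required_inputs =
                          c("outcomes", "estimation", "ld"))
  if (!is.null(seed)) config$params$seed <- seed
  prm <- config$params
  prepare_out_dir(out_dir, force)

  estimation <- read_long_stats(config$inputs$estimation)
  ld <- read_ld_matrix(config$inputs$ld)
  protein_stats <- split(estimation, estimation$protein)

  instruments <- list()
  prov <- list()
  for (oc in names(config$inputs$outcomes)) {
    stats <- read_summary_stats(config$inputs$outcomes[[oc]], quiet = TRUE)
    sel <- stats %>% filter(.data$p < prm$p_instrument)
    clumped <- suppressWarnings(
      ld_clump(sel, ld, prm$clump_r2, prm$clump_window_kb))
    strong <- filter_weak_instruments(clumped, prm$f_min, quiet = TRUE)
    instruments[[oc]] <- strong
    prov[[oc]] <- tibble(
      stage = c("significance", "ld_clump", "f_filter"),
      n_in = c(nrow(stats), nrow(sel), nrow(clumped)),
      n_kept = c(nrow(sel), nrow(clumped), nrow(strong)))
  }
  stage_counts <- bind_rows(prov) %>%
    mutate(n_dropped = .data$n_in - .data$n_kept) %>%
    group_by(.data$stage) %>%
    summarise(n_in = sum(.data$n_in), n_kept = sum(.data$n_kept),
              n_dropped = sum(.data$n_dropped), .groups = "drop")

  rev <- run_reverse_mr(instruments, protein_stats, alpha = prm$alpha,
                        palindrome_eaf_limit = prm$palindrome_eaf_limit)

  fp <- function(name) file.path(out_dir, name)
  readr::write_tsv(rev$results, fp("reverse_results.tsv"), progress = FALSE)
  sets_tbl <- purrr::imap(rev$sets, ~tibble(outcome = .y, protein = .x)) %>%
    bind_rows()
  if (nrow(sets_tbl) == 0) sets_tbl <- tibble(outcome = character(),
                                              protein = character())
  readr::write_tsv(sets_tbl, fp("reverse_sets.tsv"), progress = FALSE)
  readr::write_tsv(rev$counts$combinations, fp("intersections.tsv"),
                   progress = FALSE)

  inputs <- unlist(config$inputs)
  write_manifest(fp("manifest.txt"), config, setNames(inputs, names(inputs)),
                 counts = stage_counts,
                 extra = list(n_tests = rev$n_tests,
                              threshold = rev$threshold,
                              n_union = rev$counts$n_union,
                              seed = prm$seed))
  invisible(rev)
}
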