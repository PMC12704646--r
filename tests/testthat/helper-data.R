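# Shared builders for small, fully specified inputs.

# canonical association tibble with defaults chosen to pass validation
make_assocs <- function(n = 4, beta = 0.3, se = 0.02, chrom = "1",
                        pos = NULL, p = NULL, eaf = 0.3,
                        variant_id = NULL) {
  tibble::tibble(
    variant_id = variant_id %||% sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = pos %||% (1e6 + 1000 * seq_len(n)),
    ea = "A", oa = "G",
    beta = rep_len(beta, n), se = rep_len(se, n),
    p = p %||% (2 * stats::pnorm(-abs(rep_len(beta, n) / rep_len(se, n)))),
    eaf = rep_len(eaf, n), n = 10000
  )
}

# harmonized instrument table with known exposure/outcome effects
make_pairs <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.02) {
  n <- length(beta_exp)
  tibble::tibble(
    variant_id = sprintf("rs%03d", seq_len(n)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, n),
    beta_out = beta_out, se_out = rep_len(se_out, n)
  )
}

# pairs drawn around a true slope with iid noise
random_pairs <- function(n, slope, se_exp = 0.02, se_out = 0.02,
                         seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  bx_true <- stats::runif(n, 0.15, 0.5)
  make_pairs(
    beta_exp = bx_true + stats::rnorm(n, 0, se_exp),
    beta_out = slope * bx_true + stats::rnorm(n, 0, se_out),
    se_exp = se_exp, se_out = se_out
  )
}

# identity LD matrix over the given ids
identity_ld <- function(ids) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  trialmr::ld_matrix(m)
}

write_tmp_tsv <- function(x, name = "tmp.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(x, path, progress = FALSE)
  path
}

`%||%` <- rlang::`%||%`
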