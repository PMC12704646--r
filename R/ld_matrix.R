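# Small container for pairwise linkage-disequilibrium (r^2) matrices used by
# the clumping step.

#' Construct an LD (r-squared) matrix
#'
#' @param r2 Square numeric matrix of pairwise r-squared values with unit
#'   diagonal; `variant_ids` supplies dimnames when the matrix has none.
#' @param variant_ids Optional character vector of variant identifiers.
#' @return An object of class `ld_matrix` (a named square matrix).
#' @export
ld_matrix <- function(r2, variant_ids = NULL) {
  r2 <- as.matrix(r2)
  if (!is.null(variant_ids)) dimnames(r2) <- list(variant_ids, variant_ids)
  if (is.null(rownames(r2))) {
    abort("LD matrix needs variant identifiers (dimnames or variant_ids)",
          class = "trialmr_validation_error")
  }
  if (nrow(r2) != ncol(r2) || !isTRUE(all.equal(r2, t(r2), tolerance = 1e-8))) {
    abort("LD matrix must be square and symmetric",
          class = "trialmr_validation_error")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    abort("LD matrix diagonal must be 1", class = "trialmr_validation_error")
  }
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8)) {
    abort("r-squared values must lie in [0, 1]",
          class = "trialmr_validation_error")
  }
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from disk
#'
#' Accepts either a square matrix layout (header row and first column of
#' variant ids) or long-format triplets with columns `id1`, `id2`, `r2`
#' (absent pairs default to r-squared 0).
#'
#' @param path Tab- or comma-delimited file.
#' @param delim Field delimiter; guessed when `NULL`.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  nm <- tolower(names(raw))
  if (ncol(raw) == 3 && all(c("id1", "id2", "r2") %in% nm)) {
    ids <- sort(unique(c(raw[[which(nm == "id1")]], raw[[which(nm == "id2")]])))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    i <- match(raw[[which(nm == "id1")]], ids)
    j <- match(raw[[which(nm == "id2")]], ids)
    v <- raw[[which(nm == "r2")]]
    m[cbind(i, j)] <- v
    m[cbind(j, i)] <- v
    diag(m) <- 1
    return(ld_matrix(m))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, ids)
  ld_matrix(m)
}

#' Write an LD matrix in square layout
#'
#' @param ld An [ld_matrix()] object.
#' @param path Output path; tab-delimited with a leading `variant_id` column.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- as.data.frame(unclass(ld))
  df <- cbind(variant_id = rownames(ld), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}
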