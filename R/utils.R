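# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package takes an explicit seed and
# funnels through here, so no function disturbs the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

norm_mirna <- function(x) tolower(trimws(as.character(x)))

norm_disease_key <- function(x) tolower(trimws(as.character(x)))

# Full-precision numeric formatting so TSV round-trips are exact.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a labelled numeric matrix to TSV
#'
#' Writes a matrix with row and column identifiers (first header cell `id`)
#' at full double precision, so that [read_matrix_tsv()] restores it exactly.
#'
#' @param m numeric matrix with `dimnames`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' @param path file written by [write_matrix_tsv()].
#' @return numeric matrix with `dimnames`.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
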