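# The disease-vector model: signed, DSW-penalized miRNA weights and pairwise
# Tanimoto similarity between disease vectors.

#' Signed, DSW-penalized weight of one miRNA in one disease
#'
#' The weight of miRNA j in disease i is the signed sum of its up/down
#' records multiplied by an IDF-style penalty on the miRNA's disease spectrum
#' width (DSW) n_j, the number of distinct diseases it is recorded in:
#'
#'   w = (up - down) * log(N / n_j)
#'
#' Pan-disease miRNAs (n_j = N) are annihilated by the penalty; pairs with no
#' records at all have weight exactly 0.
#'
#' @param up_count number of up-regulation records for the pair.
#' @param down_count number of down-regulation records for the pair.
#' @param N total number of diseases in the curated dataset.
#' @param n_j disease spectrum width of the miRNA (1 <= n_j <= N).
#' @param log_base base of the penalty logarithm (default natural log; the
#'   similarity layer is provably invariant to this choice).
#' @return the weight, a single double; exactly 0 when there are no records.
#' @export
mirna_weight <- function(up_count, down_count, N, n_j, log_base = exp(1)) {
  stopifnot(up_count >= 0, down_count >= 0, N >= 1, log_base > 0)
  if (up_count + down_count == 0) return(0)
  if (n_j < 1 || n_j > N) {
    stop("n_j must satisfy 1 <= n_j <= N (got n_j = ", n_j, ", N = ", N, ")")
  }
  (up_count - down_count) * log(N / n_j, base = log_base)
}

#' Build the signed miRNA-by-disease weight matrix
#'
#' Rows are miRNAs (M), columns are diseases (N); entry (j, i) is
#' [mirna_weight()] computed over the curated records. The sparsity pattern
#' equals the record support minus the rows of pan-disease miRNAs, whose
#' penalty log(N/N) = 0 wipes the whole row. Column i is the disease vector
#' used for similarity.
#'
#' @param dataset a `curated_dataset`.
#' @param log_base penalty logarithm base, recorded as metadata.
#' @return an object of class `weight_matrix`: list with `values` (M x N
#'   matrix with miRNA rownames and disease colnames) and `log_base`.
#' @export
build_weight_matrix <- function(dataset, log_base = exp(1)) {
  stopifnot(inherits(dataset, "curated_dataset"), log_base > 0)
  W <- matrix(0, nrow = dataset$M, ncol = dataset$N,
              dimnames = list(dataset$mirnas, dataset$diseases))
  pc <- dataset$pair_counts
  penalty <- log(dataset$N / dataset$n_j[pc$mirna], base = log_base)
  W[cbind(match(pc$mirna, dataset$mirnas),
          match(pc$disease, dataset$diseases))] <-
    (pc$up - pc$down) * penalty
  structure(list(values = W, log_base = log_base), class = "weight_matrix")
}

#' Tanimoto similarity of two real vectors
#'
#' S(x, y) = x.y / (|x|^2 + |y|^2 - x.y). For real vectors the value lies in
#' \[-1/3, 1\]: S(x, x) = 1 and S(x, -x) = -1/3. Unlike the cosine, it shrinks
#' when the two vectors differ in norm, damping the apparent similarity
#' between well-studied and sparsely-studied diseases. If both vectors are
#' zero the similarity carries no information and `NA` is returned (never a
#' silent 0, which is reserved for "no shared support").
#'
#' @param x,y numeric vectors of equal length.
#' @return a single double in \[-1/3, 1\], or `NA_real_` if both vectors are
#'   all-zero.
#' @export
tanimoto <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  dot <- sum(x * y)
  denom <- sum(x * x) + sum(y * y) - dot
  if (denom == 0) return(NA_real_)  # only possible when x == y == 0
  dot / denom
}

#' Pairwise Tanimoto similarity between all disease vectors
#'
#' Computes the full symmetric N x N similarity matrix from a weight matrix.
#' Diseases whose weight vector is identically zero (no records, or every
#' associated miRNA annihilated by the DSW penalty) carry no information:
#' their rows and columns are `NA`. A similarity of exactly 0 means the two
#' diseases share no weighted miRNA support.
#'
#' @param w a `weight_matrix`.
#' @return an object of class `similarity_matrix`: list with `values`
#'   (symmetric matrix, unit diagonal on informative diseases) and `ids`.
#' @export
pairwise_similarity <- function(w) {
  stopifnot(inherits(w, "weight_matrix"))
  W <- w$values
  G <- crossprod(W)               # pairwise dot products
  n2 <- diag(G)                   # squared norms
  S <- G / (outer(n2, n2, "+") - G)
  zero <- n2 == 0
  S[zero, ] <- NA_real_
  S[, zero] <- NA_real_
  diag(S)[!zero] <- 1
  structure(list(values = S, ids = colnames(W)), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- length(x$ids)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("Disease similarity matrix: %d diseases, %d informative pairs\n",
              n, sum(!is.na(off))))
  if (any(!is.na(off))) {
    cat(sprintf("  off-diagonal range: [%.4f, %.4f]\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
  invisible(x)
}
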