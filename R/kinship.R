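# Genomic relationship matrices and positive-definite repair.

#' Additive genomic relationship matrix
#'
#' VanRaden-style additive relationship matrix from the Cockerham additive
#' incidence matrix:
#' \deqn{A = W_A W_A' / (2 \sum_k p_k (1 - p_k))}
#' The scaling makes the average diagonal approach 1 + mean inbreeding for a
#' population in Hardy-Weinberg proportions at the coding frequencies.
#'
#' @param W_A Additive incidence matrix (individuals x loci), or an
#'   `"incidence_pair"` from [code_cockerham()].
#' @param p Allele frequencies used for the coding (one per locus).
#' @return Symmetric n x n matrix with attributes `flavor` and `repaired`.
#' @export
additive_grm <- function(W_A, p) {
  if (inherits(W_A, "incidence_pair")) {
    p <- W_A$p
    W_A <- W_A$W_A
  }
  grm_impl(W_A, denom = 2 * sum(p * (1 - p)), flavor = "additive")
}

#' Dominance genomic relationship matrix
#'
#' Dominance analogue of [additive_grm()]:
#' \deqn{D = W_D W_D' / (4 \sum_k (p_k (1 - p_k))^2)}
#'
#' @param W_D Dominance incidence matrix, or an `"incidence_pair"`.
#' @inheritParams additive_grm
#' @return Symmetric n x n matrix with attributes `flavor` and `repaired`.
#' @export
dominance_grm <- function(W_D, p) {
  if (inherits(W_D, "incidence_pair")) {
    p <- W_D$p
    W_D <- W_D$W_D
  }
  grm_impl(W_D, denom = 4 * sum((p * (1 - p))^2), flavor = "dominance")
}

grm_impl <- function(W, denom, flavor) {
  if (!is.matrix(W) || !is.numeric(W)) {
    abort("The incidence matrix must be numeric.")
  }
  if (denom <= 0) {
    abort("All loci are monomorphic: the relationship denominator is zero.")
  }
  K <- tcrossprod(W) / denom
  K <- symmetrize(K)
  dimnames(K) <- list(rownames(W), rownames(W))
  attr(K, "flavor") <- flavor
  attr(K, "repaired") <- FALSE
  K
}

#' Repair a relationship matrix to positive definiteness
#'
#' Marker-based relationship matrices can be singular or indefinite (e.g.
#' with duplicated individuals or fewer markers than individuals). The
#' matrix is eigendecomposed and every non-positive eigenvalue is replaced
#' by a small strictly positive constant of decreasing magnitude: with `r`
#' replacements the least-negative original eigenvalue receives `floor`,
#' the next `floor * (r-1)/r`, and so on down to `floor / r`. Positive
#' eigenvalues (and their eigenvectors) are untouched, so the repaired
#' matrix differs from the input only on the repaired eigenspace.
#'
#' @param k Symmetric relationship matrix.
#' @param floor Largest replacement eigenvalue (default `1e-4`).
#' @param sym_tol Largest tolerated relative Frobenius asymmetry.
#' @return Positive-definite matrix; attribute `repaired` records whether
#'   any eigenvalue was replaced, `eigen_floor` the floor used, and
#'   `n_replaced` how many were replaced. Eigenvalues within numerical
#'   noise of zero (below `1e-8` of the spectral radius) count as
#'   non-positive, so rank-deficient cross-product matrices become
#'   well-conditioned after repair.
#' @export
make_positive_definite <- function(k, floor = 1e-4, sym_tol = 1e-8) {
  if (!is.matrix(k) || nrow(k) != ncol(k)) {
    abort("`k` must be a square matrix.")
  }
  if (asymmetry(k) > sym_tol) {
    abort("`k` is not symmetric within tolerance.")
  }
  flavor <- attr(k, "flavor")
  km <- symmetrize(unclass(k))
  eig <- eigen(km, symmetric = TRUE)
  # eigenvalues numerically indistinguishable from zero (rank-deficient
  # cross-products) are treated as non-positive too
  zero_tol <- max(abs(eig$values)) * 1e-8
  bad <- which(eig$values <= zero_tol)
  if (length(bad) == 0L) {
    attr(k, "repaired") <- FALSE
    attr(k, "eigen_floor") <- floor
    attr(k, "n_replaced") <- 0L
    return(k)
  }
  r <- length(bad)
  # eigen() sorts descending, so `bad` is already ordered from the
  # least-negative replaced value downwards.
  vals <- eig$values
  vals[bad] <- floor * (r:1) / r
  out <- eig$vectors %*% (vals * t(eig$vectors))
  out <- symmetrize(out)
  dimnames(out) <- dimnames(km)
  attr(out, "flavor") <- flavor
  attr(out, "repaired") <- TRUE
  attr(out, "eigen_floor") <- floor
  attr(out, "n_replaced") <- r
  out
}

is_positive_definite <- function(k, tol = 0) {
  ev <- eigen(symmetrize(unclass(k)), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

#' Read / write a square relationship matrix as CSV
#'
#' Square CSV with ids in the header row and first column.
#'
#' @param k Relationship matrix.
#' @param path File path.
#' @export
write_grm <- function(k, path) {
  df <- data.frame(id = rownames(k), unclass(k), check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
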