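# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif rbinom rbeta var cov cor complete.cases kmeans sd
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded operations never perturb it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) * 48271 + 7919 * offset) %% 2147483587)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}

# Dense block diagonal of a list of matrices.
block_diag <- function(mats) {
  mats <- mats[!vapply(mats, is.null, logical(1))]
  nr <- vapply(mats, nrow, integer(1))
  nc <- vapply(mats, ncol, integer(1))
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- c(0L, cumsum(nr))
  c0 <- c(0L, cumsum(nc))
  for (i in seq_along(mats)) {
    out[(r0[i] + 1L):r0[i + 1L], (c0[i] + 1L):c0[i + 1L]] <- mats[[i]]
  }
  out
}

symmetrize <- function(m) (m + t(m)) / 2

# Relative Frobenius asymmetry; 0 for exactly symmetric matrices.
asymmetry <- function(m) {
  denom <- sqrt(sum(m^2))
  if (denom == 0) {
    return(0)
  }
  sqrt(sum((m - t(m))^2)) / denom
}

is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

default_trait_names <- function(n_traits) {
  if (n_traits == 5L) {
    c("PH", "EH", "EL", "ERN", "KW")
  } else {
    paste0("T", seq_len(n_traits))
  }
}

# Trait-major record index helper: records of trait k within a stacked vector.
trait_block <- function(k, n) ((k - 1L) * n + 1L):(k * n)
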