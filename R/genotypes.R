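# Marker-dosage handling and Cockerham incidence coding.
#
# A marker matrix is a plain numeric matrix: rows are individuals, columns are
# loci, entries are dosages of the counted (A1) allele in [0, 2]. NA marks a
# missing call. Fractional dosages are legal and represent expected genotypes
# of a cross. Row and column names are the individual and locus identifiers.

validate_marker_matrix <- function(m, allow_missing = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort("A marker matrix must be a numeric matrix (individuals x loci).")
  }
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("ind_%03d", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("locus_%05d", seq_len(ncol(m)))
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("Individual and locus identifiers must be unique.")
  }
  if (!allow_missing && anyNA(m)) {
    abort("Missing dosages present; impute first (see `impute_mean()`).")
  }
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("Dosages must lie in [0, 2].")
  }
  m
}

#' Per-locus allele frequency of the counted allele
#'
#' The frequency of the counted (A1) allele at each locus is the mean
#' non-missing dosage divided by 2. These frequencies parameterise the
#' Cockerham incidence codes and the denominators of the genomic
#' relationship matrices, so they should be computed on the same population
#' that is being analysed (for hybrids, the hybrid population itself).
#'
#' @param m Numeric marker matrix (individuals x loci, dosages in `[0, 2]`,
#'   `NA` allowed).
#' @return Named numeric vector of frequencies in `[0, 1]`, one per locus.
#' @examples
#' m <- matrix(c(2, 1, 1, 0, 0, 0), ncol = 1,
#'             dimnames = list(NULL, "m1"))
#' allele_freq(m) # 4 alleles out of 12
#' @export
allele_freq <- function(m) {
  m <- validate_marker_matrix(m)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L)) {
    bad <- colnames(m)[n_obs == 0L]
    abort(sprintf(
      "Locus with no non-missing dosage: %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  colMeans(m, na.rm = TRUE) / 2
}

#' Replace missing dosages by the locus mean
#'
#' Each missing cell is replaced by the locus mean dosage, i.e. twice the
#' allele frequency computed from the non-missing calls. Non-missing cells
#' are untouched. This is the usual mean imputation applied before building
#' genomic relationship matrices.
#'
#' @inheritParams allele_freq
#' @return The marker matrix with no missing values.
#' @export
impute_mean <- function(m) {
  m <- validate_marker_matrix(m)
  if (!anyNA(m)) {
    return(m)
  }
  p <- allele_freq(m)
  miss <- which(is.na(m), arr.ind = TRUE)
  m[miss] <- 2 * p[miss[, 2L]]
  m
}

#' Systematic (every step-th) locus sample
#'
#' Draws the first locus uniformly at random among positions `1..step`
#' (seeded) and then takes every `step`-th locus, independently within each
#' chromosome when chromosome labels are supplied. This mirrors the uniform
#' thinning used to reduce a dense marker panel to an evenly spaced subset.
#'
#' @param locus_ids Character or integer vector of locus identifiers in map
#'   order.
#' @param step Sampling interval (>= 1); `step = 1` keeps every locus.
#' @param seed Optional integer seed for the random start.
#' @param chrom Optional vector of chromosome labels, parallel to
#'   `locus_ids`.
#' @return The sampled subset of `locus_ids`, in order.
#' @export
systematic_sample <- function(locus_ids, step, seed = NULL, chrom = NULL) {
  stopifnot_scalar_number(step, "step")
  step <- as.integer(step)
  if (step < 1L) {
    abort("`step` must be >= 1.")
  }
  if (!is.null(chrom) && length(chrom) != length(locus_ids)) {
    abort("`chrom` must be parallel to `locus_ids`.")
  }
  groups <- if (is.null(chrom)) {
    list(seq_along(locus_ids))
  } else {
    split(seq_along(locus_ids), factor(chrom, levels = unique(chrom)))
  }
  with_seed(seed, {
    picked <- lapply(groups, function(idx) {
      if (step > length(idx)) {
        abort(sprintf(
          "`step` (%d) exceeds the number of loci (%d) in a chromosome.",
          step, length(idx)
        ))
      }
      start <- sample.int(step, 1L)
      idx[seq(start, length(idx), by = step)]
    })
    locus_ids[sort(unlist(picked, use.names = FALSE))]
  })
}

# Cockerham codes for the three genotype classes at frequency p:
#   A1A1 -> W_A = 2 - 2p, W_D = -2 (1 - p)^2
#   A1A2 -> W_A = 1 - 2p, W_D =  2 p (1 - p)
#   A2A2 -> W_A =   - 2p, W_D = -2 p^2
cockerham_codes <- function(p) {
  list(
    wa = cbind(2 - 2 * p, 1 - 2 * p, -2 * p),
    wd = cbind(-2 * (1 - p)^2, 2 * p * (1 - p), -2 * p^2)
  )
}

#' Cockerham additive and dominance incidence matrices
#'
#' Maps dosages to the Cockerham orthogonal codes at the supplied allele
#' frequencies: the additive code is `dosage - 2p` for the three genotype
#' classes, and the dominance code is `-2(1-p)^2`, `2p(1-p)`, `-2p^2` for
#' A1A1, A1A2, A2A2. Fractional dosages (expected genotypes of a cross) are
#' coded as the probability-weighted average of the three class codes: when
#' the parental allele-frequency matrices of the cross are available (as
#' produced by [partial_diallel()]) the exact cross genotype-class
#' probabilities are used; otherwise a fractional dosage `g` is decomposed as
#' a cross of two parents both at frequency `g/2`, which reduces to the
#' integer coding at `g` in `{0, 1, 2}` and preserves the expected codes.
#'
#' @inheritParams allele_freq
#' @param p Allele frequencies used for coding; defaults to
#'   `allele_freq(m)`.
#' @param parent_freqs Optional list of two matrices (`p1`, `p2`) of parental
#'   allele frequencies, same shape as `m`; taken from
#'   `attr(m, "parent_freqs")` when present.
#' @return A list of class `"incidence_pair"` with elements `W_A`, `W_D`
#'   (both individuals x loci) and `p`.
#' @export
code_cockerham <- function(m, p = NULL, parent_freqs = NULL) {
  m <- validate_marker_matrix(m, allow_missing = FALSE)
  parent_freqs <- parent_freqs %||% attr(m, "parent_freqs")
  p <- p %||% allele_freq(m)
  if (length(p) != ncol(m)) {
    abort("`p` must have one frequency per locus.")
  }
  if (any(p < 0 | p > 1)) {
    abort("Allele frequencies must lie in [0, 1].")
  }
  n <- nrow(m)
  q <- ncol(m)

  # W_A is linear in the class probabilities, hence always dosage - 2p.
  W_A <- m - matrix(2 * p, n, q, byrow = TRUE)

  # Genotype-class probabilities per cell.
  if (!is.null(parent_freqs)) {
    p1 <- parent_freqs[[1L]]
    p2 <- parent_freqs[[2L]]
    if (!all(dim(p1) == dim(m)) || !all(dim(p2) == dim(m))) {
      abort("`parent_freqs` matrices must match the marker matrix shape.")
    }
    P11 <- p1 * p2
    P12 <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    P11 <- P12 <- matrix(0, n, q)
    whole <- is_whole(m)
    # observed integer genotypes are the realised class
    P11[whole & m > 1.5] <- 1
    P12[whole & abs(m - 1) < 0.5] <- 1
    # fractional expected dosages: g/2 x g/2 cross decomposition
    if (any(!whole)) {
      ph <- m[!whole] / 2
      P11[!whole] <- ph^2
      P12[!whole] <- 2 * ph * (1 - ph)
    }
  }
  P22 <- 1 - P11 - P12

  c11 <- matrix(-2 * (1 - p)^2, n, q, byrow = TRUE)
  c12 <- matrix(2 * p * (1 - p), n, q, byrow = TRUE)
  c22 <- matrix(-2 * p^2, n, q, byrow = TRUE)
  W_D <- P11 * c11 + P12 * c12 + P22 * c22

  dimnames(W_A) <- dimnames(W_D) <- dimnames(m)
  structure(list(W_A = W_A, W_D = W_D, p = p), class = "incidence_pair")
}

#' @export
print.incidence_pair <- function(x, ...) {
  cat(sprintf(
    "<incidence_pair> %d individuals x %d loci (Cockerham W_A / W_D)\n",
    nrow(x$W_A), ncol(x$W_A)
  ))
  invisible(x)
}

#' Read / write genotype dosage tables
#'
#' The on-disk format is a delimited table with a header row of locus ids,
#' one row per individual and the individual id in the first column; cells
#' are dosages in `[0, 2]` (fractional allowed) or `NA`.
#'
#' @param path File path. The delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return `read_genotypes()` returns a marker matrix; `write_genotypes()`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  validate_marker_matrix(m)
}

#' @rdname read_genotypes
#' @param m Marker matrix to write.
#' @export
write_genotypes <- function(m, path) {
  m <- validate_marker_matrix(m)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read biallelic VCF genotypes as ALT-allele dosages
#'
#' Converts the GT field of a VCF to a dosage marker matrix (0/1/2 copies of
#' the ALT allele). Multi-allelic sites are dropped with a warning;
#' half-calls and missing genotypes become `NA`.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Marker matrix (individuals x loci).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the 'vcfR' package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    warn(sprintf("Dropping %d multi-allelic site(s).", sum(!bi)))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_counts <- function(g) {
    g <- sub(":.*$", "", g)
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      if (length(x) != 2L || any(x == ".") || any(is.na(x))) {
        return(NA_real_)
      }
      sum(x == "1")
    }, numeric(1))
  }
  m <- apply(gt, 2L, allele_counts)
  if (is.null(dim(m))) {
    m <- matrix(m, nrow = 1L, dimnames = list(rownames(gt)[1L], colnames(gt)))
  }
  m <- t(m)
  colnames(m) <- rownames(gt)
  validate_marker_matrix(m)
}
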