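# Synthetic single-cross hybrid study generator.
#
# The generator emulates the data-construction pipeline of a maize hybrid
# prediction study: two divergent heterotic groups of fully inbred lines,
# a partial diallel of single-cross hybrids whose genotypes are the
# expected allelic contribution of the two parents, a pleiotropic QTN
# architecture over the marker panel, and phenotypes scaled to requested
# broad-sense heritabilities. All ground truth (genetic values and
# parametric variance components) is retained for model evaluation.

#' Simulate inbred lines in two (or more) heterotic groups
#'
#' Ancestral allele frequencies are drawn uniformly on `freq_range`; each
#' group then receives drifted frequencies from a Balding-Nichols Beta
#' distribution with fixation index `divergence`, and fully inbred line
#' genotypes (dosages 0/2) are sampled per locus. With `divergence = 0` all
#' groups share the ancestral frequencies in expectation; larger values
#' separate the groups along the leading principal component of the
#' additive relationship matrix.
#'
#' @param n_lines Total number of lines (split evenly across groups).
#' @param n_loci Number of biallelic loci.
#' @param n_groups Number of heterotic groups (default 2).
#' @param divergence Fixation index F in `[0, 1]` controlling group drift.
#' @param seed Optional integer seed.
#' @param freq_range Range of ancestral allele frequencies.
#' @return Marker matrix of inbred lines with attribute `group` (integer
#'   labels) and `group_freqs` (loci x groups allele frequencies).
#' @export
simulate_lines <- function(n_lines = 40L, n_loci = 27000L, n_groups = 2L,
                           divergence = 0.2, seed = NULL,
                           freq_range = c(0.1, 0.9)) {
  if (divergence < 0 || divergence > 1) {
    abort("`divergence` must lie in [0, 1].")
  }
  if (n_lines < n_groups) {
    abort("Need at least one line per group.")
  }
  with_seed(seed, {
    p0 <- runif(n_loci, freq_range[1L], freq_range[2L])
    grp_freq <- sapply(seq_len(n_groups), function(g) {
      if (divergence == 0) {
        p0
      } else if (divergence == 1) {
        # complete fixation: each locus fixed for one allele per group
        as.numeric(runif(n_loci) < p0)
      } else {
        f <- (1 - divergence) / divergence
        rbeta(n_loci, p0 * f, (1 - p0) * f)
      }
    })
    group <- rep(seq_len(n_groups), length.out = n_lines)
    group <- sort(group)
    m <- matrix(0, n_lines, n_loci)
    for (i in seq_len(n_lines)) {
      m[i, ] <- 2 * rbinom(n_loci, 1L, grp_freq[, group[i]])
    }
    dimnames(m) <- list(
      sprintf("L%03d", seq_len(n_lines)),
      sprintf("M%05d", seq_len(n_loci))
    )
    attr(m, "group") <- stats::setNames(group, rownames(m))
    attr(m, "group_freqs") <- grp_freq
    m
  })
}

#' Assign heterotic groups from the additive relationship matrix
#'
#' Individuals are projected on the two leading principal components of the
#' additive relationship matrix (eigenvectors scaled by the square roots of
#' their eigenvalues) and partitioned by seeded k-means on that projection.
#' Cluster labels are canonicalised by decreasing mean PC1 score so that the
#' labelling is stable under row permutations of `a`.
#'
#' @param a Additive relationship matrix (n x n).
#' @param n_groups Number of groups (default 2).
#' @param seed Optional integer seed for k-means initialisation.
#' @return Named integer vector of group labels.
#' @export
assign_heterotic_groups <- function(a, n_groups = 2L, seed = NULL) {
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    abort("`a` must be a square relationship matrix.")
  }
  n <- nrow(a)
  if (n < n_groups) {
    abort("More groups than individuals.")
  }
  if (n_groups == 1L) {
    return(stats::setNames(rep(1L, n), rownames(a)))
  }
  eig <- eigen(symmetrize(unclass(a)), symmetric = TRUE)
  if (eig$values[2L] <= sqrt(.Machine$double.eps) * max(abs(eig$values))) {
    abort("`a` is effectively of rank < 2: cannot project on two components.")
  }
  # eigenvector signs are arbitrary; canonicalise them (by skewness, which
  # is invariant under row permutations) so labels are stable
  vecs <- eig$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    s <- sum(vecs[, j]^3)
    if (s == 0) s <- vecs[which.max(abs(vecs[, j])), j]
    if (s < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- vecs %*% diag(sqrt(eig$values[1:2]))
  km <- with_seed(seed, kmeans(scores, centers = n_groups, nstart = 25L))
  # canonical order: decreasing cluster mean on PC1, ties broken on PC2
  centers <- km$centers
  ord <- order(-centers[, 1L], -centers[, 2L])
  relabel <- integer(n_groups)
  relabel[ord] <- seq_len(n_groups)
  stats::setNames(relabel[km$cluster], rownames(a))
}

#' Expected hybrid dosage at a locus
#'
#' Expectation of the genotypic value of a cross given the counted-allele
#' frequencies of the two parental lines:
#' \deqn{E(m) = 2 p_\lambda p_\Omega + p_\lambda (1 - p_\Omega) +
#'   p_\Omega (1 - p_\lambda)}
#' which simplifies to \eqn{p_\lambda + p_\Omega}. Vectorised over loci.
#'
#' @param p1,p2 Parental allele frequencies in `[0, 1]` (scalars or
#'   vectors).
#' @return Expected dosage(s) in `[0, 2]`.
#' @export
expected_hybrid_genotype <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1, na.rm = TRUE) || any(p2 < 0 | p2 > 1, na.rm = TRUE)) {
    abort("Parental allele frequencies must lie in [0, 1].")
  }
  2 * p1 * p2 + p1 * (1 - p2) + p2 * (1 - p1)
}

#' Partial diallel of single-cross hybrids
#'
#' Crosses every selected line of group 1 with every selected line of group
#' 2. The hybrid dosage at each locus is the expected genotype of the cross
#' ([expected_hybrid_genotype()]) of the parental within-line allele
#' frequencies (dosage/2; 0 or 1 for fully inbred parents, fractional for
#' residual heterozygosity). With the default 20 parents per group this
#' yields the 20 x 20 = 400 single-cross design.
#'
#' @param lines_group1,lines_group2 Marker matrices of the two parent
#'   groups (no missing values; impute first).
#' @param n_per_group Number of parents taken from the top of each group
#'   (default: all).
#' @return Marker matrix of hybrids (`n1 * n2` rows); hybrid ids encode the
#'   parent pair as `"<p1>x<p2>"`. The parental frequency matrices are
#'   attached as attribute `parent_freqs` for exact Cockerham coding of
#'   fractional dosages, and `parents` records the pair per hybrid.
#' @export
partial_diallel <- function(lines_group1, lines_group2, n_per_group = NULL) {
  g1 <- validate_marker_matrix(lines_group1, allow_missing = FALSE)
  g2 <- validate_marker_matrix(lines_group2, allow_missing = FALSE)
  if (!identical(colnames(g1), colnames(g2))) {
    abort("The two groups must share the same loci.")
  }
  if (!is.null(n_per_group)) {
    if (nrow(g1) < n_per_group || nrow(g2) < n_per_group) {
      abort("Each group must contain at least `n_per_group` lines.")
    }
    g1 <- g1[seq_len(n_per_group), , drop = FALSE]
    g2 <- g2[seq_len(n_per_group), , drop = FALSE]
  }
  if (length(intersect(rownames(g1), rownames(g2))) > 0L) {
    abort("Parent sets overlap between the two groups.")
  }
  n1 <- nrow(g1)
  n2 <- nrow(g2)
  i1 <- rep(seq_len(n1), each = n2)
  i2 <- rep(seq_len(n2), times = n1)
  p1 <- g1[i1, , drop = FALSE] / 2
  p2 <- g2[i2, , drop = FALSE] / 2
  m <- expected_hybrid_genotype(p1, p2)
  ids <- paste0(rownames(g1)[i1], "x", rownames(g2)[i2])
  dimnames(m) <- list(ids, colnames(g1))
  dimnames(p1) <- dimnames(p2) <- dimnames(m)
  attr(m, "parent_freqs") <- list(p1 = p1, p2 = p2)
  attr(m, "parents") <- data.frame(
    hybrid = ids,
    parent1 = rownames(g1)[i1],
    parent2 = rownames(g2)[i2],
    stringsAsFactors = FALSE
  )
  m
}

# Pairwise QTN-sharing counts between the five traits used as the default
# pleiotropy pattern (upper-triangular, trait order PH, EH, EL, ERN, KW).
pleiotropy_preset_counts <- function() {
  traits <- c("PH", "EH", "EL", "ERN", "KW")
  a <- matrix(0L, 5L, 5L, dimnames = list(traits, traits))
  d <- a
  a["PH", c("EH", "EL", "ERN", "KW")] <- c(17L, 3L, 1L, 0L)
  a["EH", c("EL", "ERN", "KW")] <- c(4L, 4L, 2L)
  a["EL", c("ERN", "KW")] <- c(6L, 2L)
  a["ERN", "KW"] <- 1L
  d["PH", c("EH", "EL", "ERN", "KW")] <- c(20L, 1L, 0L, 2L)
  d["EH", c("EL", "ERN", "KW")] <- c(1L, 0L, 0L)
  d["EL", c("ERN", "KW")] <- c(0L, 3L)
  d["ERN", "KW"] <- 1L
  list(additive = a, dominance = d)
}

# Draw per-trait QTN index sets with pairwise sharing. `counts` is an
# upper-triangular t x t matrix of loci shared by exactly each trait pair;
# shared loci get one common effect value across the sharing traits.
draw_qtn_sets <- function(n_loci, n_qtn, counts, n_traits, pool_used) {
  draw_from <- function(avail, k) avail[sample.int(length(avail), k)]
  sets <- replicate(n_traits, integer(0), simplify = FALSE)
  shared_effect_locus <- integer(0)
  common_pool <- attr(counts, "common_pool")
  if (!is.null(common_pool) && common_pool > 0L) {
    # scalar-fraction sharing: one pool common to every trait
    avail <- setdiff(seq_len(n_loci), pool_used)
    loci <- draw_from(avail, min(common_pool, n_qtn))
    pool_used <- c(pool_used, loci)
    for (i in seq_len(n_traits)) sets[[i]] <- loci
    shared_effect_locus <- loci
  } else if (!is.null(counts) && n_traits >= 2L) {
    for (i in seq_len(n_traits - 1L)) {
      for (j in (i + 1L):n_traits) {
        c_ij <- counts[i, j]
        if (c_ij > 0L) {
          avail <- setdiff(seq_len(n_loci), pool_used)
          loci <- draw_from(avail, c_ij)
          pool_used <- c(pool_used, loci)
          sets[[i]] <- c(sets[[i]], loci)
          sets[[j]] <- c(sets[[j]], loci)
          shared_effect_locus <- c(shared_effect_locus, loci)
        }
      }
    }
  }
  for (i in seq_len(n_traits)) {
    need <- n_qtn - length(sets[[i]])
    if (need < 0L) {
      abort("Pairwise shared QTN counts exceed the per-trait QTN count.")
    }
    avail <- setdiff(seq_len(n_loci), pool_used)
    if (length(avail) < need) {
      abort("Not enough loci for the requested QTN architecture.")
    }
    loci <- draw_from(avail, need)
    pool_used <- c(pool_used, loci)
    sets[[i]] <- sort(c(sets[[i]], loci))
  }
  list(sets = sets, shared = unique(shared_effect_locus), pool_used = pool_used)
}

#' Sample a pleiotropic QTN architecture
#'
#' Per trait, `n_add_qtn` additive and `n_dom_qtn` dominance QTN are drawn
#' without replacement from the marker panel; trait pairs share QTN to
#' induce genetic correlation. Sharing is controlled either by a scalar
#' `pleiotropy` fraction (a common pool of `round(fraction * n_qtn)` QTN
#' used by every trait) or by upper-triangular matrices of pairwise shared
#' counts (the default for five traits follows the coincidence pattern of
#' a maize QTL ranking: e.g. 17 shared additive and 20 shared dominance
#' QTN between plant and ear height). At a shared locus the effect value is
#' drawn once and used by all sharing traits, so sharing always induces a
#' positive genetic correlation contribution. Effects are Gaussian with per
#' trait standard deviation `effect_sd`, zero off-QTN, and are on the
#' genotypic scale: `a_star` holds half the homozygote difference per
#' locus, `d_star` the heterozygote deviation. Allele-substitution
#' coefficients are formed at phenotype construction (see
#' [simulate_phenotypes()]).
#'
#' @param n_loci Number of loci in the panel.
#' @param n_add_qtn,n_dom_qtn QTN per trait for additive and dominance
#'   effects (default 100 each).
#' @param n_traits Number of traits.
#' @param pleiotropy Scalar sharing fraction in `[0, 1]`, or a list with
#'   upper-triangular `additive` and `dominance` count matrices, or
#'   `"preset"` (default for 5 traits).
#' @param effect_sd Effect standard deviation, recycled per trait.
#' @param seed Optional integer seed.
#' @return Object of class `"genetic_architecture"`: matrices `a_star`,
#'   `d_star` (loci x traits, zeros off-QTN), index lists `qtn_additive`,
#'   `qtn_dominance`, and `pleiotropy_table` (realised pairwise shared
#'   counts).
#' @export
sample_architecture <- function(n_loci, n_add_qtn = 100L, n_dom_qtn = 100L,
                                n_traits = 5L, pleiotropy = NULL,
                                effect_sd = 1, seed = NULL) {
  if (n_add_qtn + n_dom_qtn > n_loci) {
    abort("Requested more QTN than loci (n_add_qtn + n_dom_qtn > n_loci).")
  }
  traits <- default_trait_names(n_traits)
  effect_sd <- rep_len(effect_sd, n_traits)

  counts <- resolve_pleiotropy(pleiotropy, n_traits, n_add_qtn, n_dom_qtn)

  with_seed(seed, {
    add <- draw_qtn_sets(n_loci, n_add_qtn, counts$additive, n_traits,
                         pool_used = integer(0))
    # dominance sets drawn from a fresh pool: a locus may carry both an
    # additive and a dominance effect, as in a joint effect ranking
    dom <- draw_qtn_sets(n_loci, n_dom_qtn, counts$dominance, n_traits,
                         pool_used = integer(0))

    a_star <- matrix(0, n_loci, n_traits, dimnames = list(NULL, traits))
    d_star <- matrix(0, n_loci, n_traits, dimnames = list(NULL, traits))
    shared_a <- stats::setNames(rnorm(length(add$shared)), add$shared)
    shared_d <- stats::setNames(rnorm(length(dom$shared)), dom$shared)
    for (i in seq_len(n_traits)) {
      qa <- add$sets[[i]]
      is_sh <- as.character(qa) %in% names(shared_a)
      a_star[qa[is_sh], i] <- shared_a[as.character(qa[is_sh])] * effect_sd[i]
      a_star[qa[!is_sh], i] <- rnorm(sum(!is_sh), sd = effect_sd[i])
      qd <- dom$sets[[i]]
      is_sh <- as.character(qd) %in% names(shared_d)
      d_star[qd[is_sh], i] <- shared_d[as.character(qd[is_sh])] * effect_sd[i]
      d_star[qd[!is_sh], i] <- rnorm(sum(!is_sh), sd = effect_sd[i])
    }

    ptab_a <- sharing_table(add$sets, traits)
    ptab_d <- sharing_table(dom$sets, traits)
    structure(
      list(
        a_star = a_star, d_star = d_star,
        qtn_additive = stats::setNames(add$sets, traits),
        qtn_dominance = stats::setNames(dom$sets, traits),
        pleiotropy_table = list(additive = ptab_a, dominance = ptab_d),
        traits = traits
      ),
      class = "genetic_architecture"
    )
  })
}

resolve_pleiotropy <- function(pleiotropy, n_traits, n_add_qtn, n_dom_qtn) {
  if (is.null(pleiotropy)) {
    pleiotropy <- if (n_traits == 5L) "preset" else 0.1
  }
  if (identical(pleiotropy, "preset")) {
    if (n_traits != 5L) {
      abort("The preset pleiotropy pattern is defined for 5 traits.")
    }
    preset <- pleiotropy_preset_counts()
    # the pattern is defined per 100 QTN; scale to the configured counts
    preset$additive[] <- as.integer(round(preset$additive * n_add_qtn / 100))
    preset$dominance[] <- as.integer(round(preset$dominance * n_dom_qtn / 100))
    return(preset)
  }
  if (is.numeric(pleiotropy) && length(pleiotropy) == 1L) {
    if (pleiotropy < 0 || pleiotropy > 1) {
      abort("`pleiotropy` fraction must lie in [0, 1].")
    }
    # common-pool sharing: model as counts on consecutive pairs is NOT
    # equivalent; instead mark with attribute and handle as common pool
    frac_counts <- function(n_qtn) {
      s <- round(pleiotropy * n_qtn)
      cnt <- matrix(0L, n_traits, n_traits)
      if (s > 0L && n_traits >= 2L) {
        attr(cnt, "common_pool") <- s
      }
      cnt
    }
    return(list(additive = frac_counts(n_add_qtn),
                dominance = frac_counts(n_dom_qtn)))
  }
  if (is.list(pleiotropy) && all(c("additive", "dominance") %in% names(pleiotropy))) {
    return(pleiotropy)
  }
  abort("`pleiotropy` must be a fraction, the string \"preset\", or a list of count matrices.")
}

sharing_table <- function(sets, traits) {
  t <- length(sets)
  tab <- matrix(0L, t, t, dimnames = list(traits, traits))
  for (i in seq_len(t)) {
    for (j in seq_len(t)) {
      if (i != j) tab[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  tab
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf(
    "<genetic_architecture> %d loci, %d trait(s); %d additive + %d dominance QTN per trait\n",
    nrow(x$a_star), length(x$traits),
    length(x$qtn_additive[[1L]]), length(x$qtn_dominance[[1L]])
  ))
  invisible(x)
}

#' Parametric additive and dominance variances from locus effects
#'
#' Locus-sum variances of the Cockerham decomposition at allele frequencies
#' `p` (with `q = 1 - p`):
#' \deqn{\sigma^2_\alpha = \sum_k 2 p_k q_k [a_k + d_k (q_k - p_k)]^2}
#' \deqn{\sigma^2_\delta = \sum_k (2 p_k q_k d_k)^2}
#' These are the linkage-equilibrium reference values; the realised variance
#' of genetic values in a structured hybrid population (e.g. a diallel) can
#' deviate through linkage disequilibrium between QTN.
#'
#' @param p Allele frequencies (length = loci).
#' @param a_star,d_star Per-locus additive and dominance effects: vectors
#'   for one trait or loci x traits matrices.
#' @return A tibble with one row per trait: `trait`, `sigma2_alpha`,
#'   `sigma2_delta`, `sigma2_g`.
#' @export
parametric_variances <- function(p, a_star, d_star) {
  a_star <- as.matrix(a_star)
  d_star <- as.matrix(d_star)
  if (nrow(a_star) != length(p) || nrow(d_star) != length(p) ||
      ncol(a_star) != ncol(d_star)) {
    abort("`p`, `a_star` and `d_star` must agree in dimension.")
  }
  q <- 1 - p
  het <- 2 * p * q
  s2a <- colSums(het * (a_star + d_star * (q - p))^2)
  s2d <- colSums((het * d_star)^2)
  traits <- colnames(a_star) %||% default_trait_names(ncol(a_star))
  tibble::tibble(
    trait = traits,
    sigma2_alpha = unname(s2a),
    sigma2_delta = unname(s2d),
    sigma2_g = unname(s2a + s2d)
  )
}

#' Simulate hybrid phenotypes at requested heritabilities
#'
#' Parametric genetic values are \eqn{g = \mu + W_A \alpha^* + W_D d^*}
#' with the Cockerham incidence matrices of the hybrid population (coded at
#' the hybrid allele frequencies). The architecture stores genotypic-scale
#' locus effects (`a` = half the homozygote difference, `d` = heterozygote
#' deviation); the coefficient entering the additive incidence is the
#' allele-substitution effect \eqn{\alpha_k = a_k + d_k (q_k - p_k)} at the
#' coding frequencies, which makes the locus-sum variance formulas of
#' [parametric_variances()] exact under linkage equilibrium. Residuals are
#' i.i.d. normal with variance
#' \eqn{\sigma^2_e = \sigma^2_g (1 - h^2) / h^2}, where \eqn{\sigma^2_g} is
#' the empirical variance of `g` over the hybrids, so the realised
#' broad-sense heritability matches the request in the generated sample.
#'
#' @param hybrids Hybrid marker matrix (e.g. from [partial_diallel()]).
#' @param arch A `"genetic_architecture"`.
#' @param h2 Requested broad-sense heritability: scalar, per-trait vector,
#'   or one of `"historical"` / `"mixed"` (five-trait presets).
#' @param mu Per-trait general mean (default 0).
#' @param seed Optional integer seed for the residual draw.
#' @return A list with `pheno` (tibble: `hybrid` id plus one column per
#'   trait) and `truth`, an object of class `"hybrid_truth"` holding the
#'   parametric genetic values (`g`, and components `g_alpha`, `g_delta`),
#'   `mu`, `h2`, the locus-sum parametric variances and the empirical
#'   `sigma2_g` / `sigma2_e` used for scaling.
#' @export
simulate_phenotypes <- function(hybrids, arch, h2, mu = 0, seed = NULL) {
  n_traits <- length(arch$traits)
  h2 <- resolve_h2(h2, arch$traits)
  if (any(h2 <= 0 | h2 >= 1)) {
    abort("`h2` entries must lie in (0, 1).")
  }
  mu <- rep_len(mu, n_traits)

  p <- allele_freq(hybrids)
  inc <- code_cockerham(hybrids, p)
  # the coefficient on the additive incidence is the allele-substitution
  # effect alpha_k = a_k + d_k (q_k - p_k), formed at the coding
  # frequencies, so the locus-sum variance formulas hold exactly
  alpha_coef <- arch$a_star + arch$d_star * (1 - 2 * p)
  g_alpha <- inc$W_A %*% alpha_coef
  g_delta <- inc$W_D %*% arch$d_star
  g <- sweep(g_alpha + g_delta, 2L, mu, "+")

  s2g <- apply(g, 2L, var)
  if (any(s2g <= 0)) {
    abort("Zero genetic variance for at least one trait: cannot scale residuals.")
  }
  s2e <- s2g * (1 - h2) / h2
  n <- nrow(g)
  e <- with_seed(seed, {
    matrix(rnorm(n * n_traits), n, n_traits) %*% diag(sqrt(s2e), n_traits)
  })
  y <- g + e
  colnames(y) <- arch$traits

  pheno <- tibble::as_tibble(as.data.frame(y))
  pheno <- tibble::add_column(pheno, hybrid = rownames(hybrids), .before = 1L)

  pv <- parametric_variances(p, arch$a_star, arch$d_star)
  truth <- structure(
    list(
      g = g, g_alpha = g_alpha, g_delta = g_delta,
      mu = stats::setNames(mu, arch$traits),
      h2 = stats::setNames(h2, arch$traits),
      parametric = pv,
      sigma2_g_emp = stats::setNames(s2g, arch$traits),
      sigma2_e = stats::setNames(s2e, arch$traits),
      traits = arch$traits
    ),
    class = "hybrid_truth"
  )
  list(pheno = pheno, truth = truth)
}

resolve_h2 <- function(h2, traits) {
  n_traits <- length(traits)
  if (is.character(h2)) {
    h2 <- match.arg(h2, c("historical", "mixed"))
    if (n_traits != 5L) {
      abort("The heritability presets are defined for the five-trait design.")
    }
    h2 <- switch(h2,
      historical = c(PH = 0.569, EH = 0.662, EL = 0.381, ERN = 0.57, KW = 0.418),
      mixed = c(PH = 0.3, EH = 0.5, EL = 0.7, ERN = 0.7, KW = 0.3)
    )
  }
  unname(rep_len(h2, n_traits))
}

#' @export
print.hybrid_truth <- function(x, ...) {
  cat(sprintf("<hybrid_truth> %d hybrids x %d trait(s)\n", nrow(x$g), length(x$traits)))
  print(x$parametric)
  invisible(x)
}

#' Simulate a complete single-cross hybrid study
#'
#' End-to-end generator: inbred lines in two heterotic groups, group
#' assignment by principal components of the line additive relationship
#' matrix, a partial diallel of hybrids, a pleiotropic QTN architecture,
#' phenotypes at the requested heritabilities, and the hybrid additive and
#' dominance relationship matrices (positive-definite repaired). Defaults
#' reproduce the study design this package targets: 20 parents per group
#' (400 hybrids), five traits, 100 + 100 QTN per trait with the preset
#' pleiotropy pattern, and the historical heritabilities
#' \{PH 0.569, EH 0.662, EL 0.381, ERN 0.57, KW 0.418\}.
#'
#' @inheritParams simulate_lines
#' @inheritParams sample_architecture
#' @inheritParams simulate_phenotypes
#' @param n_per_group Parents crossed per heterotic group.
#' @param seed Master seed; stage seeds are derived from it.
#' @return Object of class `"hybrid_study"`: marker matrices (`lines`,
#'   `hybrids`), group labels, relationship matrices `A` and `D`,
#'   `pheno`, `truth`, `arch` and the seed.
#' @export
simulate_hybrid_study <- function(n_lines = 40L, n_loci = 27000L,
                                  n_per_group = 20L, n_traits = 5L,
                                  n_add_qtn = 100L, n_dom_qtn = 100L,
                                  h2 = "historical", divergence = 0.2,
                                  pleiotropy = NULL, effect_sd = 1, mu = 0,
                                  seed = NULL) {
  if (n_add_qtn + n_dom_qtn > n_loci) {
    abort("`n_loci` is smaller than the requested QTN architecture.")
  }
  if (n_lines < 2L * n_per_group) {
    abort("Need at least `2 * n_per_group` lines for the diallel.")
  }
  lines <- simulate_lines(
    n_lines = n_lines, n_loci = n_loci, n_groups = 2L,
    divergence = divergence, seed = derive_seed(seed, 1L)
  )
  a_lines <- additive_grm(code_cockerham(lines))
  groups <- assign_heterotic_groups(a_lines, 2L, seed = derive_seed(seed, 2L))
  g1 <- lines[groups == 1L, , drop = FALSE]
  g2 <- lines[groups == 2L, , drop = FALSE]
  if (nrow(g1) < n_per_group || nrow(g2) < n_per_group) {
    abort("A heterotic group has fewer lines than `n_per_group`.")
  }
  hybrids <- partial_diallel(g1, g2, n_per_group = n_per_group)

  arch <- sample_architecture(
    n_loci = n_loci, n_add_qtn = n_add_qtn, n_dom_qtn = n_dom_qtn,
    n_traits = n_traits, pleiotropy = pleiotropy, effect_sd = effect_sd,
    seed = derive_seed(seed, 3L)
  )
  sim <- simulate_phenotypes(hybrids, arch, h2 = h2, mu = mu,
                             seed = derive_seed(seed, 4L))

  p_h <- allele_freq(hybrids)
  inc <- code_cockerham(hybrids, p_h)
  A <- make_positive_definite(additive_grm(inc$W_A, p_h))
  D <- make_positive_definite(dominance_grm(inc$W_D, p_h))

  structure(
    list(
      lines = lines, groups = groups, hybrids = hybrids,
      A = A, D = D,
      pheno = sim$pheno, truth = sim$truth, arch = arch,
      h2 = resolve_h2(h2, arch$traits), seed = seed
    ),
    class = "hybrid_study"
  )
}

#' @export
print.hybrid_study <- function(x, ...) {
  cat(sprintf(
    "<hybrid_study> %d lines -> %d hybrids, %d loci, %d trait(s)\n",
    nrow(x$lines), nrow(x$hybrids), ncol(x$hybrids), length(x$arch$traits)
  ))
  cat("h2:", paste(sprintf("%s=%.3f", x$arch$traits, x$h2), collapse = ", "), "\n")
  invisible(x)
}
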