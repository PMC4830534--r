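# Hybrid-study generator: lines, groups, diallel, architecture, phenotypes.

test_that("expected hybrid genotype equals the sum of parental frequencies", {
  grid <- expand.grid(p1 = seq(0, 1, by = 0.1), p2 = seq(0, 1, by = 0.1))
  expect_equal(
    expected_hybrid_genotype(grid$p1, grid$p2),
    grid$p1 + grid$p2
  )
  # boundary classes
  expect_equal(expected_hybrid_genotype(1, 0), 1)
  expect_equal(expected_hybrid_genotype(1, 1), 2)
  expect_equal(expected_hybrid_genotype(0.5, 0.5), 1)
  expect_error(expected_hybrid_genotype(1.2, 0), "\\[0, 1\\]")
})

test_that("simulated lines are fully inbred and deterministic under a seed", {
  m <- simulate_lines(n_lines = 4, n_loci = 10, seed = 5)
  expect_equal(dim(m), c(4L, 10L))
  expect_true(all(m %in% c(0, 2)))
  expect_identical(
    unclass(simulate_lines(n_lines = 4, n_loci = 10, seed = 5)),
    unclass(m)
  )
  # divergence 0: both groups share ancestral frequencies in expectation
  m0 <- simulate_lines(n_lines = 200, n_loci = 400, divergence = 0, seed = 1)
  gf <- attr(m0, "group_freqs")
  expect_equal(gf[, 1], gf[, 2])
})

test_that("heterotic groups are recovered from the additive GRM", {
  m <- simulate_lines(n_lines = 40, n_loci = 1200, divergence = 0.4, seed = 21)
  truth <- attr(m, "group")
  A <- additive_grm(code_cockerham(m))
  labels <- assign_heterotic_groups(A, 2, seed = 3)
  # exact recovery up to label order at this divergence
  agreement <- max(mean(labels == truth), mean(labels == 3 - truth))
  expect_equal(agreement, 1)

  # permutation equivariance (canonical labelling by PC1 cluster mean)
  perm <- sample(nrow(A))
  labels_p <- assign_heterotic_groups(A[perm, perm], 2, seed = 3)
  expect_equal(unname(labels_p), unname(labels[perm]))

  # single group and degenerate input
  expect_equal(unname(assign_heterotic_groups(A, 1)), rep(1L, 40))
  expect_error(assign_heterotic_groups(matrix(1, 5, 5), 2), "rank")
})

test_that("partial diallel crosses every pair across groups", {
  g1 <- simulate_lines(n_lines = 4, n_loci = 20, seed = 1)[1:2, ]
  g2 <- simulate_lines(n_lines = 6, n_loci = 20, seed = 2)[1:3, ]
  rownames(g2) <- paste0("B", 1:3)
  h <- partial_diallel(g1, g2)
  expect_equal(nrow(h), 6L)
  expect_true(all(h >= 0 & h <= 2))
  # 20 x 20 count contract checked cheaply via n_per_group
  g1b <- simulate_lines(n_lines = 20, n_loci = 30, seed = 3)
  g2b <- simulate_lines(n_lines = 20, n_loci = 30, seed = 4)
  rownames(g2b) <- paste0("B", 1:20)
  expect_equal(nrow(partial_diallel(g1b, g2b, n_per_group = 20)), 400L)
  # overlap guard
  expect_error(partial_diallel(g1, g1), "overlap")
  # selfing a fully inbred line reproduces its genotype
  self <- partial_diallel(g1[1, , drop = FALSE],
                          `rownames<-`(g1[1, , drop = FALSE], "copy"))
  expect_equal(unname(self[1, ]), unname(g1[1, ]))
})

test_that("architecture has the configured QTN counts and sharing", {
  arch <- sample_architecture(n_loci = 2000, n_add_qtn = 100, n_dom_qtn = 100,
                              n_traits = 5, seed = 31)
  expect_equal(unname(colSums(arch$a_star != 0)), rep(100, 5))
  expect_equal(unname(colSums(arch$d_star != 0)), rep(100, 5))
  for (tr in arch$traits) {
    expect_equal(which(arch$a_star[, tr] != 0), arch$qtn_additive[[tr]],
                 ignore_attr = TRUE)
    expect_equal(which(arch$d_star[, tr] != 0), arch$qtn_dominance[[tr]],
                 ignore_attr = TRUE)
  }
  # preset sharing realised exactly (pairs are disjoint by construction)
  expect_equal(arch$pleiotropy_table$additive["PH", "EH"], 17L)
  expect_equal(arch$pleiotropy_table$dominance["PH", "EH"], 20L)

  # no sharing -> empty pleiotropy table
  arch0 <- sample_architecture(400, 40, 40, n_traits = 3, pleiotropy = 0,
                               seed = 1)
  expect_true(all(arch0$pleiotropy_table$additive == 0))

  # determinism and argument guards
  arch2 <- sample_architecture(n_loci = 2000, n_add_qtn = 100,
                               n_dom_qtn = 100, n_traits = 5, seed = 31)
  expect_identical(arch$a_star, arch2$a_star)
  expect_error(sample_architecture(150, 100, 100, n_traits = 2), "QTN")
  expect_error(sample_architecture(400, 40, 40, n_traits = 2, pleiotropy = 2),
               "\\[0, 1\\]")
})

test_that("parametric variances match the locus-sum formulas", {
  # single locus, p = .5: a = 1, d = 0 -> (0.5, 0); a = 0, d = 1 -> (0, 0.25)
  v1 <- parametric_variances(0.5, 1, 0)
  expect_equal(v1$sigma2_alpha, 0.5)
  expect_equal(v1$sigma2_delta, 0)
  v2 <- parametric_variances(0.5, 0, 1)
  expect_equal(v2$sigma2_alpha, 0)
  expect_equal(v2$sigma2_delta, 0.25)
  # d = 0 everywhere kills the dominance variance
  p <- runif(20)
  a <- rnorm(20)
  v3 <- parametric_variances(p, a, rep(0, 20))
  expect_equal(v3$sigma2_delta, 0)
  expect_equal(v3$sigma2_alpha, sum(2 * p * (1 - p) * a^2))
  expect_error(parametric_variances(c(0.5, 0.5), 1, 1), "dimension")
})

test_that("phenotypes hit the requested heritability scaling", {
  study <- midi_study(seed = 7, h2 = 0.5)
  tr <- study$truth
  # h2 = .5 means residual variance equals empirical genetic variance
  expect_equal(unname(tr$sigma2_e), unname(tr$sigma2_g_emp))
  # realized broad-sense heritability: per-trait mean over seeds within
  # the Monte-Carlo band at 400 hybrids
  h2_real <- sapply(1:3, function(s) {
    st <- full_study(seed = 100 + s, h2 = 0.5)
    y <- as.matrix(st$pheno[, st$arch$traits])
    apply(st$truth$g, 2, var) / apply(y, 2, var)
  })
  expect_true(all(abs(rowMeans(h2_real) - 0.5) < 0.05))
  # h2 -> 1 limit: phenotype collapses onto g
  st1 <- midi_study(seed = 7, h2 = 0.999)
  y1 <- as.matrix(st1$pheno[, st1$arch$traits])
  expect_gt(min(diag(cor(y1, st1$truth$g))), 0.999)
})

test_that("simulation is deterministic and validates degenerate input", {
  s1 <- tiny_study(seed = 3)
  s2 <- tiny_study(seed = 3)
  expect_equal(s1$pheno, s2$pheno)
  expect_equal(unclass(s1$hybrids), unclass(s2$hybrids), ignore_attr = TRUE)
  expect_equal(s1$truth$g, s2$truth$g)

  # zero genetic variance cannot be scaled to a heritability
  hyb <- s1$hybrids
  arch0 <- sample_architecture(ncol(hyb), 5, 5, n_traits = 1,
                               pleiotropy = 0, seed = 1)
  arch0$a_star[] <- 0
  arch0$d_star[] <- 0
  expect_error(simulate_phenotypes(hyb, arch0, h2 = 0.5, seed = 1),
               "variance")
})

test_that("additive-only architectures yield zero dominance signal", {
  study <- midi_study(seed = 13, h2 = 0.5, n_dom_qtn = 0)
  expect_equal(unname(study$truth$parametric$sigma2_delta), rep(0, 5))
  expect_equal(max(abs(study$truth$g_delta)), 0)
})

test_that("genetic correlation increases with the pleiotropy fraction", {
  mean_abs_cor <- function(frac, seed) {
    arch <- sample_architecture(600, 50, 50, n_traits = 2,
                                pleiotropy = frac, seed = seed)
    hyb <- simulate_lines(n_lines = 60, n_loci = 600, seed = seed + 500)
    p <- allele_freq(hyb)
    inc <- code_cockerham(hyb, p)
    g <- inc$W_A %*% arch$a_star + inc$W_D %*% arch$d_star
    abs(cor(g[, 1], g[, 2]))
  }
  for (s in 1:3) {
    lo <- mean_abs_cor(0, s)
    mid <- mean_abs_cor(0.5, s)
    hi <- mean_abs_cor(1, s)
    expect_gt(hi, lo)
    expect_gt(hi, 0.9)   # full sharing with common effect values
    expect_gt(mid + 0.15, lo)  # non-decreasing up to sampling noise
  }
})
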