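test_that("diversity statistics match hand-computed and brute-force values", {
  # all individuals heterozygous at every locus
  g1 <- toy_genotypes(matrix(1L, 6, 4), rep("p", 6))
  expect_equal(pop_stats(g1, "p")$H_O, 1)

  # fixed everywhere
  g2 <- toy_genotypes(matrix(2L, 6, 4), rep("p", 6))
  s2 <- pop_stats(g2, "p")
  expect_equal(s2$H_O, 0)
  expect_equal(s2$H_E, 0)
  expect_equal(s2$pi, 0)
  expect_equal(s2$P, 1)

  # 5 diploids, dosages (0,0,1,1,2): p = 0.4, H_O = 0.4,
  # H_E = (10/9) * 2 * 0.4 * 0.6
  g3 <- toy_genotypes(matrix(c(0L, 0L, 1L, 1L, 2L), 5, 1), rep("p", 5))
  s3 <- pop_stats(g3, "p")
  expect_equal(s3$H_O, 0.4)
  expect_equal(s3$H_E, (10 / 9) * 2 * 0.4 * 0.6, tolerance = 1e-12)
  expect_equal(s3$P, 0.6)

  # random matrices against the loop oracle
  for (rep in 1:3) {
    set.seed(rep)
    g <- random_genotypes(12, 15, n_pops = 1, miss = 0.2)
    s <- pop_stats(g, "pop1")
    o <- oracle_pop_stats(g$dosage)
    expect_equal(s$P, o$P, tolerance = 1e-12)
    expect_equal(s$H_O, o$H_O, tolerance = 1e-12)
    expect_equal(s$H_E, o$H_E, tolerance = 1e-12)
  }
  expect_error(pop_stats(g1, "nope"), "no samples")
})

test_that("Weir-Cockerham theta matches the independent component oracle", {
  # complete fixation
  gf <- toy_genotypes(cbind(rep(c(0L, 2L), each = 5), rep(c(0L, 2L), each = 5)),
                      rep(c("A", "B"), each = 5))
  expect_equal(pairwise_fst(gf, "A", "B")$theta, 1)

  # popB a copy of popA: no differentiation signal
  set.seed(21)
  Xa <- matrix(rbinom(60, 2, 0.4), 6, 10)
  gc <- toy_genotypes(rbind(Xa, Xa), rep(c("A", "B"), each = 6))
  expect_lte(pairwise_fst(gc, "A", "B")$theta, 1e-10)

  # written-out 2-population 2-locus toy
  X <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(0L, 2L),
             c(2L, 2L), c(1L, 0L), c(0L, 0L), c(2L, 1L))
  g <- toy_genotypes(X, rep(c("A", "B"), each = 4))
  expect_equal(pairwise_fst(g, "A", "B")$theta,
               oracle_wc_theta(X, rep(c("A", "B"), each = 4)),
               tolerance = 1e-12)

  # random matrices with missingness
  for (rep in 1:5) {
    set.seed(rep + 50)
    g <- random_genotypes(16, 12, n_pops = 2, miss = 0.15)
    expect_equal(pairwise_fst(g, "pop1", "pop2")$theta,
                 oracle_wc_theta(g$dosage, g$pop_labels),
                 tolerance = 1e-12, label = sprintf("replicate %d", rep))
  }

  # no informative locus -> labelled, not a crash
  g0 <- toy_genotypes(matrix(0L, 8, 3), rep(c("A", "B"), each = 4))
  r0 <- pairwise_fst(g0, "A", "B")
  expect_false(r0$defined)
  expect_true(is.na(r0$theta))
})

test_that("theta is stable under sample duplication (checked against the oracle)", {
  set.seed(8)
  g <- random_genotypes(14, 20, n_pops = 2, miss = 0)
  th1 <- pairwise_fst(g, "pop1", "pop2")$theta
  gd <- toy_genotypes(rbind(g$dosage, g$dosage),
                      c(g$pop_labels, g$pop_labels))
  th2 <- pairwise_fst(gd, "pop1", "pop2")$theta
  expect_equal(th2, oracle_wc_theta(gd$dosage, gd$pop_labels),
               tolerance = 1e-12)
  expect_lt(abs(th1 - th2), 0.05)   # differs only by small-sample terms
})

test_that("permutation p-values are uniform under the null", {
  set.seed(99)
  n_rep <- 400
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    g <- random_genotypes(12, 15, n_pops = 1, miss = 0)
    labs <- sample(rep(c("A", "B"), each = 6))
    g$pop_labels <- labs
    pvals[i] <- pairwise_fst(g, "A", "B", n_perm = 79)$p_value
  }
  expect_true(all(pvals > 0 & pvals <= 1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  # discrete grid of (b+1)/80 adds at most ~1/160 to the KS statistic
  expect_lt(unname(ks$statistic), 1.63 / sqrt(n_rep) + 1 / 158)
})

test_that("expected heterozygosity matches observed in expectation under random mating", {
  set.seed(123)
  p <- runif(2000, 0.1, 0.9)
  X <- matrix(rbinom(20 * 2000, 2, rep(p, each = 20)), nrow = 20)
  g <- toy_genotypes(X, rep("p", 20))
  s <- pop_stats(g, "p")
  expect_lt(abs(s$H_E - s$H_O), 0.01)
})

test_that("Nei's distance follows its definition, with a finite cap", {
  expect_equal(nei_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(nei_distance(c(0, 0), c(1, 1)), 50)     # opposite fixation
  expect_equal(nei_distance(c(0.2, 0.8), c(0.4, 0.6)),
               oracle_nei(c(0.2, 0.8), c(0.4, 0.6)), tolerance = 1e-12)
  set.seed(4)
  fa <- runif(30); fb <- runif(30)
  expect_equal(nei_distance(fa, fb), oracle_nei(fa, fb), tolerance = 1e-12)
  expect_error(nei_distance(numeric(0), numeric(0)), "no loci")
  expect_error(nei_distance(c(0.5, 1.2), c(0.5, 0.5)), "\\[0, 1\\]")
})
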