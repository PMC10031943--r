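test_that("simulation is a pure function of seed and stream", {
  s1 <- hybridization_scenarios()[[1]]
  truth <- default_pod_truth()
  pr <- truth[intersect(names(truth), unlist(s1$params))]
  g1 <- simulate_snp_panel(s1, pr, default_sample_sizes(), 50, seed = 7,
                           stream = 3)
  g2 <- simulate_snp_panel(s1, pr, default_sample_sizes(), 50, seed = 7,
                           stream = 3)
  g3 <- simulate_snp_panel(s1, pr, default_sample_sizes(), 50, seed = 7,
                           stream = 4)
  expect_identical(g1$dosage, g2$dosage)
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("pairwise coalescence time in a panmictic population averages 2N generations", {
  s <- scenario(0, "p", c(p = 1000), list(), list(), "panmictic")
  tm <- simulate_tmrca(s, c(x = 1), c(p = 1), n_loci = 10000, seed = 31)
  # T ~ Exp(1/2N): mean 2N, sd 2N
  se <- 2000 / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("a vanishing divergence time gives F_ST centred on zero", {
  s <- scenario(0, c("a", "b"), c(a = 2000, b = 2000),
                list(ev_divergence("t", "b", "a")))
  th <- vapply(1:40, function(i) {
    g <- simulate_snp_panel(s, c(t = 1e-6), c(a = 15, b = 15), 80,
                            seed = 13, stream = i)
    pairwise_fst(g, "a", "b")$theta
  }, numeric(1))
  expect_lt(abs(mean(th)), 3 * stats::sd(th) / sqrt(length(th)) + 1e-3)
})

test_that("median F_ST increases strictly with divergence time", {
  s <- scenario(0, c("a", "b"), c(a = 1000, b = 1000),
                list(ev_divergence("t", "b", "a")))
  med <- vapply(c(20, 100, 500, 2500), function(tt) {
    th <- vapply(1:30, function(i) {
      g <- simulate_snp_panel(s, c(t = tt), c(a = 12, b = 12), 100,
                              seed = 17, stream = i)
      pairwise_fst(g, "a", "b")$theta
    }, numeric(1))
    stats::median(th)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("a hybrid founded almost entirely from one parent looks like that parent", {
  pops <- c("a", "h", "b")
  sizes <- c(a = 5000, h = 5000, b = 5000)
  s_mix <- scenario(0, pops, sizes,
                    list(ev_admixture(50, "h", "a", "b", 0.999),
                         ev_divergence(5000, "b", "a")))
  s_pure <- scenario(0, pops, sizes,
                     list(ev_divergence(50, "h", "a"),
                          ev_divergence(5000, "b", "a")))
  fst_mix <- fst_pure <- numeric(30)
  for (i in 1:30) {
    gm <- simulate_snp_panel(s_mix, c(x = 1), c(a = 12, h = 12, b = 12), 80,
                             seed = 3, stream = i)
    gp <- simulate_snp_panel(s_pure, c(x = 1), c(a = 12, h = 12, b = 12), 80,
                             seed = 4, stream = i)
    fst_mix[i] <- pairwise_fst(gm, "a", "h")$theta
    fst_pure[i] <- pairwise_fst(gp, "a", "h")$theta
  }
  expect_lt(abs(mean(fst_mix) - mean(fst_pure)),
            3 * sqrt(stats::var(fst_mix) / 30 + stats::var(fst_pure) / 30) +
              5e-3)
})

test_that("impossible configurations produce labelled errors", {
  s <- scenario(0, c("a", "b"), c(a = 100, b = 100),
                list(ev_divergence(10, "b", "a")))
  expect_error(simulate_snp_panel(s, c(x = 1), c(a = 0, b = 0), 5),
               "impossible sample configuration")
  orphan <- scenario(0, c("a", "b", "c"), c(a = 100, b = 100, c = 100),
                     list(ev_divergence(10, "b", "a")))
  expect_error(simulate_snp_panel(orphan, c(x = 1), c(a = 2, b = 2, c = 2), 5),
               "invalid scenario")
})

test_that("reference-table bookkeeping: schema, determinism, prior marginals", {
  scs <- hybridization_scenarios()[c(1, 9)]
  ss <- c(micrantha = 5L, ptilosperma = 5L, introgressed_flavida = 5L,
          flavida = 5L)
  r1 <- build_reference_table(scs, prior_set(), ss, n_loci = 10, n_sims = 3,
                              seed = 77)
  expect_equal(nrow(r1), 6)
  expect_equal(r1$scenario, rep(c(1, 9), each = 3))
  r2 <- build_reference_table(scs, prior_set(), ss, n_loci = 10, n_sims = 3,
                              seed = 77)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(is.finite(as.matrix(
    as.data.frame(r1)[, attr(r1, "stat_names")]))))
  # scenario 9 has no admixture parameters: NA in those columns
  expect_true(all(is.na(r1[r1$scenario == 9, "r2"])))

  # unconstrained parameters keep their uniform marginals
  rbig <- build_reference_table(scs[1], prior_set(), ss, n_loci = 8,
                                n_sims = 600, seed = 42)
  for (p in c("N1", "Na")) {
    ks <- stats::ks.test((rbig[[p]] - 10) / (1e5 - 10), "punif")
    expect_gt(ks$p.value, 0.001)
  }
  ks_r <- stats::ks.test((rbig[["r2"]] - 0.001) / 0.998, "punif")
  expect_gt(ks_r$p.value, 0.001)
  # constrained times still satisfy their ordering everywhere
  expect_true(all(rbig$t1 < rbig$t2 & rbig$t2 < rbig$t4))
})
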