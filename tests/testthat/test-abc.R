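make_ref <- function(df, param_names, stat_names) {
  structure(df, class = c("reference_table", "data.frame"),
            param_names = param_names, stat_names = stat_names,
            metadata = list())
}

test_that("the admixture statistic is 1 at parent P1, 0 at parent P2, and matches hand computation", {
  set.seed(3)
  XA <- matrix(rbinom(40, 2, 0.8), 5, 8)
  XB <- matrix(rbinom(40, 2, 0.2), 5, 8)
  specs <- list(list(hybrid = "H", parents = c("A", "B")))
  gA <- toy_genotypes(rbind(XA, XA, XB), rep(c("A", "H", "B"), each = 5))
  stA <- summary_stats(gA, admixed_specs = specs)
  expect_equal(unname(stA["admix_H"]), 1, tolerance = 1e-12)
  gB <- toy_genotypes(rbind(XA, XB, XB), rep(c("A", "H", "B"), each = 5))
  expect_equal(unname(summary_stats(gB, admixed_specs = specs)["admix_H"]),
               0, tolerance = 1e-12)

  # 3-group 4-locus toy against independently computed entries
  set.seed(9)
  X <- matrix(rbinom(36, 2, 0.5), 9, 4)
  labs <- rep(c("A", "H", "B"), each = 3)
  st <- summary_stats(toy_genotypes(X, labs), admixed_specs = specs)
  freq <- function(rows) colSums(X[rows, ]) / (2 * length(rows))
  pA <- freq(1:3); pH <- freq(4:6); pB <- freq(7:9)
  expect_equal(unname(st["admix_H"]),
               mean((pH - pB) * (pA - pB)) / mean((pA - pB)^2),
               tolerance = 1e-12)
  expect_equal(unname(st["fst_A.B"]), oracle_wc_theta(X[c(1:3, 7:9), ],
               labs[c(1:3, 7:9)]), tolerance = 1e-12)
  expect_equal(unname(st["nei_A.H"]), oracle_nei(pA, pH), tolerance = 1e-12)
  o <- oracle_pop_stats(X[1:3, , drop = FALSE])
  expect_equal(unname(st["het_A"]), o$H_E, tolerance = 1e-12)
  expect_error(summary_stats(toy_genotypes(X, labs),
                             admixed_specs = list(list(hybrid = "Z",
                                                       parents = c("A", "B")))),
               "absent group")
})

test_that("rejection selection reproduces the brute-force ranking", {
  set.seed(14)
  df <- data.frame(scenario = rep(1:2, each = 5),
                   s1 = rnorm(10), s2 = rnorm(10), s3 = rnorm(10))
  ref <- make_ref(df, character(0), c("s1", "s2", "s3"))
  obs <- c(s1 = 0.2, s2 = -0.4, s3 = 0.1)

  sel_all <- rejection_select(ref, obs, fraction = 1)
  expect_equal(length(sel_all$rows), 10)

  sel3 <- rejection_select(ref, obs, fraction = 0.3)
  S <- as.matrix(df[, c("s1", "s2", "s3")])
  expect_equal(sel3$rows, oracle_rejection(S, obs, 3))

  # observed identical to a simulated row
  obs2 <- c(s1 = df$s1[4], s2 = df$s2[4], s3 = df$s3[4])
  sel1 <- rejection_select(ref, obs2, fraction = 0.1)
  expect_equal(sel1$rows, 4L)
  expect_equal(sel1$distance, 0)

  # zero-variance statistic excluded with a warning
  df0 <- df; df0$s3 <- 1
  expect_warning(rejection_select(make_ref(df0, character(0),
                                           c("s1", "s2", "s3")),
                                  obs, fraction = 0.5),
                 "zero-variance")
})

test_that("direct model choice is a nearest-neighbour vote", {
  df <- data.frame(scenario = c(1, 1, 1, 2, 2, 3),
                   s1 = c(0.1, 0.2, 0.3, 5, 6, 9))
  ref <- make_ref(df, character(0), "s1")
  sel <- rejection_select(ref, c(s1 = 0), fraction = 1)
  expect_equal(unname(model_choice_direct(sel, k = 3)), c(1, 0, 0))
  probs <- model_choice_direct(sel, k = 5)
  expect_equal(unname(probs), c(3 / 5, 2 / 5, 0))
  expect_error(model_choice_direct(sel, k = 10), "exceeds")
})

test_that("logistic model choice: symmetry, separability and agreement with the direct vote", {
  set.seed(25)
  n <- 400
  # two scenarios with identical stat distributions
  df <- data.frame(scenario = rep(1:2, each = n),
                   s1 = rnorm(2 * n), s2 = rnorm(2 * n))
  ref <- make_ref(df, character(0), c("s1", "s2"))
  sel <- rejection_select(ref, c(s1 = 0, s2 = 0), fraction = 1)
  mc <- model_choice_logistic(sel)
  expect_equal(unname(mc$probs), c(0.5, 0.5), tolerance = 0.1)
  expect_true(all(mc$probs >= mc$ci[, "lower"] - 1e-9 &
                    mc$probs <= mc$ci[, "upper"] + 1e-9))
  expect_equal(sum(mc$probs), 1, tolerance = 1e-9)

  # scenario 1 linearly separable and closer to the observation
  df_sep <- data.frame(scenario = rep(1:2, each = n),
                       s1 = c(rnorm(n, 0, 0.3), rnorm(n, 4, 0.3)))
  sel_sep <- rejection_select(make_ref(df_sep, character(0), "s1"),
                              c(s1 = 0), fraction = 1)
  mc_sep <- model_choice_logistic(sel_sep)
  expect_gt(mc_sep$probs[["1"]], 0.95)

  # well-mixed table: direct and logistic agree within 0.1
  df_mix <- data.frame(scenario = rep(1:2, each = n),
                       s1 = c(rnorm(n, 0, 1), rnorm(n, 0.8, 1)))
  sel_mix <- rejection_select(make_ref(df_mix, character(0), "s1"),
                              c(s1 = 0), fraction = 1)
  direct <- model_choice_direct(sel_mix, k = 100)
  logit <- model_choice_logistic(sel_mix)$probs
  expect_lt(max(abs(direct - logit)), 0.1)
})

test_that("posterior adjustment is exact on a noiseless linear map and inert without signal", {
  s1 <- hybridization_scenarios()[[1]]
  priors <- prior_set()
  n <- 60
  set.seed(33)
  z <- rnorm(n)
  r2 <- 0.001 + 0.998 / (1 + exp(-z))
  df <- data.frame(scenario = 1, r2 = r2,
                   s1 = 2 * z + 1, s2 = rnorm(n))   # s2 carries no signal
  ref <- make_ref(df, "r2", c("s1", "s2"))
  z_star <- 0.31
  obs <- c(s1 = 2 * z_star + 1, s2 = 0)
  sel <- rejection_select(ref, obs, fraction = 1)
  post <- estimate_posterior(sel, priors, s1, params = "r2")
  true_r2 <- 0.001 + 0.998 / (1 + exp(-z_star))
  expect_equal(post$params$r2$adjusted, rep(true_r2, n), tolerance = 1e-8)
  expect_equal(post$params$r2$median, true_r2, tolerance = 1e-8)
  # adjusted draws always inside the prior interval, even when extrapolating
  expect_true(all(post$params$r2$adjusted > 0.001 &
                    post$params$r2$adjusted < 0.999))

  # zero slopes by construction: mirrored parameter values per stats row
  zz <- rnorm(n)
  df2 <- data.frame(scenario = 1,
                    r2 = 0.001 + 0.998 / (1 + exp(-c(zz, -zz))),
                    s1 = rep(rnorm(n), 2), s2 = rep(rnorm(n), 2))
  sel2 <- rejection_select(make_ref(df2, "r2", c("s1", "s2")),
                           c(s1 = 0, s2 = 0), fraction = 1)
  post2 <- estimate_posterior(sel2, priors, s1, params = "r2")
  expect_equal(sort(post2$params$r2$adjusted), sort(df2$r2),
               tolerance = 1e-8)
  expect_error(estimate_posterior(
    rejection_select(make_ref(df2[1:10, ], "r2", c("s1", "s2")),
                     c(s1 = 0, s2 = 0), fraction = 1), priors, s1),
    ">= 20")
})

test_that("model-check PCA satisfies the eigenstructure identities", {
  set.seed(77)
  S <- matrix(rnorm(300), 100, 3)
  S[, 2] <- S[, 1] * 0.5 + S[, 2]
  df <- data.frame(scenario = 1, S)
  colnames(df)[2:4] <- c("s1", "s2", "s3")
  ref <- make_ref(df, character(0), c("s1", "s2", "s3"))

  # mean vector projects to the origin
  obs_mean <- colMeans(df[, 2:4])
  chk <- model_check_pca(ref, obs_mean)
  expect_equal(unname(as.numeric(chk$obs_coords)), c(0, 0),
               tolerance = 1e-12)

  # per-component variance of projected rows equals the eigenvalues
  expect_equal(unname(apply(chk$ref_coords, 2, stats::var)),
               chk$sdev[1:2]^2, tolerance = 1e-12)

  # components match an independent eigendecomposition
  ev <- eigen(stats::cov(scale(as.matrix(df[, 2:4]))))
  expect_equal(chk$sdev^2, ev$values, tolerance = 1e-9)
  for (k in 1:2)
    expect_equal(abs(unname(chk$rotation[, k])), abs(unname(ev$vectors[, k])),
                 tolerance = 1e-9)

  # posterior-predictive rows are projected with the same transform
  chk2 <- model_check_pca(ref, obs_mean, posterior_sims = df[1:5, ])
  expect_equal(dim(chk2$post_coords), c(5L, 2L))
})
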