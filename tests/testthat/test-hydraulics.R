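test_that("RWC and CWR follow their defining arithmetic", {
  expect_equal(rwc(2.0, 1.0, 2.0), 1)
  expect_equal(rwc(1.0, 1.0, 2.0), 0)
  expect_equal(rwc(1.5, 1.0, 2.0), 0.5)
  expect_warning(r <- rwc(2.2, 1.0, 2.0), "clipped")
  expect_equal(r, 1)
  expect_error(rwc(1.5, 2.0, 1.0), "saturated mass")

  expect_equal(cwr(1, 2.0, 1.0, 0.5), 0)
  expect_equal(cwr(0.5, 2.0, 1.0, 0.5), 250)
  # total releasable water per wood volume at RWC = 0
  expect_equal(cwr(0, 2.0, 1.0, 0.5), (2 - 1) * 0.5 * 1000 / 1)
  # monotone: CWR decreases as RWC rises
  expect_true(all(diff(cwr(seq(0, 1, 0.1), 2, 1, 0.5)) < 0))
})

test_that("the hyperbolic fit recovers noiseless parameters exactly", {
  curve <- generate_water_release(a = 300, b = 2, noise_sd = 0)
  fit <- fit_hyperbolic(curve)
  expect_equal(fit$a, 300, tolerance = 1e-6)
  expect_equal(fit$b, 2, tolerance = 1e-6)
  expect_false(fit$degenerate)
  expect_equal(fit$phase_boundary, fit$b)

  # y identically zero: flagged degenerate, a = 0
  flat <- curve
  flat$cwr <- rep(0, length(flat$cwr))
  fit0 <- fit_hyperbolic(flat)
  expect_true(fit0$degenerate)
  expect_equal(fit0$a, 0)
  expect_true(is.na(fit0$b))

  expect_error(fit_hyperbolic(list(psi = c(-1, -2), cwr = c(10, 20))),
               ">= 4 observations")
})

test_that("capacitance closed forms match the generic delta-CWR computation", {
  fit <- fit_hyperbolic(generate_water_release(a = 300, b = 2, noise_sd = 0))
  cap <- capacitance(fit, psi_max = 8)
  expect_equal(cap$C_phase1, 300 / (2 * 2), tolerance = 1e-6)
  expect_equal(cap$C_phase2, 300 * (8 / 10 - 1 / 2) / 6, tolerance = 1e-6)

  # generic ratio computed from the fitted function itself
  y <- function(x) fit$a * x / (fit$b + x)
  expect_equal(cap$C_phase1, (y(fit$b) - y(0)) / (fit$b - 0),
               tolerance = 1e-12)
  expect_equal(cap$C_phase2, (y(8) - y(fit$b)) / (8 - fit$b),
               tolerance = 1e-12)

  # rapid phase always releases faster than the gradual phase
  for (a in c(50, 300)) for (b in c(0.5, 2, 6)) {
    capx <- capacitance(fit_hyperbolic(
      generate_water_release(a = a, b = b, noise_sd = 0)), psi_max = 8)
    expect_gt(capx$C_phase1, capx$C_phase2)
  }

  # phase II empty when b exceeds the driest potential
  fit_big_b <- list(a = 300, b = 9, degenerate = FALSE)
  cap_b <- capacitance(fit_big_b, psi_max = 8)
  expect_true(cap_b$phase2_empty)
  expect_true(is.na(cap_b$C_phase2))
})

test_that("noisy water-release fits recover the truth to a few percent", {
  err_a <- err_b <- numeric(60)
  for (i in 1:60) {
    curve <- generate_water_release(a = 300, b = 2, noise_sd = 15,
                                    n_points = 14, seed = i)
    fit <- fit_hyperbolic(curve)
    err_a[i] <- abs(fit$a - 300) / 300
    err_b[i] <- abs(fit$b - 2) / 2
  }
  expect_lt(stats::median(err_a), 0.10)
  expect_lt(stats::median(err_b), 0.25)
})

test_that("turgor loss point is recovered from generated pressure-volume data", {
  pv <- generate_pv(pi0 = -1.5, rwc_tlp = 0.9, noise_sd = 0, n_points = 14)
  truth <- attr(pv, "truth")
  tlp <- turgor_loss_point(pv)
  expect_lt(abs(tlp$psi_tlp - truth[["psi_tlp"]]), 0.05)
  expect_lt(abs(tlp$pi_0 - truth[["pi0"]]), 0.1)
  expect_false(tlp$boundary)

  # thermodynamic ordering: psi_TLP <= pi_0 < 0
  expect_lte(tlp$psi_tlp, tlp$pi_0)
  expect_lt(tlp$pi_0, 0)

  # zero turgor throughout: pure osmotic line, boundary flagged
  R <- seq(0.98, 0.6, length.out = 10)
  psi <- -1.5 / R
  mass <- 0.3 + R * 0.7
  pv0 <- pv_curve(psi, mass, dry_mass = 0.3, saturated_mass = 1)
  tlp0 <- turgor_loss_point(pv0)
  expect_true(tlp0$boundary)
  expect_equal(tlp0$psi_tlp, psi[1], tolerance = 1e-6)

  expect_error(turgor_loss_point(pv_curve(c(-1, -2, -3), c(0.9, 0.8, 0.7),
                                          0.3, 1)), ">= 6")
})

test_that("ordering and consistency hold over random PV parameter draws", {
  set.seed(202)
  for (i in 1:20) {
    pi0 <- runif(1, -3, -0.8)
    rt <- runif(1, 0.8, 0.95)
    pv <- generate_pv(pi0 = pi0, rwc_tlp = rt, noise_sd = 0.02,
                      n_points = 14, seed = i)
    tlp <- tryCatch(turgor_loss_point(pv, r2_min = 0.98),
                    error = function(e) NULL)
    if (is.null(tlp)) next
    expect_lte(tlp$psi_tlp, tlp$pi_0 + 1e-9)
    expect_lt(tlp$pi_0, 0)
  }

  # TLP recovery error does not decrease when sampling gets sparser
  errs <- vapply(c(20, 10, 7), function(np) {
    pv <- generate_pv(pi0 = -1.8, rwc_tlp = 0.88, noise_sd = 0,
                      n_points = np)
    abs(turgor_loss_point(pv)$psi_tlp - attr(pv, "truth")[["psi_tlp"]])
  }, numeric(1))
  expect_lte(errs[1], errs[3] + 0.02)
})
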