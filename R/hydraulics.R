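#' Relative water content
#'
#' `RWC = (W_f - W_d) / (W_s - W_d)`. Values outside [0, 1] (measurement
#' noise, slight oversaturation) are clipped with a warning.
#'
#' @param W_f fresh (current) mass, g. Vectorized.
#' @param W_d oven-dry mass, g.
#' @param W_s fully saturated mass, g (must exceed `W_d`).
#' @return RWC in [0, 1].
#' @export
rwc <- function(W_f, W_d, W_s) {
  if (any(W_s <= W_d))
    stop("saturated mass must exceed dry mass", call. = FALSE)
  r <- (W_f - W_d) / (W_s - W_d)
  if (any(r < 0 | r > 1)) {
    warning("RWC outside [0, 1] clipped", call. = FALSE)
    r <- pmin(pmax(r, 0), 1)
  }
  r
}

#' Cumulative water release per wood volume
#'
#' `CWR = (1 - RWC) * (W_s - W_d) * (rho * 1000 / W_d)` in kg m^-3, where
#' `rho` is wood density (dry mass over fresh volume, g cm^-3). Zero at full
#' saturation, increasing as the tissue dries.
#'
#' @param rwc relative water content (fraction). Vectorized.
#' @param W_s,W_d saturated and dry mass, g.
#' @param rho wood density, g cm^-3.
#' @return CWR, kg m^-3.
#' @export
cwr <- function(rwc, W_s, W_d, rho) {
  if (any(W_d <= 0)) stop("dry mass must be positive", call. = FALSE)
  (1 - rwc) * (W_s - W_d) * (rho * 1000 / W_d)
}

#' Water-release curve of a dehydrating wood segment
#'
#' Pairs of (water potential, segment mass) observations recorded while a
#' rehydrated segment dries, plus its saturated mass, dry mass and volume.
#' Water potentials may be given as negative MPa or as magnitudes; they are
#' stored as negative MPa.
#'
#' @param psi water potentials, MPa.
#' @param mass segment masses, g.
#' @param W_s,W_d saturated and dry mass, g.
#' @param volume fresh volume, cm^3.
#' @return object of class `water_release_curve` with per-observation `rwc`
#'   and `cwr`, and `rho = W_d / volume`.
#' @export
water_release_curve <- function(psi, mass, W_s, W_d, volume) {
  stopifnot(length(psi) == length(mass), volume > 0, W_d > 0, W_s > W_d)
  psi <- -abs(psi)
  rho <- W_d / volume
  r <- rwc(mass, W_d, W_s)
  structure(list(psi = psi, mass = mass, W_s = W_s, W_d = W_d,
                 volume = volume, rho = rho, rwc = r,
                 cwr = cwr(r, W_s, W_d, rho)),
            class = "water_release_curve")
}

#' Fit the hyperbolic water-release model
#'
#' Nonlinear least squares of `CWR = a * x / (b + x)` on the water-potential
#' magnitude `x = |psi|`: `a` is the asymptotic cumulative water release
#' (kg m^-3) and `b` (MPa) the half-saturation scale that also marks the
#' boundary between the initial rapid-release phase and the gradual phase.
#' Fits are started from a grid of initial values and the converged fit with
#' the lowest residual sum of squares is kept.
#'
#' @param curve a [water_release_curve()] (or a list with elements `psi` and
#'   `cwr`).
#' @return object of class `hyperbolic_fit`: `a`, `b`, `rss`,
#'   `phase_boundary` (= b), `degenerate` flag, `fitted`.
#' @export
fit_hyperbolic <- function(curve) {
  x <- abs(curve$psi)
  y <- curve$cwr
  if (length(unique(x)) < 4)
    stop("need >= 4 observations with distinct water potentials",
         call. = FALSE)
  if (all(abs(y) < 1e-12)) {
    return(structure(list(a = 0, b = NA_real_, rss = 0,
                          phase_boundary = NA_real_, degenerate = TRUE,
                          fitted = rep(0, length(x))),
                     class = "hyperbolic_fit"))
  }
  ymax <- max(y)
  starts <- expand.grid(a = ymax * c(1, 1.5, 3),
                        b = stats::median(x) * c(0.25, 1, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * x / (b + x),
                        start = list(a = starts$a[i], b = starts$b[i]),
                        lower = c(a = 0, b = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("hyperbolic fit did not converge from any start", call. = FALSE)
  cf <- coef(best$fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), rss = best$rss,
                 phase_boundary = unname(cf["b"]), degenerate = FALSE,
                 fitted = as.numeric(predict(best$fit))),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  if (x$degenerate) cat("degenerate fit: no water released (a = 0)\n")
  else cat(sprintf("CWR = a*x/(b+x): a = %.3f kg m^-3, b = %.3f MPa (rss %.3g)\n",
                   x$a, x$b, x$rss))
  invisible(x)
}

#' Two-phase hydraulic capacitance from a hyperbolic fit
#'
#' `C = dCWR / dPsi` computed over the two phases split at the fitted `b`:
#' phase I from 0 to `b` (rapid release), `C_I = (y(b) - y(0)) / b = a/(2b)`,
#' and phase II from `b` to `psi_max`,
#' `C_II = (y(psi_max) - y(b)) / (psi_max - b)`. When `b >= psi_max` phase II
#' is empty: its capacitance is NA and the result is flagged.
#'
#' @param fit a [fit_hyperbolic()] result.
#' @param psi_max magnitude of the driest measured potential, MPa (default 8).
#' @return list of class `capacitance`: `C_phase1`, `C_phase2`
#'   (kg m^-3 MPa^-1), `psi_max`, `phase2_empty` flag.
#' @export
capacitance <- function(fit, psi_max = 8) {
  if (fit$degenerate || is.na(fit$b))
    return(structure(list(C_phase1 = 0, C_phase2 = 0, psi_max = psi_max,
                          phase2_empty = FALSE, degenerate = TRUE),
                     class = "capacitance"))
  yfun <- function(x) fit$a * x / (fit$b + x)
  c1 <- (yfun(fit$b) - yfun(0)) / fit$b
  if (fit$b >= psi_max) {
    return(structure(list(C_phase1 = c1, C_phase2 = NA_real_,
                          psi_max = psi_max, phase2_empty = TRUE,
                          degenerate = FALSE), class = "capacitance"))
  }
  c2 <- (yfun(psi_max) - yfun(fit$b)) / (psi_max - fit$b)
  structure(list(C_phase1 = c1, C_phase2 = c2, psi_max = psi_max,
                 phase2_empty = FALSE, degenerate = FALSE),
            class = "capacitance")
}

#' Leaf pressure-volume curve
#'
#' Ordered (water potential, fresh mass) observations from bench drying of a
#' rehydrated leaf, with its saturated and oven-dry mass. Water potential is
#' stored as negative MPa; monotonicity is not assumed (measurement noise).
#'
#' @param psi leaf water potentials, MPa.
#' @param mass fresh masses, g.
#' @param dry_mass,saturated_mass g; `dry_mass < saturated_mass`.
#' @param leaf_area m^2 (optional; reporting only).
#' @return object of class `pv_curve`.
#' @export
pv_curve <- function(psi, mass, dry_mass, saturated_mass, leaf_area = NA) {
  stopifnot(length(psi) == length(mass), dry_mass > 0,
            saturated_mass > dry_mass, all(mass > 0))
  structure(list(psi = -abs(psi), mass = mass, dry_mass = dry_mass,
                 saturated_mass = saturated_mass, leaf_area = leaf_area),
            class = "pv_curve")
}

#' Turgor loss point from a pressure-volume curve
#'
#' Standard P-V analysis: plot `1/(-psi)` against `1 - RWC`. Beyond the
#' turgor loss point the relation is linear (purely osmotic), so the
#' post-turgor segment is grown from the driest point while the linear fit
#' keeps `R^2 >= r2_min` and the next (wetter) point's residual stays within
#' `resid_mult` RMSE of the fit. The turgor loss point is the water potential
#' predicted by that line at the wettest point of the segment,
#' `psi_TLP = -1 / yhat`, and the osmotic potential at full turgor is
#' `pi_0 = -1 / intercept`.
#'
#' @param pv a [pv_curve()] with >= 6 points spanning the turgor loss point.
#' @param r2_min minimum R^2 for the post-turgor line.
#' @param resid_mult residual tolerance in RMSE multiples when extending the
#'   segment.
#' @return list of class `tlp_fit`: `psi_tlp`, `pi_0` (MPa, negative),
#'   `segment` (indices of post-turgor points, driest first), `r2`,
#'   `boundary` flag (TRUE when every point is post-turgor, i.e. zero turgor
#'   throughout and the TLP is reported at the first observation).
#' @export
turgor_loss_point <- function(pv, r2_min = 0.995, resid_mult = 2) {
  if (length(pv$psi) < 6)
    stop("need >= 6 pressure-volume points", call. = FALSE)
  if (any(pv$psi >= 0))
    stop("water potentials must be negative (wilting leaf)", call. = FALSE)
  r <- rwc(pv$mass, pv$dry_mass, pv$saturated_mass)
  x <- 1 - r
  y <- 1 / (-pv$psi)
  ord <- order(x)                     # wettest ... driest
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  r2_of <- function(idx) {
    f <- lm(ys[idx] ~ xs[idx])
    ss <- sum(stats::resid(f)^2)
    tot <- sum((ys[idx] - mean(ys[idx]))^2)
    list(fit = f, r2 = if (tot > 0) 1 - ss / tot else 1,
         rmse = sqrt(ss / length(idx)))
  }
  seg <- seq(n - 2, n)                # driest three points
  cur <- r2_of(seg)
  if (cur$r2 < r2_min)
    stop("no linear post-turgor tail detectable (R^2 = ",
         signif(cur$r2, 3), ")", call. = FALSE)
  while (seg[1] > 1) {
    cand <- seg[1] - 1
    pred <- unname(coef(cur$fit)[1] + coef(cur$fit)[2] * xs[cand])
    if (abs(ys[cand] - pred) > resid_mult * max(cur$rmse, 1e-12)) break
    ext <- r2_of(c(cand, seg))
    if (ext$r2 < r2_min) break
    seg <- c(cand, seg)
    cur <- ext
  }
  cf <- coef(cur$fit)
  yhat_first <- unname(cf[1] + cf[2] * xs[seg[1]])
  psi_tlp <- -1 / yhat_first
  pi_0 <- -1 / unname(cf[1])
  structure(list(psi_tlp = psi_tlp, pi_0 = pi_0,
                 segment = ord[seg], r2 = cur$r2,
                 boundary = seg[1] == 1),
            class = "tlp_fit")
}

#' @export
print.tlp_fit <- function(x, ...) {
  cat(sprintf("psi_TLP = %.3f MPa, pi_0 = %.3f MPa (post-turgor segment: %d points, R^2 = %.4f)%s\n",
              x$psi_tlp, x$pi_0, length(x$segment), x$r2,
              if (x$boundary) " [boundary: zero turgor throughout]" else ""))
  invisible(x)
}
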