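#' Summary statistics for ABC
#'
#' Deterministic named vector computed from a genotype panel: per-group
#' unbiased gene diversity and proportion of monomorphic loci, pairwise
#' Weir-Cockerham F_ST and Nei's distance for every group pair, and one
#' frequency-based admixture statistic per admixed-group specification,
#' `f = mean[(p_H - p_P2)(p_P1 - p_P2)] / mean[(p_P1 - p_P2)^2]`,
#' which is 1 when the hybrid's allele frequencies equal parent P1's and 0
#' when they equal parent P2's. All entries are finite: an undefined F_ST is
#' recorded as 0, Nei's distance is capped, and an admixture statistic with
#' uninformative parents (identical frequencies at every locus) is recorded
#' as 0.5.
#'
#' @param g a [genotype_matrix()].
#' @param group_map optional named character vector mapping population labels
#'   to group labels; by default each population is its own group.
#' @param admixed_specs list of `list(hybrid =, parents = c(P1, P2))` entries;
#'   see [default_admixed_specs()].
#' @return named numeric vector with attribute `definition`.
#' @export
summary_stats <- function(g, group_map = NULL,
                          admixed_specs = default_admixed_specs()) {
  validate_genotype_matrix(g)
  labels <- g$pop_labels
  if (!is.null(group_map)) {
    unknown <- setdiff(labels, names(group_map))
    if (length(unknown) > 0)
      stop("group_map missing populations: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    labels <- unname(group_map[labels])
  }
  groups <- unique(labels)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  idx <- split(seq_along(labels), factor(labels, levels = groups))
  for (spec in admixed_specs) {
    absent <- setdiff(c(spec$hybrid, spec$parents), groups)
    if (length(absent) > 0)
      stop("admixed_specs refer to absent group(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  summary_stats_matrix(g$dosage, idx, admixed_specs)
}

# fast path on a raw dosage matrix; idx is a named list of row indices
summary_stats_matrix <- function(X, idx, admixed_specs) {
  fr <- pop_locus_freqs(X, idx)
  groups <- names(idx)
  P <- length(groups)
  out <- numeric(0)

  # per-group gene diversity (unbiased) and monomorphic proportion
  for (i in seq_len(P)) {
    n <- fr$n[i, ]; p <- fr$p[i, ]
    use <- n >= 1
    he <- (2 * n[use] / (2 * n[use] - 1)) * 2 * p[use] * (1 - p[use])
    out <- c(out, mean(he), mean(p[use] * (1 - p[use]) == 0))
  }
  names(out) <- as.vector(rbind(paste0("het_", groups),
                                paste0("mono_", groups)))

  # pairwise F_ST and Nei's distance
  for (i in seq_len(P - 1)) for (j in seq(i + 1, P)) {
    comp <- wc_components_pair(fr$n[i, ], fr$p[i, ], fr$h[i, ],
                               fr$n[j, ], fr$p[j, ], fr$h[j, ])
    fst <- if (comp$n_loci == 0L || comp$abc == 0) 0 else comp$a / comp$abc
    ok <- fr$n[i, ] >= 1 & fr$n[j, ] >= 1
    nei <- if (any(ok)) nei_distance(fr$p[i, ok], fr$p[j, ok]) else 0
    out <- c(out, setNames(c(fst, nei),
                           paste0(c("fst_", "nei_"), groups[i], ".", groups[j])))
  }

  # admixture statistics
  for (spec in admixed_specs) {
    hI <- match(spec$hybrid, groups)
    p1 <- match(spec$parents[1], groups)
    p2 <- match(spec$parents[2], groups)
    ok <- fr$n[hI, ] >= 1 & fr$n[p1, ] >= 1 & fr$n[p2, ] >= 1
    dpar <- fr$p[p1, ok] - fr$p[p2, ok]
    denom <- mean(dpar^2)
    f <- if (!any(ok) || denom < 1e-12) 0.5 else
      mean((fr$p[hI, ok] - fr$p[p2, ok]) * dpar) / denom
    out <- c(out, setNames(f, paste0("admix_", spec$hybrid)))
  }

  attr(out, "definition") <- paste(
    "per-group unbiased gene diversity and monomorphic proportion;",
    "pairwise Weir-Cockerham F_ST and Nei's distance;",
    "frequency-based admixture f per admixed spec")
  out
}

#' ABC rejection step
#'
#' Standardizes each summary statistic by its median absolute deviation over
#' the reference table (statistics with zero MAD are excluded from the
#' distance, with a warning), computes Euclidean distances from the observed
#' vector, and keeps the `ceiling(fraction * n)` closest rows (ties broken by
#' row order).
#'
#' @param ref a `reference_table` from [build_reference_table()].
#' @param obs named observed summary-statistic vector ([summary_stats()]).
#' @param fraction tolerance: fraction of rows to keep, in (0, 1].
#' @return object of class `abc_rejection`: `rows` (indices into `ref`,
#'   sorted by distance), `distance` (sorted), `table` (selected rows),
#'   `stats_used`, `d_max`, `obs`, `mads`.
#' @export
rejection_select <- function(ref, obs, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  stat_names <- attr(ref, "stat_names")
  if (!all(stat_names %in% names(obs)))
    stop("observed vector is missing statistics: ",
         paste(setdiff(stat_names, names(obs)), collapse = ", "),
         call. = FALSE)
  S <- as.matrix(as.data.frame(ref)[, stat_names, drop = FALSE])
  mads <- apply(S, 2, mad)
  usable <- mads > 0
  if (!all(usable))
    warning("excluding zero-variance statistic(s) from the distance: ",
            paste(stat_names[!usable], collapse = ", "), call. = FALSE)
  if (!any(usable)) stop("no usable summary statistic", call. = FALSE)
  su <- stat_names[usable]
  Z <- sweep(S[, su, drop = FALSE], 2, mads[su], "/")
  z_obs <- obs[su] / mads[su]
  d <- unname(sqrt(rowSums(sweep(Z, 2, z_obs, "-")^2)))
  k <- ceiling(fraction * nrow(S))
  ord <- order(d, seq_along(d))[seq_len(k)]
  structure(list(rows = ord, distance = d[ord],
                 table = as.data.frame(ref)[ord, , drop = FALSE],
                 stats_used = su, d_max = max(d[ord]),
                 obs = obs[su], mads = mads[su],
                 param_names = attr(ref, "param_names")),
            class = "abc_rejection")
}

#' Direct ABC model choice
#'
#' Posterior model probabilities as each scenario's share among the `k`
#' nearest accepted simulations.
#'
#' @param sel an [rejection_select()] result.
#' @param k number of nearest rows to vote (<= number selected).
#' @return named numeric vector of probabilities summing to 1.
#' @export
model_choice_direct <- function(sel, k = 500) {
  if (k > length(sel$rows)) stop("k exceeds the number of selected rows",
                                 call. = FALSE)
  scen <- sel$table$scenario[seq_len(k)]
  tab <- table(factor(scen, levels = sort(unique(sel$table$scenario))))
  probs <- as.numeric(tab) / k
  names(probs) <- names(tab)
  probs
}

#' Logistic-regression ABC model choice
#'
#' Multinomial logistic regression of the scenario label on the standardized
#' differences (statistic - observed), evaluated at the origin; the estimate
#' generalizes the direct vote by borrowing strength from the local gradient
#' of scenario membership. A 95% confidence interval for each scenario's
#' probability is computed by the delta method on the fit's asymptotic
#' covariance. Near-separable fits (any coefficient beyond `sep_threshold`)
#' are refit with a small weight-decay penalty and flagged.
#'
#' @param sel an [rejection_select()] result containing >= 2 scenarios.
#' @param sep_threshold absolute coefficient size that triggers the penalized
#'   refit.
#' @return list of class `abc_model_choice`: `probs` (named, sums to 1),
#'   `ci` (matrix with columns lower/upper), `penalized` flag.
#' @export
model_choice_logistic <- function(sel, sep_threshold = 15) {
  scen <- factor(sel$table$scenario)
  if (nlevels(scen) < 2)
    stop("need >= 2 scenarios among the selected rows", call. = FALSE)
  S <- as.matrix(sel$table[, sel$stats_used, drop = FALSE])
  Z <- sweep(sweep(S, 2, sel$obs, "-"), 2, sel$mads, "/")
  colnames(Z) <- sel$stats_used
  dat <- data.frame(scen = scen, Z, check.names = TRUE)
  form <- scen ~ .
  fit <- nnet::multinom(form, data = dat, trace = FALSE, Hess = TRUE,
                        maxit = 500, MaxNWts = 5000)
  penalized <- FALSE
  if (max(abs(coef(fit))) > sep_threshold) {
    fit <- nnet::multinom(form, data = dat, trace = FALSE, Hess = TRUE,
                          maxit = 500, MaxNWts = 5000, decay = 0.01)
    penalized <- TRUE
  }
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(scen)[2], names(cf)))
  eta <- c(0, cf[, "(Intercept)"])          # linear predictors at the origin
  probs <- exp(eta - max(eta))
  probs <- probs / sum(probs)
  names(probs) <- levels(scen)

  ci <- ci_multinom_origin(fit, probs, nlevels(scen))
  structure(list(probs = probs, ci = ci, penalized = penalized),
            class = "abc_model_choice")
}

# delta-method 95% CI for the origin-evaluated class probabilities of an
# nnet::multinom fit; at the origin the probabilities depend only on the
# intercepts, so slope entries get zero gradient.
ci_multinom_origin <- function(fit, probs, K) {
  ci <- cbind(lower = pmax(0, probs - 0), upper = pmin(1, probs + 0))
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  if (is.null(V)) return(ci)
  pnamesV <- rownames(V)
  # names look like "<class>:(Intercept)" for K > 2, "(Intercept)" for K = 2
  int_idx <- grep("\\(Intercept\\)", pnamesV)
  classes <- names(probs)
  for (j in seq_len(K)) {
    # gradient of p_j with respect to the K-1 intercepts (classes 2..K)
    grad <- numeric(length(pnamesV))
    for (m in seq_len(K - 1)) {
      idx <- int_idx[m]
      p_m1 <- probs[m + 1]
      grad[idx] <- if (j == m + 1) probs[j] * (1 - probs[j]) else
        -probs[j] * p_m1
    }
    se <- sqrt(max(0, t(grad) %*% V %*% grad))
    ci[j, ] <- c(max(0, probs[j] - 1.96 * se), min(1, probs[j] + 1.96 * se))
  }
  rownames(ci) <- classes
  ci
}

#' @export
print.abc_model_choice <- function(x, ...) {
  for (s in names(x$probs))
    cat(sprintf("scenario %s: %.4f (95%% CI %.4f-%.4f)\n", s, x$probs[s],
                x$ci[s, "lower"], x$ci[s, "upper"]))
  if (x$penalized) cat("(penalized fit: near-separation detected)\n")
  invisible(x)
}

#' Local-linear adjusted parameter posterior
#'
#' Beaumont-style regression adjustment with a logit transform: each accepted
#' parameter value is mapped to the real line through the logit of its
#' position inside its prior interval, regressed on the standardized
#' differences (statistic - observed) with Epanechnikov weights
#' `w = 1 - (d / d_max)^2`, and shifted to the origin by subtracting the
#' fitted linear term; back-transformation guarantees the adjusted values
#' stay inside the prior bounds. Singular designs are ridge-regularized and
#' flagged.
#'
#' @param sel an [rejection_select()] result (>= 20 rows), typically
#'   restricted to the winning scenario's rows.
#' @param priors the [prior_set()] used to build the table (supplies the
#'   logit bounds per parameter type).
#' @param scenario_obj the winning [scenario()]; classifies each parameter as
#'   size/time/admixture for its bounds.
#' @param params which parameters to adjust (default: all of the scenario's).
#' @param probs reported quantiles.
#' @return list of class `abc_posterior`: per-parameter list with `adjusted`
#'   (weighted sample), `weights`, `median`, `quantiles`; plus `ridged` flag.
#' @export
estimate_posterior <- function(sel, priors, scenario_obj, params = NULL,
                               probs = c(0.025, 0.5, 0.975)) {
  if (length(sel$rows) < 20) stop("need >= 20 accepted rows", call. = FALSE)
  pk <- scenario_obj$params
  if (is.null(params)) params <- unlist(pk, use.names = FALSE)
  bounds <- lapply(setNames(params, params), function(p) {
    if (p %in% pk$size) priors$size
    else if (p %in% pk$time) priors$time
    else if (p %in% pk$admix) priors$admix
    else stop("parameter '", p, "' not in scenario", call. = FALSE)
  })
  S <- as.matrix(sel$table[, sel$stats_used, drop = FALSE])
  Z <- sweep(sweep(S, 2, sel$obs, "-"), 2, sel$mads, "/")
  d <- sel$distance
  dmax <- max(d)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, length(d))
  w[w <= 0] <- min(w[w > 0], 1e-8)      # keep the boundary row in the fit
  X <- cbind(1, Z)
  ridged <- FALSE
  out <- list()
  for (p in params) {
    lo <- bounds[[p]][1]; hi <- bounds[[p]][2]
    th <- sel$table[[p]]
    if (all(is.na(th))) next
    u <- (th - lo) / (hi - lo)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    z <- log(u / (1 - u))
    XtW <- t(X * w)
    A <- XtW %*% X
    beta <- tryCatch(solve(A, XtW %*% z), error = function(e) NULL)
    if (is.null(beta)) {
      ridged <- TRUE
      lambda <- 1e-6 * mean(diag(A))
      beta <- solve(A + diag(lambda, ncol(A)), XtW %*% z)
    }
    z_adj <- z - Z %*% beta[-1]
    th_adj <- lo + (hi - lo) / (1 + exp(-z_adj))
    qs <- weighted_quantile(as.numeric(th_adj), w, probs)
    out[[p]] <- list(adjusted = as.numeric(th_adj), weights = w,
                     median = weighted_quantile(as.numeric(th_adj), w, 0.5),
                     quantiles = qs)
  }
  structure(list(params = out, ridged = ridged, probs = probs),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  for (p in names(x$params)) {
    q <- x$params[[p]]$quantiles
    cat(sprintf("%-4s median %.4g  [%s]\n", p, x$params[[p]]$median,
                paste(sprintf("%.4g", q), collapse = ", ")))
  }
  if (x$ridged) cat("(ridge-regularized: singular design)\n")
  invisible(x)
}

# weighted empirical quantiles (interpolated on the cumulative weights)
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    i <- findInterval(p, cw)
    x[i] + (x[i + 1] - x[i]) * (p - cw[i]) / (cw[i + 1] - cw[i])
  }, numeric(1))
}

#' Posterior model check by PCA
#'
#' Fits a PCA on the (centred, scaled) reference-table statistics and
#' projects the observed vector and optional posterior-predictive simulations
#' into it, to assess visually whether the observed data sit inside the cloud
#' reachable by the fitted scenario.
#'
#' @param ref a `reference_table`.
#' @param obs named observed summary-statistic vector.
#' @param posterior_sims optional second `reference_table` (or data.frame
#'   with the same statistic columns) of posterior-predictive simulations.
#' @return list of class `abc_model_check`: `ref_coords`, `obs_coords`,
#'   `post_coords` (2-D), `sdev`, `rotation`, `stats_used`.
#' @export
model_check_pca <- function(ref, obs, posterior_sims = NULL) {
  stat_names <- attr(ref, "stat_names")
  S <- as.matrix(as.data.frame(ref)[, stat_names, drop = FALSE])
  sds <- apply(S, 2, stats::sd)
  usable <- sds > 0
  S <- S[, usable, drop = FALSE]
  pc <- prcomp(S, center = TRUE, scale. = TRUE)
  proj <- function(M) {
    M <- M[, stat_names[usable], drop = FALSE]
    scale(M, center = pc$center, scale = pc$scale) %*% pc$rotation[, 1:2]
  }
  obs_m <- matrix(obs[stat_names[usable]], nrow = 1,
                  dimnames = list(NULL, stat_names[usable]))
  post <- NULL
  if (!is.null(posterior_sims))
    post <- proj(as.matrix(as.data.frame(posterior_sims)[,
      stat_names[usable], drop = FALSE]))
  structure(list(ref_coords = pc$x[, 1:2], obs_coords = proj(obs_m),
                 post_coords = post, sdev = pc$sdev,
                 rotation = pc$rotation, stats_used = stat_names[usable]),
            class = "abc_model_check")
}
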