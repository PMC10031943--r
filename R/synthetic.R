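#' Specification of a synthetic admixed SNP panel
#'
#' Two diverged parental populations plus one admixed population, generated
#' under the Balding-Nichols model. The defaults mirror the study system the
#' package targets: 53 / 91 parental and 17 hybrid diploids, hybrid ancestry
#' 0.68 from parent A, parental differentiation F_ST = 0.225, and a low
#' uniform missing-call rate.
#'
#' @param n_parentalA,n_parentalB,n_hybrid diploid sample counts.
#' @param n_loci number of unlinked biallelic loci.
#' @param fst_parents target parental differentiation, in [0, 1).
#' @param ancestry hybrid ancestry fraction from parent A, in [0, 1].
#' @param missing_rate per-call missing probability.
#' @param seed integer seed.
#' @return list of class `admixture_spec`.
#' @export
admixture_spec <- function(n_parentalA = 53, n_parentalB = 91,
                           n_hybrid = 17, n_loci = 500,
                           fst_parents = 0.225, ancestry = 0.68,
                           missing_rate = 0.05, seed = 1) {
  stopifnot(ancestry >= 0, ancestry <= 1, fst_parents >= 0, fst_parents < 1,
            missing_rate >= 0, missing_rate < 1, n_loci >= 1)
  structure(list(n_parentalA = n_parentalA, n_parentalB = n_parentalB,
                 n_hybrid = n_hybrid, n_loci = n_loci,
                 fst_parents = fst_parents, ancestry = ancestry,
                 missing_rate = missing_rate, seed = seed),
            class = "admixture_spec")
}

#' Generate an admixed genotype panel with known ground truth
#'
#' Ancestral allele frequencies are drawn uniformly on (0.05, 0.95); each
#' parental population's frequency is a Balding-Nichols draw,
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` with `F = fst_parents` (independent across
#' parents, so the expected parental F_ST matches `F`); hybrid genotypes are
#' binomial draws from the ancestry-weighted parental frequency. Missing
#' calls are placed uniformly at random. Pure function of the seed.
#'
#' @param spec an [admixture_spec()].
#' @return list: `genotypes` (a [genotype_matrix()] with populations
#'   `parentalA`, `hybrid`, `parentalB`), `true_ancestry`, `freqA`, `freqB`,
#'   `freq_ancestral`.
#' @export
generate_admixed_panel <- function(spec = admixture_spec()) {
  set.seed(spec$seed)
  L <- spec$n_loci
  p0 <- runif(L, 0.05, 0.95)
  bn <- function(p, F) {
    if (F <= 0) return(p)
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  pA <- bn(p0, spec$fst_parents)
  pB <- bn(p0, spec$fst_parents)
  pH <- spec$ancestry * pA + (1 - spec$ancestry) * pB
  draw <- function(n, p) {
    if (n == 0) return(matrix(integer(0), 0, length(p)))
    matrix(rbinom(n * length(p), 2, rep(p, each = n)), nrow = n)
  }
  X <- rbind(draw(spec$n_parentalA, pA),
             draw(spec$n_hybrid, pH),
             draw(spec$n_parentalB, pB))
  if (spec$missing_rate > 0) {
    miss <- matrix(runif(length(X)) < spec$missing_rate, nrow = nrow(X))
    X[miss] <- NA_integer_
  }
  pops <- rep(c("parentalA", "hybrid", "parentalB"),
              c(spec$n_parentalA, spec$n_hybrid, spec$n_parentalB))
  ids <- paste0(pops, "_", unlist(lapply(
    c(spec$n_parentalA, spec$n_hybrid, spec$n_parentalB), seq_len)))
  g <- genotype_matrix(X, ids, pops, paste0("L", seq_len(L)))
  list(genotypes = g,
       true_ancestry = rep(spec$ancestry, spec$n_hybrid),
       freqA = pA, freqB = pB, freq_ancestral = p0)
}

#' Default simulation truth for pseudo-observed datasets
#'
#' Parameter values used as ground truth when generating pseudo-observed
#' datasets under the hybrid-founding scenario: effective sizes
#' N1 = 7730, N2 = 3300, N3 = 1060, N4 = 12500, Na = 8200 diploids;
#' introgression time t1 = 97.9 and hybridization time t2 = 211 generations;
#' parental divergence t4 = 2000 generations (the package's choice; see the
#' methods vignette); micrantha ancestry fractions r2 = 0.68 (hybrid) and
#' r1 = 0.33 (introgressed lineage).
#'
#' @return named numeric vector.
#' @export
default_pod_truth <- function() {
  c(N1 = 7730, N2 = 3300, N3 = 1060, N4 = 12500, Na = 8200,
    t1 = 97.9, t2 = 211, t4 = 2000, r1 = 0.33, r2 = 0.68)
}

#' Default diploid sample sizes for the four genetic groups
#'
#' 53 micrantha, 17 ptilosperma, and the 91 flavida split into 18
#' introgressed (NG-lineage) plus 73 remaining individuals.
#'
#' @return named integer vector.
#' @export
default_sample_sizes <- function() {
  c(micrantha = 53L, ptilosperma = 17L,
    introgressed_flavida = 18L, flavida = 73L)
}

#' Generate a pseudo-observed dataset (POD)
#'
#' Simulates one SNP panel under a scenario with known parameter values and
#' records the truth alongside, for pipeline-validation experiments.
#'
#' @param s a [scenario()] (default: scenario 1 of
#'   [hybridization_scenarios()]).
#' @param params truth binding (default [default_pod_truth()], subset to the
#'   scenario's parameters).
#' @param sample_sizes named diploid counts.
#' @param n_loci number of loci (default 415).
#' @param seed,stream,maf_min passed to [simulate_snp_panel()].
#' @return list: `genotypes`, `truth`, `scenario_id`.
#' @export
generate_pod <- function(s = NULL, params = NULL,
                         sample_sizes = default_sample_sizes(),
                         n_loci = 415, seed = 1, stream = 0,
                         maf_min = 0.05) {
  if (is.null(s)) s <- hybridization_scenarios()[[1]]
  if (is.null(params)) {
    truth <- default_pod_truth()
    params <- truth[intersect(names(truth), unlist(s$params))]
  }
  g <- simulate_snp_panel(s, params, sample_sizes, n_loci, seed = seed,
                          stream = stream, maf_min = maf_min)
  list(genotypes = g, truth = params, scenario_id = s$scenario_id)
}

#' Generate a synthetic water-release curve with known parameters
#'
#' Inverts the cumulative-water-release equations: target CWR values follow
#' the hyperbola `a x / (b + x)` on a water-potential magnitude grid (plus
#' optional Gaussian noise), and are converted back to segment masses for a
#' nominal segment with `W_d = 1` g, `W_s = 2` g, volume 2 cm^3 (density
#' 0.5 g cm^-3). Noiseless output lies exactly on the generating model.
#'
#' @param a,b generating hyperbola parameters (kg m^-3; MPa).
#' @param noise_sd Gaussian noise on CWR, kg m^-3.
#' @param n_points observations, spread from -0.25 to `-psi_max` MPa.
#' @param psi_max driest magnitude, MPa.
#' @param seed integer seed.
#' @return a [water_release_curve()] with attribute `truth = c(a, b)`.
#' @export
generate_water_release <- function(a = 300, b = 2, noise_sd = 0,
                                   n_points = 12, psi_max = 8, seed = 1) {
  stopifnot(a >= 0, b > 0, n_points >= 4)
  set.seed(seed)
  W_d <- 1; W_s <- 2; volume <- 2
  rho <- W_d / volume
  cwr_cap <- (W_s - W_d) * rho * 1000 / W_d   # CWR at RWC = 0
  if (a >= cwr_cap)
    stop("asymptote a exceeds the releasable water of the nominal segment",
         call. = FALSE)
  x <- seq(0.25, psi_max, length.out = n_points)
  y <- a * x / (b + x)
  if (noise_sd > 0) y <- pmax(0, y + rnorm(n_points, 0, noise_sd))
  r <- 1 - y * W_d / ((W_s - W_d) * rho * 1000)
  mass <- W_d + r * (W_s - W_d)
  curve <- water_release_curve(-x, mass, W_s = W_s, W_d = W_d,
                               volume = volume)
  attr(curve, "truth") <- c(a = a, b = b)
  curve
}

#' Generate a synthetic pressure-volume curve with known turgor loss point
#'
#' Standard two-component P-V model with no apoplastic fraction: osmotic
#' potential `psi_s = pi0 / R` and turgor `psi_p = max(0, elasticity *
#' (R - rwc_tlp) / (1 - rwc_tlp))`, so turgor vanishes linearly at
#' `R = rwc_tlp` and the true turgor loss point is `pi0 / rwc_tlp`. Gaussian
#' noise (MPa) is added to the water potential. Masses use a nominal leaf
#' with `W_d = 0.3` g and `W_s = 1` g.
#'
#' @param pi0 osmotic potential at full turgor, MPa (negative).
#' @param rwc_tlp relative water content at turgor loss, in (0, 1).
#' @param elasticity turgor at full saturation, MPa (default `-pi0`, which
#'   makes the total potential 0 at full hydration).
#' @param noise_sd Gaussian noise on psi, MPa.
#' @param n_points observations on an RWC grid spanning the turgor loss
#'   point.
#' @param seed integer seed.
#' @return a [pv_curve()] with attribute `truth = c(psi_tlp, pi0, rwc_tlp)`.
#' @export
generate_pv <- function(pi0 = -1.5, rwc_tlp = 0.9, elasticity = -pi0,
                        noise_sd = 0, n_points = 12, seed = 1) {
  stopifnot(pi0 < 0, rwc_tlp > 0, rwc_tlp < 1, elasticity > 0,
            n_points >= 6)
  set.seed(seed)
  W_d <- 0.3; W_s <- 1
  R <- seq(0.995, rwc_tlp - 0.18, length.out = n_points)
  R <- pmax(R, 0.05)
  psi_s <- pi0 / R
  psi_p <- pmax(0, elasticity * (R - rwc_tlp) / (1 - rwc_tlp))
  psi <- psi_s + psi_p
  if (noise_sd > 0) psi <- psi + rnorm(n_points, 0, noise_sd)
  psi <- pmin(psi, -1e-3)
  mass <- W_d + R * (W_s - W_d)
  curve <- pv_curve(psi, mass, dry_mass = W_d, saturated_mass = W_s)
  attr(curve, "truth") <- c(psi_tlp = pi0 / rwc_tlp, pi0 = pi0,
                            rwc_tlp = rwc_tlp)
  curve
}
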