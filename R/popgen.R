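#' Per-population, per-locus allele frequencies and heterozygote fractions
#'
#' Internal workhorse shared by the diversity statistics, the F_ST machinery
#' and the ABC summary statistics.
#'
#' @param X dosage matrix (samples x loci, NA = missing).
#' @param idx_list named list of row-index vectors, one per population.
#' @return list of matrices (`n`, `p`, `h`), populations x loci: genotyped
#'   counts, alternate allele frequency, heterozygote fraction (`p`/`h` are
#'   NaN where `n` = 0).
#' @keywords internal
pop_locus_freqs <- function(X, idx_list) {
  P <- length(idx_list)
  L <- ncol(X)
  n <- p <- h <- matrix(0, P, L, dimnames = list(names(idx_list), NULL))
  for (i in seq_len(P)) {
    Xi <- X[idx_list[[i]], , drop = FALSE]
    if (anyNA(Xi)) {
      ok <- !is.na(Xi)
      ni <- colSums(ok)
      si <- colSums(Xi, na.rm = TRUE)
      hi <- colSums(Xi == 1L, na.rm = TRUE)
    } else {
      ni <- rep(nrow(Xi), L)
      si <- colSums(Xi)
      hi <- colSums(Xi == 1L)
    }
    n[i, ] <- ni
    p[i, ] <- si / (2 * ni)
    h[i, ] <- hi / ni
  }
  list(n = n, p = p, h = h)
}

#' Diversity statistics for one population
#'
#' Per-locus values averaged over loci with at least one genotyped
#' individual: major allele frequency `P`, observed heterozygosity `H_O`,
#' unbiased expected heterozygosity `H_E` (small-sample factor 2n/(2n-1)),
#' and nucleotide diversity `pi` at variant sites. For an anonymous biallelic
#' SNP panel `pi` per variant site equals the unbiased gene diversity, so
#' `pi == H_E` here by construction; it is reported per variant site, not per
#' sequenced base (locus lengths are unknown for such panels; flagged in the
#' `pi_units` field).
#'
#' @param g a [genotype_matrix()].
#' @param pop population label.
#' @return list of class `pop_stats`: `P`, `H_O`, `H_E`, `pi`, `n_eff`
#'   (mean genotyped individuals per locus), `n_loci_used`, `pi_units`.
#' @export
pop_stats <- function(g, pop) {
  validate_genotype_matrix(g)
  rows <- which(g$pop_labels == pop)
  if (length(rows) == 0) stop("no samples in population '", pop, "'",
                              call. = FALSE)
  X <- g$dosage[rows, , drop = FALSE]
  ok <- !is.na(X)
  n <- colSums(ok)
  use <- n >= 1
  if (!any(use)) stop("population '", pop, "' has no genotyped loci",
                      call. = FALSE)
  if (max(n) < 2) stop("population '", pop,
                       "' needs >= 2 genotyped individuals at >= 1 locus",
                       call. = FALSE)
  n <- n[use]
  p_alt <- colSums(X[, use, drop = FALSE], na.rm = TRUE) / (2 * n)
  het <- colSums(X[, use, drop = FALSE] == 1L, na.rm = TRUE) / n
  he <- ifelse(n > 0.5, (2 * n / (2 * n - 1)) * 2 * p_alt * (1 - p_alt), 0)
  structure(list(
    P = mean(pmax(p_alt, 1 - p_alt)),
    H_O = mean(het),
    H_E = mean(he),
    pi = mean(he),
    n_eff = mean(n),
    n_loci_used = sum(use),
    pi_units = "per variant site (locus lengths unknown for anonymous SNP panels)"
  ), class = "pop_stats")
}

#' @export
print.pop_stats <- function(x, ...) {
  cat(sprintf("P = %.4f  H_O = %.4f  H_E = %.4f  pi = %.4f  (n_eff = %.1f, %d loci)\n",
              x$P, x$H_O, x$H_E, x$pi, x$n_eff, x$n_loci_used))
  invisible(x)
}

# Weir & Cockerham (1984) variance components for two populations, given
# per-population per-locus genotyped counts n, alt frequencies p and
# heterozygote fractions h. Returns summed components.
wc_components_pair <- function(n1, p1, h1, n2, p2, h2) {
  valid <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  n1 <- n1[valid]; p1 <- p1[valid]; h1 <- h1[valid]
  n2 <- n2[valid]; p2 <- p2[valid]; h2 <- h2[valid]
  if (length(n1) == 0) return(list(a = 0, abc = 0, n_loci = 0L))
  r <- 2
  nbar <- (n1 + n2) / 2
  nsum <- n1 + n2
  nc <- nsum - (n1^2 + n2^2) / nsum        # (r*nbar - sum n^2/(r*nbar))/(r-1)
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / nsum
  inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = sum(a), abc = sum(a + b + cc), n_loci = length(a))
}

# theta from a dosage matrix and two row-index sets
wc_theta_idx <- function(X, rowsA, rowsB) {
  fr <- pop_locus_freqs(X, list(A = rowsA, B = rowsB))
  comp <- wc_components_pair(fr$n[1, ], fr$p[1, ], fr$h[1, ],
                             fr$n[2, ], fr$p[2, ], fr$h[2, ])
  if (comp$n_loci == 0L || comp$abc == 0) return(NA_real_)
  comp$a / comp$abc
}

#' Multi-locus Weir-Cockerham F_ST between two populations
#'
#' Weir & Cockerham (1984) theta, combining loci as the ratio of summed
#' variance components. Significance is assessed by permuting population
#' labels among the pooled samples; the p-value uses add-one smoothing,
#' p = (b + 1)/(n_perm + 1), where b counts permuted theta >= observed.
#'
#' @param g a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param n_perm number of label permutations (0 skips the test).
#' @return list of class `pairwise_fst`: `theta`, `p_value`, `n_perm`,
#'   `n_loci_used`, `defined` (FALSE when no locus is informative, in which
#'   case `theta` is NA).
#' @export
pairwise_fst <- function(g, popA, popB, n_perm = 0) {
  validate_genotype_matrix(g)
  rowsA <- which(g$pop_labels == popA)
  rowsB <- which(g$pop_labels == popB)
  if (length(rowsA) < 2 || length(rowsB) < 2)
    stop("both populations need >= 2 individuals", call. = FALSE)
  X <- g$dosage
  fr <- pop_locus_freqs(X, list(A = rowsA, B = rowsB))
  comp <- wc_components_pair(fr$n[1, ], fr$p[1, ], fr$h[1, ],
                             fr$n[2, ], fr$p[2, ], fr$h[2, ])
  if (comp$n_loci == 0L || comp$abc == 0) {
    return(structure(list(theta = NA_real_, p_value = NA_real_,
                          n_perm = n_perm, n_loci_used = comp$n_loci,
                          defined = FALSE), class = "pairwise_fst"))
  }
  theta <- comp$a / comp$abc
  p_value <- NA_real_
  if (n_perm > 0) {
    all_rows <- c(rowsA, rowsB)
    nA <- length(rowsA)
    b <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample(all_rows)
      th <- wc_theta_idx(X, perm[seq_len(nA)], perm[-seq_len(nA)])
      if (!is.na(th) && th >= theta) b <- b + 1L
    }
    p_value <- (b + 1) / (n_perm + 1)
  }
  structure(list(theta = theta, p_value = p_value, n_perm = n_perm,
                 n_loci_used = comp$n_loci, defined = TRUE),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  if (!x$defined) {
    cat("F_ST undefined: no informative locus across the pair\n")
  } else {
    cat(sprintf("Weir-Cockerham theta = %.4f (%d loci)", x$theta,
                x$n_loci_used))
    if (!is.na(x$p_value))
      cat(sprintf(", permutation p = %.4g (%d permutations)", x$p_value,
                  x$n_perm))
    cat("\n")
  }
  invisible(x)
}

#' Nei's standard genetic distance from per-locus allele frequencies
#'
#' `D = -ln(J_AB / sqrt(J_A * J_B))` where, for biallelic loci with
#' alternate-allele frequencies `p`, `J_A = mean(p_A^2 + q_A^2)`,
#' `J_B = mean(p_B^2 + q_B^2)` and `J_AB = mean(p_A p_B + q_A q_B)`, averaged
#' over loci. When the shared-allele term is zero (opposite fixation at every
#' locus) the distance is capped at `cap` instead of returning infinity, so
#' that ABC summary vectors stay finite.
#'
#' @param freqA,freqB numeric vectors of alternate-allele frequencies on the
#'   same locus set, entries in [0, 1] (NA allowed; dropped pairwise).
#' @param cap value returned when the normalized identity is 0.
#' @return Nei's distance (>= 0, up to numerical noise).
#' @export
nei_distance <- function(freqA, freqB, cap = 50) {
  if (length(freqA) != length(freqB))
    stop("frequency vectors must cover the same loci", call. = FALSE)
  ok <- !is.na(freqA) & !is.na(freqB)
  freqA <- freqA[ok]; freqB <- freqB[ok]
  if (length(freqA) == 0) stop("no loci with frequencies in both populations",
                               call. = FALSE)
  if (any(freqA < 0 | freqA > 1 | freqB < 0 | freqB > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  jA <- mean(freqA^2 + (1 - freqA)^2)
  jB <- mean(freqB^2 + (1 - freqB)^2)
  jAB <- mean(freqA * freqB + (1 - freqA) * (1 - freqB))
  if (jAB <= 0) return(cap)
  min(cap, -log(jAB / sqrt(jA * jB)))
}

#' Alternate-allele frequencies per population
#'
#' @param g a [genotype_matrix()].
#' @return matrix populations x loci of alternate-allele frequencies (NaN
#'   where a population has no genotyped individual at a locus).
#' @export
allele_freqs <- function(g) {
  validate_genotype_matrix(g)
  idx <- split(seq_along(g$pop_labels), g$pop_labels)
  fr <- pop_locus_freqs(g$dosage, idx)
  colnames(fr$p) <- g$locus_ids
  fr$p
}
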