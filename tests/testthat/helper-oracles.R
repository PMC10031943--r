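# Independent brute-force implementations used as oracles. These are written
# from the definitions with plain loops and explicit factorials, and share no
# code with the package internals.

# Exact HWE test by full enumeration of heterozygote configurations,
# conditional on the allele counts, using explicit factorial products.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  lfact <- function(k) sum(log(seq_len(k)))   # log k! by explicit product
  pr <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    exp(lfact(n) - lfact(aa) - lfact(h) - lfact(bb) + h * log(2) -
          (lfact(2 * n) - lfact(nA) - lfact(na)))
  })
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Weir & Cockerham (1984) theta for any number of populations, computed
# locus by locus with scalar loops over the genotype matrix.
oracle_wc_theta <- function(X, labels) {
  pops <- unique(labels)
  r <- length(pops)
  A <- D <- 0
  for (l in seq_len(ncol(X))) {
    n <- p <- h <- numeric(r)
    for (i in seq_len(r)) {
      x <- X[labels == pops[i], l]
      x <- x[!is.na(x)]
      n[i] <- length(x)
      if (n[i] > 0) {
        p[i] <- sum(x) / (2 * n[i])
        h[i] <- sum(x == 1) / n[i]
      }
    }
    if (any(n < 1) || sum(n) <= r) next
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a
    D <- D + a + b + cc
  }
  if (D == 0) return(NA_real_)
  A / D
}

# Nei's standard distance straight from its definition.
oracle_nei <- function(fa, fb) {
  jA <- jB <- jAB <- 0
  for (l in seq_along(fa)) {
    jA <- jA + fa[l]^2 + (1 - fa[l])^2
    jB <- jB + fb[l]^2 + (1 - fb[l])^2
    jAB <- jAB + fa[l] * fb[l] + (1 - fa[l]) * (1 - fb[l])
  }
  unname(-log((jAB / length(fa)) /
                sqrt((jA / length(fa)) * (jB / length(fa)))))
}

# Per-population diversity statistics with scalar loops.
oracle_pop_stats <- function(X) {
  P <- HO <- HE <- numeric(0)
  for (l in seq_len(ncol(X))) {
    x <- X[, l]
    x <- x[!is.na(x)]
    if (length(x) == 0) next
    n <- length(x)
    p <- sum(x) / (2 * n)
    P <- c(P, max(p, 1 - p))
    HO <- c(HO, sum(x == 1) / n)
    HE <- c(HE, if (n > 0) (2 * n / (2 * n - 1)) * 2 * p * (1 - p) else 0)
  }
  list(P = mean(P), H_O = mean(HO), H_E = mean(HE))
}

# Brute-force rejection: loop-computed MAD-standardized Euclidean distances.
oracle_rejection <- function(S, obs, k) {
  mads <- numeric(ncol(S))
  for (j in seq_len(ncol(S))) mads[j] <- stats::mad(S[, j])
  use <- which(mads > 0)
  d <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    s <- 0
    for (j in use) s <- s + ((S[i, j] - obs[j]) / mads[j])^2
    d[i] <- sqrt(s)
  }
  order(d, seq_along(d))[seq_len(k)]
}

# Rule-by-rule brute-force SNP filter (pooled MAF, missingness, biallelic,
# majority-of-populations HWE), looping over loci.
oracle_filter_keep <- function(g, cfg) {
  keep <- logical(ncol(g$dosage))
  for (l in seq_len(ncol(g$dosage))) {
    x <- g$dosage[, l]
    called <- x[!is.na(x)]
    if (length(called) == 0) next
    if (cfg$biallelic_only && length(g$allele_labels[[l]]) != 2) next
    if (mean(is.na(x)) >= cfg$max_missing) next
    p <- sum(called) / (2 * length(called))
    if (min(p, 1 - p) < cfg$maf_min) next
    fails <- tested <- 0
    for (pp in unique(g$pop_labels)) {
      xi <- x[g$pop_labels == pp]
      xi <- xi[!is.na(xi)]
      if (length(xi) < cfg$hwe_min_n) next
      tested <- tested + 1
      if (oracle_hwe(sum(xi == 0), sum(xi == 1), sum(xi == 2)) < cfg$hwe_alpha)
        fails <- fails + 1
    }
    if (tested > 0 && fails > tested / 2) next
    keep[l] <- TRUE
  }
  keep
}
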