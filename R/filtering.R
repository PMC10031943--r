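#' SNP filtering configuration
#'
#' Thresholds for the marker-retention rules applied by [filter_snps()]:
#' pooled minor allele frequency, per-locus missingness, a biallelic-only
#' switch, and the significance level of the per-population Hardy-Weinberg
#' exact test.
#'
#' @param maf_min minimum pooled minor allele frequency (retained when
#'   MAF >= `maf_min`). Default 0.05.
#' @param max_missing loci are dropped when the fraction of missing calls is
#'   `>= max_missing` ("less than 20% missing" retained). Default 0.20.
#' @param biallelic_only drop loci with more than one alternate allele.
#' @param hwe_alpha significance level of the Hardy-Weinberg exact test.
#' @param hwe_min_n minimum genotyped individuals for a population to count
#'   in the HWE rule.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, max_missing = 0.20,
                          biallelic_only = TRUE, hwe_alpha = 0.05,
                          hwe_min_n = 5) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(maf_min = maf_min, max_missing = max_missing,
                 biallelic_only = isTRUE(biallelic_only),
                 hwe_alpha = hwe_alpha, hwe_min_n = hwe_min_n),
            class = "filter_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic locus: given the observed allele
#' counts, the two-sided p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' configuration (the standard SNP exact test).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, sum >= 1).
#' @return p-value in (0, 1]. Monomorphic input returns 1 (nothing testable).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  m <- min(nA, na)                     # minor allele count
  hets <- seq(m %% 2, m, by = 2)       # feasible heterozygote counts
  # log P(h | n, nA) up to the common normalising constant
  lp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  if (is.na(obs)) stop("genotype counts inconsistent with allele counts",
                       call. = FALSE)
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Filter SNP loci by allele frequency, missingness, allele count and HWE
#'
#' Applies, in order: all-missing exclusion; biallelic-only; per-locus
#' missingness (dropped when the missing fraction is `>= max_missing`);
#' pooled minor allele frequency (retained when `>= maf_min`); and a
#' per-population Hardy-Weinberg exact test. A locus fails the HWE rule when
#' `p < hwe_alpha` in more than half of the populations with at least
#' `hwe_min_n` genotyped individuals (testing within populations avoids
#' flagging Wahlund structure in strongly subdivided data). The first
#' violated rule is logged for every dropped locus.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list with elements `genotypes` (filtered `genotype_matrix`) and
#'   `rejections` (data.frame with columns `locus`, `reason`).
#' @export
filter_snps <- function(g, cfg = filter_config()) {
  validate_genotype_matrix(g)
  if (ncol(g$dosage) == 0) stop("genotype matrix has no loci", call. = FALSE)
  d <- g$dosage
  n_samp <- nrow(d)
  pops <- unique(g$pop_labels)
  reasons <- rep(NA_character_, ncol(d))

  n_called <- colSums(!is.na(d))
  reasons[n_called == 0] <- "all_missing"

  if (cfg$biallelic_only) {
    multi <- vapply(g$allele_labels, length, integer(1)) != 2
    reasons[is.na(reasons) & multi] <- "not_biallelic"
  }

  miss_frac <- colSums(is.na(d)) / n_samp
  reasons[is.na(reasons) & miss_frac >= cfg$max_missing] <- "missingness"

  alt <- colSums(d, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  reasons[is.na(reasons) & !is.na(maf) & maf < cfg$maf_min] <- "low_maf"

  todo <- which(is.na(reasons))
  if (length(todo) > 0 && cfg$hwe_alpha > 0) {
    pop_rows <- split(seq_len(n_samp), g$pop_labels)
    for (j in todo) {
      fails <- 0L
      tested <- 0L
      for (rows in pop_rows) {
        dj <- d[rows, j]
        dj <- dj[!is.na(dj)]
        if (length(dj) < cfg$hwe_min_n) next
        tested <- tested + 1L
        p <- hwe_exact_test(sum(dj == 0), sum(dj == 1), sum(dj == 2))
        if (p < cfg$hwe_alpha) fails <- fails + 1L
      }
      if (tested > 0 && fails > tested / 2) reasons[j] <- "hwe"
    }
  }

  keep <- is.na(reasons)
  list(genotypes = subset_genotypes(g, loci = which(keep)),
       rejections = data.frame(locus = g$locus_ids[!keep],
                               reason = reasons[!keep]))
}

#' Write a per-locus rejection log as TSV
#'
#' @param rejections the `rejections` element of a [filter_snps()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rejection_log <- function(rejections, path) {
  write.table(rejections, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
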