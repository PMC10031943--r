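#' Diploid genotype matrix with population labels
#'
#' The central data container of the package: allele dosages (copies of the
#' designated alternate allele: 0, 1, 2, or `NA` for a missing call) for a set
#' of samples at a set of unlinked biallelic (or multiallelic, prior to
#' filtering) loci, together with one population label per sample and the
#' per-locus allele labels.
#'
#' @param dosage integer matrix, samples x loci; entries in \{0, 1, 2, NA\}.
#' @param sample_ids character vector, one id per row of `dosage`.
#' @param pop_labels character vector, one population label per sample.
#' @param locus_ids character vector, one id per column of `dosage`.
#' @param allele_labels list of character vectors `c(ref, alt, ...)`, one per
#'   locus. Defaults to biallelic `c("A", "T")` everywhere.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids, pop_labels, locus_ids,
                            allele_labels = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(allele_labels)) {
    allele_labels <- rep(list(c("A", "T")), ncol(dosage))
  }
  g <- structure(
    list(dosage = dosage,
         sample_ids = as.character(sample_ids),
         pop_labels = as.character(pop_labels),
         locus_ids = as.character(locus_ids),
         allele_labels = allele_labels),
    class = "genotype_matrix")
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  d <- g$dosage
  if (nrow(d) != length(g$sample_ids))
    stop("dosage rows (", nrow(d), ") do not match sample_ids (",
         length(g$sample_ids), ")", call. = FALSE)
  if (nrow(d) != length(g$pop_labels))
    stop("every sample needs exactly one population label", call. = FALSE)
  if (ncol(d) != length(g$locus_ids))
    stop("dosage columns do not match locus_ids", call. = FALSE)
  if (ncol(d) != length(g$allele_labels))
    stop("allele_labels must have one entry per locus", call. = FALSE)
  bad <- !is.na(d) & !(d %in% 0:2)
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "loci\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(x$pop_labels)),
                    as.integer(table(x$pop_labels))), collapse = ", "), "\n")
  cat("missing calls:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g a [genotype_matrix()].
#' @param samples,loci index vectors (logical, integer or character ids).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  si <- seq_len(nrow(g$dosage))
  li <- seq_len(ncol(g$dosage))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, g$sample_ids) else si[samples]
  }
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, g$locus_ids) else li[loci]
  }
  if (anyNA(si) || anyNA(li)) stop("unknown sample or locus id", call. = FALSE)
  genotype_matrix(g$dosage[si, li, drop = FALSE],
                  g$sample_ids[si], g$pop_labels[si],
                  g$locus_ids[li], g$allele_labels[li])
}
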