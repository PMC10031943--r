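#' Read a two-column population map
#'
#' @param path TSV file with two columns: sample id, population label.
#'   A header line is detected and skipped if its first field is one of
#'   `sample`, `sample_id`, `id`.
#' @return data.frame with columns `sample` and `population`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "population"),
                   colClasses = "character", comment.char = "#")
  if (tolower(pm$sample[1]) %in% c("sample", "sample_id", "id"))
    pm <- pm[-1, , drop = FALSE]
  if (anyDuplicated(pm$sample))
    stop("popmap contains duplicated sample ids", call. = FALSE)
  rownames(pm) <- NULL
  pm
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into an allele-dosage
#' [genotype_matrix()]. Dosage counts copies of the first alternate allele;
#' any missing allele in a call makes the whole call missing. Locus order is
#' preserved.
#'
#' @param path VCF file (plain text or gzipped).
#' @param popmap data.frame as returned by [read_popmap()], or a path to one.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, popmap) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                     # single-record VCF
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("VCF contains no variant records", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  missing_pm <- setdiff(samples, popmap$sample)
  if (length(missing_pm) > 0)
    stop("samples absent from popmap: ", paste(missing_pm, collapse = ", "),
         call. = FALSE)
  locus_ids <- fix[, "ID"]
  auto <- is.na(locus_ids) | locus_ids == "."
  locus_ids[auto] <- paste0(fix[auto, "CHROM"], "_", fix[auto, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  allele_labels <- mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1]]),
                          ref, alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  dos <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(fix),
                dimnames = NULL)
  for (j in seq_len(nrow(fix))) {
    calls <- gt[j, ]
    parsed <- parse_gt(calls, locus_ids[j])
    dos[, j] <- parsed
  }
  genotype_matrix(dos, samples,
                  popmap$population[match(samples, popmap$sample)],
                  locus_ids, allele_labels)
}

# GT strings -> dosage of allele "1"; any "." allele -> NA
parse_gt <- function(calls, locus_id) {
  calls[is.na(calls)] <- "./."
  parts <- strsplit(calls, "[/|]")
  lens <- lengths(parts)
  if (any(lens != 2))
    stop("malformed GT at locus ", locus_id, ": '",
         calls[which(lens != 2)[1]], "'", call. = FALSE)
  al <- matrix(unlist(parts), nrow = 2)
  ok <- al == "." | grepl("^[0-9]+$", al)
  if (!all(ok))
    stop("malformed GT at locus ", locus_id, ": '",
         calls[which(colSums(!ok) > 0)[1]], "'", call. = FALSE)
  miss <- al[1, ] == "." | al[2, ] == "."
  d <- (al[1, ] == "1") + (al[2, ] == "1")
  d[miss] <- NA_integer_
  as.integer(d)
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits one biallelic (or multiallelic, as recorded in `allele_labels`)
#' record per locus with unphased GT calls; dosage 1 is written as `0/1`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  validate_genotype_matrix(g)
  n_loci <- ncol(g$dosage)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hyborigin",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t"))
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- character(n_loci)
  for (j in seq_len(n_loci)) {
    d <- g$dosage[, j]
    calls <- ifelse(is.na(d), "./.", gt_codes[as.character(d)])
    al <- g$allele_labels[[j]]
    lines[j] <- paste(c("1", j, g$locus_ids[j], al[1],
                        paste(al[-1], collapse = ","),
                        ".", "PASS", ".", "GT", calls), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a popmap TSV for a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(g, path) {
  write.table(data.frame(sample = g$sample_ids, population = g$pop_labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
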