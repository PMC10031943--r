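#' Simulate a panel of unlinked biallelic SNPs under a scenario
#'
#' Backward-in-time coalescent simulation: each locus is an independent
#' genealogy of the sampled lineages under the scenario's event list
#' (coalescence rate 1/(2N) per lineage pair within a population of diploid
#' size N; at an admixture event each backward lineage chooses the first
#' source with the event's probability). Exactly one mutation is placed per
#' locus on a branch chosen with probability proportional to branch length
#' (Hudson fixed-S scheme), so every locus is variant in the pooled sample.
#' Loci whose pooled minor allele frequency falls below `maf_min` are redrawn
#' (SNP ascertainment mirroring the observed-data filter); set `maf_min = 0`
#' to keep every variant locus.
#'
#' Randomness comes from a generator seeded by (`seed`, `stream`) only, so
#' panels are reproducible independently of R's RNG state, and reference
#' tables can assign one stream per row.
#'
#' @param s a [scenario()].
#' @param params named parameter binding (see [draw_params()]).
#' @param sample_sizes named integer vector of diploid counts per sampled
#'   population (names must match `s$populations`).
#' @param n_loci number of SNP loci.
#' @param seed integer seed.
#' @param stream substream counter (default 0).
#' @param maf_min pooled minor-allele-frequency ascertainment threshold.
#' @return a [genotype_matrix()] with attribute `tmrca` (per-locus TMRCA in
#'   generations).
#' @export
simulate_snp_panel <- function(s, params, sample_sizes, n_loci,
                               seed = 1, stream = 0, maf_min = 0.05) {
  stopifnot(n_loci >= 1)
  viol <- validate_scenario(s, params)
  if (length(viol) > 0)
    stop("invalid scenario: ", paste(viol, collapse = "; "), call. = FALSE)
  if (is.null(names(sample_sizes)))
    stop("sample_sizes must be named by population", call. = FALSE)
  missing_pop <- setdiff(s$populations, names(sample_sizes))
  if (length(missing_pop) > 0)
    stop("sample_sizes missing for: ", paste(missing_pop, collapse = ", "),
         call. = FALSE)
  samp <- as.integer(sample_sizes[s$populations])
  if (any(samp < 0) || sum(samp) < 1)
    stop("impossible sample configuration: need >= 1 diploid in total",
         call. = FALSE)
  enc <- encode_scenario(s, params)
  res <- sim_panel_cpp(enc$ev_time, enc$ev_type, enc$ev_a, enc$ev_b,
                       enc$ev_c, enc$ev_rate, enc$sizes, samp,
                       as.integer(n_loci), maf_min,
                       as.double(seed), as.double(stream))
  pop_labels <- rep(s$populations, samp)
  ids <- unlist(lapply(seq_along(s$populations), function(i)
    paste0(s$populations[i], "_", seq_len(samp[i]))), use.names = FALSE)
  g <- genotype_matrix(res$dosage, ids, pop_labels,
                       paste0("L", seq_len(n_loci)))
  attr(g, "tmrca") <- res$heights
  g
}

#' Mean pairwise coalescence times under a scenario
#'
#' Convenience wrapper returning only the per-locus TMRCA of the simulated
#' genealogies (no ascertainment), used to check the simulator against
#' closed-form coalescent expectations.
#'
#' @inheritParams simulate_snp_panel
#' @return numeric vector of TMRCAs (generations), length `n_loci`.
#' @export
simulate_tmrca <- function(s, params, sample_sizes, n_loci, seed = 1,
                           stream = 0) {
  g <- simulate_snp_panel(s, params, sample_sizes, n_loci, seed, stream,
                          maf_min = 0)
  attr(g, "tmrca")
}

#' Build an ABC reference table
#'
#' For each scenario, draws `n_sims` parameter vectors from the priors
#' (respecting each scenario's ordering constraints), simulates a SNP panel
#' per draw, and records the summary-statistic vector. Fully reproducible
#' from `seed`: parameter draws consume R's RNG seeded once, and each panel
#' uses its own counter-derived substream.
#'
#' @param scenarios list of [scenario()] objects.
#' @param priors a [prior_set()].
#' @param sample_sizes named diploid counts (see [simulate_snp_panel()]).
#' @param n_loci loci per simulated panel.
#' @param n_sims simulations per scenario.
#' @param seed integer seed.
#' @param maf_min ascertainment threshold passed to the simulator.
#' @param admixed_specs admixture-statistic specification passed to
#'   [summary_stats()]; defaults to both candidate hybrid groups against the
#'   parental pair.
#' @return object of class `reference_table`: a data.frame with columns
#'   `scenario`, the union of parameter names, and the summary statistics;
#'   attributes `param_names`, `stat_names`, `metadata`.
#' @export
build_reference_table <- function(scenarios, priors, sample_sizes, n_loci,
                                  n_sims, seed = 1, maf_min = 0.05,
                                  admixed_specs = default_admixed_specs()) {
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  if (inherits(scenarios, "hyb_scenario")) scenarios <- list(scenarios)
  set.seed(seed)
  param_names <- unique(unlist(lapply(scenarios, function(s)
    unlist(s$params, use.names = FALSE))))
  draws <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    draws[[i]] <- lapply(seq_len(n_sims), function(k)
      draw_params(scenarios[[i]], priors))
  }
  n_total <- length(scenarios) * n_sims
  stat_rows <- vector("list", n_total)
  scen_col <- integer(n_total)
  par_mat <- matrix(NA_real_, n_total, length(param_names),
                    dimnames = list(NULL, param_names))
  row <- 0L
  for (i in seq_along(scenarios)) {
    s <- scenarios[[i]]
    viol <- validate_scenario(s)
    if (length(viol) > 0)
      stop("invalid scenario ", s$scenario_id, ": ",
           paste(viol, collapse = "; "), call. = FALSE)
    samp <- as.integer(sample_sizes[s$populations])
    if (anyNA(samp))
      stop("sample_sizes missing for scenario ", s$scenario_id, call. = FALSE)
    idx <- split(seq_len(sum(samp)), rep(s$populations, samp))
    idx <- idx[s$populations]
    for (k in seq_len(n_sims)) {
      row <- row + 1L
      pr <- draws[[i]][[k]]
      enc <- encode_scenario(s, pr)
      res <- tryCatch(
        sim_panel_cpp(enc$ev_time, enc$ev_type, enc$ev_a, enc$ev_b,
                      enc$ev_c, enc$ev_rate, enc$sizes, samp,
                      as.integer(n_loci), maf_min,
                      as.double(seed), as.double(row)),
        error = function(e) stop("simulation failed at scenario ",
                                 s$scenario_id, ", row ", row, ": ",
                                 conditionMessage(e), call. = FALSE))
      scen_col[row] <- s$scenario_id
      par_mat[row, names(pr)] <- pr
      stat_rows[[row]] <- summary_stats_matrix(res$dosage, idx, admixed_specs)
    }
  }
  stats <- do.call(rbind, stat_rows)
  if (any(!is.finite(stats)))
    stop("non-finite summary statistic in reference table", call. = FALSE)
  tab <- data.frame(scenario = scen_col, par_mat, stats, check.names = FALSE)
  structure(tab,
            class = c("reference_table", "data.frame"),
            param_names = param_names,
            stat_names = colnames(stats),
            metadata = list(sample_sizes = sample_sizes, n_loci = n_loci,
                            seed = seed, maf_min = maf_min,
                            n_sims_per_scenario = n_sims,
                            admixed_specs = admixed_specs))
}

#' Default admixture-statistic specification
#'
#' Both candidate admixed groups are scored against the ordered parental pair
#' (micrantha first, flavida second).
#'
#' @return list of specs usable by [summary_stats()].
#' @export
default_admixed_specs <- function() {
  list(list(hybrid = "ptilosperma",
            parents = c("micrantha", "flavida")),
       list(hybrid = "introgressed_flavida",
            parents = c("micrantha", "flavida")))
}

#' Restrict a reference table to one scenario
#'
#' @param ref a `reference_table`.
#' @param scenario_id scenario to keep.
#' @return a `reference_table` containing only that scenario's rows.
#' @export
subset_scenario <- function(ref, scenario_id) {
  tab <- as.data.frame(ref)
  keep <- tab$scenario == scenario_id
  if (!any(keep)) stop("no rows for scenario ", scenario_id, call. = FALSE)
  structure(tab[keep, , drop = FALSE],
            class = c("reference_table", "data.frame"),
            param_names = attr(ref, "param_names"),
            stat_names = attr(ref, "stat_names"),
            metadata = attr(ref, "metadata"))
}

#' Write / read a reference table as CSV
#'
#' @param ref a `reference_table`.
#' @param path CSV path.
#' @return `path` (write) or the reconstructed `reference_table` (read).
#' @export
write_reference_table <- function(ref, path) {
  write.table(as.data.frame(ref), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @param param_names,stat_names column classification used when reading.
#' @export
read_reference_table <- function(path, param_names, stat_names) {
  tab <- read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  structure(tab, class = c("reference_table", "data.frame"),
            param_names = param_names, stat_names = stat_names,
            metadata = list())
}
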