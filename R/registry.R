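#' The ten competing hybridization scenarios
#'
#' Registry of the ten demographic hypotheses compared for the origin of a
#' putative homoploid hybrid population and of an introgressed conspecific
#' lineage, given four sampled groups: parental species A (`micrantha`, size
#' `N1`), the putative hybrid (`ptilosperma`, size `N2`), an introgressed
#' lineage of parental species B (`introgressed_flavida`, size `N3`), and
#' parental species B (`flavida`, size `N4`). Every scenario ends with the
#' two parental species diverging from a common ancestor of size `Na` at time
#' `t4`, the oldest event. Times are in generations; admixture/pulse rates
#' are the forward-time ancestry fraction contributed by `micrantha`.
#'
#' The competing hypotheses are only sketched verbally in the source
#' analysis; this registry encodes one explicit interpretation per sentence:
#'
#' 1. Both lineages are hybrid-founded: `ptilosperma` founded by an admixture
#'    event at `t2` (micrantha fraction `r2`), `introgressed_flavida` founded
#'    by an introgression event at `t1` (`r1`), with `t1 < t2 < t4`.
#' 2. `ptilosperma` hybrid-founded at `t2`; `introgressed_flavida` splits
#'    from `flavida` at `t1` with no gene flow.
#' 3. `ptilosperma` splits from `micrantha` at `t2` and later receives a
#'    pulse from `flavida` at `t1 < t2` (rate `r2` = fraction replaced);
#'    `introgressed_flavida` splits from `flavida` at `t3`.
#' 4. `ptilosperma` splits from `flavida` at `t2` and receives a pulse from
#'    `micrantha` at `t1 < t2`; `introgressed_flavida` splits from `flavida`
#'    at `t3`.
#' 5. `ptilosperma` hybrid-founded at `t2`; `introgressed_flavida` splits
#'    from `flavida` at `t3` and later receives an introgression pulse from
#'    `micrantha` at `t1 < t3`.
#' 6. `introgressed_flavida` hybrid-founded at `t1`; `ptilosperma` splits
#'    from `flavida` at `t2` and receives a pulse from `micrantha` at
#'    `t3 < t2`.
#' 7. Single hybrid origin then cladogenesis: `introgressed_flavida` is the
#'    hybrid lineage, founded by admixture at `t2`; `ptilosperma` splits from
#'    it at `t1 < t2`.
#' 8. Mirror of 7: `ptilosperma` is the hybrid lineage founded at `t2`;
#'    `introgressed_flavida` splits from it at `t1 < t2`.
#' 9. No hybridization: both lineages split independently from `flavida`
#'    (`ptilosperma` at `t2`, `introgressed_flavida` at `t1`).
#' 10. No hybridization, nested: `ptilosperma` splits from
#'    `introgressed_flavida` at `t1`, which splits from `flavida` at `t2`.
#'
#' @return list of 10 validated [scenario()] objects.
#' @export
hybridization_scenarios <- function() {
  pops <- c("micrantha", "ptilosperma", "introgressed_flavida", "flavida")
  sizes <- c(micrantha = "N1", ptilosperma = "N2",
             introgressed_flavida = "N3", flavida = "N4")
  root <- function(t = "t4") list(
    ev_divergence(t, child = "flavida", parent = "micrantha"),
    ev_size(t, pop = "micrantha", size = "Na"))
  mk <- function(id, events, constraints, description)
    scenario(id, pops, sizes, c(events, root()), constraints, description)

  list(
    mk(1, list(
        ev_admixture("t2", "ptilosperma", "micrantha", "flavida", "r2"),
        ev_admixture("t1", "introgressed_flavida", "micrantha", "flavida", "r1")),
      list(c("t1", "t2"), c("t2", "t4")),
      "hybrid founding of ptilosperma; introgressive founding of the NG-lineage"),
    mk(2, list(
        ev_admixture("t2", "ptilosperma", "micrantha", "flavida", "r2"),
        ev_divergence("t1", "introgressed_flavida", "flavida")),
      list(c("t1", "t4"), c("t2", "t4")),
      "hybrid founding of ptilosperma; NG-lineage splits from flavida"),
    mk(3, list(
        ev_pulse("t1", "ptilosperma", "flavida", "r2"),
        ev_divergence("t2", "ptilosperma", "micrantha"),
        ev_divergence("t3", "introgressed_flavida", "flavida")),
      list(c("t1", "t2"), c("t2", "t4"), c("t3", "t4")),
      "ptilosperma diverges from micrantha then hybridizes with flavida"),
    mk(4, list(
        ev_pulse("t1", "ptilosperma", "micrantha", "r2"),
        ev_divergence("t2", "ptilosperma", "flavida"),
        ev_divergence("t3", "introgressed_flavida", "flavida")),
      list(c("t1", "t2"), c("t2", "t4"), c("t3", "t4")),
      "ptilosperma diverges from flavida then hybridizes with micrantha"),
    mk(5, list(
        ev_admixture("t2", "ptilosperma", "micrantha", "flavida", "r2"),
        ev_pulse("t1", "introgressed_flavida", "micrantha", "r1"),
        ev_divergence("t3", "introgressed_flavida", "flavida")),
      list(c("t1", "t3"), c("t2", "t4"), c("t3", "t4")),
      "ptilosperma from a cross; micrantha introgresses into the NG-lineage"),
    mk(6, list(
        ev_admixture("t1", "introgressed_flavida", "micrantha", "flavida", "r1"),
        ev_pulse("t3", "ptilosperma", "micrantha", "r2"),
        ev_divergence("t2", "ptilosperma", "flavida")),
      list(c("t3", "t2"), c("t1", "t4"), c("t2", "t4")),
      "NG-lineage from a cross; ptilosperma diverges from flavida with micrantha introgression"),
    mk(7, list(
        ev_divergence("t1", "ptilosperma", "introgressed_flavida"),
        ev_admixture("t2", "introgressed_flavida", "micrantha", "flavida", "r1")),
      list(c("t1", "t2"), c("t2", "t4")),
      "single hybrid origin; ptilosperma by cladogenesis from the hybrid lineage"),
    mk(8, list(
        ev_divergence("t1", "introgressed_flavida", "ptilosperma"),
        ev_admixture("t2", "ptilosperma", "micrantha", "flavida", "r2")),
      list(c("t1", "t2"), c("t2", "t4")),
      "single hybrid origin; NG-lineage by cladogenesis from the hybrid lineage"),
    mk(9, list(
        ev_divergence("t2", "ptilosperma", "flavida"),
        ev_divergence("t1", "introgressed_flavida", "flavida")),
      list(c("t1", "t4"), c("t2", "t4")),
      "no hybridization: both lineages diverge independently from flavida"),
    mk(10, list(
        ev_divergence("t1", "ptilosperma", "introgressed_flavida"),
        ev_divergence("t2", "introgressed_flavida", "flavida")),
      list(c("t1", "t2"), c("t2", "t4")),
      "no hybridization: nested divergence from flavida")
  )
}
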