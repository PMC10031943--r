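#' Build a demographic scenario
#'
#' A scenario is an event-list demographic model read backward in time:
#' sampled populations with (symbolic or numeric) diploid sizes, plus
#' divergence, admixture-founding, introgression-pulse and size-change
#' events. Times are in generations; rates are forward-time admixture
#' proportions from the first-named source.
#'
#' Event constructors:
#' * `ev_divergence(time, child, parent)` - child lineage merges into parent
#'   (forward: child splits from parent at `time`).
#' * `ev_admixture(time, target, source_a, source_b, rate)` - target founded
#'   at `time` by admixture; each backward lineage moves to `source_a` with
#'   probability `rate`, else to `source_b`.
#' * `ev_pulse(time, target, source, rate)` - introgression pulse: a fraction
#'   `rate` of target's ancestry jumps to `source` at `time`; target persists.
#' * `ev_size(time, pop, size)` - population size changes to `size` at `time`
#'   (looking backward).
#'
#' `time`, `rate` and `size` entries may be numbers or names of parameters
#' bound later by [draw_params()].
#'
#' @param scenario_id identifier.
#' @param populations character vector of sampled population labels, oldest
#'   bookkeeping order irrelevant.
#' @param sizes named vector (one per population) of sizes or parameter names.
#' @param events list of events built with the `ev_*` constructors.
#' @param constraints list of 2-element character vectors `c(earlier, later)`
#'   of time-parameter names that must satisfy earlier < later.
#' @param description free-text interpretation of the hypothesis.
#' @return object of class `hyb_scenario`.
#' @export
scenario <- function(scenario_id, populations, sizes, events,
                     constraints = list(), description = "") {
  stopifnot(length(sizes) == length(populations))
  if (is.null(names(sizes))) names(sizes) <- populations
  s <- structure(list(scenario_id = scenario_id,
                      populations = populations,
                      sizes = sizes,
                      events = events,
                      constraints = constraints,
                      description = description),
                 class = "hyb_scenario")
  s$params <- scenario_params(s)
  s
}

#' @rdname scenario
#' @param time,child,parent,target,source,source_a,source_b,rate,pop,size
#'   event fields; see Details.
#' @export
ev_divergence <- function(time, child, parent)
  list(type = "divergence", time = time, child = child, parent = parent)

#' @rdname scenario
#' @export
ev_admixture <- function(time, target, source_a, source_b, rate)
  list(type = "admixture", time = time, target = target,
       source_a = source_a, source_b = source_b, rate = rate)

#' @rdname scenario
#' @export
ev_pulse <- function(time, target, source, rate)
  list(type = "pulse", time = time, target = target, source = source,
       rate = rate)

#' @rdname scenario
#' @export
ev_size <- function(time, pop, size)
  list(type = "size", time = time, pop = pop, size = size)

# symbolic parameter names used by a scenario, grouped by prior type
scenario_params <- function(s) {
  syms <- function(x) if (is.character(x)) x else character(0)
  sizes <- unlist(lapply(s$sizes, syms), use.names = FALSE)
  times <- character(0); rates <- character(0)
  for (e in s$events) {
    times <- c(times, syms(e$time))
    if (!is.null(e$rate)) rates <- c(rates, syms(e$rate))
    if (!is.null(e$size)) sizes <- c(sizes, syms(e$size))
  }
  list(size = unique(sizes), time = unique(times), admix = unique(rates))
}

#' @export
print.hyb_scenario <- function(x, ...) {
  cat("scenario", x$scenario_id, "-", x$description, "\n")
  cat(" populations:", paste(x$populations, collapse = ", "), "\n")
  for (e in x$events) {
    cat(" ", switch(e$type,
      divergence = sprintf("t=%s: %s diverges from %s", e$time, e$child, e$parent),
      admixture = sprintf("t=%s: %s founded by admixture %s (%s) / %s",
                          e$time, e$target, e$source_a, e$rate, e$source_b),
      pulse = sprintf("t=%s: pulse %s -> %s at rate %s", e$time, e$source,
                      e$target, e$rate),
      size = sprintf("t=%s: size of %s set to %s", e$time, e$pop, e$size)),
      "\n")
  }
  invisible(x)
}

#' Uniform priors for scenario parameters
#'
#' Default ranges: population sizes and event times uniform on 10 to 1e5
#' (diploid individuals; generations), admixture and pulse rates uniform on
#' 0.001 to 0.999.
#'
#' @param size,time,admix length-2 numeric ranges.
#' @return object of class `prior_set`.
#' @export
prior_set <- function(size = c(10, 1e5), time = c(10, 1e5),
                      admix = c(0.001, 0.999)) {
  stopifnot(length(size) == 2, length(time) == 2, length(admix) == 2,
            size[1] < size[2], time[1] < time[2],
            admix[1] > 0, admix[2] < 1, admix[1] < admix[2])
  structure(list(size = size, time = time, admix = admix),
            class = "prior_set")
}

#' Draw scenario parameters from their priors
#'
#' Each symbolic parameter is drawn from the uniform prior of its type; draws
#' violating the scenario's time-ordering constraints are rejected and
#' redrawn, so the effective joint prior is uniform on the constrained
#' region.
#'
#' @param s a [scenario()].
#' @param priors a [prior_set()].
#' @param max_tries resampling cap.
#' @return named numeric vector of parameter values.
#' @export
draw_params <- function(s, priors = prior_set(), max_tries = 10000) {
  pk <- s$params
  for (i in seq_len(max_tries)) {
    draw <- c(
      setNames(runif(length(pk$size), priors$size[1], priors$size[2]), pk$size),
      setNames(runif(length(pk$time), priors$time[1], priors$time[2]), pk$time),
      setNames(runif(length(pk$admix), priors$admix[1], priors$admix[2]), pk$admix))
    ok <- TRUE
    for (cn in s$constraints) {
      a <- if (cn[1] %in% names(draw)) draw[[cn[1]]] else suppressWarnings(as.numeric(cn[1]))
      b <- if (cn[2] %in% names(draw)) draw[[cn[2]]] else suppressWarnings(as.numeric(cn[2]))
      if (!(a < b)) { ok <- FALSE; break }
    }
    if (ok) return(draw)
  }
  stop("could not satisfy time-ordering constraints after ", max_tries,
       " draws", call. = FALSE)
}

# resolve a symbolic-or-numeric field against a parameter binding
resolve_value <- function(x, params, what) {
  if (is.numeric(x)) return(x)
  if (!x %in% names(params))
    stop("parameter '", x, "' (", what, ") is not bound", call. = FALSE)
  params[[x]]
}

# scenario + params -> sorted numeric event encoding for the C++ simulator
encode_scenario <- function(s, params) {
  pops <- s$populations
  pid <- function(nm) match(nm, pops) - 1L
  rows <- list()
  for (e in s$events) {
    t <- resolve_value(e$time, params, "time")
    if (e$type == "divergence") {
      rows[[length(rows) + 1]] <- list(t, 0L, pid(e$child), pid(e$parent), 0L, 0)
    } else if (e$type == "admixture") {
      r <- resolve_value(e$rate, params, "rate")
      rows[[length(rows) + 1]] <- list(t, 1L, pid(e$target), pid(e$source_a),
                                       pid(e$source_b), r)
    } else if (e$type == "pulse") {
      r <- resolve_value(e$rate, params, "rate")
      rows[[length(rows) + 1]] <- list(t, 2L, pid(e$target), pid(e$source),
                                       0L, r)
    } else if (e$type == "size") {
      n <- resolve_value(e$size, params, "size")
      rows[[length(rows) + 1]] <- list(t, 3L, pid(e$pop), 0L, 0L, n)
    } else stop("unknown event type: ", e$type, call. = FALSE)
  }
  m <- if (length(rows) == 0) matrix(numeric(0), 0, 6) else
    do.call(rbind, lapply(rows, function(r) unlist(r)))
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  sizes <- vapply(s$sizes, resolve_value, numeric(1), params = params,
                  what = "size")
  list(ev_time = m[, 1], ev_type = as.integer(m[, 2]),
       ev_a = as.integer(m[, 3]), ev_b = as.integer(m[, 4]),
       ev_c = as.integer(m[, 5]), ev_rate = m[, 6], sizes = sizes)
}

#' Validate a scenario's structure
#'
#' Checks, with parameters bound (either supplied or drawn canonically from
#' the constraint graph): event times positive and applicable, admixture and
#' pulse rates inside (0, 1), no event touching a retired (already merged or
#' admixture-founded) population, and that all sampled lineages reach a
#' single common ancestor.
#'
#' @param s a [scenario()].
#' @param params optional named parameter binding; when absent, a canonical
#'   binding respecting the constraints is constructed.
#' @return character vector of violations; length 0 means the scenario is
#'   valid.
#' @export
validate_scenario <- function(s, params = NULL) {
  if (is.null(params)) params <- canonical_params(s)
  viol <- character(0)
  enc <- tryCatch(encode_scenario(s, params), error = function(e) e)
  if (inherits(enc, "error")) return(conditionMessage(enc))
  if (any(enc$ev_time <= 0)) viol <- c(viol, "event times must be strictly positive")
  rates <- enc$ev_rate[enc$ev_type %in% c(1L, 2L)]
  if (any(rates <= 0 | rates >= 1))
    viol <- c(viol, "admixture/pulse rates must lie in (0, 1)")
  if (any(enc$sizes <= 0)) viol <- c(viol, "population sizes must be positive")
  # lineage bookkeeping: which populations remain active after all events
  active <- rep(TRUE, length(s$populations))
  for (i in seq_along(enc$ev_time)) {
    a <- enc$ev_a[i] + 1L; b <- enc$ev_b[i] + 1L; cc <- enc$ev_c[i] + 1L
    type <- enc$ev_type[i]
    if (type == 0L) {            # divergence/merge
      if (!active[a]) viol <- c(viol, paste0("event at t=", enc$ev_time[i],
        ": population '", s$populations[a], "' already retired"))
      if (!active[b]) viol <- c(viol, paste0("merge target '",
        s$populations[b], "' is retired"))
      active[a] <- FALSE
    } else if (type == 1L) {     # admixture founding
      if (!active[a]) viol <- c(viol, paste0("event at t=", enc$ev_time[i],
        ": population '", s$populations[a], "' already retired"))
      if (!active[b] || !active[cc])
        viol <- c(viol, "admixture sources must be active")
      active[a] <- FALSE
    } else if (type == 2L) {     # pulse
      if (!active[a] || !active[b])
        viol <- c(viol, paste0("pulse at t=", enc$ev_time[i],
                               " touches a retired population"))
    }
  }
  if (sum(active) != 1)
    viol <- c(viol, "no common ancestor: lineages never fully merge")
  unique(viol)
}

# deterministic parameter binding respecting the constraint partial order
canonical_params <- function(s) {
  pk <- s$params
  vals <- c(setNames(rep(1000, length(pk$size)), pk$size),
            setNames(rep(0.5, length(pk$admix)), pk$admix))
  times <- pk$time
  if (length(times) > 0) {
    rank <- setNames(rep(1, length(times)), times)
    for (i in seq_len(length(times) + 1)) {  # relax ranks over constraints
      for (cn in s$constraints) {
        if (cn[1] %in% times && cn[2] %in% times &&
            rank[cn[2]] <= rank[cn[1]])
          rank[cn[2]] <- rank[cn[1]] + 1
      }
    }
    vals <- c(vals, setNames(100 * rank, times))
  }
  vals
}
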