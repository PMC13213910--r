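#' Describe a hypergeometric screening setup
#'
#' A screening benchmark is modelled as drawing `n_drawn` compounds without
#' replacement from a pool of `population_size` compounds of which
#' `n_actives` are true actives.  The number of actives recovered in the
#' draw, `k_observed`, is the quantity whose probability the exact
#' hypergeometric law describes.
#'
#' @param population_size Total number of compounds in the pool (N_tot).
#' @param n_actives Number of true actives in the pool (N_pos).
#' @param n_drawn Number of compounds designated as positives (n).
#' @param k_observed Observed number of true actives among the designated
#'   positives, or `NULL` when no observation is attached.
#'
#' @return An object of class `hypergeom_setup`.
#' @examples
#' hypergeom_setup(307, 135, 63, k_observed = 59)
#' @export
hypergeom_setup <- function(population_size, n_actives, n_drawn,
                            k_observed = NULL) {
  chk_count(population_size, "population_size", positive = TRUE)
  chk_count(n_actives, "n_actives")
  chk_count(n_drawn, "n_drawn")
  if (n_actives > population_size)
    stop("n_actives (", n_actives, ") exceeds population_size (",
         population_size, ")", call. = FALSE)
  if (n_drawn > population_size)
    stop("n_drawn (", n_drawn, ") exceeds population_size (",
         population_size, ")", call. = FALSE)
  if (!is.null(k_observed)) {
    chk_count(k_observed, "k_observed")
    sup <- hypergeom_support(population_size, n_actives, n_drawn)
    if (k_observed < sup[1L] || k_observed > sup[2L])
      stop("k_observed = ", k_observed, " lies outside the support [",
           sup[1L], ", ", sup[2L], "]", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         n_actives      = as.integer(n_actives),
         n_drawn        = as.integer(n_drawn),
         k_observed     = if (is.null(k_observed)) NULL
                          else as.integer(k_observed)),
    class = "hypergeom_setup")
}

#' @export
print.hypergeom_setup <- function(x, ...) {
  cat("Hypergeometric setup: N_tot =", x$population_size,
      " N_pos =", x$n_actives, " n =", x$n_drawn)
  if (!is.null(x$k_observed)) cat("  k =", x$k_observed)
  cat("\n")
  invisible(x)
}

#' Scaled screening scenario
#'
#' The target scale onto which a benchmark enrichment is projected, e.g. a
#' realistic campaign rescoring 1,000 docking hits containing 10 actives
#' and selecting 100 compounds for experimental testing.
#'
#' @inheritParams hypergeom_setup
#' @return A `hypergeom_setup` without an attached observation.
#' @examples
#' scaled_scenario(1000, 10, 100)
#' @export
scaled_scenario <- function(population_size, n_actives, n_drawn) {
  hypergeom_setup(population_size, n_actives, n_drawn)
}

chk_count <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
      x != round(x) || x < if (positive) 1 else 0)
    stop(name, " must be a single ",
         if (positive) "positive" else "non-negative",
         " integer", call. = FALSE)
  invisible(TRUE)
}

#' Support of the hypergeometric distribution
#'
#' @inheritParams hypergeom_setup
#' @return Integer vector `c(k_min, k_max)`.
#' @export
hypergeom_support <- function(population_size, n_actives, n_drawn) {
  c(max(0L, as.integer(n_drawn) -
          (as.integer(population_size) - as.integer(n_actives))),
    min(as.integer(n_drawn), as.integer(n_actives)))
}

as_setup_args <- function(setup, population_size, n_actives, n_drawn) {
  if (inherits(setup, "hypergeom_setup"))
    return(setup)
  hypergeom_setup(setup, population_size, n_actives, n_drawn)
}

## log C(n, k) as a sum of O(1) log-ratios: slower than log-gamma but
## accurate to ~1e-14 absolute in the log even for n in the thousands,
## and finite for populations of 1e4 and beyond; vectorised over k
lchoose_lg <- function(n, k) {
  vapply(k, function(ki) {
    if (ki < 0 || ki > n) return(-Inf)
    ki <- min(ki, n - ki)
    if (ki == 0) return(0)
    i <- seq_len(ki)
    sum(log((n - ki + i) / i))
  }, numeric(1))
}

#' Exact hypergeometric probability mass
#'
#' Probability of recovering exactly `k` actives when `n_drawn` compounds
#' are drawn uniformly without replacement from `population_size`
#' compounds containing `n_actives` actives:
#' `C(N_pos, k) C(N_tot - N_pos, n - k) / C(N_tot, n)`.
#' Binomial coefficients are evaluated in log space so the mass stays
#' finite for pools of 10^4 compounds and beyond.
#'
#' @param k Observed active count(s); vectorised.
#' @inheritParams hypergeom_setup
#' @return Probabilities, exactly 0 for `k` outside the support.
#' @examples
#' hypergeom_pmf(7, 35, 15, 7)   # C(15,7) / C(35,7)
#' @export
hypergeom_pmf <- function(k, population_size, n_actives, n_drawn) {
  hypergeom_setup(population_size, n_actives, n_drawn)  # validate
  if (!is.numeric(k) || anyNA(k) || any(k != round(k)))
    stop("k must be integer-valued", call. = FALSE)
  sup <- hypergeom_support(population_size, n_actives, n_drawn)
  out <- numeric(length(k))
  ok <- k >= sup[1L] & k <= sup[2L]
  if (any(ok)) {
    kk <- k[ok]
    out[ok] <- exp(lchoose_lg(n_actives, kk) +
                   lchoose_lg(population_size - n_actives, n_drawn - kk) -
                   lchoose_lg(population_size, n_drawn))
  }
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)`, the probability of recovering at least `k` actives by
#' uniform random selection.  This is the significance measure attached to
#' an observed hit count: a predictor whose observed `k` has a vanishing
#' upper tail is enriching far beyond chance.  The tail is accumulated
#' from the smallest terms of the sum to limit cancellation.
#'
#' @inheritParams hypergeom_pmf
#' @return Probabilities; 1 for `k` at or below the lower support bound.
#' @examples
#' hypergeom_upper_tail(51, 307, 135, 63)  # ~2.1e-11
#' @export
hypergeom_upper_tail <- function(k, population_size, n_actives, n_drawn) {
  hypergeom_setup(population_size, n_actives, n_drawn)
  if (!is.numeric(k) || anyNA(k) || any(k != round(k)))
    stop("k must be integer-valued", call. = FALSE)
  sup <- hypergeom_support(population_size, n_actives, n_drawn)
  vapply(k, function(ki) {
    if (ki <= sup[1L]) return(1)
    if (ki > sup[2L]) return(0)
    ## sum pmf from the upper end of the support downward: beyond the mode
    ## the masses decay, so this adds the small terms first
    sum(hypergeom_pmf(seq(sup[2L], ki), population_size, n_actives,
                      n_drawn))
  }, numeric(1))
}

#' Maximum of the hypergeometric probability mass function
#'
#' The largest single-outcome probability over the support; the benchmark
#' interpretation is the highest probability any hit count can have under
#' pure random selection, attained at the distribution mode.
#'
#' @inheritParams hypergeom_setup
#' @return A probability.
#' @examples
#' max_pmf(307, 135, 63)  # ~0.11
#' @export
max_pmf <- function(population_size, n_actives, n_drawn) {
  sup <- hypergeom_support(population_size, n_actives, n_drawn)
  ## mode of the hypergeometric: floor((n+1)(K+1)/(N+2)), clamped to support
  mode_k <- floor((n_drawn + 1) * (n_actives + 1) / (population_size + 2))
  ks <- unique(pmin(pmax(c(mode_k - 1, mode_k, mode_k + 1), sup[1L]),
                    sup[2L]))
  max(hypergeom_pmf(ks, population_size, n_actives, n_drawn))
}

## P(X < k), summed from the small end of the lower support; used where
## the upper tail saturates at 1 in double precision
hypergeom_lower_strict <- function(k, population_size, n_actives,
                                   n_drawn) {
  sup <- hypergeom_support(population_size, n_actives, n_drawn)
  if (k <= sup[1L]) return(0)
  if (k > sup[2L]) return(1)
  sum(hypergeom_pmf(seq(sup[1L], k - 1L), population_size, n_actives,
                    n_drawn))
}

#' Project benchmark enrichment onto a larger screening scale
#'
#' Maps an observed benchmark hit count onto a scaled scenario by matching
#' upper-tail probabilities: the projected recovery is the smallest k2 in
#' `[0, K2]` whose upper tail under the scaled scenario does not exceed the
#' benchmark's upper tail at the observed count.  When even full recovery
#' (k2 = K2) retains a larger tail than the benchmark — i.e. the benchmark
#' significance is stronger than anything the scaled scenario can express —
#' the projection is capped at full recovery.
#'
#' @param bench A [hypergeom_setup()] with `k_observed` set.
#' @param scaled A [scaled_scenario()] (or `hypergeom_setup`) giving the
#'   target scale.
#' @return Integer: projected number of actives recovered.
#' @examples
#' bench <- hypergeom_setup(307, 135, 63, k_observed = 59)
#' extrapolate_recovered_actives(bench, scaled_scenario(1000, 10, 100))
#' @export
extrapolate_recovered_actives <- function(bench, scaled) {
  stopifnot(inherits(bench, "hypergeom_setup"),
            inherits(scaled, "hypergeom_setup"))
  if (is.null(bench$k_observed))
    stop("bench must carry an observed k", call. = FALSE)
  bench_tail <- hypergeom_upper_tail(bench$k_observed,
                                     bench$population_size,
                                     bench$n_actives, bench$n_drawn)
  k2_max <- scaled$n_actives
  if (bench_tail <= 0.5) {
    for (k2 in 0:k2_max) {
      tail2 <- hypergeom_upper_tail(k2, scaled$population_size,
                                    scaled$n_actives, scaled$n_drawn)
      if (tail2 <= bench_tail) return(as.integer(k2))
    }
  } else {
    ## P(X >= k2) <= P(X >= k_obs) is exactly P(X < k2) >= P(X < k_obs);
    ## the complementary form keeps resolution where the upper tail
    ## saturates at 1 in double precision
    bench_lower <- hypergeom_lower_strict(bench$k_observed,
                                          bench$population_size,
                                          bench$n_actives, bench$n_drawn)
    for (k2 in 0:k2_max) {
      lower2 <- hypergeom_lower_strict(k2, scaled$population_size,
                                       scaled$n_actives, scaled$n_drawn)
      if (lower2 >= bench_lower) return(as.integer(k2))
    }
  }
  as.integer(k2_max)  # cap at full recovery
}

#' Smallest hit list capturing all actives at benchmark confidence
#'
#' Inverse projection: the smallest number of designated positives n2 for
#' which the probability of recovering *all* `scaled_actives` actives,
#' `P(X >= K2 | N2, K2, n2)`, is at least the benchmark's upper-tail
#' probability.  The matching rule is the package's own convention; the
#' returned size is rule-dependent and should be reported as such.
#'
#' @param bench A [hypergeom_setup()] with `k_observed` set.
#' @param scaled_population Pool size N2 of the target scenario.
#' @param scaled_actives Active count K2 of the target scenario.
#' @return Integer hit-list size n2.
#' @examples
#' bench <- hypergeom_setup(307, 135, 63, k_observed = 59)
#' min_hitlist_full_recovery(bench, 1000, 10)
#' @export
min_hitlist_full_recovery <- function(bench, scaled_population,
                                      scaled_actives) {
  stopifnot(inherits(bench, "hypergeom_setup"))
  if (is.null(bench$k_observed))
    stop("bench must carry an observed k", call. = FALSE)
  chk_count(scaled_population, "scaled_population", positive = TRUE)
  chk_count(scaled_actives, "scaled_actives")
  if (scaled_actives > scaled_population)
    stop("scaled_actives exceeds scaled_population", call. = FALSE)
  if (scaled_actives == 0L) return(0L)
  bench_tail <- hypergeom_upper_tail(bench$k_observed,
                                     bench$population_size,
                                     bench$n_actives, bench$n_drawn)
  if (bench_tail == 0) {
    warning("benchmark tail underflows to 0; only exhaustive selection ",
            "guarantees full recovery")
    return(as.integer(scaled_population))
  }
  ## P(all K2 actives among n2 draws) = prod_{i=0..K2-1} (n2-i)/(N2-i),
  ## accumulated in log space; monotone increasing in n2
  for (n2 in scaled_actives:scaled_population) {
    lp <- sum(log(n2 - seq_len(scaled_actives) + 1) -
              log(scaled_population - seq_len(scaled_actives) + 1))
    if (exp(lp) >= bench_tail) return(as.integer(n2))
  }
  as.integer(scaled_population)
}
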