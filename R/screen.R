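#' Validate a table of scored screening records
#'
#' A score table has one row per (target, ligand) with the ligand's role
#' (`active`, `decoy` or `unknown`) and its predicted binding free energy
#' in kcal/mol (more negative = tighter predicted binding).
#'
#' @param records Data frame with columns `target_id`, `ligand_id`,
#'   `role`, `dg_pred`.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_screen_records <- function(records) {
  need <- c("target_id", "ligand_id", "role", "dg_pred")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("score table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad_role <- setdiff(unique(records$role), c("active", "decoy", "unknown"))
  if (length(bad_role))
    stop("invalid role value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(records$dg_pred) || any(!is.finite(records$dg_pred)))
    stop("dg_pred must be finite numeric", call. = FALSE)
  key <- paste(records$target_id, records$ligand_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (target_id, ligand_id) key: ",
         gsub("\r", " / ", d), call. = FALSE)
  }
  records
}

#' Select the top-n scored ligands for one target
#'
#' Ranks one target's ligands by predicted binding free energy (most
#' negative first by default) and designates the top `n` as positives.
#' Ties on the score are broken by ascending `ligand_id` so the selection
#' is deterministic and independent of input order.
#'
#' @param records Data frame of screening records for a single target.
#' @param n Number of ligands to designate as positives.
#' @param higher_is_better Set `TRUE` for scores where larger means
#'   better (the default treats scores as free energies).
#' @return An object of class `selection_result` with elements
#'   `selected_ids` (data frame of `target_id`, `ligand_id` in selection
#'   order), `n_drawn`, `k_true` (actives among selected) and `tpr`.
#' @examples
#' tab <- data.frame(target_id = "T", ligand_id = c("a", "b", "c"),
#'                   role = c("active", "active", "decoy"),
#'                   dg_pred = c(-12, -11, -9))
#' select_top_n(tab, 2)
#' @export
select_top_n <- function(records, n, higher_is_better = FALSE) {
  validate_screen_records(records)
  if (length(unique(records$target_id)) != 1L)
    stop("select_top_n expects records for exactly one target",
         call. = FALSE)
  chk_count(n, "n")
  if (n > nrow(records))
    stop("n = ", n, " exceeds the ", nrow(records),
         " records available", call. = FALSE)
  score <- if (higher_is_better) -records$dg_pred else records$dg_pred
  ord <- order(score, records$ligand_id)
  sel <- records[ord[seq_len(n)], , drop = FALSE]
  k_true <- sum(sel$role == "active")
  structure(
    list(selected_ids = data.frame(target_id = sel$target_id,
                                   ligand_id = sel$ligand_id,
                                   stringsAsFactors = FALSE),
         n_drawn = as.integer(n),
         k_true  = as.integer(k_true),
         tpr     = if (n > 0) k_true / n else NA_real_),
    class = "selection_result")
}

#' True-positive rate of a selection
#'
#' @param k_true Number of actives among the designated positives.
#' @param n_drawn Number of designated positives.
#' @return `k_true / n_drawn`. Rounding to whole percent is left to the
#'   presentation layer.
#' @examples
#' tpr(59, 63)  # ~0.94
#' @export
tpr <- function(k_true, n_drawn) {
  chk_count(k_true, "k_true"); chk_count(n_drawn, "n_drawn")
  if (n_drawn == 0L)
    stop("tpr is undefined for n_drawn = 0", call. = FALSE)
  if (k_true > n_drawn)
    stop("k_true exceeds n_drawn", call. = FALSE)
  k_true / n_drawn
}

#' Expected true-positive rate of random selection
#'
#' The baseline against which enrichment is judged: drawing uniformly
#' from the pool, the expected fraction of actives in any selection is
#' simply the pool's active fraction.
#'
#' @inheritParams hypergeom_setup
#' @return `n_actives / population_size`.
#' @examples
#' random_expectation(35, 15)  # ~0.43
#' @export
random_expectation <- function(population_size, n_actives) {
  chk_count(population_size, "population_size", positive = TRUE)
  chk_count(n_actives, "n_actives")
  if (n_actives > population_size)
    stop("n_actives exceeds population_size", call. = FALSE)
  n_actives / population_size
}

#' Pool per-target selections into one benchmark setup
#'
#' Sums designated positives and recovered actives over targets and
#' attaches the caller-supplied pooled population counts.  The pooled
#' population is an explicit input rather than being inferred from the
#' nominal dataset size, because evaluated pools are often smaller than
#' nominal ones (ligands fail upstream).
#'
#' @param per_target List of [select_top_n()] results.
#' @param evaluated_population Total number of ligands actually evaluated.
#' @param evaluated_actives Total number of actives actually evaluated.
#' @return A [hypergeom_setup()] with `k_observed` set.
#' @examples
#' sels <- replicate(2, list(n_drawn = 7L, k_true = 6L), simplify = FALSE)
#' @export
pool_targets <- function(per_target, evaluated_population,
                         evaluated_actives) {
  if (!length(per_target))
    stop("per_target must be non-empty", call. = FALSE)
  n_sum <- sum(vapply(per_target, function(s) s$n_drawn, integer(1)))
  k_sum <- sum(vapply(per_target, function(s) s$k_true, integer(1)))
  if (k_sum > n_sum)
    stop("internal error: pooled k exceeds pooled n", call. = FALSE)
  hypergeom_setup(evaluated_population, evaluated_actives, n_sum,
                  k_observed = k_sum)
}

#' Full enrichment report for a multi-target score table
#'
#' Runs the top-n selection on every target, pools the results, and
#' attaches the exact hypergeometric statistics: probability mass and
#' upper tail at the pooled hit count, the maximum mass any count can
#' have under random selection, the random-selection expectation, and
#' (optionally) the projection onto a scaled screening scenario.
#'
#' @param records Multi-target score table (see
#'   [validate_screen_records()]).
#' @param per_target_n Positives designated per target.
#' @param scaled Optional [scaled_scenario()] for extrapolation.
#' @param population,actives Pooled evaluated counts; default to the
#'   number of role-annotated rows and the number of actives in
#'   `records`.
#' @param higher_is_better Passed to [select_top_n()].
#' @return An object of class `enrichment_report`.
#' @examples
#' tab <- simulate_screen_scores(screen_sim_spec(seed = 1))
#' enrichment_report(tab, 7, scaled = scaled_scenario(1000, 10, 100))
#' @export
enrichment_report <- function(records, per_target_n, scaled = NULL,
                              population = NULL, actives = NULL,
                              higher_is_better = FALSE) {
  validate_screen_records(records)
  known <- records$role != "unknown"
  all_unknown <- tapply(!known, records$target_id, all)
  if (any(all_unknown)) {
    warning("excluding target(s) with only unknown roles: ",
            paste(names(all_unknown)[all_unknown], collapse = ", "))
    keep <- !(records$target_id %in% names(all_unknown)[all_unknown])
    records <- records[keep, , drop = FALSE]
    known <- records$role != "unknown"
  }
  if (!nrow(records))
    stop("no targets with annotated roles", call. = FALSE)
  if (is.null(population)) population <- sum(known)
  if (is.null(actives)) actives <- sum(records$role == "active")

  per_target <- lapply(split(records, records$target_id), select_top_n,
                       n = per_target_n,
                       higher_is_better = higher_is_better)
  pooled <- pool_targets(per_target, population, actives)

  out <- list(
    per_target = per_target,
    pooled = pooled,
    pooled_tpr = tpr(pooled$k_observed, pooled$n_drawn),
    pmf_at_k = hypergeom_pmf(pooled$k_observed, pooled$population_size,
                             pooled$n_actives, pooled$n_drawn),
    upper_tail_at_k = hypergeom_upper_tail(
      pooled$k_observed, pooled$population_size, pooled$n_actives,
      pooled$n_drawn),
    max_pmf = max_pmf(pooled$population_size, pooled$n_actives,
                      pooled$n_drawn),
    random_expectation = random_expectation(pooled$population_size,
                                            pooled$n_actives),
    scaled = scaled,
    extrapolated_actives =
      if (is.null(scaled)) NULL
      else extrapolate_recovered_actives(pooled, scaled))
  class(out) <- "enrichment_report"
  out
}

#' @export
print.enrichment_report <- function(x, ...) {
  p <- x$pooled
  cat("Enrichment over", length(x$per_target), "target(s)\n")
  cat(sprintf("  pooled: k = %d of n = %d (TPR %.0f%%), pool %d/%d\n",
              p$k_observed, p$n_drawn, 100 * x$pooled_tpr,
              p$population_size, p$n_actives))
  cat(sprintf("  P(X >= k) = %.3g   pmf(k) = %.3g   max pmf = %.3g\n",
              x$upper_tail_at_k, x$pmf_at_k, x$max_pmf))
  cat(sprintf("  random expectation = %.0f%%\n",
              100 * x$random_expectation))
  if (!is.null(x$extrapolated_actives))
    cat(sprintf("  projected recovery at scale (%d, %d, %d): %d actives\n",
                x$scaled$population_size, x$scaled$n_actives,
                x$scaled$n_drawn, x$extrapolated_actives))
  invisible(x)
}
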