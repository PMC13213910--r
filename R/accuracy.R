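#' Convert a dissociation/inhibition constant to a binding free energy
#'
#' Standard-state relation `dG = R T ln(K / 1 M)` with
#' R = 1.98720e-3 kcal/(mol K).  K_i values are treated identically to
#' K_d.
#'
#' @param affinity_molar K_d or K_i in mol/L; vectorised.
#' @param temperature Absolute temperature in Kelvin (default 298 K).
#' @return Binding free energy in kcal/mol (negative for sub-molar
#'   affinities).
#' @examples
#' kd_to_dg(1e-9)  # ~ -12.3 kcal/mol
#' @export
kd_to_dg <- function(affinity_molar, temperature = 298) {
  if (!is.numeric(affinity_molar) || any(!is.finite(affinity_molar)) ||
      any(affinity_molar <= 0))
    stop("affinity must be a positive molar concentration", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      temperature <= 0)
    stop("temperature must be positive (Kelvin)", call. = FALSE)
  R_KCAL <- 1.98720e-3
  R_KCAL * temperature * log(affinity_molar)
}

validate_affinity_pairs <- function(pairs) {
  need <- c("target_id", "ligand_id", "dg_exp", "dg_calc")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("affinity pairs are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(pairs$dg_exp)) || any(!is.finite(pairs$dg_calc)))
    stop("dg_exp and dg_calc must be finite", call. = FALSE)
  key <- paste(pairs$target_id, pairs$ligand_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (target_id, ligand_id) in affinity pairs",
         call. = FALSE)
  pairs
}

#' Correlation and error metrics for exp/calc binding free energies
#'
#' @param pairs Data frame with columns `target_id`, `ligand_id`,
#'   `dg_exp`, `dg_calc` (kcal/mol).
#' @return List with `pearson_r`, `spearman_rho`, `rmse` and `n_pairs`.
#' @details Correlations require at least 3 pairs and non-degenerate
#'   variance on both axes; a zero-variance axis is an error, never a
#'   silent zero.  Spearman uses average ranks for ties.  RMSE is the
#'   root mean squared `dg_calc - dg_exp` difference.
#' @export
dg_accuracy <- function(pairs) {
  validate_affinity_pairs(pairs)
  list(pearson_r    = pearson_r(pairs$dg_exp, pairs$dg_calc),
       spearman_rho = spearman_rho(pairs$dg_exp, pairs$dg_calc),
       rmse         = rmse(pairs$dg_exp, pairs$dg_calc),
       n_pairs      = nrow(pairs))
}

chk_cor_input <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("correlations need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
}

#' @rdname dg_accuracy
#' @param x,y Paired numeric vectors.
#' @export
pearson_r <- function(x, y) {
  chk_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' @rdname dg_accuracy
#' @export
spearman_rho <- function(x, y) {
  chk_cor_input(x, y)
  stats::cor(x, y, method = "spearman")
}

#' @rdname dg_accuracy
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("rmse needs paired vectors of length >= 1", call. = FALSE)
  sqrt(mean((y - x)^2))
}

#' Per-target accuracy for targets with enough ligands
#'
#' Intratarget correlations are only meaningful with a reasonable number
#' of ligands per protein; targets below `min_ligands` are listed as
#' skipped rather than reported.
#'
#' @inheritParams dg_accuracy
#' @param min_ligands Minimum pairs a target needs to be reported
#'   (default 10).
#' @return List with `reports` (named list of [dg_accuracy()] results)
#'   and `skipped` (character vector of target ids below threshold).
#' @export
intratarget_correlations <- function(pairs, min_ligands = 10) {
  validate_affinity_pairs(pairs)
  by_target <- split(pairs, pairs$target_id)
  n <- vapply(by_target, nrow, integer(1))
  keep <- n >= min_ligands
  list(reports = lapply(by_target[keep], dg_accuracy),
       skipped = names(by_target)[!keep])
}

#' Accuracy above and below the median of a stratification descriptor
#'
#' Splits the pairs at the median of the named descriptor column (ties at
#' the median go to the low subset, keeping the split deterministic) and
#' reports metrics for both halves.
#'
#' @inheritParams dg_accuracy
#' @param descriptor_name Name of a numeric column present on every pair.
#' @return List with `median`, `low` and `high` accuracy reports, and the
#'   subset sizes.
#' @export
median_split_analysis <- function(pairs, descriptor_name) {
  validate_affinity_pairs(pairs)
  if (!descriptor_name %in% names(pairs))
    stop("descriptor '", descriptor_name, "' not present", call. = FALSE)
  d <- pairs[[descriptor_name]]
  if (anyNA(d)) {
    bad <- pairs$ligand_id[is.na(d)][1L]
    stop("descriptor '", descriptor_name, "' missing for ligand ",
         bad, call. = FALSE)
  }
  med <- stats::median(d)
  low <- pairs[d <= med, , drop = FALSE]
  high <- pairs[d > med, , drop = FALSE]
  if (!nrow(high))
    warning("descriptor '", descriptor_name,
            "' is degenerate at the median; the high subset is empty")
  list(descriptor = descriptor_name, median = med,
       low  = if (nrow(low) >= 3L) dg_accuracy(low) else
                list(n_pairs = nrow(low)),
       high = if (nrow(high) >= 3L) dg_accuracy(high) else
                list(n_pairs = nrow(high)))
}

#' RMSE for the tighter- and weaker-binding halves
#'
#' Ranks pairs by experimental affinity (most negative `dg_exp` = tightest
#' binders = "top") and reports the RMSE of each half.  With an odd count
#' the middle pair joins the top half.
#'
#' @inheritParams dg_accuracy
#' @return List with `rmse_top_half`, `rmse_bottom_half`, `n_top`,
#'   `n_bottom`.
#' @export
affinity_half_split_rmse <- function(pairs) {
  validate_affinity_pairs(pairs)
  if (nrow(pairs) < 2L)
    stop("need at least 2 pairs", call. = FALSE)
  ord <- order(pairs$dg_exp, pairs$ligand_id)
  n_top <- ceiling(nrow(pairs) / 2)
  top <- pairs[ord[seq_len(n_top)], ]
  bottom <- pairs[ord[-seq_len(n_top)], ]
  list(rmse_top_half = rmse(top$dg_exp, top$dg_calc),
       rmse_bottom_half = rmse(bottom$dg_exp, bottom$dg_calc),
       n_top = nrow(top), n_bottom = nrow(bottom))
}

#' Sensitivity of predictions to docking-derived starting coordinates
#'
#' For ligands with both an experimental (X-ray) and a docking-derived
#' complex, flags poses that diverge from the crystal pose (RMSD strictly
#' greater than `pose_threshold`) and prediction shifts that are
#' significant (absolute difference strictly greater than
#' `shift_threshold`), and counts how many significant shifts weaken the
#' predicted affinity (dock-derived dG higher, i.e. less negative, than
#' X-ray-derived).
#'
#' @param comparisons Data frame with columns `ligand_id`,
#'   `rmsd_to_xray` (Angstrom), `dg_from_dock`, `dg_from_xray`
#'   (kcal/mol).
#' @param pose_threshold RMSD above which a pose is divergent (default
#'   3 Angstrom).
#' @param shift_threshold dG difference above which a shift is
#'   significant (default 2 kcal/mol).
#' @return List with per-ligand flags and the counts `n_divergent`,
#'   `n_significant`, `n_weaker` (significant shifts among divergent
#'   poses, and how many of those weaken affinity).
#' @export
pose_divergence_analysis <- function(comparisons, pose_threshold = 3.0,
                                     shift_threshold = 2.0) {
  need <- c("ligand_id", "rmsd_to_xray", "dg_from_dock", "dg_from_xray")
  miss <- setdiff(need, names(comparisons))
  if (length(miss))
    stop("pose comparisons missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(comparisons$rmsd_to_xray < 0))
    stop("negative RMSD", call. = FALSE)
  if (any(!is.finite(comparisons$dg_from_dock)) ||
      any(!is.finite(comparisons$dg_from_xray)))
    stop("both dG values must be present and finite", call. = FALSE)
  divergent <- comparisons$rmsd_to_xray > pose_threshold
  shift <- comparisons$dg_from_dock - comparisons$dg_from_xray
  significant <- divergent & abs(shift) > shift_threshold
  weaker <- significant & shift > 0
  flags <- data.frame(ligand_id = comparisons$ligand_id,
                      rmsd_to_xray = comparisons$rmsd_to_xray,
                      dg_shift = shift,
                      divergent_pose = divergent,
                      significant_shift = significant,
                      weaker_affinity = weaker,
                      stringsAsFactors = FALSE)
  list(flags = flags,
       n_divergent = sum(divergent),
       n_significant = sum(significant),
       n_weaker = sum(weaker),
       pose_threshold = pose_threshold,
       shift_threshold = shift_threshold)
}
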