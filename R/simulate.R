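#' Specification for simulated exp/calc affinity pairs
#'
#' Describes a synthetic benchmark of experimental/calculated binding
#' free energy pairs with a prescribed population Pearson correlation
#' and per-target grouping.  Defaults mirror the scale of a curated
#' affinity benchmark: 632 pairs in total, experimental values spread
#' over the lead-like affinity window of -14 to -5 kcal/mol, and a
#' calculation noise of 1.5 kcal/mol.
#'
#' @param n_targets Number of protein targets.
#' @param ligands_per_target Pairs per target (>= 2).
#' @param pearson_target Desired population Pearson correlation, in the
#'   open interval (-1, 1).
#' @param dg_exp_range Range of experimental dG values, kcal/mol.
#' @param noise_sd SD of the calculation noise, kcal/mol.
#' @param seed Integer seed; the generator is a pure function of the
#'   spec.
#' @return List of class `accuracy_sim_spec`.
#' @export
accuracy_sim_spec <- function(n_targets = 8, ligands_per_target = 79,
                              pearson_target = 0.69,
                              dg_exp_range = c(-14, -5),
                              noise_sd = 1.5, seed = 1L) {
  if (pearson_target <= -1 || pearson_target >= 1)
    stop("pearson_target must lie in (-1, 1)", call. = FALSE)
  if (ligands_per_target < 2)
    stop("ligands_per_target must be >= 2", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (diff(range(dg_exp_range)) <= 0)
    stop("dg_exp_range must be a non-degenerate interval", call. = FALSE)
  structure(list(n_targets = as.integer(n_targets),
                 ligands_per_target = as.integer(ligands_per_target),
                 pearson_target = pearson_target,
                 dg_exp_range = sort(dg_exp_range),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "accuracy_sim_spec")
}

#' Simulate exp/calc binding free energy pairs
#'
#' Experimental values are uniform on the requested range; calculated
#' values are an affine response plus Gaussian noise, with the slope
#' solved from the noise SD so that the *population* Pearson
#' correlation equals `pearson_target`:
#' `a = (noise_sd / sd_exp) * r / sqrt(1 - r^2)`.  The response is
#' centred on the middle of the range so calculated values stay in a
#' physically sensible dG window.
#'
#' @param spec An [accuracy_sim_spec()].
#' @return Data frame of affinity pairs (`target_id`, `ligand_id`,
#'   `dg_exp`, `dg_calc`), byte-identical across reruns with the same
#'   spec.
#' @export
simulate_accuracy_pairs <- function(spec = accuracy_sim_spec()) {
  stopifnot(inherits(spec, "accuracy_sim_spec"))
  n <- spec$n_targets * spec$ligands_per_target
  r <- spec$pearson_target
  lo <- spec$dg_exp_range[1]; hi <- spec$dg_exp_range[2]
  sd_exp <- (hi - lo) / sqrt(12)
  a <- (spec$noise_sd / sd_exp) * r / sqrt(1 - r^2)
  centre <- (lo + hi) / 2
  withr_seed(spec$seed, {
    dg_exp <- stats::runif(n, lo, hi)
    dg_calc <- centre + a * (dg_exp - centre) +
      stats::rnorm(n, 0, spec$noise_sd)
  })
  data.frame(
    target_id = rep(sprintf("T%02d", seq_len(spec$n_targets)),
                    each = spec$ligands_per_target),
    ligand_id = sprintf("L%05d", seq_len(n)),
    dg_exp = dg_exp, dg_calc = dg_calc,
    stringsAsFactors = FALSE)
}

## evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specification for simulated active/decoy screens
#'
#' Emulates the shape of a small per-target discrimination benchmark:
#' nine targets with 15 actives and 20 decoys each, Gaussian scores
#' with a method-tunable separation between the active and decoy means.
#' The default separation (actives 3 kcal/mol below decoys at a common
#' 1.8 kcal/mol SD) is the strong, alchemical-grade regime; presets for
#' weaker regimes are available through [screen_sim_presets()].
#'
#' @param n_targets Number of targets (default 9).
#' @param actives_per_target,decoys_per_target Counts per target
#'   (defaults 15 and 20).
#' @param active_mean,decoy_mean Mean predicted dG per role, kcal/mol.
#' @param common_sd Common score SD, kcal/mol.
#' @param seed Integer seed.
#' @return List of class `screen_sim_spec`.
#' @export
screen_sim_spec <- function(n_targets = 9, actives_per_target = 15,
                            decoys_per_target = 20,
                            active_mean = -11.5, decoy_mean = -8.5,
                            common_sd = 1.8, seed = 1L) {
  if (common_sd <= 0) stop("common_sd must be positive", call. = FALSE)
  if (any(c(n_targets, actives_per_target, decoys_per_target) < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(list(n_targets = as.integer(n_targets),
                 actives_per_target = as.integer(actives_per_target),
                 decoys_per_target = as.integer(decoys_per_target),
                 active_mean = active_mean, decoy_mean = decoy_mean,
                 common_sd = common_sd, seed = as.integer(seed)),
            class = "screen_sim_spec")
}

#' Named separation presets for the screen generator
#'
#' Qualitative regimes, not reproductions of any particular predictor:
#' `abfe_like` (strong separation), `endstate_like` (moderate),
#' `ml_like` (near-zero separation).
#'
#' @return Named list of mean/SD parameter sets.
#' @export
screen_sim_presets <- function() {
  list(abfe_like     = list(active_mean = -11.5, decoy_mean = -8.5,
                            common_sd = 1.8),
       endstate_like = list(active_mean = -10.5, decoy_mean = -8.8,
                            common_sd = 1.8),
       ml_like       = list(active_mean = -9.0, decoy_mean = -8.9,
                            common_sd = 1.8))
}

#' Simulate an active/decoy score table
#'
#' @param spec A [screen_sim_spec()].
#' @return Screening-record data frame (`target_id`, `ligand_id`,
#'   `role`, `dg_pred`), byte-identical across reruns with the same
#'   spec.
#' @export
simulate_screen_scores <- function(spec = screen_sim_spec()) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  per <- spec$actives_per_target + spec$decoys_per_target
  n <- spec$n_targets * per
  roles <- rep(c(rep("active", spec$actives_per_target),
                 rep("decoy", spec$decoys_per_target)), spec$n_targets)
  means <- ifelse(roles == "active", spec$active_mean, spec$decoy_mean)
  withr_seed(spec$seed,
             scores <- stats::rnorm(n, means, spec$common_sd))
  data.frame(
    target_id = rep(sprintf("T%02d", seq_len(spec$n_targets)),
                    each = per),
    ligand_id = sprintf("L%05d", seq_len(n)),
    role = roles, dg_pred = scores,
    stringsAsFactors = FALSE)
}

#' Curated molecules with known filter outcomes
#'
#' A small fixed set of molecules where each "violator" breaks exactly
#' one named curation rule and the "clean" entries pass everything; the
#' expected outcome ships alongside each SMILES so filter tests carry
#' their own oracle.
#'
#' @return Data frame with columns `ligand_id`, `smiles`,
#'   `expected_failed_rule` (`""` for all-pass molecules).
#' @export
fixture_molecules <- function() {
  read.csv(system.file("extdata", "fixture_molecules.csv",
                       package = "vstriage", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Emit a synthetic ligand-protein complex with planted geometry
#'
#' Writes PDB text for a complex whose descriptors are known by
#' construction: ligand heavy atoms are placed 50 Angstrom apart so each
#' one's planted protein contacts (at 3.0 Angstrom) are attributable to
#' it alone; each contact atom is its own pocket residue with a residue
#' name cycled from `pocket_resnames`; distant residues, an optional
#' metal and optional waters complete the file.
#'
#' @param contacts Integer vector: planted protein-contact count per
#'   ligand atom.
#' @param pocket_resnames Residue names cycled over the contact
#'   residues.
#' @param n_far_residues Residues planted 60 Angstrom away (outside any
#'   pocket cutoff).
#' @param metal Optional list `list(element =, distance =)`; the metal
#'   is planted at that distance from the first ligand atom.
#' @param n_waters Water molecules planted (should be ignored by the
#'   parser).
#' @param seed Seed for the small coordinate jitter (<= 0.2 Angstrom per
#'   axis, preserving all planted cutoff relations).
#' @param path Optional file path; when given the text is written there.
#' @return Character vector of PDB lines (invisibly when `path` is
#'   given), with the planted oracle values attached as attributes
#'   `burial_oracle` and `pocket_resnames_used`.
#' @export
simulate_complex_geometry <- function(contacts = c(2L, 7L, 4L),
                                      pocket_resnames = "ALA",
                                      n_far_residues = 3,
                                      metal = NULL, n_waters = 0,
                                      seed = 1L, path = NULL) {
  stopifnot(all(contacts >= 0))
  lines <- character(0)
  serial <- 0L
  resno <- 0L
  jit <- local({
    total <- (sum(contacts) + n_far_residues + n_waters + 2) * 3 + 9
    withr_seed(seed, stats::runif(total, -0.2, 0.2))
  })
  ji <- 0L
  jitter3 <- function() {
    ji <<- ji + 3L
    jit[(ji - 2L):ji]
  }
  fmt <- function(type, name, resname, chain, rn, xyz, element) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, "", resname, chain, rn, "",
            xyz[1], xyz[2], xyz[3], 1, 0, element)
  }
  pocket_used <- character(0)

  ## protein contacts + pocket residues around each ligand atom
  lig_pos <- lapply(seq_along(contacts), function(i) c(50 * i, 0, 0))
  for (i in seq_along(contacts)) {
    ci <- contacts[i]
    if (ci == 0) next
    for (j in seq_len(ci)) {
      ang <- 2 * pi * (j - 1) / ci
      pos <- lig_pos[[i]] + c(0, 3.0 * cos(ang), 3.0 * sin(ang))
      serial <- serial + 1L; resno <- resno + 1L
      rn <- pocket_resnames[(resno - 1L) %% length(pocket_resnames) + 1L]
      pocket_used <- c(pocket_used, rn)
      lines <- c(lines, fmt("ATOM", "CA", rn, "A", resno, pos, "C"))
    }
  }
  ## distant residues (outside every cutoff)
  for (j in seq_len(n_far_residues)) {
    serial <- serial + 1L; resno <- resno + 1L
    pos <- c(-60, 20 * j, 0) + jitter3()
    lines <- c(lines, fmt("ATOM", "CA", "GLY", "A", resno, pos, "C"))
  }
  ## optional metal near the first ligand atom
  if (!is.null(metal)) {
    serial <- serial + 1L; resno <- resno + 1L
    pos <- lig_pos[[1]] + c(0, 0, -metal$distance)
    lines <- c(lines, fmt("HETATM", toupper(metal$element),
                          toupper(metal$element), "A", resno, pos,
                          metal$element))
  }
  ## waters
  for (j in seq_len(n_waters)) {
    serial <- serial + 1L; resno <- resno + 1L
    pos <- c(-80, -20 * j, 0) + jitter3()
    lines <- c(lines, fmt("HETATM", "O", "HOH", "A", resno, pos, "O"))
  }
  ## the ligand itself
  resno <- resno + 1L
  for (i in seq_along(contacts)) {
    serial <- serial + 1L
    lines <- c(lines, fmt("HETATM", "C1", "LIG", "A", resno,
                          unlist(lig_pos[i]), "C"))
  }
  lines <- c(lines, "END")
  attr(lines, "burial_oracle") <- stats::median(contacts)
  attr(lines, "pocket_resnames_used") <- pocket_used
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
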