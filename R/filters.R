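#' Compute the physicochemical property set used by the curation funnel
#'
#' Parses SMILES and fills every property the lead-likeness filters act
#' on: molecular weight, calculated logP, hydrogen-bond donors and
#' acceptors, rotatable bonds, ring count, phosphorus count, ionizable
#' groups (SMARTS-defined), the longest run of consecutive acyclic sp3
#' carbons, the largest fused ring system, and any reactive/toxic alerts
#' fired from the shipped SMARTS list.  MW, cLogP, HBD and HBA follow the
#' conventions of the OpenBabel backend; the variant is recorded in the
#' result's `backend` attribute since these definitions differ between
#' toolkits.
#'
#' @param smiles Character vector of SMILES, optionally named by ligand
#'   id.
#' @param ids Ligand ids (defaults to the names of `smiles`).
#' @param ionizable_smarts Data frame of SMARTS patterns defining
#'   ionizable groups (default: the shipped table, see
#'   [default_ionizable_smarts()]).
#' @param alert_smarts Data frame of reactive-group SMARTS alerts
#'   (default: the shipped table, see [default_alert_smarts()]).
#' @return Data frame with one row per molecule and a `reactive_matches`
#'   list-column of fired alert names.
#' @examples
#' compute_properties(c(ethanol = "CCO"))
#' @export
compute_properties <- function(smiles, ids = NULL,
                               ionizable_smarts = default_ionizable_smarts(),
                               alert_smarts = default_alert_smarts()) {
  sdfset <- parse_smiles(smiles, ids)
  ids <- ChemmineR::cid(sdfset)
  props <- ChemmineR::propOB(sdfset)

  graphs <- lapply(seq_along(sdfset), function(i) mol_graph(sdfset[[i]]))
  n_rings <- vapply(graphs, count_rings, numeric(1))
  n_p <- vapply(graphs, function(g) sum(g$elements == "P"), numeric(1))
  chain <- vapply(graphs, longest_sp3_chain, integer(1))
  fused <- vapply(graphs, max_fused_ring_system, integer(1))

  rot <- smarts_counts(sdfset, "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]")
  smarts_matrix <- function(patterns) {
    m <- vapply(patterns, function(s) smarts_counts(sdfset, s),
                numeric(length(sdfset)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(sdfset))
    m
  }
  n_ion <- rowSums(smarts_matrix(ionizable_smarts$smarts))
  alert_hits <- smarts_matrix(alert_smarts$smarts)
  reactive <- lapply(seq_along(sdfset), function(i)
    alert_smarts$name[alert_hits[i, ] > 0])

  out <- data.frame(
    ligand_id = ids,
    smiles = as.character(smiles),
    mw = props$MW,
    clogp = props$logP,
    hbd = as.integer(props$HBD),
    hba = as.integer(props$HBA1),
    rot_bonds = as.integer(rot),
    n_rings = as.integer(n_rings),
    n_phosphorus = as.integer(n_p),
    n_ionizable = as.integer(n_ion),
    longest_acyclic_sp3_carbon_chain = chain,
    max_fused_ring_system_size = fused,
    stringsAsFactors = FALSE)
  out$reactive_matches <- reactive
  attr(out, "backend") <- paste0("OpenBabel/ChemmineOB (MW, logP, HBD, ",
                                 "HBA1 conventions)")
  rownames(out) <- NULL
  out
}

smarts_counts <- function(sdfset, smarts) {
  as.numeric(ChemmineR::smartsSearchOB(sdfset, smarts,
                                        uniqueMatches = TRUE))
}

read_smarts_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smarts = vapply(parts, `[[`, "", 1L),
             name = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Shipped SMARTS definitions for ionizable groups and reactive alerts
#'
#' Both tables are plain-text, tab-separated `SMARTS<TAB>name` files under
#' `inst/extdata/` and can be replaced by any user table of the same
#' shape.  The ionizable set covers carboxylic, sulfonic and phosphonic
#' acids, acidic tetrazoles, basic aliphatic amines, amidines and
#' guanidines; the alert set covers acyl/sulfonyl halides, aldehydes,
#' Michael acceptors, strained three-membered heterocycles, isocyanates,
#' anhydrides, sp3 alkyl halides, nitroso and peroxide groups.
#'
#' @return Data frame with columns `smarts`, `name`.
#' @export
default_ionizable_smarts <- function() {
  read_smarts_file(system.file("extdata", "ionizable_groups.smarts",
                               package = "vstriage", mustWork = TRUE))
}

#' @rdname default_ionizable_smarts
#' @export
default_alert_smarts <- function() {
  read_smarts_file(system.file("extdata", "reactive_alerts.smarts",
                               package = "vstriage", mustWork = TRUE))
}

filter_outcome <- function(ids, failed) {
  data.frame(ligand_id = ids,
             passed = lengths(failed) == 0L,
             stringsAsFactors = FALSE,
             row.names = NULL) -> out
  out$failed_rules <- failed
  out
}

#' Amended Lipinski lead-likeness filter
#'
#' Lead-oriented variant of the rule of five: molecular weight restricted
#' to 250-600 Da (both bounds inclusive), cLogP within 1-5 (inclusive),
#' at most 5 hydrogen-bond donors, at most 10 acceptors, and strictly
#' fewer than 14 rotatable bonds.
#'
#' @param props Property table from [compute_properties()].
#' @param mw_range,clogp_range Inclusive `c(lo, hi)` bounds.
#' @param hbd_max,hba_max Inclusive upper bounds.
#' @param rot_max Strict upper bound on rotatable bonds.
#' @return Data frame with `ligand_id`, `passed` and a `failed_rules`
#'   list-column naming each violated bound (`mw_range`, `clogp_range`,
#'   `hbd`, `hba`, `rot_bonds`).
#' @export
lipinski_amended_filter <- function(props, mw_range = c(250, 600),
                                    clogp_range = c(1, 5), hbd_max = 5,
                                    hba_max = 10, rot_max = 14) {
  failed <- lapply(seq_len(nrow(props)), function(i) {
    f <- character(0)
    if (props$mw[i] < mw_range[1] || props$mw[i] > mw_range[2])
      f <- c(f, "mw_range")
    if (props$clogp[i] < clogp_range[1] || props$clogp[i] > clogp_range[2])
      f <- c(f, "clogp_range")
    if (props$hbd[i] > hbd_max) f <- c(f, "hbd")
    if (props$hba[i] > hba_max) f <- c(f, "hba")
    if (props$rot_bonds[i] >= rot_max) f <- c(f, "rot_bonds")
    f
  })
  filter_outcome(props$ligand_id, failed)
}

#' Default thresholds for the structural exclusion rules
#'
#' @return Named list: `max_phosphorus` (0: no phosphorus atoms),
#'   `max_ionizable` (2), `min_rings` (1), `max_chain_length` (6: runs of
#'   7 or more consecutive acyclic sp3 carbons fail), `max_fused_rings`
#'   (3: fused systems of 4 or more rings fail), `use_alerts` (TRUE).
#' @details The ionizable cap defaults to 2; a stricter cap of 1 is a
#'   recognised alternative reading of the rule and is one keystroke away.
#' @export
structural_rule_defaults <- function() {
  list(max_phosphorus = 0L, max_ionizable = 2L, min_rings = 1L,
       max_chain_length = 6L, max_fused_rings = 3L, use_alerts = TRUE)
}

#' Structural exclusion filter
#'
#' Applies the structural lead-likeness rules: no phosphorus atoms, a cap
#' on ionizable groups, at least one ring, no long aliphatic chains, no
#' large fused-ring systems, and no reactive/toxic alerts.
#'
#' @param props Property table from [compute_properties()].
#' @param rules Threshold list as from [structural_rule_defaults()];
#'   partial lists are completed with the defaults.
#' @return Outcome data frame as in [lipinski_amended_filter()]; rule
#'   names are `phosphorus`, `ionizable`, `no_ring`, `long_chain`,
#'   `fused_rings`, `reactive`.
#' @export
structural_filter <- function(props, rules = structural_rule_defaults()) {
  rules <- utils::modifyList(structural_rule_defaults(), rules)
  failed <- lapply(seq_len(nrow(props)), function(i) {
    f <- character(0)
    if (props$n_phosphorus[i] > rules$max_phosphorus)
      f <- c(f, "phosphorus")
    if (props$n_ionizable[i] > rules$max_ionizable)
      f <- c(f, "ionizable")
    if (props$n_rings[i] < rules$min_rings) f <- c(f, "no_ring")
    if (props$longest_acyclic_sp3_carbon_chain[i] > rules$max_chain_length)
      f <- c(f, "long_chain")
    if (props$max_fused_ring_system_size[i] > rules$max_fused_rings)
      f <- c(f, "fused_rings")
    if (isTRUE(rules$use_alerts) &&
        length(props$reactive_matches[[i]]))
      f <- c(f, "reactive")
    f
  })
  filter_outcome(props$ligand_id, failed)
}

#' Affinity-record quality filter
#'
#' Retains only measurements reported as a dissociation or inhibition
#' constant (Kd/Ki) with an exact relation; IC50 values and censored
#' relations (`<`, `>`, `~`, ...) are dropped.
#'
#' @param records Data frame with columns `ligand_id`, `measure_type`
#'   (`Kd`, `Ki`, `IC50`, `other`), `relation` and `value_molar`.
#' @return Logical vector, `TRUE` for records to keep.
#' @export
affinity_record_filter <- function(records) {
  need <- c("ligand_id", "measure_type", "relation", "value_molar")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("affinity records missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(records$value_molar <= 0))
    stop("affinity values must be positive", call. = FALSE)
  records$measure_type %in% c("Kd", "Ki") & records$relation == "="
}

#' Run the full lead-likeness curation funnel
#'
#' Applies, in order, the affinity-record filter (when affinity data are
#' supplied), the amended Lipinski filter and the structural filter, and
#' accounts for every rejection: counts entering and surviving each
#' stage plus per-rule rejection tallies.  The surviving set does not
#' depend on stage order; the staging only attributes rejections.
#'
#' @param molecules Property table from [compute_properties()], or a
#'   character vector of SMILES.
#' @param affinities Optional affinity-record table (see
#'   [affinity_record_filter()]); molecules without any retained
#'   affinity record are rejected at the affinity stage.
#' @param lipinski,structural Named lists of non-default thresholds
#'   passed on to the two filters.
#' @return A `filter_funnel` list: `stages` data frame (`stage`, `n_in`,
#'   `n_out`, `n_rejected`), `rule_tallies` named counts, `survivors`
#'   character vector of ligand ids, and per-molecule `outcomes`.
#' @export
apply_filter_pipeline <- function(molecules, affinities = NULL,
                                  lipinski = list(),
                                  structural = list()) {
  if (is.character(molecules)) molecules <- compute_properties(molecules)
  ids <- molecules$ligand_id
  stage_rows <- list()
  tallies <- integer(0)
  alive <- rep(TRUE, length(ids))

  if (!is.null(affinities) && nrow(molecules)) {
    unknown <- setdiff(affinities$ligand_id, ids)
    if (length(unknown))
      message("affinity records for ", length(unknown),
              " unknown ligand id(s) ignored")
    keep_rec <- affinity_record_filter(affinities)
    ok_ids <- unique(affinities$ligand_id[keep_rec])
    rej <- alive & !(ids %in% ok_ids)
    tallies["affinity_record"] <- sum(rej)
    stage_rows[[length(stage_rows) + 1L]] <-
      data.frame(stage = "affinity", n_in = sum(alive),
                 n_out = sum(alive & !rej), n_rejected = sum(rej))
    alive <- alive & !rej
  }

  lip <- do.call(lipinski_amended_filter,
                 c(list(molecules), lipinski))
  rej <- alive & !lip$passed
  for (r in unlist(lip$failed_rules[rej]))
    tallies[r] <- (if (r %in% names(tallies)) tallies[[r]] else 0L) + 1L
  stage_rows[[length(stage_rows) + 1L]] <-
    data.frame(stage = "lipinski", n_in = sum(alive),
               n_out = sum(alive & !rej), n_rejected = sum(rej))
  alive <- alive & !rej

  str_rules <- utils::modifyList(structural_rule_defaults(), structural)
  str_out <- structural_filter(molecules, str_rules)
  rej <- alive & !str_out$passed
  for (r in unlist(str_out$failed_rules[rej]))
    tallies[r] <- (if (r %in% names(tallies)) tallies[[r]] else 0L) + 1L
  stage_rows[[length(stage_rows) + 1L]] <-
    data.frame(stage = "structural", n_in = sum(alive),
               n_out = sum(alive & !rej), n_rejected = sum(rej))
  alive <- alive & !rej

  outcomes <- filter_outcome(ids, Map(c, lip$failed_rules,
                                      str_out$failed_rules))
  structure(list(stages = do.call(rbind, stage_rows),
                 rule_tallies = tallies,
                 survivors = ids[alive],
                 outcomes = outcomes),
            class = "filter_funnel")
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("Lead-likeness curation funnel\n")
  print(x$stages, row.names = FALSE)
  if (length(x$rule_tallies)) {
    cat("rejections by rule:\n")
    for (r in names(x$rule_tallies))
      cat(sprintf("  %-18s %d\n", r, x$rule_tallies[[r]]))
  }
  cat(length(x$survivors), "survivor(s)\n")
  invisible(x)
}
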