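props_fixture <- function() {
  fx <- fixture_molecules()
  compute_properties(fx$smiles, ids = fx$ligand_id)
}

test_that("computed properties match known molecules", {
  p <- compute_properties(c(ethanol = "CCO", benzene = "c1ccccc1",
                            octane = "CCCCCCCC"))
  expect_equal(p$mw[1], 46.07, tolerance = 1e-3)
  expect_equal(p$n_rings, c(0L, 1L, 0L))
  expect_equal(p$n_phosphorus, c(0L, 0L, 0L))
  expect_equal(p$longest_acyclic_sp3_carbon_chain[3], 8L)
  expect_error(compute_properties(c(bad = "not_a_smiles(((")),
               "unparseable.*bad")
})

test_that("each fixture molecule violates exactly its expected rule", {
  fx <- fixture_molecules()
  p <- props_fixture()
  lip <- lipinski_amended_filter(p)
  str <- structural_filter(p)
  all_failed <- Map(c, lip$failed_rules, str$failed_rules)
  for (i in seq_len(nrow(fx))) {
    expected <- fx$expected_failed_rule[i]
    if (is.na(expected) || expected == "") {
      expect_length(all_failed[[i]], 0)
    } else {
      expect_identical(all_failed[[i]], expected)
    }
  }
})

test_that("lipinski bounds are inclusive except the rotatable-bond cap", {
  p <- data.frame(ligand_id = c("lo", "hi", "rot14", "rot13"),
                  mw = c(250, 600, 400, 400), clogp = c(1, 5, 3, 3),
                  hbd = c(5, 0, 0, 0), hba = c(10, 0, 0, 0),
                  rot_bonds = c(0L, 0L, 14L, 13L),
                  stringsAsFactors = FALSE)
  out <- lipinski_amended_filter(p)
  expect_true(out$passed[1])  # all lower/upper bounds inclusive
  expect_true(out$passed[2])
  expect_false(out$passed[3])  # strictly fewer than 14
  expect_identical(out$failed_rules[[3]], "rot_bonds")
  expect_true(out$passed[4])
})

test_that("structural filter names every violated rule", {
  p <- compute_properties(c(decane = "CCCCCCCCCC"))
  out <- structural_filter(p)
  expect_setequal(out$failed_rules[[1]], c("no_ring", "long_chain"))
  acl <- compute_properties(c(acl = "CC(=O)Cl"))
  expect_true("reactive" %in% structural_filter(acl)$failed_rules[[1]])
  expect_equal(acl$reactive_matches[[1]], "acyl_halide")
})

test_that("passing is the conjunction of the individual rules", {
  p <- props_fixture()
  lip <- lipinski_amended_filter(p)
  str <- structural_filter(p)
  expect_equal(lip$passed, lengths(lip$failed_rules) == 0L)
  expect_equal(str$passed, lengths(str$failed_rules) == 0L)
  # removing a rule never shrinks the survivor set
  no_alerts <- structural_filter(p, list(use_alerts = FALSE))
  expect_true(all(str$passed <= no_alerts$passed))
  relaxed <- lipinski_amended_filter(p, mw_range = c(0, 1e4))
  expect_true(all(lip$passed <= relaxed$passed))
})

test_that("affinity records keep only exact Kd/Ki measurements", {
  rec <- data.frame(
    ligand_id = c("a", "b", "c", "d", "e"),
    measure_type = c("Ki", "IC50", "Kd", "Kd", "other"),
    relation = c("=", "=", "<", "=", "="),
    value_molar = c(1e-8, 1e-8, 1e-9, 1e-6, 1e-7),
    stringsAsFactors = FALSE)
  expect_equal(affinity_record_filter(rec),
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
  rec$value_molar[1] <- 0
  expect_error(affinity_record_filter(rec), "positive")
})

test_that("the funnel conserves counts and is idempotent", {
  fx <- fixture_molecules()
  p <- props_fixture()
  fun <- apply_filter_pipeline(p)
  # conservation at every stage
  expect_true(all(fun$stages$n_in ==
                    fun$stages$n_out + fun$stages$n_rejected))
  # stages chain: out of one = into the next
  expect_equal(fun$stages$n_in[-1],
               fun$stages$n_out[-nrow(fun$stages)])
  # survivors are exactly the engineered all-pass molecules
  expect_setequal(fun$survivors,
                  fx$ligand_id[fx$expected_failed_rule == "" |
                                 is.na(fx$expected_failed_rule)])
  # per-rule tallies match the engineered single violations
  expect_equal(sum(fun$rule_tallies),
               nrow(fx) - length(fun$survivors))
  # idempotence: filtering the survivors changes nothing
  again <- apply_filter_pipeline(p[p$ligand_id %in% fun$survivors, ])
  expect_setequal(again$survivors, fun$survivors)
  expect_equal(sum(again$rule_tallies), 0)
})

test_that("funnel handles empty and all-passing input", {
  p <- props_fixture()
  clean <- p[startsWith(p$ligand_id, "clean"), ]
  fun <- apply_filter_pipeline(clean)
  expect_equal(fun$survivors, clean$ligand_id)
  expect_equal(sum(fun$rule_tallies), 0)
  empty <- clean[0, ]
  fun0 <- apply_filter_pipeline(empty)
  expect_length(fun0$survivors, 0)
  expect_true(all(fun0$stages$n_in == 0))
})

test_that("the affinity stage drops ligands without retained records", {
  p <- props_fixture()
  clean <- p[startsWith(p$ligand_id, "clean"), ]
  aff <- data.frame(
    ligand_id = clean$ligand_id,
    measure_type = c("Kd", "IC50", "Ki"),
    relation = c("=", "=", "<"),
    value_molar = 1e-8, stringsAsFactors = FALSE)
  fun <- apply_filter_pipeline(clean, affinities = aff)
  expect_equal(fun$survivors, clean$ligand_id[1])
  expect_equal(unname(fun$rule_tallies["affinity_record"]), 2L)
})
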