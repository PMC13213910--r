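test_that("top-n selection ranks by free energy and counts actives", {
  # perfect separation
  tab <- screen_table(c(-12, -11, -10), c(-9, -8))
  sel <- select_top_n(tab, 2)
  expect_equal(sel$k_true, 2L)
  expect_equal(sel$tpr, 1.0)
  # inverted separation
  tab2 <- screen_table(c(-9, -8), c(-12, -11))
  expect_equal(select_top_n(tab2, 2)$k_true, 0L)
  # 15/20 fixture with exactly 6 actives in the top 7
  tab3 <- planted_k_table(6)[1:35, ]
  sel3 <- select_top_n(tab3, 7)
  expect_equal(sel3$k_true, 6L)
  expect_equal(sel3$tpr, 6 / 7)
})

test_that("score ties break by ligand id, independent of input order", {
  tab <- data.frame(target_id = "T",
                    ligand_id = c("z", "a", "m"),
                    role = c("decoy", "active", "decoy"),
                    dg_pred = c(-10, -10, -10),
                    stringsAsFactors = FALSE)
  sel1 <- select_top_n(tab, 2)
  sel2 <- select_top_n(tab[c(3, 1, 2), ], 2)
  expect_equal(sel1$selected_ids$ligand_id, c("a", "m"))
  expect_identical(sel1$selected_ids, sel2$selected_ids)
})

test_that("higher-is-better flag inverts the ranking", {
  tab <- screen_table(c(5, 4), c(1, 0))
  expect_equal(select_top_n(tab, 2, higher_is_better = TRUE)$k_true, 2L)
  expect_equal(select_top_n(tab, 2)$k_true, 0L)
})

test_that("selection rejects malformed requests", {
  tab <- screen_table(c(-12), c(-9))
  expect_error(select_top_n(tab, 5), "exceeds")
  two <- rbind(tab, screen_table(c(-12), c(-9), target = "U"))
  expect_error(select_top_n(two, 2), "one target")
})

test_that("pooling sums draws and hits with explicit population counts", {
  sels <- lapply(c(7, 7, 7, 7, 7, 6, 6, 6, 6), function(k)
    select_top_n(planted_k_table(k)[1:35, ], 7))
  pooled <- pool_targets(sels, 307, 135)
  expect_equal(pooled$n_drawn, 63L)
  expect_equal(pooled$k_observed, 59L)
  expect_equal(pooled$population_size, 307L)
  # identity pooling
  one <- pool_targets(sels[6], 35, 15)
  expect_equal(one$k_observed, 6L)
  expect_equal(one$n_drawn, 7L)
  # additivity
  two <- pool_targets(sels[c(1, 6)], 70, 30)
  expect_equal(two$k_observed, 13L)
  expect_equal(two$n_drawn, 14L)
})

test_that("tpr and random expectation give the benchmark percentages", {
  expect_equal(round(100 * tpr(59, 63)), 94)
  expect_equal(tpr(0, 63), 0)
  expect_equal(tpr(7, 7), 1)
  expect_error(tpr(1, 0), "undefined")
  expect_equal(round(100 * random_expectation(35, 15)), 43)
  expect_equal(random_expectation(100, 0), 0)
  expect_equal(random_expectation(307, 135), 135 / 307)
})

test_that("tail-matching extrapolation reproduces itself on identity", {
  set.seed(13)
  for (i in 1:20) {
    # keep the lower support bound at 0 (K + n <= N): at a positive
    # bound the tail is exactly 1 and the matching rule correctly
    # returns 0, not the bound itself
    N <- sample(20:400, 1)
    K <- sample(1:(N %/% 2), 1); n <- sample(1:(N %/% 2), 1)
    sup <- hypergeom_support(N, K, n)
    k <- sample(sup[1]:sup[2], 1)
    bench <- hypergeom_setup(N, K, n, k_observed = k)
    expect_equal(extrapolate_recovered_actives(bench, bench), k)
  }
})

test_that("extrapolated recovery is non-decreasing in the observed k", {
  scaled <- scaled_scenario(1000, 10, 100)
  k2 <- vapply(30:63, function(k)
    extrapolate_recovered_actives(
      hypergeom_setup(307, 135, 63, k_observed = k), scaled),
    integer(1))
  expect_true(all(diff(k2) >= 0))
})

test_that("minimum hit list for full recovery follows the tail rule", {
  # benchmark tail of 1 (k at the lower support bound): only exhaustive
  # selection guarantees recovery
  b1 <- hypergeom_setup(35, 15, 7, k_observed = 0)
  expect_equal(min_hitlist_full_recovery(b1, 1000, 10), 1000L)
  # nothing to recover
  b2 <- hypergeom_setup(307, 135, 63, k_observed = 59)
  expect_equal(min_hitlist_full_recovery(b2, 1000, 0), 0L)
  # frozen value from an exact rational-arithmetic oracle:
  # P(all 10 of 10 in n2 of 1000) first reaches the benchmark tail
  # P(X >= 59 | 307,135,63) = 1.418e-20 at n2 = 16
  expect_equal(min_hitlist_full_recovery(b2, 1000, 10), 16L)
  # output non-increasing as the benchmark tail decreases (k grows)
  n2 <- vapply(40:59, function(k)
    min_hitlist_full_recovery(
      hypergeom_setup(307, 135, 63, k_observed = k), 1000, 10),
    integer(1))
  expect_true(all(diff(n2) <= 0))
})

test_that("enrichment report composes selections and statistics", {
  tab <- planted_k_table(c(7, 7, 7, 7, 7, 6, 6, 6, 6))
  rep <- enrichment_report(tab, 7, scaled = scaled_scenario(1000, 10, 100),
                           population = 307, actives = 135)
  expect_equal(rep$pooled$k_observed, 59L)
  expect_equal(rep$pmf_at_k, hypergeom_pmf(59, 307, 135, 63))
  expect_equal(rep$upper_tail_at_k, hypergeom_upper_tail(59, 307, 135, 63))
  expect_equal(rep$max_pmf, max_pmf(307, 135, 63))
  expect_equal(rep$extrapolated_actives, 10L)
  # degenerate best case: perfect separation on all nine targets
  best <- enrichment_report(planted_k_table(rep(7, 9)), 7,
                            scaled = scaled_scenario(1000, 10, 100))
  expect_equal(best$pooled$k_observed, 63L)
  expect_equal(best$pooled_tpr, 1.0)
  expect_equal(best$extrapolated_actives, 10L)
})

test_that("targets with only unknown roles are excluded with a warning", {
  tab <- rbind(planted_k_table(5),
               data.frame(target_id = "TX",
                          ligand_id = paste0("x", 1:10),
                          role = "unknown", dg_pred = -10,
                          stringsAsFactors = FALSE))
  expect_warning(rep <- enrichment_report(tab, 7), "unknown")
  expect_equal(length(rep$per_target), 1L)
})
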