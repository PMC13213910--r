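make_pairs <- function(dg_exp, dg_calc, target = "T") {
  data.frame(target_id = target,
             ligand_id = sprintf("%s_l%03d", target, seq_along(dg_exp)),
             dg_exp = dg_exp, dg_calc = dg_calc,
             stringsAsFactors = FALSE)
}

test_that("Kd/Ki convert to dG via the standard-state relation", {
  expect_equal(kd_to_dg(1), 0)
  expect_equal(kd_to_dg(1, temperature = 310), 0)
  expect_equal(kd_to_dg(1e-9), 1.98720e-3 * 298 * log(1e-9),
               tolerance = 1e-12)
  expect_equal(kd_to_dg(1e-9), -12.27, tolerance = 1e-3)
  expect_equal(kd_to_dg(1e-6), -8.18, tolerance = 1e-2)
  expect_error(kd_to_dg(0), "positive")
  expect_error(kd_to_dg(-1e-9), "positive")
  expect_error(kd_to_dg(1e-9, temperature = -1), "positive")
})

test_that("correlation and error metrics follow their definitions", {
  p <- make_pairs(c(-12, -10, -8, -6), c(-11, -9, -7, -5))
  a <- dg_accuracy(p)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$spearman_rho, 1)
  expect_equal(a$rmse, 1)  # constant offset of 1 kcal/mol
  expect_equal(dg_accuracy(make_pairs(c(-9, -8, -7),
                                      c(-9, -8, -7)))$rmse, 0)
  # rank arithmetic: pairs (1,2),(2,1),(3,3) -> rho = 0.5
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(spearman_rho(c(1, 2, 3), c(2, 2, 2)), "variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
})

test_that("correlations are invariant under monotone transforms", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    expect_equal(pearson_r(x, y), pearson_r(2.5 * x + 3, 0.1 * y - 7),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), spearman_rho(exp(x), y^3),
                 tolerance = 1e-12)
    expect_gte(rmse(x, y), abs(mean(y - x)))
  }
})

test_that("intratarget reports gate on the minimum ligand count", {
  p <- rbind(make_pairs(rnorm(12, -9), rnorm(12, -9), "big"),
             make_pairs(rnorm(3, -9), rnorm(3, -9), "small"))
  res <- intratarget_correlations(p, min_ligands = 10)
  expect_named(res$reports, "big")
  expect_equal(res$skipped, "small")
  # all below threshold: empty map, not an error
  res2 <- intratarget_correlations(p, min_ligands = 50)
  expect_length(res2$reports, 0)
})

test_that("intratarget estimates recover a planted correlation", {
  rs <- vapply(1:20, function(s) {
    p <- simulate_accuracy_pairs(accuracy_sim_spec(
      n_targets = 1, ligands_per_target = 50, pearson_target = 0.6,
      seed = s))
    dg_accuracy(p)$pearson_r
  }, numeric(1))
  # mean of 20 estimates each with SE ~ (1-r^2)/sqrt(50) ~ 0.09
  expect_lt(abs(mean(rs) - 0.6), 3 * stats::sd(rs) / sqrt(20))
})

test_that("median splits partition deterministically with ties low", {
  p <- make_pairs(rnorm(6, -9), rnorm(6, -9))
  p$mw <- 1:6
  sp <- median_split_analysis(p, "mw")
  expect_equal(sp$low$n_pairs, 3)
  expect_equal(sp$high$n_pairs, 3)
  # constant descriptor: everything low, empty high with a warning
  p$mw <- 5
  expect_warning(sp2 <- median_split_analysis(p, "mw"), "degenerate")
  expect_equal(sp2$low$n_pairs, 6)
  expect_equal(sp2$high$n_pairs, 0)
  p$mw[2] <- NA
  expect_error(median_split_analysis(p, "mw"), "T_l002")
})

test_that("a lower-noise half shows lower RMSE under the median split", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    dg_exp <- runif(60, -14, -5)
    noise <- c(rnorm(30, 0, 2.0), rnorm(30, 0, 0.5))
    p <- make_pairs(dg_exp, dg_exp + noise)
    p$burial <- c(runif(30, 0, 1), runif(30, 2, 3))  # high half cleaner
    sp <- median_split_analysis(p, "burial")
    if (sp$high$rmse < sp$low$rmse) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("affinity half-split ranks by experimental dG", {
  # top two binders carry errors of +/-1, bottom two +/-2
  p <- make_pairs(c(-12, -11, -8, -7),
                  c(-12 + 1, -11 - 1, -8 + 2, -7 - 2))
  hs <- affinity_half_split_rmse(p)
  expect_equal(hs$rmse_top_half, 1.0)
  expect_equal(hs$rmse_bottom_half, 2.0)
  # identical errors: both halves equal |error|
  p2 <- make_pairs(c(-12, -10, -9, -6), c(-12, -10, -9, -6) + 0.7)
  hs2 <- affinity_half_split_rmse(p2)
  expect_equal(hs2$rmse_top_half, 0.7)
  expect_equal(hs2$rmse_bottom_half, 0.7)
  # odd count: middle pair joins the top half; halves partition input
  p3 <- make_pairs(rnorm(7, -9), rnorm(7, -9))
  hs3 <- affinity_half_split_rmse(p3)
  expect_equal(hs3$n_top, 4)
  expect_equal(hs3$n_bottom, 3)
})

test_that("pose divergence analysis applies strict thresholds", {
  n <- 55
  rmsd <- c(rep(1, 43), rep(5, 12))
  shift <- rep(0, n)
  shift[44:48] <- c(3, 2.5, 4, -3, 2.2)   # 5 significant among divergent
  shift[47] <- -3                          # one stronger affinity
  comp <- data.frame(ligand_id = sprintf("l%02d", 1:n),
                     rmsd_to_xray = rmsd,
                     dg_from_xray = -10,
                     dg_from_dock = -10 + shift,
                     stringsAsFactors = FALSE)
  res <- pose_divergence_analysis(comp)
  expect_equal(res$n_divergent, 12)
  expect_equal(res$n_significant, 5)
  expect_equal(res$n_weaker, 4)
  # boundary: a shift of exactly 2.0 is not significant
  comp$dg_from_dock[50] <- -8
  res2 <- pose_divergence_analysis(comp)
  expect_equal(res2$n_significant, 5)
  comp$rmsd_to_xray[1] <- -0.1
  expect_error(pose_divergence_analysis(comp), "negative")
})
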