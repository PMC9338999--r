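simple_pool <- function(kds, counts = NULL, nonspecific = NULL) {
  ids <- names(kds[[1]])
  genotypes <- stats::setNames(
    lapply(ids, function(i) c("H:1:" = "ALA")), ids)
  kd <- do.call(cbind, kds)
  rownames(kd) <- ids
  variant_pool(genotypes, kd, counts = counts, nonspecific = nonspecific)
}

test_that("affinity model has the exact closed-form behavior", {
  tab <- data.frame(position = c("H:1:", "H:2:"), aa = c("ASP", "GLN"),
                    ddg = c(log(2), -1), stringsAsFactors = FALSE)
  ## wild-type genotype (no substitutions) -> exactly kd_ref
  expect_identical(affinity_from_ddg(tab, c(), beta = 1, kd_ref = 5), 5)
  ## sum(ddg) = ln 2 / beta -> exactly 2 kd_ref
  expect_equal(affinity_from_ddg(tab, c("H:1:" = "ASP"), beta = 1,
                                 kd_ref = 5), 10, tolerance = 1e-12)
  ## monotone: adding a favorable substitution strictly lowers Kd
  k1 <- affinity_from_ddg(tab, c("H:1:" = "ASP"), kd_ref = 5)
  k2 <- affinity_from_ddg(tab, c("H:1:" = "ASP", "H:2:" = "GLN"),
                          kd_ref = 5)
  expect_lt(k2, k1)
  expect_error(affinity_from_ddg(tab, c("H:9:" = "TRP")), "H:9:")
})

test_that("zero target concentration captures nothing", {
  pool <- simple_pool(list(t1 = c(a = 1, b = 100)))
  cfg <- round_config("t1", target_concentration = 0)
  expect_error(run_round(pool, cfg), NA)
  surv <- abrescue:::.round_survival(pool, cfg)
  expect_equal(unname(surv), c(0, 0))
})

test_that("the high-affinity limit saturates capture and wash survival", {
  pool <- simple_pool(list(t1 = c(a = 1e-9, b = 100)))
  cfg <- round_config("t1", target_concentration = 10, washes = 10)
  surv <- abrescue:::.round_survival(pool, cfg)
  expect_equal(unname(surv[1]), cfg$capture_max, tolerance = 1e-6)
})

test_that("expected-value round matches the closed-form survival product", {
  kda <- 5; kdb <- 50; Tc <- 10; Kw <- 100; W <- 10
  pool <- simple_pool(list(t1 = c(a = kda, b = kdb)),
                      counts = c(a = 1000, b = 1000))
  cfg <- round_config("t1", target_concentration = Tc, washes = W,
                      wash_halfpoint = Kw, prepan_depletion = 0.9,
                      capture_max = 0.9, amplify_to = 1e6)
  out <- run_round(pool, cfg)
  ## hand-computed oracle: ratio of survival factors
  sa <- 0.9 * Tc / (Tc + kda) * (1 - kda / (kda + Kw))^W
  sb <- 0.9 * Tc / (Tc + kdb) * (1 - kdb / (kdb + Kw))^W
  expect_equal(unname(out$counts["a"] / out$counts["b"]), sa / sb,
               tolerance = 1e-9)
  expect_equal(sum(out$counts), 1e6)
})

test_that("prepan removes nonspecific binders at the configured rate", {
  pool <- simple_pool(list(t1 = c(a = 10, b = 10)),
                      nonspecific = c(a = FALSE, b = TRUE))
  cfg <- round_config("t1", prepan_depletion = 1)
  surv <- abrescue:::.round_survival(pool, cfg)
  expect_gt(surv[["a"]], 0)
  expect_identical(surv[["b"]], 0)
})

test_that("neutral selection leaves frequencies unchanged", {
  ## no washes, saturating target, uniform Kd: amplification only
  pool <- simple_pool(list(t1 = c(a = 10, b = 10, c = 10)),
                      counts = c(a = 500, b = 300, c = 200))
  cfg <- round_config("t1", target_concentration = 1e9, washes = 0,
                      prepan_depletion = 0)
  out <- run_round(pool, cfg)
  expect_equal(unname(out$counts / sum(out$counts)),
               unname(pool$counts / sum(pool$counts)), tolerance = 1e-12)
})

test_that("amplification conserves the pool size exactly", {
  truth <- build_panning_truth(seed = 5)
  cfg <- round_config("mutant", amplify_to = 123456)
  out_e <- run_round(truth$pool, cfg)
  expect_equal(sum(out_e$counts), 123456)
  out_s <- run_round(truth$pool, cfg, seed = 2, stochastic = TRUE)
  expect_identical(sum(out_s$counts), 123456)
  expect_error(round_config("mutant", amplify_to = 0), "positive")
})

test_that("lower Kd never loses ground within a round (expected mode)", {
  truth <- build_panning_truth(seed = 5)
  cfg <- round_config("mutant")
  out <- run_round(truth$pool, cfg)
  kd <- truth$pool$kd[, "mutant"]
  f0 <- truth$pool$counts / sum(truth$pool$counts)
  f1 <- out$counts / sum(out$counts)
  ids <- names(kd)[is.finite(kd)]
  for (i in ids) for (j in ids) {
    if (kd[i] < kd[j] && f0[j] > 0 && f1[j] > 0)
      expect_gte(f1[i] / f1[j], f0[i] / f0[j] - 1e-12)
  }
})

test_that("the default campaign elevates the dual binder to modal variant", {
  truth <- build_panning_truth(seed = 17, dual_binder_advantage = 10)
  sch <- selection_schedule(lapply(1:3, function(i) round_config("mutant")),
                            dual_screen_target = "wildtype")
  traj <- run_schedule(truth$pool, sch, seed = 17)
  rep <- enrichment_report(traj)
  expect_equal(rep$variant[1], truth$winner)
  ## closed-form check of the final expected frequency ranking
  expect_gt(rep[rep$variant == truth$winner, "dual_screen"], 0.5)
})

test_that("the dual screen removes single-target binders", {
  truth <- build_panning_truth(seed = 17)
  sch <- selection_schedule(lapply(1:3, function(i) round_config("mutant")),
                            dual_screen_target = "wildtype")
  traj <- run_schedule(truth$pool, sch, seed = 17)
  final <- traj$pools[[length(traj$pools)]]
  kd_wt <- truth$pool$kd[, "wildtype"]
  nonbinders <- names(kd_wt)[!is.finite(kd_wt)]
  expect_gt(length(nonbinders), 0)
  expect_true(all(final$counts[nonbinders] == 0))
  expect_gt(final$counts[truth$winner], 0)
})

test_that("trajectories are byte-reproducible for a fixed seed", {
  truth <- build_panning_truth(seed = 3)
  sch <- selection_schedule(lapply(1:3, function(i) round_config("mutant")),
                            dual_screen_target = "wildtype")
  for (mode in c(FALSE, TRUE)) {
    t1 <- run_schedule(truth$pool, sch, seed = 23, stochastic = mode)
    t2 <- run_schedule(truth$pool, sch, seed = 23, stochastic = mode)
    expect_identical(t1$frequencies, t2$frequencies)
  }
})

test_that("enrichment reports normalize and agree across modes", {
  truth <- build_panning_truth(seed = 29)
  pool <- truth$pool
  pool$counts[] <- 1e5   # deep pool so survival-stage noise is small too
  cfg <- round_config("mutant", amplify_to = 1e5)
  sch <- selection_schedule(list(cfg))
  te <- run_schedule(pool, sch, seed = 41)
  ts <- run_schedule(pool, sch, seed = 41, stochastic = TRUE)
  expect_true(all(abs(colSums(te$frequencies) - 1) < 1e-9))
  ## stochastic frequencies within 3 standard errors of expected, where the
  ## error budget covers both the binomial survival draw and the
  ## multinomial amplification draw
  fe <- te$frequencies[, 2]
  fs <- ts$frequencies[, 2]
  surv_total <- sum(pool$counts * abrescue:::.round_survival(pool, cfg))
  se <- sqrt(pmax(fe * (1 - fe), 1e-12) * (1 / 1e5 + 1 / surv_total))
  expect_true(all(abs(fs - fe) <= 3 * se + 1e-9))
  rep <- enrichment_report(te)
  expect_true(all(rep$rank >= 1))
  ## constant pool: all enrichment factors are 1
  pool <- simple_pool(list(t1 = c(a = 10, b = 10)),
                      counts = c(a = 500, b = 500))
  sch2 <- selection_schedule(list(round_config("t1", washes = 0,
                                               target_concentration = 1e9,
                                               prepan_depletion = 0)))
  rep2 <- enrichment_report(run_schedule(pool, sch2))
  expect_true(all(abs(rep2$enrichment - 1) < 1e-9))
})

test_that("library collapse is reported with the offending round", {
  pool <- simple_pool(list(t1 = c(a = Inf, b = Inf)))
  sch <- selection_schedule(list(round_config("t1")))
  expect_error(run_schedule(pool, sch), "collapsed at round 1")
})
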