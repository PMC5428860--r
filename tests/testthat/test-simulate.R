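test_that("QTN curve scaling hits the cumulative target exactly", {
  cfg <- sim_config("desk")
  q <- qtn_effect_curve(cfg)
  expect_equal(sum(q$grid), 175.21, tolerance = 1e-9)
  # constant shape over a 10-point grid with target 100 has height 10
  cfg2 <- sim_config("desk", t_min = 1, t_max = 10, qtn_base = c(1, 0, 0),
                     qtn_cumulative = 100)
  q2 <- qtn_effect_curve(cfg2)
  expect_equal(q2$grid, rep(10, 10), tolerance = 1e-9)
  # scaling invariance of the base shape
  cfg3 <- sim_config("desk", qtn_base = 2 * cfg$qtn_base)
  expect_equal(qtn_effect_curve(cfg3)$grid, q$grid, tolerance = 1e-12)
  expect_error(qtn_effect_curve(sim_config("desk", qtn_base = c(0, 1, 0),
                                           t_min = -10, t_max = 10)),
               "sums to zero")
})

test_that("population simulation produces the configured cohort", {
  cfg <- sim_config("desk")
  pop <- simulate_population(cfg, seed = 1)
  expect_equal(length(pop$phen_ids), 500L)
  expect_equal(nrow(pop$ped), 1250L)
  expect_equal(nrow(pop$snp_roles), 1002L)
  expect_equal(sum(pop$snp_roles$role == "background"), 1000L)
  # background genotypes are withheld from the analysis genotype matrix
  expect_setequal(pop$geno$snp_ids, c("qtn", "null"))
  expect_true(all(pop$geno$values %in% 0:2))
  # parents precede offspring and sires/dams have the right sex
  sires <- unique(pop$ped$sire[!is.na(pop$ped$sire)])
  expect_true(all(pop$sex[sires] == "M"))
})

test_that("paper profile yields the full-scale cohort", {
  cfg <- sim_config("paper")
  pop <- simulate_population(cfg, seed = 5)
  expect_equal(length(pop$phen_ids), 2000L)
  expect_equal(nrow(pop$ped), 1000L + 4L * 1000L)
})

test_that("cohort genotype frequencies track founder frequencies when drift is weak", {
  cfg <- tiny_sim_config(historical_size = 2000L,
                         n_historical_generations = 5L)
  devs <- hwe_p <- hist_dev <- numeric(5)
  for (s in 1:5) {
    pop <- simulate_population(cfg, seed = 40 + s)
    # historical drift at N = 2000 over 5 generations is negligible
    hist_dev[s] <- mean(abs(pop$snp_roles$drifted_freq -
                              pop$snp_roles$founder_freq))
    f0 <- pop$snp_roles$founder_freq[2]
    x <- pop$geno$values["null", ]
    # the cohort adds founder sampling and recent-pedigree drift
    devs[s] <- abs(mean(x) / 2 - f0)
    counts <- tabulate(x + 1, 3)
    p <- mean(x) / 2
    expected <- length(x) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    hwe_p[s] <- suppressWarnings(chisq.test(counts, p = expected / sum(expected))$p.value)
  }
  expect_lt(mean(hist_dev), 0.015)
  expect_lt(mean(devs), 0.15)
  expect_gt(sum(hwe_p > 0.01), 3)
})

test_that("phenotype variance partition matches the calibration targets", {
  cfg <- sim_config("desk", qtn_h2 = 0.01)
  sim <- simulate_longitudinal(cfg, 11)
  tr <- sim$truth
  # brute-force recomputation from the stored component matrices
  tv <- function(M) mean(apply(M, 2, var))
  Y <- tr$qtn_component + tr$poly + tr$pe + tr$resid +
    matrix(tr$mu, nrow(tr$poly), ncol(tr$poly), byrow = TRUE)
  expect_equal(tv(tr$qtn_component) / tr$V_P, cfg$qtn_h2, tolerance = 0.05 * cfg$qtn_h2)
  expect_equal(tv(tr$poly) / tr$V_P, cfg$trait_h2 - cfg$qtn_h2,
               tolerance = 0.05 * cfg$trait_h2)
  expect_equal(tv(tr$pe) / tr$V_P, cfg$pe_proportion,
               tolerance = 0.05 * cfg$pe_proportion)
  expect_equal(unname(tr$partition["h2_total"]),
               tv(tr$qtn_component + tr$poly) / tv(Y), tolerance = 1e-10)
})

test_that("zero QTN heritability decouples phenotype from the QTN genotype", {
  cfg <- tiny_sim_config(qtn_h2 = 0)
  sim <- simulate_longitudinal(cfg, 13)
  x <- sim$pop$geno$values["qtn", ]
  ybar <- tapply(sim$data$value, factor(sim$data$id, levels = sim$pop$phen_ids),
                 mean)
  expect_gt(summary(lm(ybar ~ x))$coefficients[2, 4], 0.01)
})

test_that("identical configuration and seed reproduce byte-identical output", {
  cfg <- tiny_sim_config()
  s1 <- simulate_longitudinal(cfg, 99)
  s2 <- simulate_longitudinal(cfg, 99)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$pop$geno$values, s2$pop$geno$values)
  expect_identical(s1$truth$partition, s2$truth$partition)
  s3 <- simulate_longitudinal(cfg, 100)
  expect_false(identical(s1$data$value, s3$data$value))
})

test_that("a smoke-scale experiment emits a complete summary", {
  cfg <- tiny_sim_config(qtn_h2 = 0.02)
  ex <- run_experiment(cfg, n_reps = 3, methods = c("fgwas-c", "residual"),
                       alphas = c(0.01, 0.05), base_seed = 71)
  expect_s3_class(ex, "gwas_experiment")
  expect_equal(nrow(ex$summary), 4L)        # 2 methods x 2 alphas
  expect_setequal(unique(ex$summary$method), c("fgwas-c", "residual"))
  expect_true(all(is.finite(ex$estimates$mean)))
  expect_equal(ex$n_failed, 0L)
  expect_equal(nrow(ex$details), 6L)
})
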