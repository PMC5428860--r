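test_that("incremental Wald statistic matches chi-square tables", {
  w0 <- wald_incremental(10, 10, 2, 3)
  expect_equal(w0$W, 0)
  expect_equal(w0$p, 1)
  w1 <- wald_incremental(3.841459, 0, 1, 1)
  expect_equal(w1$p, 0.05, tolerance = 1e-5)
  w2 <- wald_incremental(10, 0, 1, 4)
  expect_equal(w2$p, 0.040428, tolerance = 1e-5)
  expect_error(wald_incremental(1, 0, 1, 0), "positive integer")
  expect_error(wald_incremental(0, 10, 1, 2), "numerical slack")
})

test_that("cumulative effects equal brute-force grid summation", {
  dom <- time_domain(5, 50)
  Tn <- length(dom$grid)
  # constant curve of height h: only the order-0 coefficient
  h <- 2.5
  expect_equal(cumulative_effect(c(h / sqrt(1 / 2)), dom), h * Tn,
               tolerance = 1e-10)
  # odd basis component sums to ~0 over the symmetric grid
  expect_equal(cumulative_effect(c(0, 1), dom), 0, tolerance = 1e-9)
  set.seed(2)
  cf <- rnorm(4)
  brute <- sum(vapply(dom$grid, function(t) {
    sum(legendre_matrix(3, t, dom) * cf)
  }, numeric(1)))
  expect_equal(cumulative_effect(cf, dom), brute, tolerance = 1e-9)
})

test_that("fGWAS-F decomposition follows the genetic-effect formulas", {
  dom <- time_domain(5, 50)
  cc <- 1.7
  const <- function(v) c(v / sqrt(1 / 2), 0)
  dec <- decompose_fgwas_f(list(lambda_AA = const(cc), lambda_Aa = const(0.3),
                                lambda_aa = const(-cc)), 0.3, dom)
  expect_equal(dec$add, rep(cc, length(dom$grid)), tolerance = 1e-10)
  # p = q = 0.5 kills the dominance term in the variance
  dec2 <- decompose_fgwas_f(list(lambda_AA = const(1), lambda_Aa = const(5),
                                 lambda_aa = const(-1)), 0.5, dom)
  expect_equal(dec2$sigma2_a, rep(0.5, length(dom$grid)), tolerance = 1e-10)
  # literal re-substitution oracle on random curves
  set.seed(5)
  lam <- list(lambda_AA = rnorm(3), lambda_Aa = rnorm(3), lambda_aa = rnorm(3))
  p <- 0.37
  dec3 <- decompose_fgwas_f(lam, p, dom)
  Phi <- legendre_matrix(2, dom$grid, dom)
  AA <- drop(Phi %*% lam$lambda_AA); Aa <- drop(Phi %*% lam$lambda_Aa)
  aa <- drop(Phi %*% lam$lambda_aa)
  add <- (AA - aa) / 2; dom_t <- Aa - add
  expect_equal(dec3$add, add, tolerance = 1e-12)
  expect_equal(dec3$dom, dom_t, tolerance = 1e-12)
  expect_equal(dec3$sigma2_a, 2 * p * (1 - p) * (add + dom_t * (1 - 2 * p))^2,
               tolerance = 1e-12)
  # midpoint convention differs unless the reference curve is zero
  dec4 <- decompose_fgwas_f(lam, p, dom, convention = "midpoint")
  expect_equal(dec4$dom, Aa - (AA + aa) / 2, tolerance = 1e-12)
  expect_error(decompose_fgwas_f(lam, 1, dom), "strictly in")
})

test_that("fGWAS-C equals the dense mixed-model oracle and is scale invariant", {
  set.seed(8)
  ped <- toy_pedigree()
  ids <- as.character(3:10)
  dat <- toy_balanced_data(ids)
  dom <- time_domain(5, 50)
  spec <- model_spec(0, 0, 0)
  vc <- toy_vc(1, 1)
  x <- c(0, 1, 2, 1, 0, 2, 1, 0); names(x) <- ids
  gm <- genotype_matrix(matrix(x, 1, dimnames = list("s1", ids)))
  fit <- list(engine = longgwas:::.make_rotated_engine(dat, spec, dom, ped),
              vc = vc, spec = spec, domain = dom, data = dat, ped = ped)
  class(fit) <- "rrm_fit"
  sc <- scan_fgwas_c(fit = fit, geno = gm)
  # dense oracle: squared effect over its sampling variance
  extra <- x[match(dat$id, ids)] * legendre_matrix(0, dat$time, dom)
  o_full <- dense_blup_oracle(dat, spec, dom, ped, vc, extra = extra)
  o_red <- dense_blup_oracle(dat, spec, dom, ped, vc)
  W_oracle <- (o_full$rss - o_red$rss) / vc$sigma_e2
  expect_equal(sc$W, W_oracle, tolerance = 1e-6)
  # scale invariance: x/2 on the dosage scale gives the identical statistic
  gm2 <- genotype_matrix(matrix(x / 2, 1, dimnames = list("s1", ids)))
  expect_equal(scan_fgwas_c(fit = fit, geno = gm2)$W, sc$W, tolerance = 1e-8)
})

test_that("monomorphic SNPs are flagged untestable; dosages give finite tests", {
  set.seed(13)
  cfg <- tiny_sim_config()
  sim <- simulate_longitudinal(cfg, 7)
  fit <- reml_fit(sim$data, model_spec(1, 1, 1), sim$pop$ped,
                  domain = sim$domain, solver = "none")
  ids <- sim$pop$phen_ids
  vals <- rbind(rep(2, length(ids)),
                runif(length(ids), 0, 2),
                sim$pop$geno$values["qtn", ])
  dimnames(vals) <- list(c("mono", "dose", "qtn"), ids)
  sc <- scan_fgwas_c(fit = fit, geno = genotype_matrix(vals))
  expect_false(sc$tested[sc$snp == "mono"])
  expect_equal(sc$W[sc$snp == "mono"], 0)
  expect_equal(sc$p[sc$snp == "mono"], 1)
  expect_true(sc$tested[sc$snp == "dose"])
  expect_true(is.finite(sc$W[sc$snp == "dose"]))
  # the factor model refuses dosages outright
  expect_error(scan_fgwas_f(fit = fit, geno = genotype_matrix(vals)),
               "dosages")
})

test_that("fGWAS-F counts classes into the degrees of freedom", {
  set.seed(14)
  cfg <- tiny_sim_config()
  sim <- simulate_longitudinal(cfg, 9)
  fit <- reml_fit(sim$data, model_spec(1, 1, 1), sim$pop$ped,
                  domain = sim$domain, solver = "none")
  ids <- sim$pop$phen_ids
  n <- length(ids)
  vals <- rbind(sample(c(0, 2), n, replace = TRUE),          # no heterozygotes
                sample(0:2, n, replace = TRUE))
  dimnames(vals) <- list(c("twoclass", "threeclass"), ids)
  sf <- scan_fgwas_f(fit = fit, geno = genotype_matrix(vals))
  nf1 <- fit$spec$nf + 1L
  expect_equal(sf$df[sf$snp == "twoclass"], nf1)
  expect_equal(sf$df[sf$snp == "threeclass"], 2L * nf1)
  expect_true(all(sf$W >= 0))
  expect_true(all(sf$p > 0 & sf$p <= 1))
})

test_that("fGWAS-C and fGWAS-F agree strongly on the same scan", {
  set.seed(15)
  cfg <- tiny_sim_config(n_snps = 142L, qtn_h2 = 0.02)
  # a small cohort can leave one null marker just under the MAF floor
  sim <- suppressWarnings(simulate_longitudinal(cfg, 21))
  fit <- reml_fit(sim$data, model_spec(2, 2, 2), sim$pop$ped,
                  domain = sim$domain, solver = "none")
  sc <- scan_fgwas_c(fit = fit, geno = sim$pop$geno)
  sf <- scan_fgwas_f(fit = fit, geno = sim$pop$geno)
  keep <- sc$tested & sf$tested
  expect_gt(cor(-log10(sc$p[keep]), -log10(sf$p[keep])), 0.8)
})

test_that("purely additive QTN yields near-zero cumulative dominance", {
  cfg <- sim_config("desk", qtn_h2 = 0.02, n_snps = 102L, n_background = 100L)
  doms <- adds <- numeric(8)
  for (r in 1:8) {
    sim <- simulate_longitudinal(cfg, 300 + r)
    fit <- reml_fit(sim$data, model_spec(2, 2, 2), sim$pop$ped,
                    domain = sim$domain, solver = "none")
    sf <- scan_fgwas_f(fit = fit, geno = sim$pop$geno)
    doms[r] <- sf$cumulative_dom[sf$snp == "qtn"]
    adds[r] <- sf$cumulative_add[sf$snp == "qtn"]
  }
  # additive estimates center on the truth; dominance centers on zero
  expect_lt(abs(mean(doms)), 0.45 * cfg$qtn_cumulative)
  expect_gt(mean(adds), 0.5 * cfg$qtn_cumulative)
})

test_that("per-SNP REML agrees with the plug-in strategy on a small instance", {
  set.seed(17)
  cfg <- tiny_sim_config(n_founder_m = 12L, n_founder_f = 12L, n_sires = 4L,
                         n_dams = 12L, n_snps = 32L, n_background = 30L,
                         n_records = 5L, qtn_h2 = 0.05)
  sim <- simulate_longitudinal(cfg, 2)
  spec <- model_spec(1, 1, 1)
  fit <- reml_fit(sim$data, spec, sim$pop$ped, domain = sim$domain,
                  solver = "none")
  plug <- scan_fgwas_c(fit = fit, geno = sim$pop$geno)
  per <- scan_fgwas_c(fit = fit, geno = sim$pop$geno, per_snp_reml = TRUE)
  expect_true(all(is.finite(per$W)))
  expect_equal(per$W, plug$W, tolerance = 0.5)
})
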