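test_that("design matrices have the random regression structure", {
  dom <- time_domain(5, 50)
  ped <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA))
  d1 <- longitudinal_data("a", 20, 3.2)
  des <- build_design(d1, model_spec(0, 0, 0), dom,
                      pedigree("a", NA, NA))
  expect_equal(dim(des$X), c(1L, 1L))
  expect_equal(unname(des$X[1, 1]), sqrt(1 / 2))
  expect_equal(as.matrix(des$Q)[1, 1], sqrt(1 / 2))
  expect_equal(as.matrix(des$Z)[1, 1], sqrt(1 / 2))

  d2 <- longitudinal_data(c("a", "a", "b"), c(10, 30, 20), c(1, 2, 3))
  des2 <- build_design(d2, model_spec(2, 1, 1), dom, ped)
  # Q block-diagonal: records of a have zeros in b's block and vice versa
  Qd <- as.matrix(des2$Q)
  expect_true(all(Qd[1:2, 3:4] == 0))
  expect_true(all(Qd[3, 1:2] == 0))
  expect_equal(des2$X, legendre_matrix(2, d2$time, dom), ignore_attr = TRUE)
})

test_that("solve_mme equals the dense GLS/BLUP oracle on an unbalanced instance", {
  set.seed(42)
  ped <- toy_pedigree()
  ids <- as.character(3:8)
  mi <- c(3, 4, 2, 5, 3, 4)
  id <- rep(ids, mi)
  tt <- unlist(lapply(mi, function(k) sort(sample(5:50, k))))
  dat <- longitudinal_data(id, tt, rnorm(length(id), 10, 2))
  dom <- time_domain(5, 50)
  spec <- model_spec(1, 1, 1)
  vc <- toy_vc(2, 2)
  des <- build_design(dat, spec, dom, ped)
  ai <- a_inverse(ped)
  fit <- solve_mme(des, vc, ai, a_logdet = attr(ai, "logdet_A"))
  oracle <- dense_blup_oracle(dat, spec, dom, ped, vc)
  expect_equal(unname(fit$b_hat), unname(oracle$b), tolerance = 1e-8)
  expect_equal(as.vector(t(fit$a_hat)), oracle$u, tolerance = 1e-8)
  expect_equal(as.vector(t(fit$p_hat)), oracle$pe, tolerance = 1e-8)
  expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
  expect_equal(fit$logL, oracle$logL, tolerance = 1e-6)
  # first-order conditions: residuals orthogonal to X in the V metric
  expect_equal(fit$residuals, dat$value - fit$fitted, tolerance = 1e-10)
})

test_that("with huge prior variances the MME solutions approach OLS", {
  set.seed(9)
  ped <- pedigree(c("a", "b", "c"), rep(NA, 3), rep(NA, 3))
  dat <- toy_balanced_data(c("a", "b", "c"), times = c(5, 20, 35, 50))
  dom <- time_domain(5, 50)
  spec <- model_spec(1, 0, 0)
  vc_big <- variance_components(diag(1e8, 1), diag(1e8, 1), 1)
  des <- build_design(dat, spec, dom, ped)
  ai <- a_inverse(ped)
  fit <- solve_mme(des, vc_big, ai)
  # shrinkage vanishes: equivalent to OLS with one intercept per individual
  ols <- lm(dat$value ~ 0 + des$X + factor(dat$id))
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-4)
  expect_error(
    solve_mme(build_design(longitudinal_data(c("a", "a"), c(5, 10), c(1, 2)),
                           model_spec(0, 0, 0), dom, ped),
              toy_vc(1, 1),
              a_inverse(ped), extra = matrix(sqrt(1 / 2), 2, 1)),
    "rank deficient")
})

test_that("rotated-engine restricted likelihood equals the MME determinant identity", {
  set.seed(7)
  ped <- toy_pedigree()
  ids <- as.character(3:10)
  dat <- toy_balanced_data(ids)
  dom <- time_domain(5, 50)
  for (spec in list(model_spec(1, 1, 1), model_spec(2, 2, 1))) {
    vc <- toy_vc(spec$nr1 + 1, spec$nr2 + 1)
    des <- build_design(dat, spec, dom, ped)
    ai <- a_inverse(ped)
    fit <- solve_mme(des, vc, ai, a_logdet = attr(ai, "logdet_A"))
    eng <- longgwas:::.make_rotated_engine(dat, spec, dom, ped)
    expect_equal(-0.5 * longgwas:::.engine_neg2logLR(eng, vc), fit$logL,
                 tolerance = 1e-8)
  }
})

test_that("analytic REML gradient matches central differences", {
  set.seed(3)
  ped <- toy_pedigree()
  dat <- toy_balanced_data(as.character(3:10))
  dom <- time_domain(5, 50)
  spec <- model_spec(2, 1, 1)
  eng <- longgwas:::.make_rotated_engine(dat, spec, dom, ped)
  th <- c(longgwas:::.mat_to_theta(matrix(c(2, .3, .3, 1), 2)),
          longgwas:::.mat_to_theta(matrix(c(1.5, -.2, -.2, .8), 2)),
          log(1.3))
  fg <- longgwas:::.engine_reml_fg(eng, longgwas:::.theta_to_vc(th, 2, 2))
  num <- vapply(seq_along(th), function(j) {
    h <- 1e-6
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (longgwas:::.engine_neg2logLR(eng, longgwas:::.theta_to_vc(tp, 2, 2)) -
       longgwas:::.engine_neg2logLR(eng, longgwas:::.theta_to_vc(tm, 2, 2))) / (2 * h)
  }, numeric(1))
  expect_equal(fg$grad, num, tolerance = 1e-5)
})

test_that("REML on pure-noise data recovers unit residual variance and no structure", {
  set.seed(11)
  ids <- as.character(1:200)
  dat <- longitudinal_data(rep(ids, each = 10),
                           rep(seq(5, 50, 5), 200),
                           rnorm(2000))
  fit <- reml_fit(dat, model_spec(0, 0, 0), solver = "none")
  expect_equal(fit$vc$sigma_e2, 1, tolerance = 0.1)
  expect_lt(fit$vc$G[1, 1], 0.05)
  expect_lt(fit$vc$P[1, 1], 0.05)
})

test_that("REML recovers simulated covariance components (recovery harness)", {
  G0 <- matrix(c(3, 0.5, 0.5, 1), 2)
  P0 <- matrix(c(2, -0.3, -0.3, 0.8), 2)
  se0 <- 1.5
  times <- seq(5, 50, length.out = 8)
  dom <- time_domain(5, 50)
  nfam <- 40
  ests <- t(vapply(1:5, function(sd_i) {
    set.seed(100 + sd_i)
    # 40 sire families of 4 half sibs
    sires <- paste0("s", 1:nfam)
    kids <- paste0("k", 1:(4 * nfam))
    ped <- pedigree(c(sires, kids), c(rep(NA, nfam), rep(sires, each = 4)),
                    rep(NA, nfam + 4 * nfam))
    A <- numerator_relationship_matrix(ped)
    idx <- match(kids, ped$id)
    La <- t(chol(kronecker(A[idx, idx], G0)))
    a_coef <- matrix(La %*% rnorm(2 * length(kids)), ncol = 2, byrow = TRUE)
    p_coef <- matrix(rnorm(2 * length(kids)), ncol = 2) %*% chol(P0)
    Phi <- legendre_matrix(1, times, dom)
    Y <- (a_coef + p_coef) %*% t(Phi) +
      matrix(rnorm(length(kids) * 8, sd = sqrt(se0)), ncol = 8) + 10
    dat <- longitudinal_data(rep(kids, each = 8), rep(times, length(kids)),
                             as.vector(t(Y)))
    fit <- reml_fit(dat, model_spec(1, 1, 1), ped, domain = dom,
                    solver = "none")
    c(fit$vc$G[1, 1], fit$vc$G[2, 2], fit$vc$P[1, 1], fit$vc$sigma_e2)
  }, numeric(4)))
  truth <- c(G0[1, 1], G0[2, 2], P0[1, 1], se0)
  means <- colMeans(ests)
  ses <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(means - truth) < 3 * ses + 0.15 * truth))
})

test_that("optimized restricted likelihood is no worse than at the start", {
  set.seed(21)
  ped <- toy_pedigree()
  dat <- toy_balanced_data(as.character(3:10))
  spec <- model_spec(1, 1, 1)
  dom <- time_domain(5, 50)
  s <- sd(dat$value)
  init <- variance_components(diag(0.5 / 2, 2) * s^2, diag(0.5 / 2, 2) * s^2,
                              0.5 * s^2)
  fit <- reml_fit(dat, spec, ped, domain = dom, solver = "none")
  eng <- longgwas:::.make_rotated_engine(dat, spec, dom, ped)
  logL_init <- -0.5 * longgwas:::.engine_neg2logLR(eng, init)
  expect_gte(fit$logL, logL_init - 1e-6)
})

test_that("information criteria follow the REML parameter-count convention", {
  fake <- list(logL = -100, spec = model_spec(1, 1, 1), n_records = 1000)
  # k = 3 + 3 + 1 = 7
  ic <- information_criteria(fake)
  expect_equal(unname(ic["aic"]), 2 * 100 + 2 * 7)
  expect_equal(unname(ic["bic"]), 2 * 100 + 7 * log(1000))
  expect_equal(longgwas:::.n_vc_par(model_spec(2, 3, 5)), 10 + 21 + 1)
  # worked mini-example: logL=-100, k=4 would give aic 208 / bic ~227.63
  expect_equal(-2 * (-100) + 2 * 4, 208)
  expect_equal(-2 * (-100) + 4 * log(1000), 227.6310, tolerance = 1e-4)
})

test_that("increasing the genetic order never decreases the likelihood", {
  set.seed(31)
  cfg <- tiny_sim_config()
  sim <- simulate_longitudinal(cfg, 5)
  f0 <- reml_fit(sim$data, model_spec(2, 0, 1), sim$pop$ped,
                 domain = sim$domain, solver = "none")
  f1 <- reml_fit(sim$data, model_spec(2, 1, 1), sim$pop$ped,
                 domain = sim$domain, solver = "none")
  f2 <- reml_fit(sim$data, model_spec(2, 2, 1), sim$pop$ped,
                 domain = sim$domain, solver = "none")
  expect_gte(f1$logL, f0$logL - 1e-4)
  expect_gte(f2$logL, f1$logL - 1e-4)
})

test_that("order selection returns the BIC winner with parsimony tie-break", {
  set.seed(41)
  cfg <- tiny_sim_config(qtn_h2 = 0.02)
  sim <- simulate_longitudinal(cfg, 3)
  one <- select_orders(sim$data, sim$pop$ped, list(model_spec(1, 1, 1)),
                       domain = sim$domain)
  expect_equal(one$nr1, 1L)
  grid <- list(model_spec(2, 0, 0), model_spec(2, 1, 1), model_spec(2, 2, 2))
  best <- select_orders(sim$data, sim$pop$ped, grid, domain = sim$domain)
  tab <- attr(best, "criteria")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$bic[match(TRUE, tab$nr1 == best$nr1)], min(tab$bic))
  # simulated genetic curves are quadratic; selection should keep order >= 1
  expect_gte(best$nr1, 1L)
})
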