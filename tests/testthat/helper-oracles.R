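# Shared fixtures and independent oracles for the test suite.

# Dense GLS/BLUP oracle: forms the full phenotypic covariance V explicitly
# and computes BLUE/BLUP, y'Py, R(model) and the restricted log-likelihood
# from textbook formulas. Only usable at desk scale (n <= a few dozen).
dense_blup_oracle <- function(data, spec, domain, ped, vc, extra = NULL) {
  des <- build_design(data, spec, domain, ped)
  X <- des$X
  if (!is.null(extra)) X <- cbind(X, extra)
  Qd <- as.matrix(des$Q); Zd <- as.matrix(des$Z)
  A <- numerator_relationship_matrix(ped)
  n_phen <- length(des$phen_ids)
  V <- Qd %*% kronecker(A, vc$G) %*% t(Qd) +
    Zd %*% kronecker(diag(n_phen), vc$P) %*% t(Zd) +
    diag(vc$sigma_e2, nrow(X))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% data$value)
  r <- data$value - X %*% b
  u <- kronecker(A, vc$G) %*% t(Qd) %*% Vi %*% r
  pe <- kronecker(diag(n_phen), vc$P) %*% t(Zd) %*% Vi %*% r
  ypy <- drop(t(data$value) %*% Vi %*% r)
  m <- length(data$value); p <- ncol(X)
  logL <- -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                    ypy + (m - p) * log(2 * pi))
  list(b = drop(b), u = drop(u), pe = drop(pe), ypy = ypy,
       rss = sum(data$value^2) - vc$sigma_e2 * ypy,
       logL = as.numeric(logL))
}

# A 10-individual pedigree with founders, full sibs and an inbred mating.
toy_pedigree <- function() {
  pedigree(as.character(1:10),
           sire = c(NA, NA, NA, "1", "1", "4", NA, "4", "6", "6"),
           dam  = c(NA, NA, NA, "2", "3", "5", "2", "7", "5", "7"))
}

# Balanced longitudinal records for the given individuals.
toy_balanced_data <- function(ids, times = c(5, 15, 25, 35, 45, 50),
                              sd = 2, mean = 10) {
  longitudinal_data(rep(ids, each = length(times)),
                    rep(times, length(ids)),
                    rnorm(length(ids) * length(times), mean, sd))
}

toy_vc <- function(na = 2, np = 2, se2 = 1.3) {
  variance_components(diag(seq(2, 1, length.out = na), nrow = na) + 0.2,
                      diag(seq(1.5, 0.7, length.out = np), nrow = np) + 0.1,
                      se2)
}

# Rebuild a sim_config with some fields overridden (re-validates).
sim_config_override <- function(cfg, ...) {
  args <- utils::modifyList(unclass(cfg)[setdiff(names(cfg), "profile")],
                            list(...))
  do.call(sim_config, c(list(profile = cfg$profile), args))
}

# Small, fast simulation settings used across tests.
tiny_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_founder_m = 40L, n_founder_f = 40L, n_sires = 10L,
         n_dams = 40L, n_snps = 102L, n_background = 100L),
    list(...))
  do.call(sim_config, c(list(profile = "desk"), args))
}
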