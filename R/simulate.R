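# Seeded forward-in-time simulator of pedigreed longitudinal phenotypes.
#
# Design emulated: a base population drifts for a number of discrete
# Wright-Fisher generations (creating realistic allele frequencies and
# relatedness), a recent expansion founds the pedigree, and four recent
# generations of 'n_sires' males each mated to the previous generation's
# females produce the phenotyped cohort of females. Among the simulated
# SNPs, one carries a time-varied additive QTN effect with a fixed
# cumulative value over the recording grid, one is a null marker, and the
# remaining SNPs carry random-regression polygenic effects whose genotypes
# are withheld from the analysis files.

#' Simulation configuration
#'
#' @param profile `"paper"` (2,000 phenotyped females: 50 sires x 500 dams
#'   over 4 generations) or `"desk"` (500 phenotyped females: 25 sires x
#'   125 dams), both with 10 records per female on days 5..305.
#' @param ... overrides of any field below.
#' @return An object of class `"sim_config"`. Fields: `n_founder_m`,
#'   `n_founder_f`, `n_sires`, `n_dams`, `n_generations`,
#'   `n_historical_generations`, `historical_size`, `n_snps`,
#'   `n_background`, `n_records`, `t_min`, `t_max`, `trait_h2`,
#'   `pe_proportion`, `qtn_h2`, `qtn_cumulative`, `qtn_freq`,
#'   `phenotypic_var` (absolute scale used only when `qtn_h2 = 0`),
#'   `mu_coef` (population mean as a natural polynomial in t),
#'   `qtn_base` (unscaled Legendre coefficients of the QTN curve shape),
#'   `bg_coef_scales`, `pe_coef_scales` (relative variances of the
#'   order-0..2 random coefficients), `maf_floor`, `max_retries`.
#' @export
sim_config <- function(profile = c("paper", "desk"), ...) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    n_founder_m = 500L, n_founder_f = 500L,
    n_sires = 50L, n_dams = 500L, n_generations = 4L,
    n_historical_generations = 100L, historical_size = 100L,
    n_snps = 1002L, n_background = 1000L,
    n_records = 10L, t_min = 5, t_max = 305,
    trait_h2 = 0.3, pe_proportion = 0.2,
    qtn_h2 = 0.01, qtn_cumulative = 175.21, qtn_freq = 0.5,
    phenotypic_var = 15,
    mu_coef = c(20, 0.08, -2e-4),
    qtn_base = c(1, 0.3, -0.2),
    bg_coef_scales = c(1, 0.5, 0.25),
    pe_coef_scales = c(1, 0.5, 0.25),
    maf_floor = 0.05, max_retries = 20L)
  if (profile == "desk") {
    base$n_founder_m <- 125L; base$n_founder_f <- 125L
    base$n_sires <- 25L; base$n_dams <- 125L
  }
  cfg <- utils::modifyList(base, list(...))
  stopifnot(cfg$trait_h2 + cfg$pe_proportion < 1,
            cfg$qtn_h2 < cfg$trait_h2, cfg$qtn_h2 >= 0,
            cfg$n_snps >= cfg$n_background + 2L,
            cfg$n_sires <= cfg$n_founder_m, cfg$n_sires <= cfg$n_dams,
            cfg$n_dams <= cfg$n_founder_f,
            cfg$n_records >= 3L, cfg$t_min < cfg$t_max)
  class(cfg) <- "sim_config"
  cfg
}

#' QTN additive effect curve
#'
#' A smooth order-2 normalized-Legendre curve scaled so that its sum over
#' the integer grid equals `cfg$qtn_cumulative` exactly.
#'
#' @param cfg a [sim_config()].
#' @param domain a [time_domain()]; defaults to `cfg$t_min..cfg$t_max`.
#' @return List with `coef` (scaled Legendre coefficients), `grid`
#'   (curve on the integer grid) and `cumulative`.
#' @export
qtn_effect_curve <- function(cfg, domain = NULL) {
  if (is.null(domain)) domain <- time_domain(cfg$t_min, cfg$t_max)
  base <- cfg$qtn_base
  Phi <- legendre_matrix(length(base) - 1L, domain$grid, domain)
  raw <- drop(Phi %*% base)
  tot <- sum(raw)
  if (abs(tot) < 1e-10) {
    stop("qtn_effect_curve: base curve sums to zero over the grid; cannot scale")
  }
  coef <- base * (cfg$qtn_cumulative / tot)
  list(coef = coef, grid = drop(Phi %*% coef), cumulative = cfg$qtn_cumulative)
}

# One gamete per offspring from each parent: allele picked at random per
# locus (unlinked loci).
.gametes <- function(H1, H2, parent_rows) {
  mask <- matrix(stats::runif(length(parent_rows) * ncol(H1)) < 0.5,
                 length(parent_rows), ncol(H1))
  H1[parent_rows, , drop = FALSE] * mask +
    H2[parent_rows, , drop = FALSE] * (1 - mask)
}

#' Simulate the pedigree and SNP genotypes
#'
#' Wright-Fisher drift of founder allele frequencies (drawn Uniform(0.1,
#' 0.9); the QTN and null marker start at `qtn_freq` and 0.5) over the
#' historical generations, then Mendelian gene-dropping through the recent
#' pedigree. The QTN and null-marker drift trajectories are redrawn
#' (bounded retries) if drift takes them too close to fixation for the
#' phenotyped cohort to segregate.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `"sim_population"`: `ped` ([pedigree()]),
#'   `phen_ids`, `geno` ([genotype_matrix()] of the QTN and null marker for
#'   the phenotyped cohort), `X_bg` (background dosages, phenotyped cohort),
#'   `sex` and `generation` vectors, and the SNP role table.
#' @export
simulate_population <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nsnp <- cfg$n_snps
  N <- cfg$historical_size

  drift <- function(f0, ngen) {
    f <- f0
    for (g in seq_len(ngen)) f <- stats::rbinom(length(f), 2L * N, f) / (2 * N)
    f
  }
  n_null <- nsnp - 1L - cfg$n_background
  targets <- seq_len(1L + n_null)      # QTN plus null marker(s)
  f0 <- stats::runif(nsnp, 0.1, 0.9)
  f0[1L] <- cfg$qtn_freq; f0[2L] <- 0.5
  f <- drift(f0, cfg$n_historical_generations)
  # keep the target markers well clear of fixation
  for (s in targets) {
    tries <- 0L
    while ((f[s] < 0.15 || f[s] > 0.85) && tries < cfg$max_retries) {
      # QTN restarts from its configured founder frequency; null markers
      # resample theirs from the founder distribution
      if (s > 1L) f0[s] <- stats::runif(1, 0.1, 0.9)
      f[s] <- drift(f0[s], cfg$n_historical_generations)
      tries <- tries + 1L
    }
    if (f[s] < 0.15 || f[s] > 0.85) {
      warning("simulate_population: target marker ", s,
              " stayed near fixation after ", cfg$max_retries, " retries")
    }
  }

  nm <- cfg$n_founder_m; nf <- cfg$n_founder_f
  n0 <- nm + nf
  draw_h <- function(n) {
    matrix(stats::rbinom(n * nsnp, 1L, rep(f, each = n)), n, nsnp)
  }
  H1 <- draw_h(n0); H2 <- draw_h(n0)
  id <- as.character(seq_len(n0))
  sire <- rep(NA_character_, n0); dam <- rep(NA_character_, n0)
  sex <- rep(c("M", "F"), c(nm, nf))
  gen <- rep(0L, n0)
  males <- which(sex == "M"); females <- which(sex == "F")

  next_id <- n0
  for (g in seq_len(cfg$n_generations)) {
    sires <- sample(males, cfg$n_sires)
    dams <- if (length(females) > cfg$n_dams) sample(females, cfg$n_dams) else females
    mate <- sample(sires, length(dams), replace = TRUE)
    n_off <- 2L * length(dams)
    off_sire <- rep(mate, each = 2L)
    off_dam <- rep(dams, each = 2L)
    H1 <- rbind(H1, .gametes(H1, H2, off_sire))
    H2 <- rbind(H2, .gametes(H1, H2, off_dam))
    off_idx <- next_id + seq_len(n_off)
    id <- c(id, as.character(off_idx))
    sire <- c(sire, id[off_sire])
    dam <- c(dam, id[off_dam])
    off_sex <- rep(c("M", "F"), length(dams))
    sex <- c(sex, off_sex)
    gen <- c(gen, rep(g, n_off))
    males <- off_idx[off_sex == "M"]
    females <- off_idx[off_sex == "F"]
    next_id <- next_id + n_off
  }

  ped <- pedigree(id, sire, dam)
  phen <- id[sex == "F" & gen >= 1L]
  X <- H1 + H2
  rownames(X) <- id
  Xp <- X[phen, , drop = FALSE]

  # phenotyped cohort must segregate at the target markers
  mafs <- pmin(colMeans(Xp[, targets, drop = FALSE]) / 2,
               1 - colMeans(Xp[, targets, drop = FALSE]) / 2)
  if (any(mafs < cfg$maf_floor)) {
    warning("simulate_population: target marker MAF ",
            signif(min(mafs), 3), " below floor ", cfg$maf_floor)
  }

  null_ids <- if (n_null == 1L) "null" else c("null", paste0("null", 2:n_null))
  snp_ids <- c("qtn", null_ids, paste0("bg", seq_len(cfg$n_background)))
  gm <- t(Xp[, targets, drop = FALSE])
  rownames(gm) <- snp_ids[targets]
  colnames(gm) <- phen
  structure(list(
    ped = ped, phen_ids = phen,
    geno = genotype_matrix(gm),
    X_bg = Xp[, 1L + n_null + seq_len(cfg$n_background), drop = FALSE],
    sex = stats::setNames(sex, id), generation = stats::setNames(gen, id),
    snp_roles = data.frame(snp = snp_ids,
                           role = c("qtn", rep("null", n_null),
                                    rep("background", cfg$n_background)),
                           founder_freq = f0, drifted_freq = f,
                           stringsAsFactors = FALSE),
    cfg = cfg), class = "sim_population")
}

#' Simulate longitudinal phenotypes on a simulated population
#'
#' Each phenotyped female gets `n_records` equally spaced records on the
#' grid. Records are `y_i(t) = mu(t) + x_i qtn(t) + a_i(t) + pe_i(t) +
#' e_it`: the polygenic curve `a_i(t)` sums the background-SNP dosages
#' times per-SNP random order-2 regression coefficients, `pe_i(t)` is an
#' individual order-2 random curve, and `e_it` is white noise. The QTN
#' curve is fixed (its grid sum equals the configured cumulative effect);
#' the total phenotypic variance is set to `var_QTN / qtn_h2`, and the
#' polygenic, permanent-environment and residual components are scaled to
#' their configured time-averaged shares of it.
#'
#' @param pop a [simulate_population()] result.
#' @param cfg a [sim_config()] (defaults to the one in `pop`).
#' @param seed integer seed or `NULL`.
#' @return List with `data` ([longitudinal_data()]) and `truth` (class
#'   `"sim_truth"`): QTN curve, per-individual genetic curves, realized
#'   variance partition, and the component matrices.
#' @export
simulate_phenotypes <- function(pop, cfg = NULL, seed = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  if (is.null(cfg)) cfg <- pop$cfg
  if (!is.null(seed)) set.seed(seed)
  domain <- time_domain(cfg$t_min, cfg$t_max)
  times <- round(seq(cfg$t_min, cfg$t_max, length.out = cfg$n_records))
  n <- length(pop$phen_ids)
  T <- length(times)

  qtn <- qtn_effect_curve(cfg, domain)
  Phi_rec <- legendre_matrix(2L, times, domain)
  qv <- drop(Phi_rec %*% qtn$coef)
  x_q <- pop$geno$values["qtn", pop$phen_ids]

  Xb <- scale(pop$X_bg, center = TRUE, scale = FALSE)
  alpha <- matrix(stats::rnorm(ncol(Xb) * 3L), ncol(Xb), 3L) %*%
    diag(sqrt(cfg$bg_coef_scales))
  a_mat <- (Xb %*% alpha) %*% t(Phi_rec)
  pe_mat <- (matrix(stats::rnorm(n * 3L), n, 3L) %*%
               diag(sqrt(cfg$pe_coef_scales))) %*% t(Phi_rec)

  v_qtn <- stats::var(x_q) * mean(qv^2)
  V_P <- if (cfg$qtn_h2 > 0) v_qtn / cfg$qtn_h2 else cfg$phenotypic_var
  if (cfg$qtn_h2 > 0 && v_qtn <= 0) {
    stop("simulate_phenotypes: QTN does not segregate; cannot calibrate variance")
  }
  tv <- function(M) mean(apply(M, 2, stats::var))
  v_poly_target <- (cfg$trait_h2 - cfg$qtn_h2) * V_P
  v_pe_target <- cfg$pe_proportion * V_P
  se2 <- (1 - cfg$trait_h2 - cfg$pe_proportion) * V_P
  a_mat <- a_mat * sqrt(v_poly_target / tv(a_mat))
  pe_mat <- pe_mat * sqrt(v_pe_target / tv(pe_mat))
  e_mat <- matrix(stats::rnorm(n * T, sd = sqrt(se2)), n, T)

  mu_t <- cfg$mu_coef[1] + cfg$mu_coef[2] * times + cfg$mu_coef[3] * times^2
  qtn_mat <- outer(x_q, qv)
  Y <- matrix(mu_t, n, T, byrow = TRUE) + qtn_mat + a_mat + pe_mat + e_mat

  gen_mat <- qtn_mat + a_mat
  partition <- c(h2_total = tv(gen_mat) / tv(Y),
                 h2_qtn = tv(qtn_mat) / tv(Y),
                 h2_poly = tv(a_mat) / tv(Y),
                 pe = tv(pe_mat) / tv(Y),
                 resid = se2 / tv(Y))

  data <- longitudinal_data(
    id = rep(pop$phen_ids, each = T),
    time = rep(times, n),
    value = as.vector(t(Y)))

  truth <- structure(list(
    qtn_coef = qtn$coef, qtn_grid = qtn$grid,
    cumulative_qtn = cfg$qtn_cumulative,
    record_times = times, domain = domain,
    genetic = gen_mat, qtn_component = qtn_mat, poly = a_mat,
    pe = pe_mat, resid = e_mat, mu = mu_t,
    partition = partition, V_P = V_P, sigma_e2 = se2,
    ids = pop$phen_ids), class = "sim_truth")
  list(data = data, truth = truth)
}

#' One-call seeded simulation of population and phenotypes
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (all randomness derives from it).
#' @return List `pop`, `data`, `truth`, `domain`.
#' @export
simulate_longitudinal <- function(cfg, seed) {
  set.seed(seed)
  pop <- simulate_population(cfg, seed = NULL)
  ph <- simulate_phenotypes(pop, cfg, seed = NULL)
  list(pop = pop, data = ph$data, truth = ph$truth,
       domain = time_domain(cfg$t_min, cfg$t_max))
}
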