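# Time-varied SNP association scans.
#
# fGWAS-C fits the SNP dosage as a fixed regression with its own Legendre
# coefficient curve; fGWAS-F fits one curve per observed genotype class
# (reference = lowest dosage class, whose curve is zero). Both are tested
# by the incremental Wald statistic against the reduced (no-SNP) model with
# plug-in covariance components.

#' Incremental Wald statistic
#'
#' `W = (R(full) - R(reduced)) / sigma_e2`, where `R(model)` is the
#' reduction in sums of squares of the mixed model fit; under the null of
#' no SNP effect `W` is chi-square with `df` degrees of freedom.
#'
#' @param rss_full,rss_reduced reductions in sums of squares of the models
#'   with and without the SNP term.
#' @param sigma_e2 REML residual variance of the reduced model.
#' @param df degrees of freedom of the SNP term (positive integer).
#' @return List with elements `W` (clipped at 0) and `p` (upper chi-square
#'   tail).
#' @export
wald_incremental <- function(rss_full, rss_reduced, sigma_e2, df) {
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != round(df)) {
    stop("wald_incremental: df must be a positive integer")
  }
  if (sigma_e2 <= 0) stop("wald_incremental: sigma_e2 must be positive")
  if (rss_full < rss_reduced - 1e-8 * max(1, abs(rss_reduced))) {
    stop("wald_incremental: R(full) < R(reduced) beyond numerical slack")
  }
  W <- max((rss_full - rss_reduced) / sigma_e2, 0)
  list(W = W, p = stats::pchisq(W, df = df, lower.tail = FALSE))
}

#' Sum of a coefficient curve over the accumulation grid
#'
#' Evaluates `sum_t sum_k coef_k phi_k(t)` over the integer grid of the
#' domain, i.e. `Q_c' coef`.
#'
#' @param coef basis coefficients (length = order + 1).
#' @param domain a [time_domain()].
#' @return Scalar cumulative effect.
#' @export
cumulative_effect <- function(coef, domain) {
  drop(crossprod(accumulation_vector(length(coef) - 1L, domain), coef))
}

#' Genetic decomposition of fGWAS-F class curves
#'
#' From the three genotype-class curves, derives the additive effect curve
#' `add(t) = (SNP_AA(t) - SNP_aa(t)) / 2`, the dominance curve (default
#' convention `dom(t) = SNP_Aa(t) - add(t)`, appropriate when the `aa`
#' class is the reference with zero curve; `"midpoint"` uses
#' `SNP_Aa(t) - (SNP_AA(t) + SNP_aa(t))/2`), and the SNP additive genetic
#' variance `sigma2_a(t) = 2 p q (add(t) + dom(t) (q - p))^2`.
#'
#' @param curves list with coefficient vectors `lambda_AA`, `lambda_Aa`,
#'   `lambda_aa` (each length nf+1).
#' @param p coded-allele frequency in (0, 1).
#' @param domain a [time_domain()]; curves are evaluated on its grid.
#' @param convention `"printed"` (default) or `"midpoint"`.
#' @return List with vectors `add`, `dom`, `sigma2_a` on the grid and the
#'   coefficient vectors `add_coef`, `dom_coef`.
#' @export
decompose_fgwas_f <- function(curves, p, domain,
                              convention = c("printed", "midpoint")) {
  convention <- match.arg(convention)
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    stop("decompose_fgwas_f: allele frequency must lie strictly in (0, 1)")
  }
  lAA <- curves$lambda_AA; lAa <- curves$lambda_Aa; laa <- curves$lambda_aa
  stopifnot(!is.null(lAA), !is.null(lAa), !is.null(laa))
  add_coef <- (lAA - laa) / 2
  dom_coef <- switch(convention,
                     printed  = lAa - add_coef,
                     midpoint = lAa - (lAA + laa) / 2)
  Phi <- legendre_matrix(length(lAA) - 1L, domain$grid, domain)
  add <- drop(Phi %*% add_coef)
  dom <- drop(Phi %*% dom_coef)
  q <- 1 - p
  list(add = add, dom = dom,
       sigma2_a = 2 * p * q * (add + dom * (q - p))^2,
       add_coef = add_coef, dom_coef = dom_coef)
}

# ---- shared scan plumbing ----------------------------------------------

# Reduced-model context: engine prep + reduced quadratic, or MME fallback.
.scan_context <- function(fit) {
  vc <- fit$vc
  if (!is.null(fit$engine)) {
    eng <- fit$engine
    prep <- .engine_prepare(eng, vc)
    red <- .engine_quad(prep, list(list(v = eng$one_rot, Phi = eng$Phi_f)))
    yty <- sum(eng$Y^2)
    list(type = "rotated", eng = eng, prep = prep, vc = vc,
         q_red = red$q, rss_red = yty - vc$sigma_e2 * red$q, yty = yty,
         ids = eng$ids, domain = fit$domain, spec = fit$spec)
  } else {
    data <- fit$data
    design <- build_design(data, fit$spec, fit$domain, fit$ped)
    A <- numerator_relationship_matrix(fit$ped)
    a_inv <- a_inverse(fit$ped, A)
    red <- solve_mme(design, vc, a_inv)
    list(type = "mme", design = design, a_inv = a_inv, vc = vc, data = data,
         q_red = red$ypy, rss_red = red$rss, yty = sum(data$value^2),
         ids = unique(data$id), domain = fit$domain, spec = fit$spec)
  }
}

# Full-model quadratic given per-individual vectors (list of v, one basis
# block of order nf each). Returns rss_full and the stacked SNP coefficients
# (mean block coefficients dropped).
.scan_quad <- function(ctx, vlist) {
  nf1 <- ctx$spec$nf + 1L
  if (ctx$type == "rotated") {
    eng <- ctx$eng
    blocks <- c(list(list(v = eng$one_rot, Phi = eng$Phi_f)),
                lapply(vlist, function(v) {
                  list(v = drop(crossprod(eng$U, v)), Phi = eng$Phi_f)
                }))
    gq <- .engine_quad(ctx$prep, blocks)
    n_mean <- ncol(eng$Phi_f)
    list(rss = ctx$yty - ctx$vc$sigma_e2 * gq$q,
         coef = gq$coef[-seq_len(n_mean)])
  } else {
    data <- ctx$data
    ii <- match(data$id, ctx$ids)
    Phi <- legendre_matrix(ctx$spec$nf, data$time, ctx$domain)
    extra <- do.call(cbind, lapply(vlist, function(v) v[ii] * Phi))
    fit <- solve_mme(ctx$design, ctx$vc, ctx$a_inv, extra = extra)
    nb <- length(fit$b_hat)
    k <- length(vlist) * nf1
    list(rss = fit$rss, coef = fit$b_hat[(nb - k + 1L):nb])
  }
}

# Model-implied phenotypic variance curve on the grid (reduced model).
.grid_pheno_var <- function(ctx) {
  g <- ctx$domain$grid
  Pa <- legendre_matrix(ctx$spec$nr1, g, ctx$domain)
  Pp <- legendre_matrix(ctx$spec$nr2, g, ctx$domain)
  rowSums((Pa %*% ctx$vc$G) * Pa) + rowSums((Pp %*% ctx$vc$P) * Pp) +
    ctx$vc$sigma_e2
}

.empty_scan_row <- function(snp, df) {
  data.frame(snp = snp, df = df, W = 0, p = 1, cumulative_add = NA_real_,
             cumulative_dom = NA_real_, mean_qtn_h2 = NA_real_,
             tested = FALSE, stringsAsFactors = FALSE)
}

#' fGWAS-C: time-varied SNP scan with the dosage as a covariate
#'
#' For each SNP, augments the fixed effects of the reduced random
#' regression model with `nf + 1` columns `x_i * phi_k(t)` (dosage times
#' mean-curve basis), refits with plug-in covariance components and tests
#' the SNP curve by the incremental Wald statistic with `nf + 1` degrees of
#' freedom. Accepts hard calls or dosages in `[0, 2]`; missing values are
#' mean-imputed per SNP.
#'
#' @param data a [longitudinal_data()] (ignored when `fit` is supplied).
#' @param geno a [genotype_matrix()].
#' @param spec a [model_spec()].
#' @param ped a [pedigree()] or `NULL`.
#' @param fit optional reduced-model fit from [reml_fit()]; when absent the
#'   reduced model is fitted here (plug-in strategy: covariance components
#'   estimated once and reused for every SNP).
#' @param maf minor-allele-frequency filter; SNPs below it are flagged
#'   untestable (default 0.01).
#' @param per_snp_reml re-estimate covariance components under each SNP's
#'   full model (slow; intended for single-QTN designs).
#' @return A data frame of class `"scan_result"`: per SNP `df`, `W`, `p`,
#'   `cumulative_add`, `mean_qtn_h2`, `tested`, and the SNP curve
#'   coefficients `eta0..eta<nf>`.
#' @export
scan_fgwas_c <- function(data, geno, spec = model_spec(), ped = NULL,
                         fit = NULL, maf = 0.01, per_snp_reml = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(fit)) fit <- reml_fit(data, spec, ped, solver = "none")
  ctx <- .scan_context(fit)
  ids <- ctx$ids
  miss <- setdiff(ids, geno$ind_ids)
  if (length(miss)) {
    stop("scan_fgwas_c: no genotypes for individual(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  Gm <- geno$values[, ids, drop = FALSE]
  nf1 <- ctx$spec$nf + 1L
  qc <- accumulation_vector(ctx$spec$nf, ctx$domain)
  vpt <- .grid_pheno_var(ctx)
  n_snp <- nrow(Gm)
  rows <- vector("list", n_snp)
  coefs <- matrix(NA_real_, n_snp, nf1,
                  dimnames = list(geno$snp_ids, paste0("eta", 0:(nf1 - 1L))))
  for (s in seq_len(n_snp)) {
    x <- Gm[s, ]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    pfreq <- mean(x) / 2
    if (stats::var(x) < 1e-12 || min(pfreq, 1 - pfreq) < maf) {
      rows[[s]] <- .empty_scan_row(geno$snp_ids[s], nf1)
      next
    }
    res <- if (per_snp_reml) {
      .per_snp_reml_quad(fit, x, ctx)
    } else {
      tryCatch(.scan_quad(ctx, list(x)), error = function(e) e)
    }
    if (inherits(res, "error")) {
      warning("scan_fgwas_c: SNP ", geno$snp_ids[s], " skipped: ",
              conditionMessage(res))
      rows[[s]] <- .empty_scan_row(geno$snp_ids[s], nf1)
      next
    }
    wt <- wald_incremental(res$rss, res$rss_red %||% ctx$rss_red,
                           res$sigma_e2 %||% ctx$vc$sigma_e2, nf1)
    eta <- res$coef
    coefs[s, ] <- eta
    addt <- drop(legendre_matrix(ctx$spec$nf, ctx$domain$grid, ctx$domain) %*% eta)
    s2a <- 2 * pfreq * (1 - pfreq) * addt^2
    rows[[s]] <- data.frame(snp = geno$snp_ids[s], df = nf1, W = wt$W,
                            p = wt$p, cumulative_add = drop(crossprod(qc, eta)),
                            cumulative_dom = 0,
                            mean_qtn_h2 = mean(s2a / (vpt + s2a)),
                            tested = TRUE, stringsAsFactors = FALSE)
  }
  out <- cbind(do.call(rbind, rows), coefs)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  attr(out, "model") <- "fgwas-c"
  attr(out, "map") <- geno$map
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-SNP REML: re-estimate (G, P, se2) with the SNP columns included as
# covariates (forces the general MME likelihood), then evaluate the reduced
# model at those components.
.per_snp_reml_quad <- function(fit, x, ctx) {
  data <- fit$data
  ii <- match(data$id, ctx$ids)
  Phi <- legendre_matrix(ctx$spec$nf, data$time, ctx$domain)
  cov <- as.data.frame(x[ii] * Phi)
  names(cov) <- paste0("snpcov", seq_len(ncol(cov)))
  data_full <- data
  attr(data_full, "covariates") <- cov
  full <- reml_fit(data_full, fit$spec, fit$ped, domain = fit$domain,
                   solver = "mme")
  # reduced model at the full model's components
  design <- build_design(data, fit$spec, fit$domain, full$ped)
  a_inv <- a_inverse(full$ped)
  red <- solve_mme(design, full$vc, a_inv)
  nb <- length(full$b_hat)
  k <- ncol(Phi)
  list(rss = full$rss, rss_red = red$rss, sigma_e2 = full$vc$sigma_e2,
       coef = full$b_hat[(nb - k + 1L):nb])
}

#' fGWAS-F: time-varied SNP scan with genotype classes as a factor
#'
#' Fits one Legendre curve per observed genotype class (hard calls 0/1/2
#' required; dosages are rejected). The lowest observed dosage class is the
#' reference with zero curve, so the remaining class curves are effects
#' relative to it; with all three classes observed the SNP term has
#' `2 (nf + 1)` degrees of freedom. Additive and dominance curves and the
#' SNP additive variance follow from the class-curve contrasts.
#'
#' @inheritParams scan_fgwas_c
#' @param dom_convention dominance convention passed to
#'   [decompose_fgwas_f()].
#' @return A data frame of class `"scan_result"` with per-SNP `df`, `W`,
#'   `p`, `cumulative_add`, `cumulative_dom`, `mean_qtn_h2`, `tested`;
#'   class-curve coefficients are in `attr(, "class_curves")`.
#' @export
scan_fgwas_f <- function(data, geno, spec = model_spec(), ped = NULL,
                         fit = NULL, maf = 0.01,
                         dom_convention = c("printed", "midpoint")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dom_convention <- match.arg(dom_convention)
  if (is.null(fit)) fit <- reml_fit(data, spec, ped, solver = "none")
  ctx <- .scan_context(fit)
  ids <- ctx$ids
  Gm <- geno$values[, ids, drop = FALSE]
  if (any(abs(Gm - round(Gm)) > 1e-6, na.rm = TRUE)) {
    stop("scan_fgwas_f: genotype dosages detected; the factor model needs ",
         "hard 0/1/2 calls - use scan_fgwas_c for dosages")
  }
  nf1 <- ctx$spec$nf + 1L
  qc <- accumulation_vector(ctx$spec$nf, ctx$domain)
  vpt <- .grid_pheno_var(ctx)
  n_snp <- nrow(Gm)
  rows <- vector("list", n_snp)
  curves <- vector("list", n_snp)
  names(curves) <- geno$snp_ids
  for (s in seq_len(n_snp)) {
    g <- round(Gm[s, ])
    keep <- !is.na(g)
    if (!all(keep)) {
      # records with missing calls are dropped for this SNP, which breaks
      # the balanced rotation; fall back to the general MME route
      res <- .fgwas_f_missing(fit, g, ctx, nf1)
      if (is.null(res)) {
        rows[[s]] <- .empty_scan_row(geno$snp_ids[s], nf1)
        next
      }
      cls <- res$cls; coef <- res$coef; wt <- res$wt
    } else {
      cls <- sort(unique(g))
      if (length(cls) < 2L) {
        rows[[s]] <- .empty_scan_row(geno$snp_ids[s], nf1)
        next
      }
      pfreq <- mean(g) / 2
      if (min(pfreq, 1 - pfreq) < maf) {
        rows[[s]] <- .empty_scan_row(geno$snp_ids[s], nf1)
        next
      }
      vlist <- lapply(cls[-1L], function(cl) as.numeric(g == cl))
      res <- tryCatch(.scan_quad(ctx, vlist), error = function(e) e)
      if (inherits(res, "error")) {
        warning("scan_fgwas_f: SNP ", geno$snp_ids[s], " skipped: ",
                conditionMessage(res))
        rows[[s]] <- .empty_scan_row(geno$snp_ids[s], nf1)
        next
      }
      df <- (length(cls) - 1L) * nf1
      wt <- wald_incremental(res$rss, ctx$rss_red, ctx$vc$sigma_e2, df)
      coef <- res$coef
    }
    pfreq <- mean(g, na.rm = TRUE) / 2
    lam <- .class_coefs(cls, coef, nf1)
    curves[[s]] <- lam
    dec <- NULL
    if (all(c("0", "1", "2") %in% names(lam)) && pfreq > 0 && pfreq < 1) {
      dec <- decompose_fgwas_f(
        list(lambda_AA = lam[["2"]], lambda_Aa = lam[["1"]],
             lambda_aa = lam[["0"]]),
        pfreq, ctx$domain, convention = dom_convention)
      cum_add <- cumulative_effect(dec$add_coef, ctx$domain)
      cum_dom <- cumulative_effect(dec$dom_coef, ctx$domain)
      mean_h2 <- mean(dec$sigma2_a / (vpt + dec$sigma2_a))
    } else if (length(lam) == 2L) {
      # two observed classes: additive substitution effect per dosage unit
      dd <- diff(as.numeric(names(lam)))
      a_coef <- (lam[[2L]] - lam[[1L]]) / dd
      cum_add <- cumulative_effect(a_coef, ctx$domain)
      cum_dom <- NA_real_
      addt <- drop(legendre_matrix(ctx$spec$nf, ctx$domain$grid, ctx$domain) %*% a_coef)
      s2a <- 2 * pfreq * (1 - pfreq) * addt^2
      mean_h2 <- mean(s2a / (vpt + s2a))
    } else {
      cum_add <- NA_real_; cum_dom <- NA_real_; mean_h2 <- NA_real_
    }
    rows[[s]] <- data.frame(snp = geno$snp_ids[s],
                            df = (length(cls) - 1L) * nf1,
                            W = wt$W, p = wt$p, cumulative_add = cum_add,
                            cumulative_dom = cum_dom, mean_qtn_h2 = mean_h2,
                            tested = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  attr(out, "model") <- "fgwas-f"
  attr(out, "map") <- geno$map
  attr(out, "class_curves") <- curves
  out
}

# Class coefficient curves on the raw (reference-zero) scale.
.class_coefs <- function(cls, coef, nf1) {
  lam <- list()
  lam[[as.character(cls[1L])]] <- numeric(nf1)
  for (j in seq_along(cls[-1L])) {
    lam[[as.character(cls[j + 1L])]] <- coef[(j - 1L) * nf1 + seq_len(nf1)]
  }
  lam
}

# fGWAS-F for a SNP with missing calls: refit reduced and full model on the
# subset of individuals with calls, via the sparse MME.
.fgwas_f_missing <- function(fit, g, ctx, nf1) {
  keep_ids <- ctx$ids[!is.na(g)]
  g <- g[!is.na(g)]
  cls <- sort(unique(g))
  if (length(cls) < 2L) return(NULL)
  data <- fit$data
  sub <- data[data$id %in% keep_ids, , drop = FALSE]
  class(sub) <- class(data)
  design <- build_design(sub, ctx$spec, ctx$domain, fit$ped)
  a_inv <- a_inverse(fit$ped)
  red <- solve_mme(design, ctx$vc, a_inv)
  ii <- match(sub$id, keep_ids)
  Phi <- legendre_matrix(ctx$spec$nf, sub$time, ctx$domain)
  extra <- do.call(cbind, lapply(cls[-1L], function(cl) {
    as.numeric(g[ii] == cl) * Phi
  }))
  full <- solve_mme(design, ctx$vc, a_inv, extra = extra)
  df <- (length(cls) - 1L) * nf1
  nb <- length(full$b_hat)
  k <- df
  list(cls = cls, coef = full$b_hat[(nb - k + 1L):nb],
       wt = wald_incremental(full$rss, red$rss, ctx$vc$sigma_e2, df))
}
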