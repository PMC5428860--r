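# Pseudo-phenotype comparison strategies: accumulated EBVs, deregressed
# proofs, and averaged residuals, each scanned with a single-coefficient
# (df = 1) regression, with or without a pedigree polygenic term.

#' Accumulated EBVs from a reduced-model fit
#'
#' `EBV_i = Q_c' a_hat_i`, the individual's estimated genetic curve summed
#' over the integer time grid.
#'
#' @param fit an [reml_fit()] result with `solver = "mme"` (BLUP solutions
#'   required).
#' @param domain accumulation domain; defaults to the fit's.
#' @return Data frame `id`, `value`, `source`, `reliability` (NA here),
#'   one row per pedigree individual.
#' @export
accumulate_ebv <- function(fit, domain = NULL) {
  stopifnot(inherits(fit, "rrm_fit"))
  if (is.null(fit$a_hat)) {
    stop("accumulate_ebv: fit lacks BLUP solutions; refit with solver = 'mme'")
  }
  if (is.null(domain)) domain <- fit$domain
  qc <- accumulation_vector(fit$spec$nr1, domain)
  data.frame(id = rownames(fit$a_hat),
             value = drop(fit$a_hat %*% qc),
             source = "ebv", reliability = NA_real_,
             stringsAsFactors = FALSE)
}

#' Deregressed proofs
#'
#' Removes the parent-average information from accumulated EBVs:
#' `PA_i = (EBV_sire + EBV_dam) / 2` (unknown parent contributes 0) and
#' `DRP_i = PA_i + (EBV_i - PA_i) / max(r2_i, r2_floor)`. This single-step
#' parent-average deregression retains the Mendelian-sampling signal while
#' stripping the family mean; the reliability floor caps variance
#' inflation for poorly proven individuals.
#'
#' @param ebv output of [accumulate_ebv()] (must cover parents).
#' @param ped a [pedigree()].
#' @param r2 named reliabilities in `[0, 1)`, see [reliabilities()].
#' @param r2_floor lower bound on the deregression divisor (default 0.1).
#' @return Data frame like `ebv` with `source = "drp"` and the reliability
#'   used.
#' @export
deregress <- function(ebv, ped, r2, r2_floor = 0.1) {
  stopifnot(inherits(ped, "pedigree"))
  if (all(r2 < r2_floor, na.rm = TRUE)) {
    stop("deregress: all reliabilities below the floor (", r2_floor, ")")
  }
  val <- stats::setNames(ebv$value, ebv$id)
  out <- ebv
  for (k in seq_len(nrow(ebv))) {
    i <- ebv$id[k]
    r <- match(i, ped$id)
    pa <- 0
    if (!is.na(r)) {
      es <- if (!is.na(ped$sire[r])) val[ped$sire[r]] else 0
      ed <- if (!is.na(ped$dam[r]))  val[ped$dam[r]]  else 0
      es <- ifelse(is.na(es), 0, es); ed <- ifelse(is.na(ed), 0, ed)
      pa <- (es + ed) / 2
    }
    ri <- max(if (i %in% names(r2)) r2[[i]] else r2_floor, r2_floor)
    out$value[k] <- pa + (val[[i]] - pa) / ri
    out$reliability[k] <- ri
  }
  out$source <- "drp"
  out
}

#' Averaged estimated residuals
#'
#' GRAMMAR-style pseudo-phenotype: the mean of an individual's estimated
#' residuals from the reduced (no-SNP) random regression model.
#'
#' @param fit an [reml_fit()] result with `solver = "mme"`.
#' @return Data frame `id`, `value`, `source`, `reliability` (NA), one row
#'   per phenotyped individual.
#' @export
average_residuals <- function(fit) {
  stopifnot(inherits(fit, "rrm_fit"))
  if (is.null(fit$residuals) || is.null(fit$data)) {
    stop("average_residuals: fit lacks residuals; refit with solver = 'mme'")
  }
  mu <- tapply(fit$residuals, factor(fit$data$id, levels = unique(fit$data$id)),
               mean)
  data.frame(id = names(mu), value = as.numeric(mu), source = "residual",
             reliability = NA_real_, stringsAsFactors = FALSE)
}

#' Single-value (pseudo-phenotype) association scan
#'
#' Regresses a per-individual scalar response on each SNP dosage, testing
#' the regression coefficient with one degree of freedom. With
#' `fit_polygenic = TRUE` the model adds a pedigree polygenic effect
#' `u ~ N(0, A sigma_a^2)` whose variance is REML-estimated once under the
#' no-SNP model and plugged into every test; with `FALSE` it is an ordinary
#' least-squares regression.
#'
#' @param y data frame with columns `id`, `value` (e.g. from
#'   [accumulate_ebv()], [deregress()] or [average_residuals()]).
#' @param geno a [genotype_matrix()].
#' @param ped a [pedigree()] (required when `fit_polygenic = TRUE`).
#' @param fit_polygenic logical.
#' @param maf minor-allele-frequency filter (default 0.01).
#' @return Data frame of class `"scan_result"`: per SNP `beta` (the
#'   regression coefficient, on the same accumulated scale as `y`), `df`,
#'   `W`, `p`, `tested`; `cumulative_add` mirrors `beta` for comparison
#'   with the functional scans.
#' @export
scan_single_value <- function(y, geno, ped = NULL, fit_polygenic = FALSE,
                              maf = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ids <- y$id
  if (!all(ids %in% geno$ind_ids)) {
    stop("scan_single_value: genotypes missing for some individuals")
  }
  yy <- y$value
  if (!all(is.finite(yy))) stop("scan_single_value: non-finite response")
  Gm <- geno$values[, ids, drop = FALSE]
  n <- length(yy)

  if (fit_polygenic) {
    if (is.null(ped)) stop("scan_single_value: pedigree required with polygenic term")
    A <- numerator_relationship_matrix(ped)
    miss <- setdiff(ids, ped$id)
    if (length(miss)) stop("scan_single_value: individuals not in pedigree")
    Ann <- A[ids, ids, drop = FALSE]
    eA <- eigen(Ann, symmetric = TRUE)
    U <- eA$vectors; dA <- pmax(eA$values, 1e-10)
    yr <- drop(crossprod(U, yy))
    onr <- colSums(U)
    # 1-parameter REML profile over the variance ratio sigma_a^2/sigma_e^2
    neg2ll <- function(loglam) {
      lam <- exp(loglam)
      w <- 1 / (lam * dA + 1)
      xwx <- sum(w * onr^2)
      mu <- sum(w * onr * yr) / xwx
      q <- sum(w * yr^2) - mu * sum(w * onr * yr)
      sum(log(lam * dA + 1)) + log(xwx) + (n - 1) * log(q / (n - 1))
    }
    op <- stats::optimize(neg2ll, c(-12, 12))
    lam <- exp(op$minimum)
    w <- 1 / (lam * dA + 1)
    xwx <- sum(w * onr^2)
    q_red <- sum(w * yr^2) - sum(w * onr * yr)^2 / xwx
    se2 <- q_red / (n - 1)
  }

  rows <- vector("list", nrow(Gm))
  for (s in seq_len(nrow(Gm))) {
    x <- Gm[s, ]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    pfreq <- mean(x) / 2
    if (stats::var(x) < 1e-12 || min(pfreq, 1 - pfreq) < maf) {
      rows[[s]] <- data.frame(snp = geno$snp_ids[s], beta = NA_real_, df = 1L,
                              W = 0, p = 1, cumulative_add = NA_real_,
                              tested = FALSE, stringsAsFactors = FALSE)
      next
    }
    if (fit_polygenic) {
      xr <- drop(crossprod(U, x))
      X <- cbind(onr, xr)
      XtWX <- crossprod(X, w * X)
      XtWy <- crossprod(X, w * yr)
      b <- solve(XtWX, XtWy)
      q_full <- sum(w * yr^2) - sum(XtWy * b)
      W <- max((q_red - q_full) / se2, 0)
      beta <- b[2L]
    } else {
      xc <- x - mean(x); yc <- yy - mean(yy)
      sxx <- sum(xc^2)
      beta <- sum(xc * yc) / sxx
      rss <- sum((yc - beta * xc)^2)
      W <- beta^2 * sxx / (rss / (n - 2))
    }
    rows[[s]] <- data.frame(snp = geno$snp_ids[s], beta = beta, df = 1L,
                            W = W,
                            p = stats::pchisq(W, 1, lower.tail = FALSE),
                            cumulative_add = beta, tested = TRUE,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  attr(out, "model") <- if (fit_polygenic) "single-value-polygenic" else "single-value-ols"
  attr(out, "map") <- geno$map
  out
}
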