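# REML estimation of the random regression covariance components.
#
# The restricted likelihood is maximized by quasi-Newton (L-BFGS-B) over an
# unconstrained log-Cholesky parameterization of (G, P, sigma_e^2), which
# keeps every iterate positive definite. Two exact evaluation routes:
#  - balanced recording designs (every individual measured at the same
#    times): spectral decomposition of the phenotyped block of A decouples
#    individuals after rotation, so one evaluation costs O(n T^2);
#  - general designs: Graser's determinant identity on the sparse MME.
# Both compute the same restricted likelihood (tested).

# ---- log-Cholesky parameterization -------------------------------------

.ltri_index <- function(k) {
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  list(idx = idx, diag = which(idx[, 1] == idx[, 2]), n = nrow(idx))
}

.theta_to_mat <- function(th, k) {
  L <- matrix(0, k, k)
  li <- .ltri_index(k)
  th[li$diag] <- exp(pmin(pmax(th[li$diag], -12), 8))
  L[li$idx] <- th
  tcrossprod(L)
}

.mat_to_theta <- function(M) {
  k <- nrow(M)
  ev <- eigen(M, symmetric = TRUE)
  Mpd <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
  L <- t(chol(Mpd))
  li <- .ltri_index(k)
  th <- L[li$idx]
  th[li$diag] <- log(th[li$diag])
  th
}

.theta_to_vc <- function(th, na, np) {
  ng <- na * (na + 1) / 2
  npp <- np * (np + 1) / 2
  G <- .theta_to_mat(th[seq_len(ng)], na)
  P <- .theta_to_mat(th[ng + seq_len(npp)], np)
  se2 <- exp(pmin(pmax(th[ng + npp + 1], -20), 20))
  variance_components(G, P, se2)
}

.vc_to_theta <- function(vc) {
  c(.mat_to_theta(vc$G), .mat_to_theta(vc$P), log(vc$sigma_e2))
}

# ---- rotated engine for balanced designs -------------------------------

# Returns NULL when the recording design is not balanced (or covariates are
# attached); callers then fall back to the sparse-MME likelihood.
.make_rotated_engine <- function(data, spec, domain, ped, A = NULL) {
  if (!is.null(attr(data, "covariates"))) return(NULL)
  ids <- unique(data$id)
  sp <- split(seq_len(nrow(data)), factor(data$id, levels = ids))
  o1 <- sp[[1L]][order(data$time[sp[[1L]]])]
  t0 <- data$time[o1]
  T <- length(t0)
  ok <- vapply(sp, function(ix) {
    length(ix) == T && all(sort(data$time[ix]) == t0)
  }, logical(1))
  if (!all(ok)) return(NULL)
  Y <- matrix(0, length(ids), T)
  for (i in seq_along(ids)) {
    ix <- sp[[i]]
    Y[i, ] <- data$value[ix[order(data$time[ix])]]
  }
  if (is.null(A)) A <- numerator_relationship_matrix(ped)
  Ann <- A[ids, ids, drop = FALSE]
  eA <- eigen(Ann, symmetric = TRUE)
  structure(list(ids = ids, times = t0, U = eA$vectors,
                 d = pmax(eA$values, 1e-10), Y = Y,
                 Ytil = crossprod(eA$vectors, Y),
                 Phi_f = legendre_matrix(spec$nf, t0, domain),
                 Phi_a = legendre_matrix(spec$nr1, t0, domain),
                 Phi_p = legendre_matrix(spec$nr2, t0, domain),
                 one_rot = colSums(eA$vectors),
                 spec = spec, domain = domain),
            class = "rrm_engine")
}

# Per-variance-component preparation: joint diagonalization of the
# individual covariance V_i = d_i Phi_a G Phi_a' + (Phi_p P Phi_p' + se2 I).
.engine_prepare <- function(eng, vc) {
  T <- length(eng$times)
  W <- eng$Phi_p %*% vc$P %*% t(eng$Phi_p) + diag(vc$sigma_e2, T)
  eW <- eigen(W, symmetric = TRUE)
  if (min(eW$values) <= 0) stop("engine: within-individual covariance not PD")
  Whi <- eW$vectors %*% ((1 / sqrt(eW$values)) * t(eW$vectors))
  Sa <- eng$Phi_a %*% vc$G %*% t(eng$Phi_a)
  eB <- eigen(Whi %*% Sa %*% Whi, symmetric = TRUE)
  lam <- pmax(eB$values, 0)
  M <- Whi %*% eB$vectors
  w <- 1 / (1 + outer(eng$d, lam))
  Ystar <- eng$Ytil %*% M
  list(M = M, w = w, Ystar = Ystar,
       logdetV = nrow(w) * sum(log(eW$values)) + sum(log1p(outer(eng$d, lam))),
       ytVy = sum(w * Ystar^2), vc = vc)
}

# Generalized least squares on the rotated data for fixed-effect structures
# of the form (per-individual vector) x (basis over times). `blocks` is a
# list of list(v = rotated n-vector, Phi = T x k basis matrix).
.engine_quad <- function(prep, blocks) {
  Fs <- lapply(blocks, function(b) crossprod(prep$M, b$Phi))
  ks <- vapply(Fs, ncol, integer(1))
  off <- cumsum(c(0L, ks))
  ktot <- sum(ks)
  XtVX <- matrix(0, ktot, ktot)
  rhs <- numeric(ktot)
  for (a in seq_along(blocks)) {
    ra <- off[a] + seq_len(ks[a])
    va <- blocks[[a]]$v
    rhs[ra] <- crossprod(Fs[[a]], colSums(va * prep$w * prep$Ystar))
    for (b in a:length(blocks)) {
      rb <- off[b] + seq_len(ks[b])
      u <- colSums((va * blocks[[b]]$v) * prep$w)
      cross <- crossprod(Fs[[a]], u * Fs[[b]])
      XtVX[ra, rb] <- cross
      if (b > a) XtVX[rb, ra] <- t(cross)
    }
  }
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) {
    stop("rank-deficient fixed-effect design in GLS step")
  }
  coef <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  list(q = prep$ytVy - sum(rhs * coef), coef = coef,
       logdetX = 2 * sum(log(diag(ch))), XtVX = XtVX, chol = ch)
}

# -2 restricted log-likelihood via the rotated engine (mean curve as the
# only fixed term, plus optional rotated extra blocks).
.engine_neg2logLR <- function(eng, vc, extra_blocks = NULL) {
  prep <- .engine_prepare(eng, vc)
  blocks <- c(list(list(v = eng$one_rot, Phi = eng$Phi_f)), extra_blocks)
  gq <- .engine_quad(prep, blocks)
  m <- length(eng$ids) * length(eng$times)
  p <- (eng$spec$nf + 1) +
    sum(vapply(extra_blocks, function(b) ncol(b$Phi), integer(1)))
  prep$logdetV + gq$logdetX + gq$q + (m - p) * log(2 * pi)
}

# Value AND analytic gradient of -2 lR with respect to the log-Cholesky
# parameter vector, for the rotated engine (mean curve as the only fixed
# term). Uses the standard REML derivative
#   d(-2lR)/da = tr(P dV/da) - y'P (dV/da) P y
# evaluated blockwise in the doubly-rotated ("star") coordinates, where
# V_i^-1 = M diag(w_i) M'.
.engine_reml_fg <- function(eng, vc) {
  prep <- .engine_prepare(eng, vc)
  M <- prep$M; w <- prep$w; Ystar <- prep$Ystar
  d <- eng$d; cc <- eng$one_rot
  Ff <- crossprod(M, eng$Phi_f)
  Fa <- crossprod(M, eng$Phi_a)
  Fp <- crossprod(M, eng$Phi_p)
  n <- nrow(w); T <- ncol(w)
  m <- n * T; pf <- ncol(Ff)

  u1 <- colSums(cc^2 * w)
  XtVX <- crossprod(Ff, u1 * Ff)
  rhs <- drop(crossprod(Ff, colSums(cc * w * Ystar)))
  ch <- chol(XtVX)
  B <- chol2inv(ch)
  b <- drop(B %*% rhs)
  q <- prep$ytVy - sum(rhs * b)
  value <- prep$logdetV + 2 * sum(log(diag(ch))) + q + (m - pf) * log(2 * pi)

  Zs <- w * (Ystar - outer(cc, drop(Ff %*% b)))   # w o (residual star) = "Py" star
  S <- crossprod(M)
  K <- Ff %*% B %*% t(Ff)

  # G block
  W2g <- crossprod(w, (d * cc^2) * w)
  M1G <- crossprod(Fa, colSums(d * w) * Fa) -
    crossprod(Fa, (W2g * K) %*% Fa) -
    crossprod(Fa, crossprod(Zs, d * Zs) %*% Fa)
  # P block
  W2p <- crossprod(w, cc^2 * w)
  M1P <- crossprod(Fp, colSums(w) * Fp) -
    crossprod(Fp, (W2p * K) %*% Fp) -
    crossprod(Fp, crossprod(Zs) %*% Fp)
  # residual variance
  s1 <- sum(diag(S) * colSums(w)) - sum(W2p * K * S) - sum(Zs * (Zs %*% S))

  chain <- function(M1, Cmat) {
    k <- nrow(Cmat)
    li <- .ltri_index(k)
    L <- t(chol(Cmat))
    Gd <- 2 * (M1 %*% L)
    g <- Gd[li$idx]
    g[li$diag] <- g[li$diag] * diag(L)
    g
  }
  grad <- c(chain((M1G + t(M1G)) / 2, vc$G),
            chain((M1P + t(M1P)) / 2, vc$P),
            s1 * vc$sigma_e2)
  list(value = value, grad = grad)
}

# ---- REML driver --------------------------------------------------------

#' Estimate covariance components by REML
#'
#' Maximizes the restricted likelihood of the random regression model over
#' the additive-genetic coefficient covariance `G`, the permanent
#' environment coefficient covariance `P` and the residual variance,
#' using L-BFGS-B on a log-Cholesky parameterization (all iterates stay
#' positive definite). Balanced recording designs use an exact spectral
#' decomposition of the phenotyped block of the relationship matrix; other
#' designs evaluate the same likelihood through the sparse mixed model
#' equations.
#'
#' @param data a [longitudinal_data()].
#' @param spec a [model_spec()].
#' @param ped a [pedigree()]; phenotyped individuals missing from it are
#'   added as unrelated founders with a warning. `NULL` treats all
#'   individuals as unrelated.
#' @param init optional starting [variance_components()].
#' @param domain a [time_domain()]; default spans the observed times.
#' @param solver `"mme"` additionally solves the mixed model equations at
#'   the REML estimates (giving BLUP solutions, residuals and reliabilities);
#'   `"none"` returns only components, likelihood and the scan engine.
#' @param control list of optimizer settings (`maxit`, `factr`).
#' @return An object of class `"rrm_fit"` carrying `vc`, `logL`, and (for
#'   `solver = "mme"`) BLUE/BLUP solutions and residuals.
#' @export
reml_fit <- function(data, spec, ped = NULL, init = NULL, domain = NULL,
                     solver = c("mme", "none"), control = list()) {
  solver <- match.arg(solver)
  stopifnot(inherits(data, "longitudinal_data"), inherits(spec, "model_spec"))
  if (is.null(domain)) domain <- time_domain_from_data(data$time)
  ids <- unique(data$id)
  if (is.null(ped)) {
    ped <- pedigree(ids, rep(NA, length(ids)), rep(NA, length(ids)))
  } else {
    miss <- setdiff(ids, ped$id)
    if (length(miss)) {
      warning("reml_fit: ", length(miss),
              " phenotyped individual(s) absent from pedigree; added as founders")
      ped <- pedigree(c(ped$id, miss),
                      c(ped$sire, rep(NA, length(miss))),
                      c(ped$dam, rep(NA, length(miss))))
    }
  }
  mi <- max(table(data$id))
  if (spec$nr1 + 1 > mi || spec$nr2 + 1 > mi) {
    stop("reml_fit: random regression orders exceed the maximum record count (",
         mi, ") per individual; model not identifiable")
  }

  ctrl <- utils::modifyList(list(maxit = 300L, factr = 1e7), control)
  A <- numerator_relationship_matrix(ped)
  s <- stats::sd(data$value)
  if (!is.finite(s) || s <= 0) stop("reml_fit: phenotype variance is zero")
  data_s <- data
  data_s$value <- data$value / s

  na <- spec$nr1 + 1L; np <- spec$nr2 + 1L
  m <- nrow(data)

  eng <- .make_rotated_engine(data_s, spec, domain, ped, A)
  design <- NULL; a_inv <- NULL
  if (is.null(eng)) {
    design <- build_design(data_s, spec, domain, ped)
    a_inv <- a_inverse(ped, A)
  }
  p_fix <- spec$nf + 1L + length(attr(data, "covariates"))

  if (!is.null(eng)) {
    # analytic value+gradient, memoized so optim's fn/gr pair costs one pass
    cache <- new.env(parent = emptyenv())
    fg <- function(th) {
      if (!is.null(cache$th) && identical(th, cache$th)) return(cache$res)
      res <- tryCatch({
        vc <- .theta_to_vc(th, na, np)
        r <- .engine_reml_fg(eng, vc)
        if (!is.finite(r$value) || !all(is.finite(r$grad))) stop("non-finite")
        r
      }, error = function(e) list(value = 1e10, grad = rep(0, length(th))))
      cache$th <- th; cache$res <- res
      res
    }
    obj <- function(th) fg(th)$value
    grd <- function(th) fg(th)$grad
  } else {
    grd <- NULL
    obj <- function(th) {
      vc <- tryCatch(.theta_to_vc(th, na, np), error = function(e) NULL)
      if (is.null(vc)) return(1e10)
      val <- tryCatch({
        fit <- solve_mme(design, vc, a_inv, a_logdet = attr(a_inv, "logdet_A"))
        -2 * fit$logL
      }, error = function(e) NA_real_)
      if (!is.finite(val)) 1e10 else val
    }
  }

  if (is.null(init)) {
    vc0 <- variance_components(diag(0.5 / na, na), diag(0.5 / np, np), 0.5)
  } else {
    vc0 <- variance_components(init$G / s^2, init$P / s^2, init$sigma_e2 / s^2)
  }
  th0 <- .vc_to_theta(vc0)
  opt <- stats::optim(th0, obj, gr = grd, method = "L-BFGS-B",
                      control = list(maxit = ctrl$maxit, factr = ctrl$factr))
  if (opt$convergence == 1L) {
    stop("reml_fit: REML did not converge within ", ctrl$maxit,
         " iterations (final -2logLR = ", format(opt$value), ")")
  }
  if (opt$value >= 1e10) stop("reml_fit: restricted likelihood not evaluable")

  vc_s <- .theta_to_vc(opt$par, na, np)
  vc_hat <- variance_components(vc_s$G * s^2, vc_s$P * s^2, vc_s$sigma_e2 * s^2)
  logL <- -0.5 * opt$value - (m - p_fix) * log(s)

  if (!is.null(eng)) {   # restore natural units for downstream scans
    eng$Y <- eng$Y * s
    eng$Ytil <- eng$Ytil * s
  }

  if (solver == "mme") {
    if (is.null(design)) {
      design <- build_design(data, spec, domain, ped)
      a_inv <- a_inverse(ped, A)
    } else {
      design$y <- data$value
    }
    fit <- solve_mme(design, vc_hat, a_inv, a_logdet = attr(a_inv, "logdet_A"))
  } else {
    fit <- structure(list(vc = vc_hat, spec = spec, domain = domain,
                          data_ids = ids, n_records = m),
                     class = "rrm_fit")
  }
  fit$vc <- vc_hat
  fit$logL <- logL
  fit$engine <- eng
  fit$ped <- ped
  fit$data <- data
  fit$reml <- list(convergence = opt$convergence, counts = opt$counts,
                   message = opt$message, neg2logLR = opt$value)
  fit
}

#' Information criteria of a REML fit
#'
#' `AIC = -2 logL + 2 k` and `BIC = -2 logL + k log(m)` with `k` the number
#' of free covariance parameters,
#' `k = (nr1+1)(nr1+2)/2 + (nr2+1)(nr2+2)/2 + 1`, and `m` the number of
#' records. Comparisons are meaningful between fits sharing the same fixed
#' mean structure (REML likelihoods are not comparable across different
#' fixed effects).
#'
#' @param fit an [reml_fit()] result (or any list with `logL`, `spec`,
#'   `n_records`).
#' @return Named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  k <- .n_vc_par(fit$spec)
  c(aic = -2 * fit$logL + 2 * k,
    bic = -2 * fit$logL + k * log(fit$n_records))
}

.n_vc_par <- function(spec) {
  (spec$nr1 + 1) * (spec$nr1 + 2) / 2 + (spec$nr2 + 1) * (spec$nr2 + 2) / 2 + 1
}

#' Select basis orders by information criterion
#'
#' Fits each candidate [model_spec()] by REML and returns the one with the
#' smallest BIC (AIC reported alongside); ties break toward fewer
#' covariance parameters. Candidates that fail to converge are skipped with
#' a warning.
#'
#' @param data a [longitudinal_data()].
#' @param ped a [pedigree()] or `NULL`.
#' @param grid list of [model_spec()] candidates.
#' @param domain optional [time_domain()].
#' @return The selected [model_spec()], with attribute `"criteria"` holding
#'   the per-candidate AIC/BIC table.
#' @export
select_orders <- function(data, ped, grid, domain = NULL) {
  stopifnot(length(grid) >= 1L)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    sp <- grid[[i]]
    res <- tryCatch(
      reml_fit(data, sp, ped, domain = domain, solver = "none"),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("select_orders: spec (", sp$nf, ",", sp$nr1, ",", sp$nr2,
              ") skipped: ", conditionMessage(res))
      rows[[i]] <- data.frame(nf = sp$nf, nr1 = sp$nr1, nr2 = sp$nr2,
                              k = .n_vc_par(sp), logL = NA, aic = NA, bic = NA)
    } else {
      ic <- information_criteria(res)
      rows[[i]] <- data.frame(nf = sp$nf, nr1 = sp$nr1, nr2 = sp$nr2,
                              k = .n_vc_par(sp), logL = res$logL,
                              aic = ic["aic"], bic = ic["bic"])
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (all(is.na(tab$bic))) stop("select_orders: no candidate converged")
  ord <- order(tab$bic, tab$k)
  best <- grid[[ord[1L]]]
  attr(best, "criteria") <- tab
  best
}
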