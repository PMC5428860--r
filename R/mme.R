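#' Build the design matrices of the random regression model
#'
#' Constructs the fixed-effect design `X` (population-mean Legendre
#' regression, plus any extra covariate columns carried by the data), the
#' additive-genetic design `Q` (one block of `nr1 + 1` columns per pedigree
#' individual) and the permanent-environment design `Z` (one block of
#' `nr2 + 1` columns per phenotyped individual).
#'
#' @param data a [longitudinal_data()].
#' @param spec a [model_spec()].
#' @param domain a [time_domain()] covering all recording times.
#' @param ped a [pedigree()] containing every phenotyped individual.
#' @return A list with elements `X` (dense), `Q`, `Z` (sparse), `y`,
#'   `ped_ids`, `phen_ids`, `spec`, `domain`.
#' @export
build_design <- function(data, spec, domain, ped) {
  stopifnot(inherits(data, "longitudinal_data"), inherits(spec, "model_spec"),
            inherits(domain, "time_domain"), inherits(ped, "pedigree"))
  m <- nrow(data)
  phen_ids <- unique(data$id)
  miss <- setdiff(phen_ids, ped$id)
  if (length(miss)) {
    stop("build_design: individuals absent from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  X <- legendre_matrix(spec$nf, data$time, domain)
  colnames(X) <- paste0("mu", 0:spec$nf)
  cov <- attr(data, "covariates")
  if (!is.null(cov)) {
    Xc <- as.matrix(data.frame(lapply(cov, as.numeric)))
    X <- cbind(X, Xc)
  }
  na <- spec$nr1 + 1L; np <- spec$nr2 + 1L
  Phi_a <- legendre_matrix(spec$nr1, data$time, domain)
  Phi_p <- legendre_matrix(spec$nr2, data$time, domain)
  ia <- match(data$id, ped$id)
  ip <- match(data$id, phen_ids)
  rows <- rep(seq_len(m), each = na)
  cols <- as.vector(t((ia - 1L) * na + matrix(seq_len(na), m, na, byrow = TRUE)))
  Q <- Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(t(Phi_a)),
                            dims = c(m, nrow(ped) * na))
  rows <- rep(seq_len(m), each = np)
  cols <- as.vector(t((ip - 1L) * np + matrix(seq_len(np), m, np, byrow = TRUE)))
  Z <- Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(t(Phi_p)),
                            dims = c(m, length(phen_ids) * np))
  list(X = X, Q = Q, Z = Z, y = data$value, ped_ids = ped$id,
       phen_ids = phen_ids, spec = spec, domain = domain)
}

#' Solve Henderson's mixed model equations
#'
#' Assembles and solves the sparse MME of the random regression model with
#' `var(a) = A (x) G`, `var(p) = I (x) P` and `var(e) = I sigma_e^2`,
#' returning BLUE/BLUP solutions, per-record residuals, the reduction in
#' sums of squares `R(model)` and the restricted log-likelihood (computed
#' from the sparse factorization by the determinant identity
#' `log|V| + log|X'V^-1 X| = log|R| + log|A (x) G| + log|I (x) P| + log|C|`).
#'
#' @param design output of [build_design()].
#' @param vc a [variance_components()] object.
#' @param a_inv sparse inverse relationship matrix from [a_inverse()]
#'   (pedigree order must match `design$ped_ids`).
#' @param extra optional extra fixed-effect columns (matrix with one row per
#'   record), e.g. SNP covariate regressions.
#' @param a_logdet `log|A|`; see [a_logdet()]. Required for the likelihood.
#' @return An object of class `"rrm_fit"`.
#' @export
solve_mme <- function(design, vc, a_inv, extra = NULL, a_logdet = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  X <- design$X
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == nrow(X))
    X <- cbind(X, extra)
  }
  y <- design$y
  Q <- design$Q; Z <- design$Z
  m <- length(y)
  se2 <- vc$sigma_e2
  na <- design$spec$nr1 + 1L; np <- design$spec$nr2 + 1L
  n_ped <- length(design$ped_ids); n_phen <- length(design$phen_ids)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("solve_mme: fixed-effect design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  Ginv <- solve(vc$G); Pinv <- solve(vc$P)
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  W <- cbind(Xs, Q, Z)
  C <- Matrix::crossprod(W) / se2
  ia <- ncol(X) + seq_len(n_ped * na)
  ip <- ncol(X) + n_ped * na + seq_len(n_phen * np)
  C[ia, ia] <- C[ia, ia] + Matrix::kronecker(a_inv, Ginv)
  C[ip, ip] <- C[ip, ip] + Matrix::kronecker(Matrix::Diagonal(n_phen), Pinv)
  rhs <- as.vector(Matrix::crossprod(W, y)) / se2

  C <- Matrix::forceSymmetric(C)
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                 error = function(e) {
                   stop("solve_mme: coefficient matrix not positive definite: ",
                        conditionMessage(e))
                 })
  sol <- as.vector(Matrix::solve(ch, rhs))

  nb <- ncol(X)
  b_hat <- sol[seq_len(nb)]; names(b_hat) <- colnames(X)
  a_hat <- matrix(sol[ia], nrow = n_ped, ncol = na, byrow = TRUE,
                  dimnames = list(design$ped_ids, NULL))
  p_hat <- matrix(sol[ip], nrow = n_phen, ncol = np, byrow = TRUE,
                  dimnames = list(design$phen_ids, NULL))
  fitted <- as.vector(X %*% b_hat + Q %*% sol[ia] + Z %*% sol[ip])
  resid <- y - fitted
  rss <- sum(sol * rhs) * se2       # R(model) = sol' [X'y; Q'y; Z'y]
  ypy <- (sum(y^2) - rss) / se2     # y' V^-1 (y - X b_hat)

  logL <- NA_real_
  if (!is.null(a_logdet)) {
    ldC <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus  # log|C|
    ldG <- na * a_logdet + n_ped * determinant(vc$G)$modulus +
      n_phen * determinant(vc$P)$modulus
    logL <- -0.5 * (m * log(se2) + as.numeric(ldG) + as.numeric(ldC) + ypy +
                      (m - nb) * log(2 * pi))
  }

  structure(list(b_hat = b_hat, a_hat = a_hat, p_hat = p_hat,
                 residuals = resid, fitted = fitted, rss = rss, ypy = ypy,
                 logL = logL, vc = vc, spec = design$spec,
                 domain = design$domain, data_ids = design$phen_ids,
                 n_records = m,
                 mme = list(C = C, chol = ch, a_offset = nb,
                            ped_ids = design$ped_ids,
                            a_diag = attr(a_inv, "a_diag"))),
            class = "rrm_fit")
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat(sprintf("<rrm_fit> orders nf=%d nr1=%d nr2=%d, %d records, logL = %.3f\n",
              x$spec$nf, x$spec$nr1, x$spec$nr2, x$n_records,
              if (is.null(x$logL)) NA else x$logL))
  cat("sigma_e2 =", format(x$vc$sigma_e2, digits = 5), "\n")
  invisible(x)
}
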