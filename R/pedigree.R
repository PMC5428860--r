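#' Pedigree objects
#'
#' A pedigree is a data frame of `(id, sire, dam)` triples, one row per
#' individual, with `0`/`NA`/empty for unknown parents. Construction
#' topologically sorts the records so parents precede offspring and checks
#' for duplicated ids and ancestry cycles.
#'
#' @param id,sire,dam vectors (character or integer-like) of individual and
#'   parent identifiers; `0`, `NA` or `""` mark unknown parents.
#' @return A data frame of class `"pedigree"` with character columns
#'   `id`, `sire`, `dam` (`NA` = unknown), sorted parents-first.
#' @export
pedigree <- function(id, sire, dam) {
  id   <- as.character(id)
  sire <- .norm_parent(sire)
  dam  <- .norm_parent(dam)
  if (anyNA(id) || any(id == "" | id == "0")) {
    stop("pedigree: individual ids must be non-missing and not '0'")
  }
  if (anyDuplicated(id)) {
    stop("pedigree: duplicated id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  n <- length(id)
  stopifnot(length(sire) == n, length(dam) == n)

  # add parents that never appear as individuals, as founders
  known <- c(sire, dam)
  known <- unique(known[!is.na(known)])
  extra <- setdiff(known, id)
  if (length(extra)) {
    id   <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam  <- c(dam, rep(NA_character_, length(extra)))
    n <- length(id)
  }

  ord <- .ped_toposort(id, sire, dam)
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

.norm_parent <- function(p) {
  p <- as.character(p)
  p[!is.na(p) & (p == "0" | p == "")] <- NA_character_
  p
}

# Kahn's algorithm; reports a cycle if one exists.
.ped_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), NA_integer_, idx[sire])
  di <- ifelse(is.na(dam),  NA_integer_, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree: ancestry cycle involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  ord
}

#' Read a pedigree file
#'
#' Expects a CSV or TSV file with a header naming columns `id`, `sire` and
#' `dam` (any order, case-insensitive); `0` or empty marks an unknown
#' parent. The delimiter is sniffed from the header line.
#'
#' @param path file path.
#' @return A [pedigree()] object, topologically sorted.
#' @export
read_pedigree <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("read_pedigree: file must have header columns id, sire, dam; got: ",
         paste(names(df), collapse = ", "))
  }
  pedigree(df$id, df$sire, df$dam)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix `A` by the tabular
#' recursion, accounting for inbreeding: `A_ii = 1 + 0.5 * A_sd`, and
#' `A_ij = 0.5 * (A_{j,s(i)} + A_{j,d(i)})` for `j` preceding `i`; unknown
#' parents contribute zero.
#'
#' @param ped a [pedigree()].
#' @return Dense symmetric matrix with dimnames equal to the pedigree ids
#'   (pedigree order). Diagonal is `1 + F_i`.
#' @export
numerator_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  NA_integer_, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(s)) rel <- rel + 0.5 * A[j, s]
      if (!is.na(d)) rel <- rel + 0.5 * A[j, d]
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

# Mendelian sampling variances d_i used by both a_inverse() and log|A|.
# d_i = 1 - 0.25 (A_ss + A_dd) with terms only for known parents
# (Quaas: parental inbreeding shrinks the sampling variance).
.mendelian_variances <- function(ped, A = NULL) {
  if (is.null(A)) A <- numerator_relationship_matrix(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  NA_integer_, idx[ped$dam])
  d <- rep(1, n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) d[i] <- d[i] - 0.25 * A[si[i], si[i]]
    if (!is.na(di[i])) d[i] <- d[i] - 0.25 * A[di[i], di[i]]
  }
  list(d = d, si = si, di = di)
}

#' Inverse of the numerator relationship matrix
#'
#' Builds `A^{-1}` directly from the pedigree by Henderson's rules with the
#' Quaas correction for inbreeding (Mendelian sampling variances taken from
#' the tabular `A`). The result is exact: `A %*% a_inverse(ped)` is the
#' identity up to numerical round-off.
#'
#' @param ped a [pedigree()].
#' @param A optionally, a precomputed [numerator_relationship_matrix()].
#' @return A sparse symmetric matrix (class `dsCMatrix`).
#' @export
a_inverse <- function(ped, A = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (is.null(A)) A <- numerator_relationship_matrix(ped)
  mv <- .mendelian_variances(ped, A)
  d <- mv$d; si <- mv$si; di <- mv$di
  if (any(d <= 0)) stop("a_inverse: non-positive Mendelian sampling variance")
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    w <- 1 / d[i]
    add(i, i, w)
    par <- c(si[i], di[i]); par <- par[!is.na(par)]
    for (p in par) {
      add(i, p, -0.5 * w); add(p, i, -0.5 * w)
    }
    if (length(par)) {
      for (p in par) for (q in par) add(p, q, 0.25 * w)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  M <- Matrix::forceSymmetric(M)
  # carried along for likelihood evaluation and reliabilities
  attr(M, "logdet_A") <- sum(log(d))
  attr(M, "a_diag") <- if (is.null(A)) NULL else diag(A)
  M
}

#' Log-determinant of A from the pedigree
#'
#' `log|A|` equals the sum of log Mendelian sampling variances; needed for
#' the restricted likelihood evaluated through the mixed model equations.
#'
#' @param ped a [pedigree()].
#' @param A optional precomputed relationship matrix.
#' @return Scalar `log(det(A))`.
#' @export
a_logdet <- function(ped, A = NULL) {
  sum(log(.mendelian_variances(ped, A)$d))
}

#' Reliabilities of accumulated EBVs
#'
#' Computes, for each requested individual, the reliability of its
#' accumulated EBV `Q_c' a_i` from the prediction error variance:
#' `r2_i = 1 - PEV_i / (A_ii * Q_c' G Q_c)` with
#' `PEV_i = Q_c' C^{aa}_i Q_c`, where `C^{aa}_i` is the individual's
#' diagonal block of the inverse mixed-model-equation coefficient matrix.
#' Values are clipped to `[0, 1)`.
#'
#' @param fit a fit returned by [reml_fit()] or [solve_mme()] (must carry the
#'   MME factorization).
#' @param ids individuals to report; default all pedigree individuals.
#' @return Named numeric vector of reliabilities in `[0, 1)`.
#' @export
reliabilities <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "rrm_fit"))
  if (is.null(fit$mme)) {
    stop("reliabilities: fit does not carry mixed-model-equation internals; ",
         "refit with solver = 'mme'")
  }
  m <- fit$mme
  ped_ids <- m$ped_ids
  if (is.null(ids)) ids <- ped_ids
  qc <- accumulation_vector(fit$spec$nr1, fit$domain)
  gvar <- drop(crossprod(qc, fit$vc$G %*% qc))
  if (gvar <= 0) {
    stop("reliabilities: non-positive genetic variance of the accumulated EBV")
  }
  na <- fit$spec$nr1 + 1L
  ii <- match(ids, ped_ids)
  if (anyNA(ii)) stop("reliabilities: unknown individual ",
                      ids[which(is.na(ii))[1]])
  out <- numeric(length(ids)); names(out) <- ids
  # PEV_i = Q_c' C^{aa}_i Q_c: one linear solve per individual against the
  # accumulated-EBV contrast, batched for speed
  chunk <- 500L
  for (start in seq(1L, length(ids), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(ids))
    E <- matrix(0, nrow(m$C), length(sel))
    for (j in seq_along(sel)) {
      cols <- m$a_offset + (ii[sel[j]] - 1L) * na + seq_len(na)
      E[cols, j] <- qc
    }
    sol <- as.matrix(Matrix::solve(m$chol, E))
    pev <- colSums(E * sol)
    out[sel] <- pmin(pmax(1 - pev / (m$a_diag[ii[sel]] * gvar), 0), 1 - 1e-12)
  }
  out
}
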