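# Multiple-testing thresholds and result tables.

#' Bonferroni genome-wide threshold
#'
#' @param alpha experiment-wise significance level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(n_tests), length(n_tests) == 1L, n_tests >= 1)
  alpha / n_tests
}

#' Storey q-values
#'
#' False-discovery-rate adjusted significance measures. The null
#' proportion pi0 is estimated by Storey's smoother over a lambda grid
#' (0.05..0.95); with fewer than 100 tests, or when the smoother is
#' unstable, pi0 = 1 is used, which reduces to Benjamini-Hochberg.
#'
#' @param pvals p-values in (0, 1].
#' @return Numeric vector of q-values (same order as input).
#' @export
qvalues <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) || any(pvals <= 0) ||
      any(pvals > 1)) {
    stop("qvalues: p-values must lie in (0, 1]")
  }
  n <- length(pvals)
  pi0 <- 1
  if (n >= 100L) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- tryCatch(stats::smooth.spline(lam, pi0_lam, df = 3),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      est <- stats::predict(fit, x = max(lam))$y
      if (is.finite(est) && est > 0) pi0 <- min(est, 1)
    }
  }
  pmin(pi0 * stats::p.adjust(pvals, method = "BH"), 1)
}

#' Significance report for a scan
#'
#' @param result a `scan_result` data frame (column `p` required).
#' @param alpha experiment-wise level (default 0.05).
#' @return The scan with added columns `bonferroni_threshold`,
#'   `bonferroni_sig`, `q`, `q_sig`.
#' @export
significance_report <- function(result, alpha = 0.05) {
  stopifnot("p" %in% names(result))
  tested <- if ("tested" %in% names(result)) result$tested else rep(TRUE, nrow(result))
  thr <- bonferroni_threshold(alpha, max(sum(tested), 1L))
  result$bonferroni_threshold <- thr
  result$bonferroni_sig <- result$p < thr & tested
  q <- rep(NA_real_, nrow(result))
  q[tested] <- qvalues(result$p[tested])
  result$q <- q
  result$q_sig <- !is.na(q) & q < alpha
  result
}

#' Write a scan result table
#'
#' Tab-separated with a `#`-prefixed provenance header (package version,
#' model, seed). Rows are sorted by `(chrom, pos)` when a map is attached,
#' otherwise kept in input order. Re-reading the file with
#' `read.table(..., comment.char = "#")` round-trips the values.
#'
#' @param results a `scan_result` (optionally from [significance_report()]).
#' @param path output file path.
#' @param seed seed to record in the header (optional).
#' @return The path, invisibly.
#' @export
write_scan_table <- function(results, path, seed = NULL) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("write_scan_table: empty results; no file written")
  }
  map <- attr(results, "map")
  out <- results
  if (!is.null(map) && all(c("chrom", "pos") %in% names(map))) {
    mi <- match(out$snp, map$snp)
    out$chrom <- map$chrom[mi]
    out$pos <- map$pos[mi]
    out <- out[order(out$chrom, out$pos), ]
  }
  hdr <- c(
    paste0("# longgwas ", as.character(utils::packageVersion("longgwas"))),
    paste0("# model: ", attr(results, "model") %||% "unknown"),
    if (!is.null(seed)) paste0("# seed: ", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
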