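#' Time domain for standardized basis functions
#'
#' A random regression model evaluates all time-varied terms on a common
#' standardized time axis. `time_domain()` records the earliest and latest
#' recording time and the integer grid `t_min..t_max` used for accumulation
#' sums (e.g. accumulated EBVs and cumulative SNP effects). Times `t` are
#' mapped to `x(t) = 2 (t - t_min) / (t_max - t_min) - 1`, so `t_min -> -1`
#' and `t_max -> +1`.
#'
#' @param t_min earliest recording time (e.g. days in milk).
#' @param t_max latest recording time; must exceed `t_min`.
#' @return An object of class `"time_domain"` with elements `t_min`, `t_max`
#'   and `grid` (integer time points `ceiling(t_min)..floor(t_max)`).
#' @examples
#' dom <- time_domain(5, 305)
#' standardize_time(c(5, 155, 305), dom)
#' @export
time_domain <- function(t_min, t_max) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), length(t_min) == 1L,
            length(t_max) == 1L, is.finite(t_min), is.finite(t_max))
  if (t_min >= t_max) {
    stop("time_domain: t_min (", t_min, ") must be strictly less than t_max (",
         t_max, ")")
  }
  grid <- seq(ceiling(t_min), floor(t_max), by = 1)
  structure(list(t_min = t_min, t_max = t_max, grid = grid),
            class = "time_domain")
}

#' @export
print.time_domain <- function(x, ...) {
  cat(sprintf("<time_domain> [%g, %g], accumulation grid of %d points\n",
              x$t_min, x$t_max, length(x$grid)))
  invisible(x)
}

#' Derive a time domain from observed recording times
#'
#' @param times numeric vector of recording times.
#' @return A [time_domain()] spanning the observed range.
#' @export
time_domain_from_data <- function(times) {
  times <- times[is.finite(times)]
  if (length(times) < 2L) stop("time_domain_from_data: need at least two finite times")
  time_domain(min(times), max(times))
}

#' Map recording times onto the standardized interval [-1, 1]
#'
#' @param times numeric vector of times.
#' @param domain a [time_domain()].
#' @return Numeric vector of the same length with values in `[-1, 1]`.
#' @export
standardize_time <- function(times, domain) {
  stopifnot(inherits(domain, "time_domain"), is.numeric(times))
  bad <- which(times < domain$t_min - 1e-9 | times > domain$t_max + 1e-9)
  if (length(bad)) {
    stop(sprintf(
      "standardize_time: time %g (record %d) outside domain [%g, %g]",
      times[bad[1]], bad[1], domain$t_min, domain$t_max))
  }
  2 * (times - domain$t_min) / (domain$t_max - domain$t_min) - 1
}

#' Normalized Legendre basis matrix
#'
#' Evaluates the normalized Legendre polynomials
#' `phi_k(x) = sqrt((2k + 1) / 2) * P_k(x)` (the Kirkpatrick convention
#' standard in random regression animal models) at the standardized times
#' `x(t)`, for `k = 0..order`. The normalization makes the basis orthonormal
#' on `[-1, 1]`; it rescales regression coefficients but leaves fitted
#' curves, Wald tests and cumulative effects unchanged.
#'
#' @param order highest polynomial degree (a term of order `q` has `q + 1`
#'   coefficients).
#' @param times numeric vector of recording times.
#' @param domain a [time_domain()] containing all `times`.
#' @return Numeric matrix with `length(times)` rows and `order + 1` columns;
#'   column `k + 1` holds `phi_k`.
#' @examples
#' dom <- time_domain(5, 305)
#' legendre_matrix(2, c(5, 155, 305), dom)
#' @export
legendre_matrix <- function(order, times, domain) {
  if (!is.numeric(order) || length(order) != 1L || order < 0 ||
      order != round(order)) {
    stop("legendre_matrix: 'order' must be a non-negative integer")
  }
  x <- standardize_time(times, domain)
  n <- length(x)
  P <- matrix(0, n, order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L) {
    # Bonnet recurrence (k+1) P_{k+1} = (2k+1) x P_k - k P_{k-1}
    for (k in 1L:(order - 1L)) {
      P[, k + 2L] <- ((2 * k + 1) * x * P[, k + 1L] - k * P[, k]) / (k + 1)
    }
  }
  norm <- sqrt((2 * (0:order) + 1) / 2)
  sweep(P, 2L, norm, `*`)
}

#' Accumulation vector over the integer time grid
#'
#' Returns `Q_c = sum_t Q_t`, the column sums of the basis matrix over the
#' integer grid of the domain. `crossprod(Q_c, coef)` is then the curve's
#' sum over the grid (accumulated EBV, cumulative SNP effect).
#'
#' @param order basis order.
#' @param domain a [time_domain()].
#' @return Numeric vector of length `order + 1`.
#' @export
accumulation_vector <- function(order, domain) {
  colSums(legendre_matrix(order, domain$grid, domain))
}
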