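#' Standard-normal bivariate rectangle probability
#'
#' `P(X <= h, Y <= k)` for standard bivariate normal with correlation `rho`,
#' computed through Plackett's identity: the derivative of the CDF in `rho`
#' is the bivariate normal density at `(h, k)`, so the CDF is the independent
#' product plus a one-dimensional integral over the correlation, evaluated by
#' adaptive quadrature (relative tolerance 1e-10).
#'
#' @param h,k upper limits (may be infinite).
#' @param rho correlation in (-1, 1).
#' @return probability.
#' @keywords internal
pbvnorm <- function(h, k, rho) {
  if (is.infinite(h) && h < 0) return(0)
  if (is.infinite(k) && k < 0) return(0)
  if (is.infinite(h)) return(stats::pnorm(k))
  if (is.infinite(k)) return(stats::pnorm(h))
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  f <- function(r)
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) / (2 * pi * sqrt(1 - r^2))
  base + stats::integrate(f, 0, rho, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Bivariate-normal cell probabilities for threshold vectors tau1, tau2.
bvn_cell_probs <- function(tau1, tau2, rho) {
  a <- c(-Inf, tau1, Inf)
  b <- c(-Inf, tau2, Inf)
  M <- outer(a, b, Vectorize(function(x, y) pbvnorm(x, y, rho)))
  P <- M[-1, -1, drop = FALSE] - M[-nrow(M), -1, drop = FALSE] -
       M[-1, -ncol(M), drop = FALSE] + M[-nrow(M), -ncol(M), drop = FALSE]
  pmax(P, 0)
}

#' Normal thresholds from marginal category proportions
#'
#' Inverse standard-normal quantiles of the cumulative category proportions:
#' `tau_c = qnorm(F(c))`, `c = 1..C-1`. Counts are accepted and normalised.
#'
#' @param p positive category proportions (or counts) over C categories.
#' @return strictly increasing threshold vector of length C - 1.
#' @export
#' @examples
#' thresholds_from_margins(c(0.5, 0.5))              # 0
#' thresholds_from_margins(rep(0.25, 4))             # standard normal quartiles
thresholds_from_margins <- function(p) {
  if (any(is.na(p)) || any(p <= 0))
    stop("zero-frequency category: collapse adjacent categories before estimating thresholds")
  p <- p / sum(p)
  stats::qnorm(cumsum(p)[-length(p)])
}

#' Polychoric correlation (two-step maximum likelihood)
#'
#' Latent correlation of two ordinal variables assumed to discretise a
#' bivariate normal. Thresholds are fixed at the marginal quantiles
#' ([thresholds_from_margins()]); the correlation maximises the multinomial
#' log likelihood with bivariate-normal cell probabilities over a bounded
#' search in (-0.999, 0.999) (scalar optimisation, tolerance 1e-8).
#'
#' @param crosstab C1 x C2 contingency table (matrix or `table`) with at
#'   least 10 observations; all-empty marginal categories are dropped.
#' @param zero_correction add 0.5 to empty cells before estimation
#'   (default FALSE).
#' @return object of class `polychoric`: list with `rho`, `tau1`, `tau2`,
#'   `loglik`, `converged` (FALSE when the optimum sits at the search bound,
#'   flagged with a warning), `n`.
#' @export
polychoric_rho <- function(crosstab, zero_correction = FALSE) {
  m <- as.matrix(crosstab)
  if (any(m < 0)) stop("counts must be non-negative")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least two non-empty categories on each margin")
  n <- sum(m)
  if (n < 10) stop("too few observations for polychoric estimation (n < 10)")
  if (zero_correction && any(m == 0)) m[m == 0] <- 0.5
  tau1 <- thresholds_from_margins(rowSums(m) / sum(m))
  tau2 <- thresholds_from_margins(colSums(m) / sum(m))
  ll <- function(rho) sum(m * log(pmax(bvn_cell_probs(tau1, tau2, rho), 1e-300)))
  opt <- stats::optimize(ll, c(-0.999, 0.999), maximum = TRUE, tol = 1e-8)
  rho <- opt$maximum
  at_bound <- abs(rho) > 0.998
  if (at_bound)
    warning(sprintf("polychoric correlation at the search bound (%.3f); estimate unreliable", rho))
  structure(list(rho = rho, tau1 = tau1, tau2 = tau2,
                 loglik = opt$objective, converged = !at_bound, n = n),
            class = "polychoric")
}

#' @export
print.polychoric <- function(x, ...) {
  cat(sprintf("Polychoric correlation: rho = %.4f (n = %d%s)\n", x$rho,
              as.integer(x$n), if (x$converged) "" else ", at bound"))
  invisible(x)
}

#' Cronbach-form alpha from a correlation matrix
#'
#' `alpha = (k/(k-1)) * (1 - k / sum(R))` for a `k x k` correlation matrix
#' with unit diagonal. With constant off-diagonal `r`, this reduces to
#' `k*r / (1 + (k-1)*r)`.
#'
#' @param R correlation matrix.
#' @return alpha (<= 1).
#' @export
alpha_from_corr <- function(R) {
  R <- as.matrix(R)
  k <- nrow(R)
  if (k < 2 || ncol(R) != k) stop("'R' must be a square matrix, k >= 2")
  k / (k - 1) * (1 - k / sum(R))
}

#' Ordinal alpha (internal consistency on polychoric correlations)
#'
#' Cronbach-type alpha computed from the pairwise polychoric correlation
#' matrix of a set of ordinal items. Unlike raw-score alpha this assumes
#' continuity only in the underlying construct, not in the observed
#' responses. Rows with any missing item are dropped (complete-case).
#'
#' @param items n x k matrix or data frame of ordinal responses, k >= 2.
#' @param zero_correction passed to [polychoric_rho()].
#' @return object of class `alpha_result`: list with `alpha`, `k`, `n`
#'   (complete cases used), `mean_offdiag` (mean inter-item polychoric
#'   correlation) and the matrix `R`.
#' @export
ordinal_alpha <- function(items, zero_correction = FALSE) {
  X <- as.matrix(items)
  k <- ncol(X)
  if (k < 2) stop("need at least two items")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 10) stop("too few complete cases for polychoric estimation")
  R <- diag(k)
  failures <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      est <- tryCatch(
        polychoric_rho(table(X[, i], X[, j]), zero_correction = zero_correction),
        error = function(e) e)
      if (inherits(est, "error")) {
        failures <- c(failures, sprintf("%d-%d (%s)", i, j, conditionMessage(est)))
      } else {
        R[i, j] <- R[j, i] <- est$rho
      }
    }
  }
  if (length(failures))
    stop("polychoric estimation failed for item pair(s): ",
         paste(failures, collapse = "; "))
  structure(list(alpha = alpha_from_corr(R), k = k, n = n,
                 mean_offdiag = mean(R[lower.tri(R)]), R = R),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("Ordinal alpha = %.3f (k = %d items, n = %d complete cases, mean inter-item rho = %.3f)\n",
              x$alpha, x$k, as.integer(x$n), x$mean_offdiag))
  invisible(x)
}
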