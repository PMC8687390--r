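#' @keywords internal
check_order <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= 0 || beta > 1) {
    stop("fractional order beta must lie in (0, 1]; got ", beta,
         call. = FALSE)
  }
  beta
}

#' Fractional Euler step coefficient
#'
#' The factor \eqn{h^\beta / \Gamma(\beta + 1)} multiplying the right-hand
#' side in the fractional Euler method.  At \eqn{\beta = 1} it reduces to the
#' classical Euler step `h`.
#'
#' @param h Step size, positive.
#' @param beta Fractional order in `(0, 1]`.
#' @return A scalar.
#' @examples
#' euler_coefficient(0.1, 1)    # 0.1
#' euler_coefficient(1, 0.5)    # 1 / gamma(1.5)
#' @export
euler_coefficient <- function(h, beta) {
  check_order(beta)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("step size h must be a positive scalar", call. = FALSE)
  }
  h^beta / gamma(beta + 1)
}

#' Midpoint predictor offset for the fractional modified Euler method
#'
#' The offset \eqn{\Gamma(\beta+1) h^\beta / \Gamma(2\beta+1)} at which the
#' predictor stage is evaluated.  At \eqn{\beta = 1} it reduces to the
#' classical midpoint offset `h/2`.
#'
#' @inheritParams euler_coefficient
#' @return A scalar.
#' @examples
#' midpoint_offset(0.1, 1)    # 0.05
#' @export
midpoint_offset <- function(h, beta) {
  check_order(beta)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("step size h must be a positive scalar", call. = FALSE)
  }
  gamma(beta + 1) * h^beta / gamma(2 * beta + 1)
}

#' Riemann-Liouville fractional integral
#'
#' Computes \eqn{J^\beta f(t) = \frac{1}{\Gamma(\beta)} \int_0^t
#' (t-\tau)^{\beta-1} f(\tau)\, d\tau} numerically.  `beta = 0` is the
#' identity operator, returning `f(t)`.  The weakly singular kernel is removed
#' exactly by the substitution \eqn{s = (t-\tau)^\beta}, after which
#' [stats::integrate()] handles a smooth integrand:
#' \eqn{J^\beta f(t) = \frac{1}{\Gamma(\beta+1)} \int_0^{t^\beta}
#' f(t - s^{1/\beta})\, ds}.
#'
#' Intended primarily as a high-accuracy verification oracle for the solvers.
#'
#' @param f Function of one variable, integrable on `[0, t]`.
#' @param beta Order, `0` or in `(0, 1]`.
#' @param t Upper limit, positive.
#' @param rel.tol Relative quadrature tolerance.
#' @return A scalar.
#' @examples
#' rl_integral(function(x) rep(1, length(x)), 1, 2)  # 2
#' @export
rl_integral <- function(f, beta, t, rel.tol = 1e-10) {
  stopifnot(is.function(f), is.numeric(t), length(t) == 1L, t > 0)
  if (identical(beta, 0) || identical(beta, 0L)) return(f(t))
  check_order(beta)
  integrand <- function(s) {
    vapply(s, function(si) f(t - si^(1 / beta)), numeric(1))
  }
  q <- stats::integrate(integrand, 0, t^beta, rel.tol = rel.tol,
                        abs.tol = 1e-12, stop.on.error = FALSE)
  if (q$message != "OK") {
    stop("Riemann-Liouville quadrature failed at rel.tol = ", rel.tol,
         ": ", q$message, call. = FALSE)
  }
  q$value / gamma(beta + 1)
}

#' Caputo fractional derivative
#'
#' Computes \eqn{{}^C D^\beta f(t) = \frac{1}{\Gamma(1-\beta)} \int_0^t
#' (t-\tau)^{-\beta} f'(\tau)\, d\tau} for \eqn{0 < \beta < 1}; at
#' \eqn{\beta = 1} it is the ordinary derivative \eqn{f'(t)}.  Only orders in
#' `(0, 1]` are supported.  The endpoint singularity is removed exactly by
#' the substitution \eqn{s = (t-\tau)^{1-\beta}}, yielding
#' \eqn{\frac{1}{\Gamma(2-\beta)} \int_0^{t^{1-\beta}}
#' f'(t - s^{1/(1-\beta)})\, ds}.
#'
#' Constants differentiate to zero and classical initial conditions apply,
#' which is why this operator (rather than Riemann-Liouville differentiation)
#' underlies the solvers in this package.
#'
#' @param f Smooth function of one variable.
#' @param beta Fractional order in `(0, 1]`.
#' @param t Evaluation point, positive.
#' @param deriv Optional analytic first derivative of `f`; when `NULL`,
#'   a central-difference derivative ([pracma::fderiv()]) is used, which
#'   requires `f` to be evaluable in a small neighbourhood of `[0, t]`.
#' @param rel.tol Relative quadrature tolerance.
#' @return A scalar.
#' @examples
#' caputo_derivative(function(x) x, 0.5, 1)  # 1/gamma(1.5)
#' @export
caputo_derivative <- function(f, beta, t, deriv = NULL, rel.tol = 1e-10) {
  check_order(beta)
  stopifnot(is.function(f), is.numeric(t), length(t) == 1L, t > 0)
  fp <- if (is.null(deriv)) {
    function(x) pracma::fderiv(f, x, n = 1, method = "central")
  } else {
    stopifnot(is.function(deriv))
    deriv
  }
  if (beta == 1) return(fp(t))
  p <- 1 - beta
  integrand <- function(s) {
    vapply(s, function(si) fp(t - si^(1 / p)), numeric(1))
  }
  q <- stats::integrate(integrand, 0, t^p, rel.tol = rel.tol,
                        abs.tol = 1e-12, stop.on.error = FALSE)
  if (q$message != "OK") {
    stop("Caputo quadrature failed at rel.tol = ", rel.tol, ": ", q$message,
         call. = FALSE)
  }
  q$value / gamma(2 - beta)
}

#' Generalised Taylor partial sum
#'
#' Evaluates \eqn{\sum_{n=0}^{j} \frac{t^{n\beta}}{\Gamma(n\beta+1)} c_n}
#' where \eqn{c_n} are the iterated Caputo derivatives of a function at
#' \eqn{0^+}.  The (existential, non-computable) remainder term is dropped.
#' At \eqn{\beta = 1} this is the classical Taylor partial sum.  The
#' truncation at \eqn{j = 1} is the local model underlying the fractional
#' Euler method.
#'
#' @param coeffs Numeric vector of length `j + 1`: the derivative values
#'   \eqn{c_0, \ldots, c_j}.
#' @param beta Fractional order in `(0, 1]`.
#' @param t Evaluation point, `>= 0`.
#' @param j Truncation order; defaults to `length(coeffs) - 1`.
#' @return A scalar.
#' @examples
#' generalized_taylor(c(1, 2), 0.5, 0.1)  # 1 + 2 * 0.1^0.5 / gamma(1.5)
#' @export
generalized_taylor <- function(coeffs, beta, t, j = length(coeffs) - 1L) {
  check_order(beta)
  stopifnot(is.numeric(coeffs), is.numeric(t), length(t) == 1L, t >= 0)
  if (length(coeffs) != j + 1L) {
    stop("coeffs must have length j + 1 = ", j + 1L, "; got ",
         length(coeffs), call. = FALSE)
  }
  n <- seq.int(0L, j)
  sum(t^(n * beta) * coeffs / gamma(n * beta + 1))
}

#' Mittag-Leffler function (one-parameter)
#'
#' Evaluates \eqn{E_\beta(z) = \sum_{n \ge 0} z^n / \Gamma(n\beta + 1)} by
#' its power series with lgamma-scaled terms.  \eqn{E_1(z) = e^z}.  Adequate
#' for the moderate arguments used as solver references
#' (\eqn{E_\beta(-t^\beta)} solves \eqn{{}^C D^\beta u = -u}, \eqn{u(0)=1});
#' not a scaled algorithm for large `|z|`.
#'
#' @param z Numeric vector of arguments.
#' @param beta Order, positive.
#' @param tol Series truncation tolerance (relative).
#' @param max_terms Hard cap on the number of series terms.
#' @return Numeric vector, same length as `z`.
#' @examples
#' mittag_leffler(-1, 1)  # exp(-1)
#' @export
mittag_leffler <- function(z, beta, tol = 1e-15, max_terms = 500L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  vapply(z, function(zi) {
    if (zi == 0) return(1)
    total <- 1
    lz <- log(abs(zi))
    sgn <- if (zi < 0) -1 else 1
    settled <- 0L
    for (n in seq_len(max_terms)) {
      term <- sgn^n * exp(n * lz - lgamma(n * beta + 1))
      total <- total + term
      if (abs(term) < tol * max(abs(total), 1)) {
        settled <- settled + 1L
        if (settled >= 3L) return(total)
      } else settled <- 0L
    }
    warning("Mittag-Leffler series did not settle in ", max_terms,
            " terms; returning partial sum")
    total
  }, numeric(1))
}
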