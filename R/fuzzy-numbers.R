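#' Triangular fuzzy number
#'
#' Constructs a triangular fuzzy number \eqn{(m, n, o)}: a convex, normalised
#' fuzzy subset of the real line whose membership rises linearly from the left
#' support endpoint \eqn{m} to 1 at the core \eqn{n} and falls linearly to the
#' right endpoint \eqn{o}.  Degenerate shapes (\eqn{m = n}, \eqn{n = o}, or a
#' fully crisp \eqn{m = n = o}) are allowed; their membership is defined by
#' limits, so a crisp initial condition is the zero-width special case.
#'
#' @param m Left support endpoint.
#' @param n Core (the unique point of membership 1).
#' @param o Right support endpoint.  Requires `m <= n <= o`.
#' @return An object of class `c("triangular_fuzzy", "fuzzy_number")`.
#' @seealso [exponential_fuzzy()], [membership()], [rcut()], [validate_fuzzy()]
#' @examples
#' u0 <- triangular_fuzzy(1.2, 1.3, 1.4)
#' membership(u0, c(1.25, 1.3, 1.35))
#' rcut(u0, c(0, 0.5, 1))
#' @export
triangular_fuzzy <- function(m, n, o) {
  stopifnot(is.numeric(m), is.numeric(n), is.numeric(o),
            length(m) == 1L, length(n) == 1L, length(o) == 1L,
            is.finite(m), is.finite(n), is.finite(o))
  if (!(m <= n && n <= o)) {
    stop("triangular fuzzy number requires m <= n <= o, got (",
         m, ", ", n, ", ", o, ")", call. = FALSE)
  }
  structure(list(m = m, n = n, o = o),
            class = c("triangular_fuzzy", "fuzzy_number"))
}

#' Exponential fuzzy number
#'
#' Constructs an exponential fuzzy number \eqn{(m, n, o)} whose membership
#' decays as \eqn{\exp(-(n-x)/(n-m))} left of the core and
#' \eqn{\exp(-(x-n)/(o-n))} right of it, truncated to zero outside the support
#' \eqn{[m, o]}.  The ordering must be strict so that both decay scales
#' \eqn{n-m} and \eqn{o-n} are positive; at the support endpoints the
#' membership equals \eqn{e^{-1}}.
#'
#' @inheritParams triangular_fuzzy
#' @return An object of class `c("exponential_fuzzy", "fuzzy_number")`.
#' @examples
#' v0 <- exponential_fuzzy(0.5, 0.6, 0.7)
#' membership(v0, 0.5)  # exp(-1)
#' @export
exponential_fuzzy <- function(m, n, o) {
  stopifnot(is.numeric(m), is.numeric(n), is.numeric(o),
            length(m) == 1L, length(n) == 1L, length(o) == 1L,
            is.finite(m), is.finite(n), is.finite(o))
  if (!(m < n && n < o)) {
    stop("exponential fuzzy number requires strict ordering m < n < o, got (",
         m, ", ", n, ", ", o, ")", call. = FALSE)
  }
  structure(list(m = m, n = n, o = o),
            class = c("exponential_fuzzy", "fuzzy_number"))
}

#' @export
print.fuzzy_number <- function(x, ...) {
  shape <- if (inherits(x, "triangular_fuzzy")) "triangular" else "exponential"
  cat(sprintf("<%s fuzzy number> (m = %g, n = %g, o = %g)\n",
              shape, x$m, x$n, x$o))
  invisible(x)
}

#' Membership grade of a fuzzy number
#'
#' Evaluates the membership function at the points `x` (vectorised).
#'
#' @param fn A fuzzy number.
#' @param x Numeric vector of evaluation points.
#' @param ... Passed to methods.
#' @return Numeric vector of grades in `[0, 1]`.
#' @export
membership <- function(fn, x, ...) UseMethod("membership")

#' @rdname membership
#' @export
membership.triangular_fuzzy <- function(fn, x, ...) {
  m <- fn$m; n <- fn$n; o <- fn$o
  out <- numeric(length(x))
  if (m == n && n == o) {            # crisp: indicator of {n}
    out[x == n] <- 1
    return(out)
  }
  left <- x >= m & x <= n
  if (m < n) {
    out[left] <- (x[left] - m) / (n - m)
  } else {
    out[x == n] <- 1                 # collapsed left branch
  }
  right <- x >= n & x <= o
  if (n < o) {
    out[right] <- (o - x[right]) / (o - n)
  }
  out[x == n] <- 1
  out
}

#' @rdname membership
#' @export
membership.exponential_fuzzy <- function(fn, x, ...) {
  m <- fn$m; n <- fn$n; o <- fn$o
  out <- numeric(length(x))
  left <- x >= m & x <= n
  out[left] <- exp(-(n - x[left]) / (n - m))
  right <- x > n & x <= o
  out[right] <- exp(-(x[right] - n) / (o - n))
  out
}

#' r-cut interval of a fuzzy number
#'
#' Returns the grade-indexed closed interval(s) of a fuzzy number in
#' parametric form.  For a triangular number \eqn{(m,n,o)} the cut at grade
#' \eqn{r \in [0,1]} is \eqn{[(n-m)r + m,\; o - (o-n)r]}; for an exponential
#' number, valid for \eqn{r \in (0,1]}, it is
#' \eqn{[n + (n-m)\log r,\; n - (o-n)\log r]} (natural logarithm, the only
#' base under which the cut at \eqn{r = e^{-1}} recovers the support).
#'
#' Exponential cuts below \eqn{e^{-1}} exceed the membership support
#' \eqn{[m,o]}; they are computed as the formula dictates but flagged with a
#' classed warning (`ffde_support_warning`) so callers can choose an r-grid
#' floor.
#'
#' @param fn A fuzzy number.
#' @param r Numeric vector of membership grades.
#' @param ... Passed to methods.
#' @return A data frame with columns `grade`, `lower`, `upper`, one row per
#'   grade, of class `c("rcut", "data.frame")`.
#' @examples
#' rcut(triangular_fuzzy(1.2, 1.3, 1.4), 0)        # the support [1.2, 1.4]
#' rcut(exponential_fuzzy(0.5, 0.6, 0.7), exp(-1)) # also the support
#' @export
rcut <- function(fn, r, ...) UseMethod("rcut")

new_rcut <- function(grade, lower, upper) {
  structure(data.frame(grade = grade, lower = lower, upper = upper),
            class = c("rcut", "data.frame"))
}

#' @rdname rcut
#' @export
rcut.triangular_fuzzy <- function(fn, r, ...) {
  if (any(r < 0 | r > 1)) {
    stop("triangular r-cut requires grades in [0, 1]", call. = FALSE)
  }
  new_rcut(r, (fn$n - fn$m) * r + fn$m, fn$o - (fn$o - fn$n) * r)
}

#' @rdname rcut
#' @export
rcut.exponential_fuzzy <- function(fn, r, ...) {
  if (any(r <= 0 | r > 1)) {
    stop("exponential r-cut requires grades in (0, 1]: log(r) must be finite",
         call. = FALSE)
  }
  if (any(r < exp(-1))) {
    warning(warningCondition(
      paste0("exponential r-cut below exp(-1) ~ 0.3679: interval exceeds ",
             "the membership support [m, o]"),
      class = "ffde_support_warning"))
  }
  new_rcut(r, fn$n + (fn$n - fn$m) * log(r), fn$n - (fn$o - fn$n) * log(r))
}

#' Diagnostic validation of a fuzzy-number triple
#'
#' Checks the defining properties of a fuzzy number for an arbitrary
#' `(m, n, o)` triple without constructing it: ordering, normality (a point of
#' membership 1 exists), convexity (membership unimodal — non-decreasing then
#' non-increasing on a test grid) and compact support.  Diagnostics only:
#' nothing is rejected.
#'
#' @param points Numeric triple `c(m, n, o)`.
#' @param shape `"triangular"` or `"exponential"`.
#' @param grid_n Number of test-grid points for the convexity scan.
#' @return A list of class `"fuzzy_validation"` with logical fields
#'   `ordering`, `normality`, `convexity`, `compact_support`, `degenerate`,
#'   and `valid` (all properties pass).
#' @examples
#' validate_fuzzy(c(1.2, 1.3, 1.4))       # all pass
#' validate_fuzzy(c(1.4, 1.3, 1.2))       # ordering violation
#' validate_fuzzy(c(0, 0, 0))             # crisp, passes with zero width
#' @export
validate_fuzzy <- function(points, shape = c("triangular", "exponential"),
                           grid_n = 201L) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(points), length(points) == 3L)
  m <- points[1]; n <- points[2]; o <- points[3]
  strict <- shape == "exponential"
  ordering <- if (strict) (m < n && n < o) else (m <= n && n <= o)

  normality <- FALSE
  convexity <- FALSE
  compact_support <- all(is.finite(points))
  degenerate <- m == o

  if (ordering) {
    fn <- if (shape == "triangular") triangular_fuzzy(m, n, o)
          else exponential_fuzzy(m, n, o)
    pad <- max(o - m, 1) * 0.1
    grid <- sort(unique(c(seq(m - pad, o + pad, length.out = grid_n), m, n, o)))
    mu <- membership(fn, grid)
    normality <- any(abs(mu - 1) < 1e-12)
    # unimodal: non-decreasing up to the peak, non-increasing after
    peak <- which.max(mu)
    eps <- 1e-12
    convexity <- all(diff(mu[seq_len(peak)]) >= -eps) &&
      all(diff(mu[peak:length(mu)]) <= eps)
  }

  structure(list(points = points, shape = shape, ordering = ordering,
                 normality = normality, convexity = convexity,
                 compact_support = compact_support, degenerate = degenerate,
                 valid = ordering && normality && convexity && compact_support),
            class = "fuzzy_validation")
}

#' @export
print.fuzzy_validation <- function(x, ...) {
  cat(sprintf("Fuzzy-number validation (%s) for (%g, %g, %g)\n",
              x$shape, x$points[1], x$points[2], x$points[3]))
  flag <- function(ok) if (ok) "pass" else "FAIL"
  cat("  ordering:        ", flag(x$ordering), "\n")
  cat("  normality:       ", flag(x$normality), "\n")
  cat("  convexity:       ", flag(x$convexity), "\n")
  cat("  compact support: ", flag(x$compact_support), "\n")
  if (x$degenerate) cat("  (degenerate: zero-width, crisp number)\n")
  invisible(x)
}
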